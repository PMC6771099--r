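pipeline_stage <- function(name, expr, quiet = FALSE) {
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (!quiet) message(sprintf("[%s] done", name))
  res
}

#' Run the full patient-flow analysis pipeline
#'
#' Executes, in order: read admissions and units, validate, build the OD
#' matrix, apply the origin flow filter, delineate the functional region,
#' compute the hierarchical sufficiency table, run the successive
#' enlargement for each micro-region and for the designated region, build
#' the cross-border flow network and its hub-excluded counterpart,
#' compute catchment quartiles for every destination and displacement
#' statistics for the top hub, and write everything to `output_dir`. The
#' run is deterministic: re-running with the same inputs and
#' configuration reproduces the outputs byte for byte.
#'
#' On error the stage name is reported and any files already written in
#' this run are removed.
#'
#' @param admissions_path,units_path Input CSV paths.
#' @param output_dir Directory for the report bundle (created if needed).
#' @param config A [study_config()].
#' @param quiet Suppress stage messages.
#'
#' @return A `report_bundle` list: file paths of all outputs plus the key
#'   in-memory results (`od`, `sufficiency`, `functional_region`,
#'   `cross_border`, `enlargements`, `hubs`, `displacement`) and run
#'   metadata.
#' @export
run_pipeline <- function(admissions_path, units_path, output_dir,
                         config = study_config(), quiet = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  out <- function(name) {
    p <- file.path(output_dir, name)
    written <<- c(written, p)
    p
  }
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    records <- pipeline_stage("read", {
      list(records = read_admissions(admissions_path, config, quiet = TRUE),
           units = read_units(units_path))
    }, quiet)
    units <- records$units
    valid <- pipeline_stage("validate", {
      v <- validate_dataset(records$records, units, mode = "strict", quiet = TRUE)
      write_validation_report(v$report, out("validation.json"))
      v
    }, quiet)
    od_raw <- pipeline_stage("od_build", build_od_matrix(valid$records, units), quiet)
    hset <- hospital_units(od_raw)
    od <- pipeline_stage("origin_filter", {
      f <- apply_origin_filter(od_raw, hset, config$min_sent_patients)
      write_od_matrix(f, out("od_long.csv"))
      written <<- c(written, file.path(output_dir, "od_long.csv.json"))
      f
    }, quiet)

    designated <- units$unit_id[nzchar(units$designated_region)]
    designated_hosp <- intersect(designated, hset)
    functional <- pipeline_stage("functional_region", {
      fr <- delineate_functional_region(od_raw, designated_hosp,
                                        config$min_sent_patients,
                                        designated_units = designated)
      writeLines(fr, out("functional_region.txt"))
      fr
    }, quiet)

    suff <- pipeline_stage("sufficiency", {
      s <- sufficiency_table(od, units, config$sufficiency_threshold)
      write_sufficiency_table(s, out("sufficiency_table.csv"))
      s
    }, quiet)

    enlargements <- pipeline_stage("frech_enlargement", {
      seeds <- list()
      micro <- units$micro_region[match(designated, units$unit_id)]
      for (m in sort(unique(micro[nzchar(micro)]))) {
        seeds[[m]] <- designated[micro == m]
      }
      if (length(designated) > 0L) seeds[["designated_region"]] <- designated
      res <- lapply(names(seeds), function(nm) {
        e <- frech_enlarge(od, seeds[[nm]], config$sufficiency_threshold)
        write_enlargement_trace(e, out(paste0("enlargement_", nm, ".json")))
        e
      })
      names(res) <- names(seeds)
      res
    }, quiet)

    network <- pipeline_stage("network", {
      g <- build_flow_graph(od)
      write_flow_graph(g, out("network_edges.csv"),
                       graphml = out("network.graphml"),
                       nodes_csv = out("network_nodes.csv"))
      hubs <- identify_hubs(g, k = 5L)
      if (length(hubs) > 0L) {
        g2 <- remove_node_subnetwork(g, hubs[1L])
        write_flow_graph(g2, out("network_edges_nohub.csv"))
        written <<- c(written, file.path(output_dir, "network_edges_nohub.csv"))
      }
      list(graph = g, hubs = hubs)
    }, quiet)

    cb <- pipeline_stage("cross_border", {
      scope <- if (length(designated) > 0L) designated else od$unit_ids
      s <- cross_border_summary(od, scope)
      jsonlite::write_json(s, out("cross_border.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      s
    }, quiet)

    catchdisp <- pipeline_stage("catchment", {
      dests <- hospital_units(od)
      catch <- lapply(dests, function(dd) catchment_quartiles(od, dd))
      names(catch) <- dests
      all_rows <- do.call(rbind, lapply(catch, function(cc) {
        cbind(destination = attr(cc, "destination"), as.data.frame(cc))
      }))
      write.csv(all_rows, out("catchments.csv"), row.names = FALSE, quote = FALSE)
      disp <- NULL
      if (length(network$hubs) > 0L) {
        write_catchment(catch[[network$hubs[1L]]], units,
                        geojson = out("catchment_hub.geojson"))
        disp <- displacement_stats(od, units, network$hubs[1L],
                                   config$earth_radius_km)
        jsonlite::write_json(disp, out("displacement.json"), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
      }
      list(catchments = catch, displacement = disp)
    }, quiet)

    meta <- pipeline_stage("metadata", {
      m <- list(config = unclass(config),
                admissions_path = normalizePath(admissions_path),
                units_path = normalizePath(units_path),
                n_records = nrow(valid$records),
                od_total = sum(od$counts),
                package_version = as.character(utils::packageVersion("regionflow")),
                r_version = R.version.string)
      jsonlite::write_json(m, out("run_metadata.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      m
    }, quiet)

    structure(list(
      output_dir = output_dir,
      files = written,
      od = od,
      functional_region = functional,
      sufficiency = suff,
      enlargements = enlargements,
      graph = network$graph,
      hubs = network$hubs,
      cross_border = cb,
      catchments = catchdisp$catchments,
      displacement = catchdisp$displacement,
      metadata = meta
    ), class = "report_bundle")
  }, error = on_fail)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Patient-flow report bundle:", x$output_dir, "\n")
  cat(sprintf("  %d patients, %d cross-border (%.1f%%)\n",
              x$cross_border$total, x$cross_border$cross_border,
              x$cross_border$proportion_pct))
  cat("  functional region:", length(x$functional_region), "units\n")
  cat("  top hub:", if (length(x$hubs)) x$hubs[1] else "(none)", "\n")
  cat("  files:", length(x$files), "\n")
  invisible(x)
}

#' Human-readable summary of a report bundle
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of report lines, invisibly; printed unless
#'   `quiet`.
#' @param quiet Do not print.
#' @export
report_summary <- function(bundle, quiet = FALSE) {
  s <- bundle$sufficiency
  lines <- c(
    sprintf("Hospitalizations (designated-region residents): %d", bundle$cross_border$total),
    sprintf("Cross-border admissions: %d (%.1f%%)",
            bundle$cross_border$cross_border, bundle$cross_border$proportion_pct),
    sprintf("Functional region size: %d units", length(bundle$functional_region)),
    sprintf("Top attraction hub: %s",
            if (length(bundle$hubs)) bundle$hubs[1] else "(none)"),
    "Sufficiency:",
    sprintf("  %-20s %-13s LIFO %3.0f%%  LOFI %3.0f%%  %s",
            s$subject, s$level, s$lifo_pct, s$lofi_pct, s$label)
  )
  if (!quiet) writeLines(lines)
  invisible(lines)
}
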