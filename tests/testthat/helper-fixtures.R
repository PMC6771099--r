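# toy3: closed three-unit system A, B, C with flows
#   A->A 66, A->B 34, B->B 50, C->B 10, C->C 40   (200 records)
toy3_units_path <- function() {
  system.file("extdata", "toy3_units.csv", package = "regionflow")
}
toy3_admissions_path <- function() {
  system.file("extdata", "toy3_admissions.csv", package = "regionflow")
}
toy3_units <- function() read_units(toy3_units_path())
toy3_records <- function() {
  read_admissions(toy3_admissions_path(), study_config(year_filter = 2012),
                  quiet = TRUE)
}
toy3_od <- function() build_od_matrix(toy3_records(), toy3_units())

# random small dataset for oracle-equivalence checks
random_dataset <- function(n_units = 5L, n_records = 200L) {
  ids <- LETTERS[seq_len(n_units)]
  units <- data.frame(
    unit_id = ids, name = ids,
    lat = runif(n_units, -22, -20), lon = runif(n_units, -49, -47),
    population = sample(1000:20000, n_units, replace = TRUE),
    beds = sample(0:100, n_units, replace = TRUE),
    designated_region = "D1",
    micro_region = sample(c("M1", "M2"), n_units, replace = TRUE),
    stringsAsFactors = FALSE
  )
  records <- data.frame(
    residence_unit = sample(ids, n_records, replace = TRUE),
    hospital_unit = sample(ids, n_records, replace = TRUE,
                           prob = seq_len(n_units)),
    diagnosis_group = "XV", year = 2012L,
    stringsAsFactors = FALSE
  )
  list(units = units, records = records)
}
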