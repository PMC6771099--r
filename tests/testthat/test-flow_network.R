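test_that("build_flow_graph keeps cross-border edges and stores self-flows", {
  g <- build_flow_graph(toy3_od())
  edges <- igraph::as_data_frame(g, what = "edges")
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$weight[edges$from == "A" & edges$to == "B"], 34)
  expect_equal(edges$weight[edges$from == "C" & edges$to == "B"], 10)
  expect_equal(sum(edges$weight), 44)  # = cross-border count

  v <- igraph::as_data_frame(g, what = "vertices")
  expect_equal(v$self_flow[match(c("A", "B", "C"), v$name)], c(66, 50, 40))
  expect_equal(v$resident_total[v$name == "A"], 100)
  expect_equal(v$hospitalized_total[v$name == "B"], 94)

  dm <- diag(c(9L, 9L))
  dimnames(dm) <- list(c("A", "B"), c("A", "B"))
  g0 <- build_flow_graph(od_matrix(dm))
  expect_equal(igraph::ecount(g0), 0L)
  expect_equal(igraph::vcount(g0), 2L)
})

test_that("node strengths sum incident weights and balance globally", {
  g <- build_flow_graph(toy3_od())
  s <- node_strengths(g)
  expect_equal(s$in_strength[s$unit_id == "B"], 44)
  expect_equal(s$out_strength[s$unit_id == "B"], 0)
  expect_equal(s$in_strength[s$unit_id == "A"], 0)
  expect_equal(sum(s$in_strength), sum(s$out_strength))
  expect_equal(sum(s$in_strength), 44)
})

test_that("strengths equal the record-iteration oracle on random data", {
  set.seed(404)
  for (rep in 1:25) {
    d <- random_dataset(n_units = sample(3:8, 1), n_records = sample(50:400, 1))
    g <- build_flow_graph(build_od_matrix(d$records, d$units))
    s <- node_strengths(g)
    for (u in d$units$unit_id) {
      o <- oracle_strengths(d$records, u)
      expect_equal(s$in_strength[s$unit_id == u], unname(o["in_strength"]))
      expect_equal(s$out_strength[s$unit_id == u], unname(o["out_strength"]))
    }
  }
})

test_that("identify_hubs ranks by in-strength with lexicographic ties", {
  g <- build_flow_graph(toy3_od())
  expect_equal(identify_hubs(g, 1), "B")
  expect_equal(identify_hubs(g, 10), c("B", "A", "C"))  # truncated, ties A<C

  dm <- diag(c(1L, 1L, 1L))
  dimnames(dm) <- list(c("C", "A", "B"), c("C", "A", "B"))
  g0 <- build_flow_graph(od_matrix(dm))
  expect_equal(identify_hubs(g0, 3), c("A", "B", "C"))  # all tie at zero
})

test_that("removing a node removes its incident flows and nothing else", {
  g <- build_flow_graph(toy3_od())
  s <- node_strengths(g)
  g2 <- remove_node_subnetwork(g, "B")
  expect_setequal(igraph::V(g2)$name, c("A", "C"))
  expect_equal(igraph::ecount(g2), 0L)
  lost <- s$in_strength[s$unit_id == "B"] + s$out_strength[s$unit_id == "B"]
  expect_equal(sum(igraph::E(g)$weight) - sum(igraph::E(g2)$weight), lost)
  expect_error(remove_node_subnetwork(g, "Z"), "unknown unit")

  # removing an isolated node leaves the edge set alone
  ids <- c("A", "B", "I")
  m <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  m["A", "B"] <- 3L
  gi <- remove_node_subnetwork(build_flow_graph(od_matrix(m)), "I")
  expect_equal(igraph::ecount(gi), 1L)
})

test_that("weak components ignore direction and sort by size", {
  g <- build_flow_graph(toy3_od())
  expect_equal(weak_components(g), list(c("A", "B", "C")))

  comp <- weak_components(remove_node_subnetwork(g, "B"))
  expect_equal(comp, list("A", "C"))

  # star: one component regardless of direction
  ids <- c("H", "X", "Y", "Z")
  m <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  m[c("X", "Y"), "H"] <- 5L; m["H", "Z"] <- 2L
  expect_length(weak_components(build_flow_graph(od_matrix(m))), 1L)

  # removing a connected node never reduces the component count
  set.seed(505)
  d <- random_dataset(6, 120)
  g6 <- build_flow_graph(build_od_matrix(d$records, d$units))
  n0 <- length(weak_components(g6))
  for (u in d$units$unit_id) {
    if (igraph::degree(g6, u) == 0) next
    expect_gte(length(weak_components(remove_node_subnetwork(g6, u))), n0)
  }
})

test_that("two distant hospital towns under short decay split into two components", {
  sc <- synthetic_scenario(n_units = 8, n_designated = 8, n_micro_regions = 1,
                           decay_scale_km = 5, hub_preference = 1,
                           local_preference = 1, seed = 9)
  units <- data.frame(
    unit_id = sprintf("U%02d", 1:8), name = sprintf("U%02d", 1:8),
    lat = c(-21, -21.05, -21.1, -21.02, -20.0, -20.05, -20.1, -20.02),
    lon = c(-47.8, -47.85, -47.9, -47.82, -47.0, -47.05, -47.1, -47.02),
    population = rep(20000, 8),
    beds = c(100, 0, 0, 0, 100, 0, 0, 0),
    designated_region = "D1", micro_region = "M1")
  rec <- generate_admissions(sc, units)
  g <- build_flow_graph(build_od_matrix(rec, units))
  comp <- weak_components(g)
  multi <- comp[lengths(comp) > 1]
  expect_length(multi, 2L)
  expect_setequal(unlist(multi), units$unit_id)
})

test_that("origin entropy measures destination dispersal", {
  od <- toy3_od()
  h <- origin_entropy(od)
  expect_equal(unname(h["B"]), 0)  # single destination
  expect_equal(unname(h["A"]),
               -(0.66 * log(0.66) + 0.34 * log(0.34)) / log(2))
  expect_equal(unname(h["A"]), 0.9248, tolerance = 1e-4)

  # uniform flows are maximum entropy for any number of destinations
  for (m_dest in c(2L, 4L)) {
    ids <- c("O", paste0("D", seq_len(m_dest)))
    mm <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    mm["O", -1] <- 7L
    h1 <- origin_entropy(od_matrix(mm))
    expect_equal(unname(h1["O"]), 1)
  }

  # excluding self-flows re-normalizes over the remaining destinations
  h_ns <- origin_entropy(od, include_self = FALSE)
  expect_equal(unname(h_ns["A"]), 0)  # only B remains
  expect_true(is.na(h_ns["B"]))       # B never leaves: no flows at all

  # normalized entropy stays in [0, 1]; splitting one destination into two
  # raises the unnormalized entropy
  set.seed(606)
  d <- random_dataset(7, 300)
  hn <- origin_entropy(build_od_matrix(d$records, d$units))
  expect_true(all(hn[!is.na(hn)] >= 0 & hn[!is.na(hn)] <= 1))

  ids <- c("O", "D1", "D2")
  one <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  two <- one
  one["O", "D1"] <- 10L
  two["O", "D1"] <- 5L; two["O", "D2"] <- 5L
  expect_gt(origin_entropy(od_matrix(two), normalize = FALSE)["O"],
            origin_entropy(od_matrix(one), normalize = FALSE)["O"])
})

test_that("flow graphs export to edge CSV, GraphML and node metrics", {
  g <- build_flow_graph(toy3_od())
  edges_csv <- withr::local_tempfile(fileext = ".csv")
  graphml <- withr::local_tempfile(fileext = ".graphml")
  nodes_csv <- withr::local_tempfile(fileext = ".csv")
  write_flow_graph(g, edges_csv, graphml = graphml, nodes_csv = nodes_csv)
  el <- read.csv(edges_csv)
  expect_equal(names(el), c("origin", "destination", "weight"))
  expect_equal(sum(el$weight), 44)
  expect_true(file.size(graphml) > 0)
  nm <- read.csv(nodes_csv)
  expect_equal(nm$self_flow[nm$unit_id == "A"], 66)
})
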