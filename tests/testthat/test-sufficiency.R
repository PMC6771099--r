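test_that("lifo_lofi reproduces the service-exporter and dependent patterns", {
  od <- toy3_od()

  # A: no inflow, 66 of 100 residents treated locally
  a <- lifo_lofi(od, "A")
  expect_equal(unname(a["lifo"]), 100)
  expect_equal(unname(a["lofi"]), 66)

  # B: 94 hospitalized (50 local + 34 + 10 imported), no resident leaves
  b <- lifo_lofi(od, "B")
  expect_equal(unname(b["lifo"]), (1 - 44 / 94) * 100, tolerance = 1e-12)
  expect_equal(unname(b["lifo"]), 53.19, tolerance = 1e-3)
  expect_equal(unname(b["lofi"]), 100)

  # the whole closed system is trivially self-contained
  all3 <- lifo_lofi(od, c("A", "B", "C"))
  expect_identical(unname(all3), c(100, 100))

  expect_error(lifo_lofi(od, character()), "empty subject")
  expect_error(lifo_lofi(od, "Z"), "unknown")
})

test_that("coefficients of a set aggregate flows before the ratio", {
  od <- toy3_od()
  ab <- lifo_lofi(od, c("A", "B"))
  # inside hospitalizations 160, inflow only C->B 10
  expect_equal(unname(ab["lifo"]), (1 - 10 / 160) * 100)
  expect_equal(unname(ab["lofi"]), 100)
  # not the mean of the member coefficients
  expect_false(isTRUE(all.equal(unname(ab["lifo"]),
                                mean(c(100, (1 - 44 / 94) * 100)))))
})

test_that("undefined coefficients arise from zero activity, not zero flows", {
  ids <- c("A", "N")
  m <- matrix(c(10L, 0L, 0L, 0L), 2, 2, byrow = TRUE, dimnames = list(ids, ids))
  od <- od_matrix(m)
  n <- lifo_lofi(od, "N")
  expect_true(is.na(n["lifo"]))
  expect_true(is.na(n["lofi"]))
  expect_equal(classify_sufficiency(n["lifo"], n["lofi"]), "Undefined")
})

test_that("classification uses strict unrounded comparison against the threshold", {
  expect_equal(classify_sufficiency(78, 96), "Sufficient")
  expect_equal(classify_sufficiency(71, 100), "Insufficient")
  expect_equal(classify_sufficiency(100, 66), "Insufficient")
  # exactly at the threshold fails; just above passes even if it prints as 75%
  expect_equal(classify_sufficiency(87, 75), "Insufficient")
  expect_equal(classify_sufficiency(87, 75.4), "Sufficient")
  expect_equal(classify_sufficiency(75.0001, 75.0001), "Sufficient")
})

test_that("sufficiency_table builds the municipal / micro-region / region hierarchy", {
  od <- toy3_od()
  tab <- sufficiency_table(od, toy3_units())
  expect_equal(sum(tab$level == "municipality"), 3L)
  expect_equal(sum(tab$level == "micro_region"), 2L)
  expect_equal(sum(tab$level == "region"), 1L)

  reg <- tab[tab$level == "region", ]
  expect_equal(reg$lifo_pct, 100)
  expect_equal(reg$lofi_pct, 100)
  expect_equal(reg$label, "Sufficient")
  expect_equal(reg$n_units, 3L)

  a <- tab[tab$subject == "A", ]
  expect_equal(a$label, "Insufficient")
  expect_equal(a$lofi_rounded, 66)

  # a unit with beds but no admissions is excluded from municipal rows
  units4 <- rbind(toy3_units(),
                  data.frame(unit_id = "D", name = "Delta", lat = -21.1,
                             lon = -47.7, population = 2000, beds = 10,
                             designated_region = "D1", micro_region = "M2"))
  rec <- toy3_records()
  od4 <- build_od_matrix(rec, units4)
  tab4 <- sufficiency_table(od4, units4)
  expect_false("D" %in% tab4$subject[tab4$level == "municipality"])
})

test_that("lifo_lofi equals the direct record-count oracle on random data", {
  set.seed(202)
  for (rep in 1:50) {
    d <- random_dataset(n_units = sample(3:10, 1), n_records = sample(20:500, 1))
    od <- build_od_matrix(d$records, d$units)
    subject <- sample(d$units$unit_id, sample(seq_len(nrow(d$units) - 1), 1))
    expect_identical(lifo_lofi(od, subject), oracle_lifo_lofi(d$records, subject))
  }
})

test_that("inflow/outflow and local treatment satisfy the integer identities", {
  set.seed(303)
  d <- random_dataset(n_units = 6, n_records = 400)
  od <- build_od_matrix(d$records, d$units)
  for (u in d$units$unit_id) {
    local <- od$counts[u, u]
    inflow <- sum(od$counts[, u]) - local
    outflow <- sum(od$counts[u, ]) - local
    expect_identical(inflow + local, sum(od$counts[, u]))
    expect_identical(outflow + local, sum(od$counts[u, ]))
  }
})

test_that("frech_enlarge reproduces the hand-derived toy trace", {
  od <- toy3_od()
  res <- frech_enlarge(od, "A")
  expect_equal(res$final_set, c("A", "B"))
  expect_equal(res$label, "Sufficient")
  expect_equal(nrow(res$trace), 2L)
  expect_true(is.na(res$trace$added[1]))
  expect_equal(res$trace$added[2], "B")
  expect_equal(res$trace$lifo_pct[2], 93.75)
  expect_equal(res$trace$lofi_pct[2], 100)
  expect_equal(res$trace$label, c("Insufficient", "Sufficient"))
})

test_that("frech_enlarge stops immediately on an already sufficient seed", {
  od <- toy3_od()
  res <- frech_enlarge(od, c("A", "B", "C"))
  expect_equal(res$final_set, c("A", "B", "C"))
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$label, "Sufficient")
})

test_that("frech_enlarge halts without positive exchange and bounds its steps", {
  # two disconnected blocks: enlargement from the dependent one cannot
  # reach sufficiency and must stop when no candidate exchanges patients
  ids <- c("A", "B", "X")
  m <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  m["A", "A"] <- 2L; m["A", "B"] <- 8L; m["B", "B"] <- 5L; m["X", "X"] <- 9L
  res <- frech_enlarge(od_matrix(m), "A")
  expect_equal(res$final_set, c("A", "B"))
  expect_equal(res$label, "Sufficient")

  # a chain that is never sufficient absorbs everything and terminates
  m2 <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  m2["A", "B"] <- 10L; m2["B", "X"] <- 10L; m2["X", "A"] <- 10L
  res2 <- frech_enlarge(od_matrix(m2), "A")
  expect_lte(nrow(res2$trace), 3L)
  expect_true(all(c("A") %in% res2$final_set))
  expect_equal(res2$final_set, sort(union("A", res2$trace$added[-1])))
})

test_that("enlargement candidates rank by exchanged flow with lexicographic ties", {
  ids <- c("A", "P", "Q")
  m <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  m["A", "P"] <- 5L; m["A", "Q"] <- 5L; m["A", "A"] <- 1L
  m["P", "P"] <- 100L; m["Q", "Q"] <- 100L
  res <- frech_enlarge(od_matrix(m), "A")
  expect_equal(res$trace$added[2], "P")  # tie 5 vs 5 -> lexicographic
})

test_that("enlargement traces serialize to JSON", {
  res <- frech_enlarge(toy3_od(), "A")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_enlargement_trace(res, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$final_set, c("A", "B"))
  expect_equal(back$trace$added[2], "B")
})
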