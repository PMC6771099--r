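# independent oracles: direct iteration over raw records, no matrix algebra

oracle_lifo_lofi <- function(records, subject) {
  in_subj_h <- records$hospital_unit %in% subject
  in_subj_r <- records$residence_unit %in% subject
  H <- sum(in_subj_h)
  inflow <- sum(in_subj_h & !in_subj_r)
  R <- sum(in_subj_r)
  outflow <- sum(in_subj_r & !in_subj_h)
  c(lifo = if (H > 0) (1 - inflow / H) * 100 else NA_real_,
    lofi = if (R > 0) (1 - outflow / R) * 100 else NA_real_)
}

oracle_cross_border <- function(records, scope) {
  rows <- records[records$residence_unit %in% scope, , drop = FALSE]
  c(total = nrow(rows),
    cross_border = sum(rows$residence_unit != rows$hospital_unit))
}

oracle_strengths <- function(records, unit) {
  moved <- records$residence_unit != records$hospital_unit
  c(in_strength = sum(moved & records$hospital_unit == unit),
    out_strength = sum(moved & records$residence_unit == unit))
}
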