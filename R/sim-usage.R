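#' Simulate per-3'UTR CS usage tables at the count level
#'
#' Directly generates multi-CS 3'UTR usage tables (the input of
#' [apa_test()]) by multinomial sampling, bypassing read simulation: the
#' fast route for statistical calibration at hundreds of UTRs. Each UTR has
#' two CSs with a baseline proximal usage drawn uniformly from
#' `base_pui_range`; a fraction `frac_shifted` of UTRs gets a planted
#' proximal-usage change of magnitude `delta_pui` in the treated condition
#' (sign random per UTR).
#'
#' @param n_utrs number of multi-CS 3'UTRs.
#' @param reads_per_condition total reads per UTR per condition.
#' @param frac_shifted fraction of UTRs with a planted usage shift.
#' @param delta_pui magnitude of the planted proximal-usage change.
#' @param base_pui_range range of the baseline proximal usage.
#' @param seed integer seed.
#' @return list with `tables` (as from [build_utr_tables()]) and
#'   `shifted` (character vector of UTR ids with a planted shift).
#' @export
simulate_usage_tables <- function(n_utrs = 500L, reads_per_condition = 200L,
                                  frac_shifted = 0, delta_pui = 0.3,
                                  base_pui_range = c(0.35, 0.65),
                                  seed = 1L) {
  set.seed(seed)
  ids <- sprintf("utr%04d", seq_len(n_utrs))
  shifted <- sort(sample(ids, round(frac_shifted * n_utrs)))
  p0 <- stats::runif(n_utrs, base_pui_range[1], base_pui_range[2])
  sgn <- sample(c(-1, 1), n_utrs, replace = TRUE)
  p1 <- p0 + ifelse(ids %in% shifted, sgn * delta_pui, 0)
  p1 <- pmin(pmax(p1, 0.02), 0.98)
  tables <- lapply(seq_len(n_utrs), function(i) {
    ctl <- stats::rmultinom(1, reads_per_condition, c(p0[i], 1 - p0[i]))
    trt <- stats::rmultinom(1, reads_per_condition, c(p1[i], 1 - p1[i]))
    counts <- cbind(control_1 = ctl[, 1], treated_1 = trt[, 1])
    list(gene_id = ids[i], positions = c(100L, 300L), strand = "+",
         counts = counts,
         conditions = c(control_1 = "control", treated_1 = "treated"))
  })
  names(tables) <- ids
  list(tables = tables, shifted = shifted)
}
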