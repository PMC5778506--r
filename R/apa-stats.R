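# Differential cleavage-site usage statistics: per-3'UTR chi-square tests
# of CS x condition contingency tables with BH-FDR control, the Proximal
# Usage Index (PUI), direction-of-shift classification, and the global
# 3'UTR shortening/lengthening trend assessment.

#' Build per-3'UTR usage tables
#'
#' Collects, for every gene with at least two called CSs in the admitted
#' genomic categories, the CS x sample count matrix with CSs ordered
#' proximal (closest to the stop codon, 5'-most in transcript orientation)
#' to distal. Genes with fewer than two qualifying CSs are excluded —
#' differential usage is only defined for multi-CS 3'UTRs.
#'
#' @param sites data.frame from [call_cleavage_sites()] (`gene_id`, `pos`,
#'   `strand`, `category`).
#' @param counts site x sample count matrix, rows parallel to `sites`.
#' @param condition_map named character vector mapping sample -> condition;
#'   every column of `counts` must be present.
#' @param categories genomic categories admitted into tables (default
#'   `"3UTR"`; add `"downstream_extension"` to include distal novel sites).
#' @return named list of usage tables; each is a list with `gene_id`,
#'   `positions` (proximal first), `counts` (CS x sample matrix) and
#'   `conditions` (per-sample labels).
#' @export
build_utr_tables <- function(sites, counts, condition_map,
                             categories = "3UTR") {
  stopifnot(nrow(sites) == nrow(counts))
  miss <- setdiff(colnames(counts), names(condition_map))
  if (length(miss))
    stop("sample(s) without condition label: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- sites$category %in% categories
  sites <- sites[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  out <- list()
  for (g in unique(sites$gene_id)) {
    idx <- which(sites$gene_id == g)
    if (length(idx) < 2L) next
    strand <- sites$strand[idx[1]]
    ord <- order(if (strand == "+") sites$pos[idx] else -sites$pos[idx])
    idx <- idx[ord]
    out[[g]] <- list(gene_id = g, positions = sites$pos[idx],
                     strand = strand,
                     counts = counts[idx, , drop = FALSE],
                     conditions = condition_map[colnames(counts)])
  }
  out
}

#' Chi-square test of differential CS usage
#'
#' Pools replicate samples within each condition into a CS x 2 contingency
#' table and applies Pearson's chi-square test of independence (no
#' continuity correction), df = (number of CSs with nonzero pooled counts)
#' minus 1. Tables with any expected count below 5 are flagged, not
#' substituted.
#'
#' @param table a usage table from [build_utr_tables()].
#' @param condition_a,condition_b the two condition labels to compare
#'   (a = control/reference, b = treated).
#' @return list with `chi2`, `df`, `p` and `low_expected` (logical flag).
#' @export
chisq_apa_test <- function(table, condition_a, condition_b) {
  m <- .pool_conditions(table, condition_a, condition_b)
  if (any(colSums(m) == 0))
    stop("condition with zero total counts in gene ", table$gene_id,
         call. = FALSE)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2L)
    return(list(chi2 = 0, df = 0L, p = 1, low_expected = TRUE))
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), low_expected = any(ht$expected < 5))
}

.pool_conditions <- function(table, condition_a, condition_b) {
  conds <- table$conditions
  a <- rowSums(table$counts[, conds == condition_a, drop = FALSE])
  b <- rowSums(table$counts[, conds == condition_b, drop = FALSE])
  cbind(a = a, b = b)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard BH step-up q-values (monotone). Thin, validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NaN` is an error.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.nan(p))) stop("NaN p-value", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]",
                                             call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Proximal Usage Index
#'
#' Relative usage of a 3'UTR's most proximal CS: reads at the proximal CS
#' divided by total reads over all the UTR's CSs, for one sample or pooled
#' over one condition. Undefined (NA) when the total is zero.
#'
#' @param table a usage table from [build_utr_tables()].
#' @param sample a sample name, or
#' @param condition a condition label (pools its samples).
#' @return PUI in `[0, 1]`, or `NA` for a zero total.
#' @export
compute_pui <- function(table, sample = NULL, condition = NULL) {
  if (is.null(sample) == is.null(condition))
    stop("give exactly one of 'sample' or 'condition'", call. = FALSE)
  cnt <- if (!is.null(sample)) table$counts[, sample]
         else rowSums(table$counts[, table$conditions == condition, drop = FALSE])
  tot <- sum(cnt)
  if (tot == 0) return(NA_real_)
  unname(cnt[1] / tot)
}

#' Classify the direction of a CS-usage shift
#'
#' `delta_pui` is the treated-minus-control difference of condition-pooled
#' PUIs; positive means enhanced proximal usage (3'UTR shortening). An
#' exact zero is classified `"none"` and excluded from direction counts.
#'
#' @param table a usage table from [build_utr_tables()].
#' @param condition_a control condition; @param condition_b treated.
#' @return list with `direction` (`"proximal_enhanced"`,
#'   `"proximal_reduced"` or `"none"`) and `delta_pui`.
#' @export
classify_shift <- function(table, condition_a, condition_b) {
  pui_a <- compute_pui(table, condition = condition_a)
  pui_b <- compute_pui(table, condition = condition_b)
  if (is.na(pui_a) || is.na(pui_b))
    stop("undefined PUI (zero counts) in gene ", table$gene_id, call. = FALSE)
  d <- pui_b - pui_a
  list(direction = if (d > 0) "proximal_enhanced"
                   else if (d < 0) "proximal_reduced" else "none",
       delta_pui = d)
}

#' Test all 3'UTR usage tables for differential CS usage
#'
#' Runs [chisq_apa_test()] on every table, adjusts p-values with
#' [bh_fdr()] and attaches condition-pooled PUIs and the direction call.
#'
#' @param tables list from [build_utr_tables()].
#' @param condition_a control condition; @param condition_b treated.
#' @return data.frame with one row per 3'UTR: `gene_id`, `n_cs`, `chi2`,
#'   `df`, `p`, `q`, `pui_a`, `pui_b`, `delta_pui`, `direction`,
#'   `low_expected`.
#' @export
apa_test <- function(tables, condition_a, condition_b) {
  rows <- lapply(tables, function(tb) {
    ht <- chisq_apa_test(tb, condition_a, condition_b)
    sh <- classify_shift(tb, condition_a, condition_b)
    data.frame(gene_id = tb$gene_id, n_cs = nrow(tb$counts),
               chi2 = ht$chi2, df = ht$df, p = ht$p,
               pui_a = compute_pui(tb, condition = condition_a),
               pui_b = compute_pui(tb, condition = condition_b),
               delta_pui = sh$delta_pui, direction = sh$direction,
               low_expected = ht$low_expected, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- bh_fdr(res$p)
  res[, c("gene_id", "n_cs", "chi2", "df", "p", "q", "pui_a", "pui_b",
          "delta_pui", "direction", "low_expected")]
}

#' Global 3'UTR shortening/lengthening trend assessment
#'
#' Among 3'UTRs with a significant usage shift (`q < fdr`) and a defined
#' direction, tests the proximal-enhanced vs proximal-reduced split against
#' the 50/50 ratio expected by chance (two-sided exact binomial test).
#' Additionally compares the paired per-UTR PUI distributions (treated vs
#' control) over ALL multi-CS 3'UTRs with a two-sided Wilcoxon signed-rank
#' test — a global effect on proximal CS usage would shift this
#' distribution even below the per-UTR significance threshold.
#'
#' @param results data.frame from [apa_test()].
#' @param fdr FDR threshold selecting significant 3'UTRs (default 0.05).
#' @return list with `n_significant`, `n_enhanced`, `n_reduced`,
#'   `fraction_proximal_enhanced`, `binomial_p_vs_half` and
#'   `paired_pui_test_p`.
#' @export
global_trend_test <- function(results, fdr = 0.05) {
  if (nrow(results) == 0L) stop("empty results", call. = FALSE)
  sig <- results[results$q < fdr & results$direction != "none", , drop = FALSE]
  n_enh <- sum(sig$direction == "proximal_enhanced")
  n_red <- sum(sig$direction == "proximal_reduced")
  binom_p <- if (n_enh + n_red > 0)
    stats::binom.test(n_enh, n_enh + n_red, p = 0.5)$p.value else NA_real_
  wil_p <- if (any(results$delta_pui != 0))
    suppressWarnings(stats::wilcox.test(results$pui_b, results$pui_a,
                                        paired = TRUE))$p.value
    else 1
  list(n_significant = sum(results$q < fdr),
       n_enhanced = n_enh, n_reduced = n_red,
       fraction_proximal_enhanced =
         if (n_enh + n_red > 0) n_enh / (n_enh + n_red) else NA_real_,
       binomial_p_vs_half = binom_p, paired_pui_test_p = wil_p)
}
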