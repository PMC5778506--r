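# Auxiliary omics computations: RNA-seq expression fold-change (RPKM,
# quantile normalization, a 1.0 expression floor against fold-change
# inflation in lowly expressed genes) and the IP-MS interactor-selection
# filter (>2-fold in at least two of three replicates) with edge-list
# export.

#' RPKM normalization
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `count / (length_kb * libsize_millions)`.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths gene lengths in nt (recycled along rows); must be > 0.
#' @param library_sizes per-sample library sizes in reads; default column
#'   sums of `counts`; must be > 0.
#' @return matrix of RPKM values, same dimensions as `counts`.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    stop("'gene_lengths' must have one value per gene", call. = FALSE)
  if (length(library_sizes) != ncol(counts))
    stop("'library_sizes' must have one value per sample", call. = FALSE)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  counts / (gene_lengths / 1e3) / rep(library_sizes / 1e6, each = nrow(counts))
}

#' Quantile normalization
#'
#' Forces every column to the identical value distribution (the row-wise
#' mean of the column-sorted values), with tied ranks receiving the mean of
#' the reference values at those ranks. Delegates to
#' [limma::normalizeQuantiles()]. Idempotent; a single-column matrix is
#' returned unchanged.
#'
#' @param m numeric matrix (genes x samples), no missing values.
#' @return quantile-normalized matrix, dimnames preserved.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("missing/non-finite values not allowed",
                               call. = FALSE)
  if (ncol(m) < 2L) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2 expression fold-change with an expression floor
#'
#' Both expression vectors are floored at `floor` (default 1.0) before
#' computing `log2(b / a)`, preventing inflated fold-changes for lowly
#' expressed genes.
#'
#' @param expr_a,expr_b matched per-gene expression values (a = control,
#'   b = treated).
#' @param floor expression floor (default 1.0).
#' @return per-gene log2 fold-changes.
#' @export
log2_fold_change <- function(expr_a, expr_b, floor = 1.0) {
  if (length(expr_a) != length(expr_b))
    stop("gene sets must match", call. = FALSE)
  log2(pmax(expr_b, floor) / pmax(expr_a, floor))
}

#' Select IP-MS interactors by replicate-consistent fold-change
#'
#' A protein is selected as an interactor when its log2 intensity in the
#' reference pulldown exceeds the control by more than `log2(min_fold)`
#' (strictly, by default) in at least `min_reps` of the replicates. A
#' missing intensity in either matrix counts as a failing replicate.
#'
#' @param log2_ref protein x replicate log2-intensity matrix, reference
#'   pulldown (rownames = protein ids).
#' @param log2_ctl matching matrix for the control; identical proteins and
#'   replicate count required.
#' @param min_fold fold-change threshold (default 2).
#' @param min_reps minimum passing replicates (default 2).
#' @param strict use strict `>` on the log2 difference (default TRUE).
#' @return data.frame: `protein_id`, per-replicate `diff_*` columns,
#'   `n_replicates_passing`, `selected`.
#' @export
call_interactors <- function(log2_ref, log2_ctl, min_fold = 2,
                             min_reps = 2L, strict = TRUE) {
  log2_ref <- as.matrix(log2_ref); log2_ctl <- as.matrix(log2_ctl)
  if (!identical(dim(log2_ref), dim(log2_ctl)) ||
      !identical(rownames(log2_ref), rownames(log2_ctl)))
    stop("mismatched protein sets or replicate counts", call. = FALSE)
  d <- log2_ref - log2_ctl
  thr <- log2(min_fold)
  pass <- if (strict) d > thr else d >= thr
  pass[is.na(pass)] <- FALSE
  n_pass <- rowSums(pass)
  out <- data.frame(protein_id = rownames(log2_ref), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(d))) out[[paste0("diff_", j)]] <- d[, j]
  out$n_replicates_passing <- as.integer(n_pass)
  out$selected <- n_pass >= min_reps
  rownames(out) <- NULL
  out
}

#' Classify interactors of two pulldowns and export an edge list
#'
#' Combines the phospho-specific and total pulldown interactor sets:
#' proteins selected only in the phospho pulldown are `phospho_only`,
#' proteins selected in both are `phospho_and_total` (the red/blue node
#' distinction of a bait-interactor network).
#'
#' @param phospho,total data.frames from [call_interactors()].
#' @param bait name of the bait protein (edge source, default "pPABPN1").
#' @return data.frame with `source`, `target`, `class` — one edge per
#'   phospho-pulldown interactor.
#' @export
interactor_edges <- function(phospho, total, bait = "pPABPN1") {
  sel_p <- phospho$protein_id[phospho$selected]
  sel_t <- total$protein_id[total$selected]
  cls <- ifelse(sel_p %in% sel_t, "phospho_and_total", "phospho_only")
  data.frame(source = rep(bait, length(sel_p)), target = sel_p,
             class = cls, stringsAsFactors = FALSE)
}
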