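#' Configuration for the synthetic 3'-Seq data generator
#'
#' Builds and validates the parameter set that drives
#' [simulate_transcriptome()] and [simulate_reads()]. The defaults describe
#' the generative structure the downstream analysis assumes: each gene has a
#' single-exon transcript (5'UTR, CDS, 3'UTR), one to three cleavage sites
#' (CS) planted inside the 3'UTR, a polyadenylation-signal hexamer ending
#' `pas_offset` nt upstream of each CS, per-read cleavage jitter around the
#' major site, untemplated poly(A) tails appended to genuine reads, and
#' (optionally) internal-priming artifact reads ending in *templated*
#' genomic A-tracts.
#'
#' @param n_genes number of genes to simulate.
#' @param utr_len 3'UTR length in nt; a single value or a `c(min, max)` range
#'   sampled uniformly per gene.
#' @param n_cs_per_utr number of CSs planted per 3'UTR (1, 2 or 3).
#' @param cs_spacing_true distance (nt) between consecutive planted CSs.
#' @param pas_offset distance (nt) from the PAS hexamer 3' end to the
#'   cleavage position, in transcript orientation. Default 20, the canonical
#'   placement of AATAAA upstream of the CS.
#' @param pas_motif hexamer planted upstream of each CS (DNA sense).
#' @param cs_jitter_sd standard deviation (nt) of the discretized normal
#'   per-read cleavage scatter around the major site, truncated to +/-10 nt.
#' @param tail_len_range `c(min, max)` untemplated tail length in nt.
#' @param read_len read length in nt.
#' @param seq_error_rate per-base substitution error probability.
#' @param internal_priming_rate number of internal-priming artifact reads
#'   emitted per (gene, sample), as a fraction of `reads_per_utr`.
#' @param soft_clip_frac fraction of genuine reads whose untemplated tail is
#'   represented as a terminal soft-clip in the SAM record; the remainder
#'   carry the tail as aligned mismatching bases (both dialects occur in
#'   real data, depending on the aligner).
#' @param usage_props named list (one element per condition) of per-UTR CS
#'   usage proportions: either a numeric vector of length `n_cs_per_utr`
#'   applied to every gene, or an `n_genes x n_cs_per_utr` matrix. Each row
#'   must be nonnegative and sum to 1.
#' @param reads_per_utr genuine reads emitted per gene per sample.
#' @param n_samples_per_condition replicate samples per condition.
#' @param strands `NULL` to alternate genes between '+' and '-' (roughly half
#'   on each strand), or a single `"+"`/`"-"` to force all genes onto one
#'   strand (used by strand-symmetry checks).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   simulated outputs.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 20L,
                       utr_len = c(300L, 400L),
                       n_cs_per_utr = 2L,
                       cs_spacing_true = 150L,
                       pas_offset = 20L,
                       pas_motif = "AATAAA",
                       cs_jitter_sd = 3,
                       tail_len_range = c(10L, 30L),
                       read_len = 50L,
                       seq_error_rate = 0.001,
                       internal_priming_rate = 0.05,
                       soft_clip_frac = 0.5,
                       usage_props = NULL,
                       reads_per_utr = 200L,
                       n_samples_per_condition = 1L,
                       strands = NULL,
                       seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(n_cs_per_utr, "n_cs_per_utr")
  if (n_cs_per_utr > 3L) stop("'n_cs_per_utr' must be 1, 2 or 3", call. = FALSE)
  stopifnot_scalar_count(cs_spacing_true, "cs_spacing_true")
  stopifnot_scalar_count(read_len, "read_len", min = 9L)
  stopifnot_scalar_count(reads_per_utr, "reads_per_utr")
  stopifnot_scalar_count(n_samples_per_condition, "n_samples_per_condition")
  if (pas_offset < 0) stop("'pas_offset' must be >= 0", call. = FALSE)
  if (length(utr_len) == 1L) utr_len <- rep(as.integer(utr_len), 2L)
  utr_len <- as.integer(utr_len)
  if (length(utr_len) != 2L || utr_len[1] > utr_len[2] || utr_len[1] < 1L)
    stop("'utr_len' must be a positive value or c(min, max) range", call. = FALSE)
  tail_len_range <- as.integer(tail_len_range)
  if (length(tail_len_range) != 2L || tail_len_range[1] > tail_len_range[2])
    stop("'tail_len_range' must be c(min, max)", call. = FALSE)
  if (tail_len_range[2] >= read_len)
    stop("'tail_len_range' max must be < read_len", call. = FALSE)
  if (nchar(pas_motif) != 6L || grepl("[^ACGT]", pas_motif))
    stop("'pas_motif' must be a DNA hexamer", call. = FALSE)
  if (seq_error_rate < 0 || seq_error_rate > 0.2)
    stop("'seq_error_rate' must be in [0, 0.2]", call. = FALSE)
  if (internal_priming_rate < 0 || internal_priming_rate > 1)
    stop("'internal_priming_rate' must be in [0, 1]", call. = FALSE)
  if (soft_clip_frac < 0 || soft_clip_frac > 1)
    stop("'soft_clip_frac' must be in [0, 1]", call. = FALSE)
  if (!is.null(strands) && !identical(strands, "+") && !identical(strands, "-"))
    stop("'strands' must be NULL, \"+\" or \"-\"", call. = FALSE)

  if (is.null(usage_props)) {
    p <- rep(1 / n_cs_per_utr, n_cs_per_utr)
    usage_props <- list(control = p, treated = p)
  }
  if (is.null(names(usage_props)) || anyDuplicated(names(usage_props)))
    stop("'usage_props' must be a named list with unique condition names",
         call. = FALSE)
  usage_props <- lapply(usage_props, function(p) {
    if (is.matrix(p)) {
      if (nrow(p) != n_genes || ncol(p) != n_cs_per_utr)
        stop("usage matrix must be n_genes x n_cs_per_utr", call. = FALSE)
      m <- p
    } else {
      if (length(p) != n_cs_per_utr)
        stop("usage vector length must equal n_cs_per_utr", call. = FALSE)
      m <- matrix(p, nrow = n_genes, ncol = n_cs_per_utr, byrow = TRUE)
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
      stop("usage proportions must be nonnegative and sum to 1", call. = FALSE)
    m
  })

  # Geometry: first CS sits 40 nt into the UTR; all CSs plus a 12-nt jitter
  # margin must fit inside the shortest UTR.
  first_cs <- 40L
  need <- first_cs + (n_cs_per_utr - 1L) * cs_spacing_true + 12L
  if (need > utr_len[1])
    stop(sprintf(
      "planted CSs do not fit: need %d nt of 3'UTR but utr_len min is %d",
      need, utr_len[1]), call. = FALSE)
  # PAS hexamer for the proximal CS must still land inside the transcript
  # (the CS sits 40 nt into the UTR, preceded by a 60-nt 5'UTR and 300-nt CDS).
  if (pas_offset > 300L)
    stop("'pas_offset' too large for CS placement", call. = FALSE)

  cfg <- list(
    n_genes = as.integer(n_genes), utr_len = utr_len,
    n_cs_per_utr = as.integer(n_cs_per_utr),
    cs_spacing_true = as.integer(cs_spacing_true),
    pas_offset = as.integer(pas_offset), pas_motif = pas_motif,
    cs_jitter_sd = cs_jitter_sd, tail_len_range = tail_len_range,
    read_len = as.integer(read_len), seq_error_rate = seq_error_rate,
    internal_priming_rate = internal_priming_rate,
    soft_clip_frac = soft_clip_frac, usage_props = usage_props,
    reads_per_utr = as.integer(reads_per_utr),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    strands = strands, first_cs_offset = first_cs,
    utr5_len = 60L, cds_len = 300L, gene_gap = 300L, chrom_flank = 200L,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Load a simulator configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [sim_config()] arguments and returns
#' the validated configuration.
#'
#' @param path path to a YAML file.
#' @param seed optional seed overriding the file's value.
#' @return A `"sim_config"` object.
#' @export
sim_config_from_yaml <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (!is.null(seed)) vals$seed <- seed
  if (!is.null(vals$usage_props))
    vals$usage_props <- lapply(vals$usage_props, function(p)
      if (is.list(p)) do.call(rbind, p) else unlist(p))
  do.call(sim_config, vals)
}
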