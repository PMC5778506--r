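# Polyadenylation-signal (PAS) hexamer scanning around called cleavage
# sites: a positional-enrichment profile in a +/-100 nt window serves as a
# precision check on CS mapping — genuine sites show a sharp peak of
# canonical AATAAA (and variants) ending ~20 nt upstream of the CS.

#' Default PAS hexamer catalogue
#'
#' The canonical AATAAA plus eleven common single-substitution variants
#' (DNA sense).
#'
#' @return character vector of hexamers.
#' @export
pas_motifs <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
    "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' Scan for PAS hexamers around one cleavage site
#'
#' Extracts the transcript-sense sequence of the `+/-flank` window around
#' the CS (reverse-complemented for minus-strand sites) and reports every
#' exact hexamer match. Offsets are measured at the hexamer's 3' end
#' relative to the CS, negative upstream: the canonical placement yields
#' offset -20. Windows truncated at a chromosome edge are scanned over the
#' available part and flagged.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param chrom,pos,strand site coordinates (1-based) and strand.
#' @param motifs hexamer set (default [pas_motifs()]).
#' @param flank half-window in nt (default 100).
#' @return data.frame with `motif` and `offset`; attribute `"truncated"`
#'   is `TRUE` when the window hit a chromosome edge.
#' @export
scan_pas <- function(genome, chrom, pos, strand, motifs = pas_motifs(),
                     flank = 100L) {
  slen <- Biostrings::width(genome[chrom])
  lo <- max(1L, pos - flank); hi <- min(slen, pos + flank)
  truncated <- (lo > pos - flank) || (hi < pos + flank)
  win <- as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
  if (strand == "-") win <- revcomp(win)
  cs_idx <- if (strand == "+") pos - lo + 1L else hi - pos + 1L
  hits <- lapply(motifs, function(m) {
    st <- gregexpr(m, win, fixed = TRUE)[[1]]
    st <- st[st > 0]
    if (!length(st)) return(NULL)
    data.frame(motif = m, offset = as.integer(st + 5L - cs_idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), hits))
  if (is.null(out))
    out <- data.frame(motif = character(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  out <- out[out$offset >= -flank & out$offset <= flank, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}

#' PAS positional-enrichment profile over a set of cleavage sites
#'
#' Aggregates [scan_pas()] hits over all sites into per-offset counts
#' (offset of the hexamer 3' end relative to the CS, transcript
#' orientation), and reports the modal offset, the fraction of sites with
#' at least one motif in the window, and a descriptive enrichment measure:
#' the peak/background count ratio plus a one-sided binomial test of the
#' peak offset count against a uniform-offset null.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param motifs hexamer set (default [pas_motifs()]).
#' @param flank half-window in nt (default 100).
#' @return list with `profile` (data.frame `offset`, `count`; only offsets
#'   with hits), `modal_offset`, `frac_sites_with_motif`, `n_sites`,
#'   `peak_background_ratio`, `binomial_p` and `motifs`.
#' @export
pas_positional_profile <- function(sites, genome, motifs = pas_motifs(),
                                   flank = 100L) {
  if (nrow(sites) == 0L) stop("empty site list", call. = FALSE)
  per_site <- lapply(seq_len(nrow(sites)), function(i)
    scan_pas(genome, sites$chrom[i], sites$pos[i], sites$strand[i],
             motifs = motifs, flank = flank))
  n_hit_sites <- sum(vapply(per_site, nrow, integer(1)) > 0L)
  all_hits <- do.call(rbind, per_site)
  if (nrow(all_hits) == 0L) {
    profile <- data.frame(offset = integer(0), count = integer(0))
    return(list(profile = profile, modal_offset = NA_integer_,
                frac_sites_with_motif = 0, n_sites = nrow(sites),
                peak_background_ratio = NA_real_, binomial_p = NA_real_,
                motifs = motifs))
  }
  tab <- table(all_hits$offset)
  profile <- data.frame(offset = as.integer(names(tab)), count = as.integer(tab))
  profile <- profile[order(profile$offset), , drop = FALSE]
  rownames(profile) <- NULL
  # Modal offset; ties resolved toward the most upstream offset.
  peak <- max(profile$count)
  modal <- min(profile$offset[profile$count == peak])
  n_offsets <- 2L * flank + 1L
  total <- sum(profile$count)
  background <- (total - peak) / (n_offsets - 1L)
  btest <- stats::binom.test(peak, total, p = 1 / n_offsets,
                             alternative = "greater")
  list(profile = profile, modal_offset = modal,
       frac_sites_with_motif = n_hit_sites / nrow(sites),
       n_sites = nrow(sites),
       peak_background_ratio = if (background > 0) peak / background else Inf,
       binomial_p = btest$p.value, motifs = motifs)
}
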