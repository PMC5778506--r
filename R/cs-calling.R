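# Cleavage-site calling: gene assignment of tail calls, per-gene CS
# profiles, greedy local-maxima site selection under support and spacing
# rules, genomic-category annotation and per-sample quantification.

#' Assign tail calls to genes
#'
#' A tail call is assigned to the gene whose span (extended `downstream` nt
#' past the annotated 3' end, to capture distal and novel cleavage) contains
#' its cleavage position on the same strand. Calls overlapping an
#' unextended gene span win over extension-only overlaps; remaining ties go
#' to the first gene in annotation order.
#'
#' @param tailcalls data.frame from [detect_tails()].
#' @param models a `gene_models` object.
#' @param downstream nt of downstream extension past the gene 3' end.
#' @return `tailcalls` with a `gene_id` column (`NA` when unassigned).
#' @export
assign_tailcalls <- function(tailcalls, models, downstream = 1000L) {
  tailcalls$gene_id <- rep(NA_character_, nrow(tailcalls))
  if (nrow(tailcalls) == 0L) return(tailcalls)
  tc <- GenomicRanges::GRanges(tailcalls$chrom,
                               IRanges::IRanges(tailcalls$cleavage_pos, width = 1L),
                               strand = tailcalls$strand)
  genes <- models$genes
  ext <- .extend_downstream(genes, downstream)
  hits <- GenomicRanges::findOverlaps(tc, ext)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    # Pairwise containment of the width-1 tail call in the unextended span
    # (chromosome and strand already agree through the overlap).
    p <- GenomicRanges::start(tc)[qh]
    inside <- p >= GenomicRanges::start(genes)[sh] &
              p <= GenomicRanges::end(genes)[sh]
    ord <- order(qh, !inside, sh)
    first <- !duplicated(qh[ord])
    tailcalls$gene_id[qh[ord][first]] <- genes$gene_id[sh[ord][first]]
  }
  tailcalls
}

.extend_downstream <- function(genes, downstream) {
  pos <- as.character(GenomicRanges::strand(genes)) == "+"
  st <- GenomicRanges::start(genes); en <- GenomicRanges::end(genes)
  GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                         IRanges::IRanges(ifelse(pos, st, pmax(1L, st - downstream)),
                                          ifelse(pos, en + downstream, en)),
                         strand = GenomicRanges::strand(genes))
}

#' Build a poly(A) cleavage-site profile
#'
#' Histogram of supported cleavage positions for one gene (and optionally
#' one sample): the number of tail-call reads supporting a cleavage at each
#' genomic position. Positions with zero support are absent.
#'
#' @param tailcalls data.frame with `gene_id` assigned
#'   (see [assign_tailcalls()]).
#' @param gene gene identifier to profile.
#' @param sample optional sample identifier; default pools all samples.
#' @return data.frame with `pos` and `count`, sorted by position.
#' @export
build_cs_profile <- function(tailcalls, gene, sample = NULL) {
  x <- tailcalls[!is.na(tailcalls$gene_id) & tailcalls$gene_id == gene, , drop = FALSE]
  if (!is.null(sample)) x <- x[x$sample == sample, , drop = FALSE]
  if (nrow(x) == 0L)
    return(data.frame(pos = integer(0), count = integer(0)))
  tab <- table(x$cleavage_pos)
  data.frame(pos = as.integer(names(tab)), count = as.integer(tab))
}

#' Select cleavage sites from a pooled CS profile
#'
#' Greedy local-maxima selection under the spacing rule: candidate positions
#' are ranked by support (descending; ties broken in favour of the more
#' proximal position, i.e. 5'-most in transcript orientation) and accepted
#' iff they lie at least `min_spacing` nt from every already-accepted site —
#' when two sites are closer than the spacing, the stronger one is kept.
#' After selection, profile support is re-aggregated onto the accepted sites
#' within `+/-window` nt and sites with pooled support below `min_support`
#' are dropped.
#'
#' @param profile data.frame with `pos`, `count` (pooled over samples).
#' @param strand `"+"` or `"-"`; defines which direction is proximal.
#' @param min_support minimum pooled read support per site (default 10).
#' @param min_spacing minimum distance between accepted sites (default 50).
#' @param window half-width of the support aggregation window (default 25).
#' @return data.frame with `pos` and `support`, sorted by position.
#' @export
select_cleavage_sites <- function(profile, strand = "+", min_support = 10L,
                                  min_spacing = 50L, window = 25L) {
  if (nrow(profile) == 0L)
    return(data.frame(pos = integer(0), support = integer(0)))
  prox <- if (strand == "+") profile$pos else -profile$pos
  ord <- order(-profile$count, prox)
  accepted <- integer(0)
  for (i in ord) {
    p <- profile$pos[i]
    if (!length(accepted) || all(abs(accepted - p) >= min_spacing))
      accepted <- c(accepted, p)
  }
  support <- .aggregate_support(profile$pos, profile$count, accepted,
                                window, strand)
  keep <- support >= min_support
  out <- data.frame(pos = accepted[keep], support = support[keep])
  out[order(out$pos), , drop = FALSE]
}

# Sum profile counts onto the nearest accepted site within +/-window;
# equidistant positions go to the more proximal site.
.aggregate_support <- function(pos, count, sites, window, strand) {
  if (!length(sites)) return(integer(0))
  support <- stats::setNames(rep(0L, length(sites)), sites)
  for (i in seq_along(pos)) {
    d <- abs(sites - pos[i])
    if (min(d) > window) next
    near <- which(d == min(d))
    if (length(near) > 1L)
      near <- near[order(if (strand == "+") sites[near] else -sites[near])][1L]
    support[near] <- support[near] + count[i]
  }
  as.integer(support)
}

#' Annotate cleavage sites with a genomic category
#'
#' Assigns each site the highest-priority category among the annotation
#' intervals it overlaps on its own strand:
#' `3UTR > CDS > 5UTR > intron > downstream_extension > intergenic`.
#' `downstream_extension` covers positions within `downstream` nt past a
#' gene's annotated 3' end.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`.
#' @param models a `gene_models` object.
#' @param downstream downstream-extension window (default 1000 nt).
#' @return character vector of categories, one per site.
#' @export
assign_genomic_category <- function(sites, models, downstream = 1000L) {
  if (nrow(sites) == 0L) return(character(0))
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L),
                               strand = sites$strand)
  cat <- rep("intergenic", nrow(sites))
  genes <- models$genes
  pos_strand <- as.character(GenomicRanges::strand(genes)) == "+"
  st <- GenomicRanges::start(genes); en <- GenomicRanges::end(genes)
  ext_only <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(ifelse(pos_strand, en + 1L, pmax(1L, st - downstream)),
                     ifelse(pos_strand, en + downstream, pmax(1L, st - 1L))),
    strand = GenomicRanges::strand(genes))
  layers <- list(downstream_extension = ext_only,
                 intron = models$introns, `5UTR` = models$utr5,
                 CDS = models$cds, `3UTR` = models$utr3)
  for (nm in names(layers)) {
    lay <- layers[[nm]]
    if (length(lay)) cat[IRanges::overlapsAny(gr, lay)] <- nm
  }
  cat
}

#' Quantify per-sample support of called cleavage sites
#'
#' Each tail call is assigned to the nearest accepted CS of its gene within
#' `+/-window` nt; calls equidistant between two sites go to the more
#' proximal one. Calls with no site within the window are left unassigned
#' and counted.
#'
#' @param tailcalls tail calls with `gene_id` and `sample` columns.
#' @param sites data.frame of accepted sites with `gene_id`, `pos`, `strand`.
#' @param samples character vector of all sample names (fixes column order).
#' @param window assignment half-window in nt (default 25).
#' @return list with `counts` (matrix, sites x samples) and `unassigned`
#'   (number of tail calls not within the window of any site).
#' @export
quantify_cs <- function(tailcalls, sites, samples, window = 25L) {
  counts <- matrix(0L, nrow = nrow(sites), ncol = length(samples),
                   dimnames = list(NULL, samples))
  unassigned <- 0L
  if (nrow(tailcalls) == 0L || nrow(sites) == 0L)
    return(list(counts = counts, unassigned = nrow(tailcalls)))
  site_idx_by_gene <- split(seq_len(nrow(sites)), sites$gene_id)
  for (i in seq_len(nrow(tailcalls))) {
    g <- tailcalls$gene_id[i]
    if (is.na(g) || is.null(site_idx_by_gene[[g]])) { unassigned <- unassigned + 1L; next }
    idx <- site_idx_by_gene[[g]]
    d <- abs(sites$pos[idx] - tailcalls$cleavage_pos[i])
    if (min(d) > window) { unassigned <- unassigned + 1L; next }
    near <- idx[d == min(d)]
    if (length(near) > 1L) {
      prox <- if (tailcalls$strand[i] == "+") sites$pos[near] else -sites$pos[near]
      near <- near[order(prox)][1L]
    }
    counts[near, tailcalls$sample[i]] <- counts[near, tailcalls$sample[i]] + 1L
  }
  list(counts = counts, unassigned = unassigned)
}

#' Call cleavage sites from aligned 3'-Seq reads
#'
#' End-to-end CS calling: detect untemplated tails, assign them to genes,
#' build pooled per-gene CS profiles, select sites under the support and
#' spacing rules, annotate genomic categories and quantify per-sample
#' support.
#'
#' @param reads data.frame of uniquely mapped reads (all samples together)
#'   with a `sample` column, as produced by [read_sam()] plus a sample label.
#' @param genome named [Biostrings::DNAStringSet].
#' @param models a `gene_models` object.
#' @param min_support,min_spacing,window see [select_cleavage_sites()].
#' @param downstream gene-extension window for tail-call assignment.
#' @param min_run,min_mismatch see [detect_tails()].
#' @return list with `sites` (data.frame: `gene_id`, `chrom`, `pos`,
#'   `strand`, `support_pooled`, `category`), `counts` (site x sample
#'   matrix), `tailcalls` (the assigned tail calls) and `unassigned`.
#' @export
call_cleavage_sites <- function(reads, genome, models, min_support = 10L,
                                min_spacing = 50L, window = 25L,
                                downstream = 1000L, min_run = 8L,
                                min_mismatch = 5L) {
  if (is.null(reads$sample)) reads$sample <- "sample_1"
  tc <- detect_tails(reads, genome, min_run = min_run, min_mismatch = min_mismatch)
  if (is.null(tc$sample)) tc$sample <- "sample_1"
  tc <- assign_tailcalls(tc, models, downstream = downstream)
  samples <- sort(unique(reads$sample))

  strand_of <- stats::setNames(as.character(GenomicRanges::strand(models$genes)),
                               models$genes$gene_id)
  chrom_of <- stats::setNames(as.character(GenomicRanges::seqnames(models$genes)),
                              models$genes$gene_id)
  genes <- sort(unique(stats::na.omit(tc$gene_id)))
  site_rows <- lapply(genes, function(g) {
    prof <- build_cs_profile(tc, g)
    sel <- select_cleavage_sites(prof, strand = strand_of[[g]],
                                 min_support = min_support,
                                 min_spacing = min_spacing, window = window)
    if (nrow(sel) == 0L) return(NULL)
    data.frame(gene_id = g, chrom = chrom_of[[g]], pos = sel$pos,
               strand = strand_of[[g]], support_pooled = sel$support,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, Filter(Negate(is.null), site_rows))
  if (is.null(sites))
    sites <- data.frame(gene_id = character(0), chrom = character(0),
                        pos = integer(0), strand = character(0),
                        support_pooled = integer(0), stringsAsFactors = FALSE)
  sites$category <- assign_genomic_category(sites, models, downstream = downstream)
  q <- quantify_cs(tc, sites, samples, window = window)
  rownames(sites) <- NULL
  list(sites = sites, counts = q$counts, tailcalls = tc,
       unassigned = q$unassigned)
}
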