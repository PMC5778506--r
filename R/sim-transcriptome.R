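#' Simulate a toy genome, gene models and cleavage-site ground truth
#'
#' Generates `n_genes` single-exon genes laid out in tandem on one synthetic
#' chromosome, each with a 5'UTR, CDS and 3'UTR. Inside every 3'UTR,
#' `n_cs_per_utr` cleavage sites are planted `cs_spacing_true` nt apart, each
#' preceded by the configured PAS hexamer ending `pas_offset` nt upstream in
#' transcript orientation. Genes alternate between the two strands unless
#' `config$strands` forces one. When `internal_priming_rate > 0`, a 12-nt
#' templated A-tract is planted in each 3'UTR away from every CS, as an
#' internal-priming decoy; its position is recorded in the truth table.
#'
#' Background sequence is A-depleted and a +/-12 nt zone around each CS is
#' kept A-free so that the first untemplated tail base is identifiable; this
#' mirrors the fact that genuine cleavage sites do not sit inside genomic
#' A-tracts (those are exactly the internal-priming artifacts the tail rule
#' guards against).
#'
#' @param config a [sim_config()] object.
#' @return A list with components `genome` (named [Biostrings::DNAStringSet]),
#'   `models` (a `gene_models` object, see [read_gtf()]) and `truth`, a list
#'   with `cs` (data.frame: gene_id, chrom, strand, cs_index with 1 = most
#'   proximal, tx_pos, genomic_pos, pas_end_genomic), `decoys` (data.frame of
#'   planted A-tract intervals), `usage` (per-condition usage matrices) and
#'   the per-gene transcript sequences used by [simulate_reads()].
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  utr5 <- config$utr5_len; cds <- config$cds_len
  utr_lens <- if (config$utr_len[1] == config$utr_len[2]) rep(config$utr_len[1], n)
              else sample(config$utr_len[1]:config$utr_len[2], n, replace = TRUE)
  strands <- if (is.null(config$strands)) rep(c("+", "-"), length.out = n)
             else rep(config$strands, n)

  tx_len <- utr5 + cds + utr_lens
  gap <- config$gene_gap; flank <- config$chrom_flank
  gstart <- flank + c(0L, cumsum(tx_len[-n] + gap)) + 1L
  gend <- gstart + tx_len - 1L
  chrom_len <- gend[n] + flank
  chrom <- "chrS"

  gene_ids <- sprintf("gene%03d", seq_len(n))
  cs_k <- seq_len(config$n_cs_per_utr)
  first_cs <- config$first_cs_offset

  tx_seqs <- character(n)
  cs_rows <- vector("list", n)
  decoy_rows <- vector("list", n)

  for (i in seq_len(n)) {
    tlen <- tx_len[i]
    s <- strsplit(random_dna(tlen), "", fixed = TRUE)[[1]]
    # CS positions in transcript coordinates (1-based from transcript 5').
    cs_tx <- utr5 + cds + first_cs + (cs_k - 1L) * config$cs_spacing_true
    # A-free zone +/-12 nt around each CS.
    for (cs in cs_tx) {
      zone <- max(1L, cs - 12L):min(tlen, cs + 12L)
      hitA <- zone[s[zone] == "A"]
      if (length(hitA))
        s[hitA] <- sample(c("C", "G", "T"), length(hitA), replace = TRUE)
    }
    # Plant PAS hexamer ending pas_offset nt upstream of each CS.
    pas_end_tx <- cs_tx - config$pas_offset
    for (pe in pas_end_tx)
      s[(pe - 5L):pe] <- strsplit(config$pas_motif, "", fixed = TRUE)[[1]]
    # Internal-priming decoy: 12 templated As, >= 25 nt from every CS and
    # clear of every PAS hexamer.
    decoy_tx <- NA_integer_
    if (config$internal_priming_rate > 0) {
      utr_start <- utr5 + cds + 1L
      cand <- utr_start:(tlen - 12L)
      ok <- vapply(cand, function(st) {
        en <- st + 11L
        all(st > cs_tx + 25L | en < cs_tx - 32L)
      }, logical(1))
      cand <- cand[ok]
      if (length(cand)) {
        decoy_tx <- cand[ceiling(length(cand) / 2)]
        s[decoy_tx:(decoy_tx + 11L)] <- "A"
      }
    }
    tx_seqs[i] <- paste(s, collapse = "")

    g <- function(t) tx2genome(gstart[i], tx_len[i], strands[i], t)
    cs_rows[[i]] <- data.frame(
      gene_id = gene_ids[i], chrom = chrom, strand = strands[i],
      cs_index = cs_k, tx_pos = cs_tx, utr_pos = first_cs + (cs_k - 1L) * config$cs_spacing_true,
      genomic_pos = as.integer(g(cs_tx)),
      pas_end_genomic = as.integer(g(pas_end_tx)),
      stringsAsFactors = FALSE)
    if (!is.na(decoy_tx)) {
      dg <- sort(as.integer(g(c(decoy_tx, decoy_tx + 11L))))
      decoy_rows[[i]] <- data.frame(
        gene_id = gene_ids[i], chrom = chrom, strand = strands[i],
        tx_start = decoy_tx, genomic_start = dg[1], genomic_end = dg[2],
        stringsAsFactors = FALSE)
    }
  }

  # Assemble the chromosome: flanks and inter-gene gaps are background.
  chrom_seq <- strsplit(random_dna(chrom_len), "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) {
    insert <- if (strands[i] == "+") tx_seqs[i] else revcomp(tx_seqs[i])
    chrom_seq[gstart[i]:gend[i]] <- strsplit(insert, "", fixed = TRUE)[[1]]
  }
  genome <- Biostrings::DNAStringSet(structure(paste(chrom_seq, collapse = ""),
                                               names = chrom))

  models <- .build_gene_models(gene_ids, chrom, strands, gstart, gend,
                               tx_len, utr5, cds, utr_lens)

  truth <- list(
    cs = do.call(rbind, cs_rows),
    decoys = if (length(dr <- Filter(Negate(is.null), decoy_rows))) do.call(rbind, dr)
             else data.frame(gene_id = character(0), chrom = character(0),
                             strand = character(0), tx_start = integer(0),
                             genomic_start = integer(0), genomic_end = integer(0)),
    usage = config$usage_props,
    tx_seqs = structure(tx_seqs, names = gene_ids),
    gene_start = structure(as.integer(gstart), names = gene_ids),
    gene_len = structure(as.integer(tx_len), names = gene_ids),
    strand = structure(strands, names = gene_ids),
    chrom = chrom, config = config)

  list(genome = genome, models = models, truth = truth)
}

# Build the gene_models container for the simulated single-exon genes.
.build_gene_models <- function(gene_ids, chrom, strands, gstart, gend,
                               tx_len, utr5, cds, utr_lens) {
  n <- length(gene_ids)
  span <- GenomicRanges::GRanges(chrom, IRanges::IRanges(gstart, gend),
                                 strand = strands, gene_id = gene_ids)
  # Transcript-local category intervals, then mapped to genomic.
  cat_gr <- function(t1, t2) {
    a <- tx2genome(gstart, tx_len, strands, t1)
    b <- tx2genome(gstart, tx_len, strands, t2)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pmin(a, b), pmax(a, b)),
                           strand = strands, gene_id = gene_ids)
  }
  utr5_gr <- cat_gr(rep(1L, n), rep(utr5, n))
  cds_gr <- cat_gr(rep(utr5 + 1L, n), rep(utr5 + cds, n))
  utr3_gr <- cat_gr(rep(utr5 + cds + 1L, n), tx_len)
  structure(list(genes = span, exons = span, cds = cds_gr,
                 utr5 = utr5_gr, utr3 = utr3_gr,
                 introns = GenomicRanges::GRanges()),
            class = "gene_models")
}
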