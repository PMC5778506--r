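#' Simulate aligned 3'-Seq reads with ground-truth counts
#'
#' Emits, for every sample of every condition, `reads_per_utr` genuine reads
#' per gene. A genuine read covers the transcript up to a jittered cleavage
#' position and then carries an untemplated poly(A) tail whose length is
#' drawn from `tail_len_range`; reads are distributed over the gene's planted
#' CSs according to the condition's usage proportions (multinomial). Per-base
#' substitution errors are applied at `seq_error_rate`. The tail is written
#' in one of two SAM dialects: a terminal soft-clip (probability
#' `soft_clip_frac`) or aligned mismatching bases (the Bowtie-era
#' representation); downstream tail detection must handle both. When
#' `internal_priming_rate > 0`, additional artifact reads are emitted that
#' end in the planted *templated* A-tract decoys.
#'
#' @param sim result of [simulate_transcriptome()].
#' @param config the same [sim_config()] object.
#' @return A list: `reads`, a named list (one element per sample) of
#'   data.frames with SAM-style fields (`qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq` as stored on the forward genomic strand,
#'   `strand`); `samples`, a data.frame mapping sample to condition; and
#'   `truth` extended with `read_counts` (reads emitted per gene, sample and
#'   CS) and `ip_counts` (artifact reads per gene and sample).
#' @export
simulate_reads <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim$truth
  set.seed(config$seed + 1L)

  conditions <- names(config$usage_props)
  samples <- data.frame(
    sample = unlist(lapply(conditions, function(cn)
      paste0(cn, "_", seq_len(config$n_samples_per_condition)))),
    condition = rep(conditions, each = config$n_samples_per_condition),
    stringsAsFactors = FALSE)

  gene_ids <- names(truth$tx_seqs)
  cs_by_gene <- split(truth$cs, truth$cs$gene_id)
  decoy_by_gene <- split(truth$decoys, truth$decoys$gene_id)
  n_ip <- round(config$internal_priming_rate * config$reads_per_utr)

  reads_out <- vector("list", nrow(samples))
  names(reads_out) <- samples$sample
  count_rows <- list()
  ip_rows <- list()

  for (si in seq_len(nrow(samples))) {
    smp <- samples$sample[si]; cond <- samples$condition[si]
    props <- config$usage_props[[cond]]
    per_gene <- vector("list", length(gene_ids))
    for (gi in seq_along(gene_ids)) {
      gid <- gene_ids[gi]
      cs_tab <- cs_by_gene[[gid]]
      counts <- as.integer(stats::rmultinom(1, config$reads_per_utr, props[gi, ]))
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        gene_id = gid, sample = smp, condition = cond,
        cs_index = cs_tab$cs_index, count = counts, stringsAsFactors = FALSE)

      ntot <- config$reads_per_utr
      cs_tx <- rep(cs_tab$tx_pos, counts)
      jit <- .rjitter(ntot, config$cs_jitter_sd)
      cleave <- cs_tx + jit
      tail_len <- sample(config$tail_len_range[1]:config$tail_len_range[2],
                         ntot, replace = TRUE)
      tpl_len <- config$read_len - tail_len
      txs <- truth$tx_seqs[[gid]]
      templated <- substring(txs, cleave - tpl_len, cleave - 1L)
      rd <- paste0(templated, strrep("A", tail_len))
      rd <- .apply_errors(rd, config$seq_error_rate)
      soft <- stats::runif(ntot) < config$soft_clip_frac

      gs <- truth$gene_start[[gid]]; gl <- truth$gene_len[[gid]]
      strand <- truth$strand[[gid]]
      g <- function(t) as.integer(tx2genome(gs, gl, strand, t))
      if (strand == "+") {
        pos <- g(cleave - tpl_len)
        cigar <- ifelse(soft, paste0(tpl_len, "M", tail_len, "S"),
                        paste0(config$read_len, "M"))
        seq_store <- rd; flag <- 0L
      } else {
        pos <- ifelse(soft, g(cleave - 1L), g(cleave + tail_len - 1L))
        cigar <- ifelse(soft, paste0(tail_len, "S", tpl_len, "M"),
                        paste0(config$read_len, "M"))
        seq_store <- revcomp(rd); flag <- 16L
      }
      df <- data.frame(
        qname = sprintf("%s:%s:%04d", gid, smp, seq_len(ntot)),
        flag = flag, chrom = truth$chrom, pos = pos, mapq = 42L,
        cigar = cigar, seq = seq_store, strand = strand,
        stringsAsFactors = FALSE)

      # Internal-priming artifact reads: fully templated, ending at the
      # decoy A-tract (the oligo-dT primer annealed to genomic As).
      dec <- decoy_by_gene[[gid]]
      if (n_ip > 0 && !is.null(dec) && nrow(dec) == 1L) {
        end_tx <- dec$tx_start + 11L
        ipseq <- rep(substring(txs, end_tx - config$read_len + 1L, end_tx), n_ip)
        ipseq <- .apply_errors(ipseq, config$seq_error_rate)
        ip_pos <- if (strand == "+") g(end_tx - config$read_len + 1L) else g(end_tx)
        ipdf <- data.frame(
          qname = sprintf("%s:%s:ip%03d", gid, smp, seq_len(n_ip)),
          flag = if (strand == "+") 0L else 16L, chrom = truth$chrom,
          pos = rep(as.integer(ip_pos), n_ip), mapq = 42L,
          cigar = paste0(config$read_len, "M"),
          seq = if (strand == "+") ipseq else revcomp(ipseq),
          strand = strand, stringsAsFactors = FALSE)
        df <- rbind(df, ipdf)
        ip_rows[[length(ip_rows) + 1L]] <- data.frame(
          gene_id = gid, sample = smp, n_ip = n_ip, stringsAsFactors = FALSE)
      }
      per_gene[[gi]] <- df
    }
    reads_out[[si]] <- do.call(rbind, per_gene)
    rownames(reads_out[[si]]) <- NULL
  }

  truth$read_counts <- do.call(rbind, count_rows)
  truth$ip_counts <- if (length(ip_rows)) do.call(rbind, ip_rows)
                     else data.frame(gene_id = character(0), sample = character(0),
                                     n_ip = integer(0))
  list(reads = reads_out, samples = samples, truth = truth)
}

# Discretized normal jitter truncated to +/-10 nt.
.rjitter <- function(n, sd) {
  if (n == 0L) return(integer(0))
  if (sd == 0) return(integer(n))
  j <- as.integer(round(stats::rnorm(n, 0, sd)))
  while (any(bad <- abs(j) > 10L))
    j[bad] <- as.integer(round(stats::rnorm(sum(bad), 0, sd)))
  j
}

# Per-base substitution errors on a character vector of reads.
.apply_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads[1])
  nerr <- stats::rbinom(length(reads), len, rate)
  for (i in which(nerr > 0)) {
    s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    at <- sample.int(len, nerr[i])
    for (p in at) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Write aligned reads as a SAM file
#'
#' Emits a SAM v1.6 file (text, LF line endings) from the read table produced
#' by [simulate_reads()]. Output is byte-deterministic for a fixed input.
#'
#' @param reads data.frame with `qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq` (forward-genomic-strand, as stored in SAM).
#' @param seqlengths named integer vector of chromosome lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)),
           "@PG\tID:apaseq\tPN:apaseq")
  qual <- strrep("I", nchar(reads$seq))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos,
                  reads$mapq, reads$cigar, reads$seq, qual)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
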