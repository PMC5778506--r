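# Untemplated poly(A) tail detection.
#
# A read supports a cleavage-site call iff, in transcript orientation, its
# 3' end carries a terminal run of >= 8 As and at least 5 of the first 8 As
# of that run mismatch the reference bases they align to (or extrapolate to,
# for soft-clipped tails). A templated genomic A-tract matches the reference
# and is rejected: this is the internal-priming guard. The cleavage position
# is the genomic coordinate of the first base of the run ("where the
# untemplated A stretch started").

.parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || paste(ops, collapse = "") != cigar)
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  list(op = substring(ops, nchar(ops)), len = as.integer(sub(".$", "", ops)))
}

.cigar_query_len <- function(cigar) {
  p <- .parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
}

# Genomic coordinate of stored-orientation query position q. Soft-clipped
# bases are extrapolated past the alignment boundary (leading S before
# `pos`, trailing S after the last aligned base). Insertions return NA.
.query_to_genome <- function(cigar, pos, q) {
  p <- .parse_cigar(cigar)
  ref <- pos
  qq <- 0L
  for (i in seq_along(p$op)) {
    op <- p$op[i]; len <- p$len[i]
    if (op %in% c("M", "=", "X")) {
      if (q <= qq + len) return(ref + (q - qq - 1L))
      qq <- qq + len; ref <- ref + len
    } else if (op == "S") {
      if (q <= qq + len) {
        if (i == 1L) return(ref - len + (q - qq - 1L))
        return(ref + (q - qq - 1L))
      }
      qq <- qq + len
    } else if (op == "I") {
      if (q <= qq + len) return(NA_integer_)
      qq <- qq + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    }
  }
  NA_integer_
}

#' Detect untemplated poly(A) tails in aligned reads
#'
#' Scans each read (in transcript orientation, i.e. the `seq` column as
#' produced by [read_sam()]) for a terminal A-run at its 3' end. The run may
#' span 3' soft-clipped bases and trailing aligned bases — both SAM tail
#' dialects are reconstructed through the CIGAR. A tail call is made iff the
#' run is at least `min_run` As long and at least `min_mismatch` of its
#' first 8 bases mismatch the corresponding reference bases (i.e. the
#' reference there is not A). Reads ending in templated genomic A-tracts
#' (internal-priming artifacts) fail the mismatch requirement and are
#' rejected.
#'
#' @param reads data.frame from [read_sam()] (`qname`, `chrom`, `pos`,
#'   `strand`, `cigar`, `seq` as sequenced); an optional `sample` column is
#'   carried through.
#' @param genome named [Biostrings::DNAStringSet] covering the read loci.
#' @param min_run minimum terminal A-run length (default 8).
#' @param min_mismatch minimum mismatching bases among the run's first 8
#'   (default 5).
#' @return data.frame of tail calls: `read_id`, `chrom`, `strand`,
#'   `cleavage_pos` (genomic coordinate of the first untemplated A),
#'   `tail_len`, `mismatches_first8` and `sample` (if supplied). Reads with
#'   no passing tail are absent.
#' @export
detect_tails <- function(reads, genome, min_run = 8L, min_mismatch = 5L) {
  if (nrow(reads) == 0L) return(.empty_tailcalls(!is.null(reads$sample)))
  check_len <- 8L
  run <- nchar(reads$seq) - nchar(sub("A*$", "", reads$seq))
  cand <- which(run >= min_run)
  if (!length(cand)) return(.empty_tailcalls(!is.null(reads$sample)))

  qlen <- nchar(reads$seq[cand])
  p_start <- qlen - run[cand] + 1L            # sequenced-orientation run start
  neg <- reads$strand[cand] == "-"
  q1 <- ifelse(neg, qlen - p_start + 1L, p_start)
  q8 <- ifelse(neg, q1 - (check_len - 1L), q1 + (check_len - 1L))

  g1 <- integer(length(cand)); g8 <- integer(length(cand))
  for (i in seq_along(cand)) {
    j <- cand[i]
    g1[i] <- .query_to_genome(reads$cigar[j], reads$pos[j], q1[i])
    g8[i] <- .query_to_genome(reads$cigar[j], reads$pos[j], q8[i])
  }
  slen <- stats::setNames(Biostrings::width(genome), names(genome))
  regular <- !is.na(g1) & !is.na(g8) & abs(g8 - g1) == check_len - 1L
  mm <- rep(NA_integer_, length(cand))

  keep <- which(regular)
  if (length(keep)) {
    chroms <- reads$chrom[cand[keep]]
    lo <- pmin(g1[keep], g8[keep]); hi <- pmax(g1[keep], g8[keep])
    if (any(lo < 1L) || any(hi > slen[chroms]))
      stop("reference shorter than needed for tail comparison (malformed input)",
           call. = FALSE)
    refs <- extract_ranges(genome, chroms, lo, hi)
    refs[neg[keep]] <- Biostrings::reverseComplement(refs[neg[keep]])
    mm[keep] <- check_len - as.integer(Biostrings::letterFrequency(refs, "A"))
  }
  # Indel-interrupted windows (rare): map the 8 run bases one by one; bases
  # falling in insertions have no reference and count as mismatches.
  for (i in which(!regular & !is.na(g1))) {
    j <- cand[i]
    qs <- q1[i] + (if (neg[i]) -(0:(check_len - 1L)) else 0:(check_len - 1L))
    gpos <- vapply(qs, function(q) .query_to_genome(reads$cigar[j], reads$pos[j], q),
                   integer(1))
    inb <- !is.na(gpos)
    if (any(gpos[inb] < 1L | gpos[inb] > slen[[reads$chrom[j]]]))
      stop("reference shorter than needed for tail comparison (malformed input)",
           call. = FALSE)
    base <- rep("N", check_len)
    if (any(inb)) {
      b <- as.character(extract_ranges(genome, rep(reads$chrom[j], sum(inb)),
                                       gpos[inb], gpos[inb]))
      if (neg[i]) b <- revcomp(b)
      base[inb] <- b
    }
    mm[i] <- sum(base != "A")
  }

  pass <- !is.na(mm) & mm >= min_mismatch
  idx <- cand[pass]
  g1k <- g1[pass]; mmk <- mm[pass]
  out <- data.frame(
    read_id = reads$qname[idx], chrom = reads$chrom[idx],
    strand = reads$strand[idx], cleavage_pos = g1k,
    tail_len = run[idx], mismatches_first8 = mmk,
    stringsAsFactors = FALSE)
  if (!is.null(reads$sample)) out$sample <- reads$sample[idx]
  rownames(out) <- NULL
  out
}

#' Judge a single aligned read for an untemplated poly(A) tail
#'
#' Single-read wrapper around [detect_tails()].
#'
#' @inheritParams detect_tails
#' @param read a one-row data.frame (or list) with `qname`, `chrom`, `pos`,
#'   `strand`, `cigar` and `seq` in transcript orientation.
#' @return A one-row tail-call data.frame, or `NULL` if the read does not
#'   qualify.
#' @export
detect_untemplated_tail <- function(read, genome, min_run = 8L, min_mismatch = 5L) {
  df <- as.data.frame(read, stringsAsFactors = FALSE)
  res <- detect_tails(df, genome, min_run = min_run, min_mismatch = min_mismatch)
  if (nrow(res) == 0L) NULL else res
}

.empty_tailcalls <- function(with_sample = FALSE) {
  out <- data.frame(read_id = character(0), chrom = character(0),
                    strand = character(0), cleavage_pos = integer(0),
                    tail_len = integer(0), mismatches_first8 = integer(0),
                    stringsAsFactors = FALSE)
  if (with_sample) out$sample <- character(0)
  out
}
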