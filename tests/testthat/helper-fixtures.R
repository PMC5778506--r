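# Shared fixtures and independent oracles for the test suite.

quiet_read_sam <- function(...) suppressMessages(read_sam(...))

# Convert simulate_reads() stored-orientation sequences to as-sequenced
# (transcript-sense) orientation, as read_sam() exposes them.
revcomp_chr <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# A single-chromosome genome from a literal sequence.
mini_genome <- function(seq, name = "chr1") {
  Biostrings::DNAStringSet(structure(seq, names = name))
}

# One aligned read as the data.frame read_sam() would produce
# (seq in transcript orientation / as sequenced).
mini_read <- function(seq, pos, cigar, strand = "+", chrom = "chr1",
                      qname = "r1") {
  data.frame(qname = qname, flag = if (strand == "+") 0L else 16L,
             chrom = chrom, pos = pos, strand = strand, mapq = 42L,
             cigar = cigar, seq = seq, stringsAsFactors = FALSE)
}

# Independent brute-force reimplementation of the greedy site-selection
# rule, deliberately written as plain nested loops: candidates ranked by
# support (ties to the proximal position), accepted when no closer than
# min_spacing to any accepted site, support then re-aggregated to the
# nearest accepted site within +/-window (ties proximal), low-support
# sites dropped.
oracle_select <- function(profile, strand, min_support = 10, min_spacing = 50,
                          window = 25) {
  n <- nrow(profile)
  if (n == 0) return(data.frame(pos = integer(0), support = integer(0)))
  remaining <- seq_len(n)
  accepted <- integer(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    for (i in remaining) {
      better <- profile$count[i] > profile$count[best]
      tie <- profile$count[i] == profile$count[best]
      more_prox <- if (strand == "+") profile$pos[i] < profile$pos[best]
                   else profile$pos[i] > profile$pos[best]
      if (better || (tie && more_prox)) best <- i
    }
    p <- profile$pos[best]
    conflict <- FALSE
    for (a in accepted) if (abs(a - p) < min_spacing) conflict <- TRUE
    if (!conflict) accepted <- c(accepted, p)
    remaining <- setdiff(remaining, best)
  }
  support <- rep(0L, length(accepted))
  for (i in seq_len(n)) {
    dmin <- Inf; pick <- 0L
    for (k in seq_along(accepted)) {
      d <- abs(accepted[k] - profile$pos[i])
      closer <- d < dmin
      tie_prox <- d == dmin && pick > 0L &&
        (if (strand == "+") accepted[k] < accepted[pick]
         else accepted[k] > accepted[pick])
      if (closer || tie_prox) { dmin <- d; pick <- k }
    }
    if (dmin <= window) support[pick] <- support[pick] + profile$count[i]
  }
  keep <- support >= min_support
  out <- data.frame(pos = accepted[keep], support = as.integer(support[keep]))
  out[order(out$pos), , drop = FALSE]
}

random_profile <- function(npos = 12, max_pos = 200, max_count = 40) {
  pos <- sort(sample.int(max_pos, npos))
  data.frame(pos = pos, count = sample.int(max_count, npos, replace = TRUE))
}

# Tail-rule micro-fixtures: a 20-nt templated prefix followed by a
# configurable reference region under the read's terminal A-run.
tail_fixture <- function(ref_under_tail, tail, prefix = "GTCGTACGGATCCTAGGCAT") {
  chrom_seq <- paste0(strrep("T", 10), prefix, ref_under_tail,
                      strrep("C", 30))
  genome <- mini_genome(chrom_seq)
  read_seq <- paste0(prefix, tail)
  read <- mini_read(read_seq, pos = 11L,
                    cigar = paste0(nchar(read_seq), "M"))
  list(genome = genome, read = read,
       cleavage_pos = 11L + nchar(prefix))
}
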