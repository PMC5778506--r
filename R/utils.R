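# Internal helpers shared across modules.
#
# Coordinate convention: all internal coordinates are 1-based closed
# (the GRanges/IRanges convention). GTF is read/written 1-based closed
# natively; BED conversion to 0-based half-open happens only at the BED
# boundary. "Transcript orientation" means 5'->3' along the mRNA: increasing
# genomic coordinate on '+' genes, decreasing on '-' genes.

# Map a transcript-local 1-based position to a genomic coordinate for a gene
# occupying genomic span [gstart, gstart + glen - 1].
tx2genome <- function(gstart, glen, strand, tpos) {
  n <- max(length(gstart), length(glen), length(strand), length(tpos))
  gstart <- rep_len(gstart, n); glen <- rep_len(glen, n)
  strand <- rep_len(strand, n); tpos <- rep_len(tpos, n)
  ifelse(strand == "+", gstart + tpos - 1L, gstart + glen - tpos)
}

genome2tx <- function(gstart, glen, strand, gpos) {
  n <- max(length(gstart), length(glen), length(strand), length(gpos))
  gstart <- rep_len(gstart, n); glen <- rep_len(glen, n)
  strand <- rep_len(strand, n); gpos <- rep_len(gpos, n)
  ifelse(strand == "+", gpos - gstart + 1L, gstart + glen - gpos)
}

# Extract [lo, hi] subsequences from a named DNAStringSet, vectorized over
# ranges possibly spanning several chromosomes.
extract_ranges <- function(genome, chrom, lo, hi) {
  out <- Biostrings::DNAStringSet(rep("", length(chrom)))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    out[idx] <- Biostrings::extractAt(genome[[ch]],
                                      IRanges::IRanges(lo[idx], hi[idx]))
  }
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Positional distance from CS in transcript orientation: negative = upstream.
tx_offset <- function(strand, pos, cs) {
  ifelse(strand == "+", pos - cs, cs - pos)
}

# Sample n bases with an A-depleted background composition; `alphabet_probs`
# is the package-wide default background for simulated sequence.
.bg_probs <- c(A = 0.12, C = 0.30, G = 0.30, T = 0.28)

random_dna <- function(n, probs = .bg_probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
}
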