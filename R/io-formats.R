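#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return Named [Biostrings::DNAStringSet]; sequence names are the first
#'   whitespace-delimited token of each header; lowercase input is
#'   uppercased (DNA alphabet normalization).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate chromosome names in FASTA: ", path, call. = FALSE)
  x
}

#' Write a FASTA genome
#'
#' @param genome named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses a GTF (1-based closed coordinates, the native convention used
#' internally throughout this package) into a `gene_models` container
#' holding per-category [GenomicRanges::GRanges]: gene spans, exons, CDS,
#' 5'UTRs, 3'UTRs and introns (derived as gaps between a gene's exons).
#' Recognized feature types are `exon`, `CDS`, `five_prime_utr`/`5UTR` and
#' `three_prime_utr`/`3UTR`. On a minus-strand gene the 3'UTR is the
#' genomically leftmost interval.
#'
#' @param path GTF file.
#' @return A list of class `gene_models` with elements `genes`, `exons`,
#'   `cds`, `utr5`, `utr3`, `introns`, each a `GRanges` carrying a
#'   `gene_id` metadata column.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("GTF records lack a gene_id attribute: ", path, call. = FALSE)
  pick <- function(types) {
    x <- gr[as.character(gr$type) %in% types]
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(gene_id = x$gene_id)
    unname(x)
  }
  exons <- pick("exon")
  if (length(exons) == 0L) stop("GTF contains no exon features", call. = FALSE)
  ex_by_gene <- GenomicRanges::split(exons, exons$gene_id)
  genes <- unlist(range(ex_by_gene))
  genes$gene_id <- names(genes)
  names(genes) <- NULL
  introns <- unlist(GenomicRanges::psetdiff(
    unlist(range(ex_by_gene)), ex_by_gene))
  introns$gene_id <- names(introns)
  names(introns) <- NULL
  structure(list(genes = genes, exons = exons, cds = pick("CDS"),
                 utr5 = pick(c("five_prime_utr", "5UTR")),
                 utr3 = pick(c("three_prime_utr", "3UTR")),
                 introns = introns),
            class = "gene_models")
}

#' Write gene models as GTF
#'
#' Emits exon, CDS, five_prime_utr and three_prime_utr features (GTF2.2,
#' 1-based closed intervals) with `gene_id`/`transcript_id` attributes.
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  fmt <- function(gr, type) {
    if (length(gr) == 0L) return(character(0))
    sprintf("%s\tapaseq\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            as.character(GenomicRanges::seqnames(gr)), type,
            GenomicRanges::start(gr), GenomicRanges::end(gr),
            as.character(GenomicRanges::strand(gr)), gr$gene_id, gr$gene_id)
  }
  lines <- c(fmt(models$exons, "exon"), fmt(models$cds, "CDS"),
             fmt(models$utr5, "five_prime_utr"),
             fmt(models$utr3, "three_prime_utr"))
  # Stable order: by gene then coordinate then feature text.
  lines <- lines[order(sub(".*gene_id \"([^\"]+)\".*", "\\1", lines),
                       as.integer(sub("^[^\t]*\t[^\t]*\t[^\t]*\t(\\d+).*", "\\1", lines)),
                       lines)]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read uniquely mapped alignments from SAM/BAM
#'
#' Loads alignment records and exposes them in the orientation the tail
#' detector needs: `seq` is the read *as sequenced* (reverse-complemented
#' back from the SAM store for minus-strand alignments, i.e. transcript
#' sense for 3'-Seq), `pos` is the 1-based leftmost aligned genomic
#' coordinate and `cigar` is in reference order. Unmapped records are always
#' dropped; with `unique_only = TRUE` (default), secondary (0x100) and
#' supplementary (0x800) records and records with MAPQ 0 are dropped too —
#' a flag-level proxy for "uniquely mapped" since aligner-specific
#' uniqueness flags are not portable. The number of dropped records is
#' reported via `message()` and attached as attribute `"dropped"`.
#'
#' @param path SAM (or BAM) file with headers.
#' @param unique_only drop multimapper proxies (see above).
#' @return data.frame with `qname`, `flag`, `chrom`, `pos`, `strand`,
#'   `mapq`, `cigar`, `seq`.
#' @export
read_sam <- function(path, unique_only = TRUE) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
         else suppressMessages(Rsamtools::asBam(
           path, tempfile(), overwrite = TRUE, indexDestination = FALSE))
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")))[[1]]
  df <- data.frame(qname = res$qname, flag = res$flag,
                   chrom = as.character(res$rname), pos = res$pos,
                   strand = as.character(res$strand), mapq = res$mapq,
                   cigar = res$cigar, seq = as.character(res$seq),
                   stringsAsFactors = FALSE)
  n0 <- nrow(df)
  df <- df[bitwAnd(df$flag, 4L) == 0L, , drop = FALSE]
  if (unique_only)
    df <- df[bitwAnd(df$flag, 256L) == 0L & bitwAnd(df$flag, 2048L) == 0L &
               !is.na(df$mapq) & df$mapq > 0L, , drop = FALSE]
  bad <- vapply(seq_len(nrow(df)), function(i)
    .cigar_query_len(df$cigar[i]) != nchar(df$seq[i]), logical(1))
  if (any(bad))
    stop("CIGAR/sequence length mismatch for read(s): ",
         paste(utils::head(df$qname[bad], 3L), collapse = ", "), call. = FALSE)
  neg <- df$strand == "-"
  df$seq[neg] <- revcomp(df$seq[neg])
  dropped <- n0 - nrow(df)
  message(sprintf("read_sam: kept %d records, dropped %d", nrow(df), dropped))
  rownames(df) <- NULL
  attr(df, "dropped") <- dropped
  df
}

#' Write called cleavage sites as BED6
#'
#' Internal 1-based positions are converted to BED's 0-based half-open
#' single-base intervals at this boundary; the score column carries pooled
#' read support.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based), `gene_id`,
#'   `support_pooled`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cs_bed <- function(sites, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(sites) == 0L) { writeLines(character(0), con); return(invisible(path)) }
  name <- if (!is.null(sites$site_id)) sites$site_id
          else sprintf("%s_cs%d", sites$gene_id, seq_len(nrow(sites)))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$chrom,
                     sites$pos - 1L, sites$pos, name,
                     as.integer(sites$support_pooled), sites$strand),
             con, sep = "\n")
  invisible(path)
}

#' Read a BED6 cleavage-site file back into 1-based site coordinates
#'
#' @param path BED6 file written by [write_cs_bed()].
#' @return data.frame with `chrom`, `pos` (1-based), `site_id`,
#'   `support_pooled`, `strand`.
#' @export
read_cs_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      site_id = character(0), support_pooled = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start0", "end0", "site_id",
                                       "score", "strand"))
  data.frame(chrom = b$chrom, pos = b$start0 + 1L, site_id = b$site_id,
             support_pooled = b$score, strand = b$strand,
             stringsAsFactors = FALSE)
}

#' Write a data.frame as a TSV file
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
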