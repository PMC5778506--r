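# The synthetic 3'-Seq generator: determinism, geometry validation,
# read-count conservation and the statistical structure of emitted reads.

small_cfg <- function(...) sim_config(n_genes = 4L, reads_per_utr = 50L,
                                      seed = 11L, ...)

test_that("invalid configurations are rejected", {
  expect_error(sim_config(utr_len = 100, n_cs_per_utr = 3, cs_spacing_true = 60),
               "do not fit")
  expect_error(sim_config(usage_props = list(a = c(0.6, 0.5))), "sum to 1")
  expect_error(sim_config(read_len = 8), "read_len")
  expect_error(sim_config(tail_len_range = c(10, 60), read_len = 50),
               "tail_len_range")
})

test_that("a single-CS config plants exactly one CS with the PAS 20 nt upstream", {
  cfg <- sim_config(n_genes = 1, n_cs_per_utr = 1, pas_offset = 20,
                    usage_props = list(a = 1, b = 1), seed = 3)
  sim <- simulate_transcriptome(cfg)
  expect_equal(nrow(sim$truth$cs), 1L)
  cs <- sim$truth$cs
  expect_equal(abs(cs$genomic_pos - cs$pas_end_genomic), 20L)
  # The planted hexamer reads AATAAA in transcript sense.
  g <- sim$genome[["chrS"]]
  hex <- as.character(Biostrings::subseq(g, cs$pas_end_genomic - 5L,
                                         cs$pas_end_genomic))
  expect_equal(hex, "AATAAA")
})

test_that("identical config and seed give byte-identical outputs", {
  run <- function() {
    cfg <- small_cfg(internal_priming_rate = 0.1)
    sim <- simulate_transcriptome(cfg)
    rr <- simulate_reads(sim, cfg)
    d <- tempfile(); dir.create(d)
    write_fasta(sim$genome, file.path(d, "g.fa"))
    write_gtf(sim$models, file.path(d, "g.gtf"))
    write_sam(rr$reads[[1]],
              stats::setNames(Biostrings::width(sim$genome), names(sim$genome)),
              file.path(d, "r.sam"))
    unname(tools::md5sum(file.path(d, c("g.fa", "g.gtf", "r.sam"))))
  }
  expect_identical(run(), run())
})

test_that("truth read counts are conserved against emitted SAM records", {
  cfg <- small_cfg(internal_priming_rate = 0.1)
  sim <- simulate_transcriptome(cfg)
  rr <- simulate_reads(sim, cfg)
  rc <- rr$truth$read_counts
  # Genuine reads per (gene, sample) sum to reads_per_utr.
  sums <- tapply(rc$count, list(rc$gene_id, rc$sample), sum)
  expect_true(all(sums == cfg$reads_per_utr))
  # Genuine + internal-priming reads equal the SAM record count per gene.
  for (smp in names(rr$reads)) {
    emitted <- table(sub(":.*", "", rr$reads[[smp]]$qname))
    ip <- rr$truth$ip_counts[rr$truth$ip_counts$sample == smp, ]
    for (g in names(emitted)) {
      expected <- cfg$reads_per_utr + sum(ip$n_ip[ip$gene_id == g])
      expect_equal(unname(emitted[[g]]), expected)
    }
  }
})

test_that("degenerate proportions put every read on the single CS", {
  cfg <- sim_config(n_genes = 1, n_cs_per_utr = 1, reads_per_utr = 100,
                    usage_props = list(a = 1), internal_priming_rate = 0,
                    seed = 5)
  rr <- simulate_reads(simulate_transcriptome(cfg), cfg)
  expect_equal(rr$truth$read_counts$count, 100L)
  expect_equal(nrow(rr$reads[[1]]), 100L)
  expect_false(any(grepl(":ip", rr$reads[[1]]$qname)))
})

test_that("empirical per-CS fractions follow the usage proportions", {
  n <- 10000L
  cfg <- sim_config(n_genes = 1, n_cs_per_utr = 2, reads_per_utr = n,
                    usage_props = list(a = c(0.7, 0.3)),
                    internal_priming_rate = 0, seed = 21)
  rr <- simulate_reads(simulate_transcriptome(cfg), cfg)
  frac <- rr$truth$read_counts$count[1] / n
  # binomial 99% CI around 0.7
  half <- qnorm(0.995) * sqrt(0.7 * 0.3 / n)
  expect_gt(frac, 0.7 - half)
  expect_lt(frac, 0.7 + half)
})

test_that("forced plus and minus strand simulations are mirror images", {
  cfg_p <- small_cfg(strands = "+", cs_jitter_sd = 0)
  cfg_m <- small_cfg(strands = "-", cs_jitter_sd = 0)
  sp <- simulate_transcriptome(cfg_p)
  sm <- simulate_transcriptome(cfg_m)
  # Same transcript-local CS positions; genomic coordinates mirrored within
  # the gene span.
  expect_equal(sp$truth$cs$tx_pos, sm$truth$cs$tx_pos)
  gs <- sm$truth$gene_start[sm$truth$cs$gene_id]
  gl <- sm$truth$gene_len[sm$truth$cs$gene_id]
  expect_equal(sm$truth$cs$genomic_pos,
               as.integer(gs + gl - sm$truth$cs$tx_pos))
})

test_that("auxiliary matrices carry recoverable planted truth", {
  aux <- simulate_aux_matrices(seed = 9)
  expect_equal(dim(aux$ipms$log2_ref), dim(aux$ipms$log2_ctl))
  expect_true(all(aux$rnaseq$gene_lengths > 0))
  # All-equal expression gives fold-change 0 after flooring.
  fc <- log2_fold_change(rep(5, 3), rep(5, 3))
  expect_equal(fc, rep(0, 3))
})
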