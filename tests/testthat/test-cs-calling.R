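# CS profiles, greedy site selection under support/spacing rules,
# genomic-category priority and per-sample quantification.

test_that("CS profiles are exact histograms of tail calls", {
  tc <- data.frame(gene_id = "g1", cleavage_pos = c(100L, 100L, 100L, 140L),
                   sample = "s1", stringsAsFactors = FALSE)
  prof <- build_cs_profile(tc, "g1")
  expect_equal(prof, data.frame(pos = c(100L, 140L), count = c(3L, 1L)))
  expect_equal(sum(prof$count), nrow(tc))
  expect_equal(nrow(build_cs_profile(tc, "absent")), 0L)
})

test_that("close peaks collapse to the stronger site; distant peaks both survive", {
  p1 <- data.frame(pos = c(100L, 130L), count = c(30L, 20L))
  s1 <- select_cleavage_sites(p1, "+")
  expect_equal(s1$pos, 100L)
  p2 <- data.frame(pos = c(100L, 160L), count = c(30L, 20L))
  s2 <- select_cleavage_sites(p2, "+")
  expect_equal(s2$pos, c(100L, 160L))
  expect_equal(s2$support, c(30L, 20L))
})

test_that("sites supported by fewer than ten reads are not called", {
  p <- data.frame(pos = 100L, count = 9L)
  expect_equal(nrow(select_cleavage_sites(p, "+", min_support = 10)), 0L)
  expect_equal(nrow(select_cleavage_sites(p, "+", min_support = 9)), 1L)
})

test_that("greedy selection matches the brute-force oracle on random profiles", {
  set.seed(42)
  for (i in 1:300) {
    strand <- sample(c("+", "-"), 1)
    prof <- random_profile(npos = sample(3:15, 1))
    got <- select_cleavage_sites(prof, strand)
    want <- oracle_select(prof, strand)
    expect_equal(got$pos, want$pos)
    expect_equal(got$support, want$support)
    # Spacing invariant.
    if (nrow(got) > 1) expect_true(min(diff(got$pos)) >= 50)
  }
})

test_that("every strong rejected candidate is dominated by a nearby accepted site", {
  set.seed(7)
  for (i in 1:50) {
    prof <- random_profile(npos = 12)
    got <- select_cleavage_sites(prof, "+", min_support = 10)
    if (nrow(got) == 0) next
    agg_support <- stats::setNames(got$support, got$pos)
    rejected <- prof[!prof$pos %in% got$pos & prof$count >= 10, , drop = FALSE]
    for (j in seq_len(nrow(rejected))) {
      d <- abs(got$pos - rejected$pos[j])
      expect_true(any(d < 50 & got$support >= rejected$count[j]) || all(d >= 50))
    }
  }
})

test_that("genomic categories follow the documented priority", {
  # Gene A (+): 3'UTR 400-500. Gene B (+): exons 100-450 and 600-700, so
  # 451-599 is intron; 420 lies in both A's 3'UTR and B's intron.
  gr <- function(s, e, g) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                                 strand = "+", gene_id = g)
  models <- structure(list(
    genes = c(gr(100, 500, "A"), gr(100, 700, "B")),
    exons = c(gr(100, 500, "A"), gr(100, 450, "B"), gr(600, 700, "B")),
    cds = gr(200, 399, "A"), utr5 = gr(100, 199, "A"),
    utr3 = gr(400, 500, "A"), introns = gr(451, 599, "B")),
    class = "gene_models")
  sites <- data.frame(chrom = "chr1", pos = c(420L, 550L, 300L, 150L, 900L, 5000L),
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(assign_genomic_category(sites, models),
               c("3UTR", "intron", "CDS", "5UTR", "downstream_extension",
                 "intergenic"))
})

test_that("tail calls are quantified to the nearest site within the window", {
  sites <- data.frame(gene_id = "g1", pos = c(100L, 140L), strand = "+",
                      stringsAsFactors = FALSE)
  tc <- data.frame(gene_id = "g1", strand = "+", sample = "s1",
                   cleavage_pos = c(105L, 133L, 120L),
                   stringsAsFactors = FALSE)
  q <- quantify_cs(tc, sites, samples = "s1", window = 25L)
  # 105 -> site 100 (d=5); 133 -> site 140 (d=7); 120 -> equidistant (d=20),
  # tie goes to the more proximal site 100.
  expect_equal(unname(q$counts[, "s1"]), c(2L, 1L))
  expect_equal(q$unassigned, 0L)
  far <- data.frame(gene_id = "g1", strand = "+", sample = "s1",
                    cleavage_pos = 140L, stringsAsFactors = FALSE)
  q2 <- quantify_cs(far, sites[1, , drop = FALSE], samples = "s1",
                    window = 25L)
  expect_equal(q2$unassigned, 1L)   # 40 nt from the only site
})

test_that("no CS is called at planted templated A-tracts", {
  cfg <- sim_config(n_genes = 8, internal_priming_rate = 0.2, seed = 13)
  sim <- simulate_transcriptome(cfg)
  rr <- simulate_reads(sim, cfg)
  reads <- do.call(rbind, lapply(names(rr$reads), function(s) {
    df <- rr$reads[[s]]; df$sample <- s
    df$seq[df$strand == "-"] <- revcomp_chr(df$seq[df$strand == "-"])
    df
  }))
  tc <- detect_tails(reads, sim$genome)
  dec <- rr$truth$decoys
  expect_gt(nrow(dec), 0)
  for (i in seq_len(nrow(dec)))
    expect_false(any(tc$cleavage_pos >= dec$genomic_start[i] - 12 &
                     tc$cleavage_pos <= dec$genomic_end[i] + 1 &
                     tc$chrom == dec$chrom[i]))
})

test_that("minus-strand genes recover the same CSs as mirrored plus genes", {
  run_strand <- function(st) {
    cfg <- sim_config(n_genes = 6, strands = st, seed = 17,
                      internal_priming_rate = 0)
    sim <- simulate_transcriptome(cfg)
    rr <- simulate_reads(sim, cfg)
    reads <- do.call(rbind, lapply(names(rr$reads), function(s) {
      df <- rr$reads[[s]]; df$sample <- s
      df$seq[df$strand == "-"] <- revcomp_chr(df$seq[df$strand == "-"])
      df
    }))
    res <- call_cleavage_sites(reads, sim$genome, sim$models)
    merged <- merge(res$sites, sim$truth$cs,
                    by.x = c("gene_id", "pos"),
                    by.y = c("gene_id", "genomic_pos"))
    sort(table(res$sites$gene_id))
  }
  expect_equal(unname(run_strand("+")), unname(run_strand("-")))
})
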