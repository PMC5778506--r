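#' Run the simulate -> call -> test -> report pipeline end to end
#'
#' Executes the full synthetic-data smoke path: simulate a transcriptome
#' and aligned 3'-Seq reads, write them as FASTA/GTF/SAM, read everything
#' back through the standard-format readers, detect untemplated tails, call
#' and quantify cleavage sites, build the PAS positional profile, test
#' every multi-CS 3'UTR for differential usage and assess the global
#' proximal/distal trend — then score the calls against the simulation's
#' ground truth. All outputs (including `report.json` and a `manifest.json`
#' of parameters and input digests) are written under `out_dir`.
#' `report.json` is byte-identical across runs with the same config.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if needed).
#' @param fdr FDR threshold for the differential-usage calls (default 0.05,
#'   i.e. FDR < 5 percent).
#' @param downstream,min_support,min_spacing,window CS-calling parameters,
#'   see [call_cleavage_sites()].
#' @return the report, an invisible named list (also written as JSON).
#' @export
run_end_to_end <- function(config, out_dir = tempfile("apaseq_run_"),
                           fdr = 0.05, min_support = 10L, min_spacing = 50L,
                           window = 25L, downstream = 1000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- stage("simulate", {
    s <- simulate_transcriptome(config)
    rr <- simulate_reads(s, config)
    write_fasta(s$genome, file.path(out_dir, "genome.fa"))
    write_gtf(s$models, file.path(out_dir, "genes.gtf"))
    for (smp in names(rr$reads))
      write_sam(rr$reads[[smp]],
                stats::setNames(Biostrings::width(s$genome), names(s$genome)),
                file.path(out_dir, sprintf("reads_%s.sam", smp)))
    write_tsv(rr$truth$cs, file.path(out_dir, "truth_cs.tsv"))
    write_tsv(rr$truth$read_counts, file.path(out_dir, "truth_usage.tsv"))
    list(s = s, rr = rr)
  })
  truth <- sim$rr$truth

  inputs <- stage("load", {
    genome <- read_fasta(file.path(out_dir, "genome.fa"))
    models <- read_gtf(file.path(out_dir, "genes.gtf"))
    reads <- do.call(rbind, lapply(names(sim$rr$reads), function(smp) {
      df <- suppressMessages(read_sam(file.path(out_dir,
                                                sprintf("reads_%s.sam", smp))))
      df$sample <- smp
      df
    }))
    list(genome = genome, models = models, reads = reads)
  })

  cs <- stage("call-cs", {
    res <- call_cleavage_sites(inputs$reads, inputs$genome, inputs$models,
                               min_support = min_support,
                               min_spacing = min_spacing, window = window,
                               downstream = downstream)
    write_cs_bed(res$sites, file.path(out_dir, "cs_sites.bed"))
    write_tsv(cbind(res$sites, as.data.frame(res$counts)),
              file.path(out_dir, "cs_counts.tsv"))
    res
  })

  pas <- stage("pas-profile", {
    if (nrow(cs$sites) == 0L) NULL
    else {
      pp <- pas_positional_profile(cs$sites, inputs$genome)
      write_tsv(pp$profile, file.path(out_dir, "pas_profile.tsv"))
      pp
    }
  })

  apa <- stage("apa-test", {
    condition_map <- stats::setNames(sim$rr$samples$condition,
                                     sim$rr$samples$sample)
    tables <- build_utr_tables(cs$sites, cs$counts, condition_map)
    conds <- unique(sim$rr$samples$condition)
    if (length(tables) && length(conds) >= 2L) {
      res <- apa_test(tables, conds[1], conds[2])
      trend <- global_trend_test(res, fdr = fdr)
      write_tsv(res, file.path(out_dir, "apa_results.tsv"))
      list(tables = tables, results = res, trend = trend)
    } else list(tables = tables, results = NULL, trend = NULL)
  })

  # Recovery against ground truth: a planted CS is recovered when a site of
  # the same gene is called within +/-2 nt; decoy check: no called site may
  # fall inside a planted templated A-tract.
  recov <- vapply(seq_len(nrow(truth$cs)), function(i) {
    hits <- cs$sites$pos[cs$sites$gene_id == truth$cs$gene_id[i]]
    if (!length(hits)) return(NA_real_)
    d <- min(abs(hits - truth$cs$genomic_pos[i]))
    if (d <= 2) d else NA_real_
  }, numeric(1))
  n_at_decoy <- if (nrow(truth$decoys)) sum(vapply(seq_len(nrow(cs$sites)),
    function(i) any(cs$sites$pos[i] >= truth$decoys$genomic_start &
                    cs$sites$pos[i] <= truth$decoys$genomic_end &
                    cs$sites$gene_id[i] == truth$decoys$gene_id),
    logical(1))) else 0L

  cat_tab <- table(factor(cs$sites$category,
                          levels = c("3UTR", "CDS", "5UTR", "intron",
                                     "downstream_extension", "intergenic")))
  report <- list(
    n_genes = config$n_genes,
    n_reads_total = nrow(inputs$reads),
    n_tailcalls = nrow(cs$tailcalls),
    n_cs_called = nrow(cs$sites),
    category_distribution = as.list(cat_tab),
    prop_cs_3utr = if (nrow(cs$sites)) unname(cat_tab[["3UTR"]] / nrow(cs$sites))
                   else NA_real_,
    pas_modal_offset = if (!is.null(pas)) pas$modal_offset else NA_integer_,
    pas_frac_sites_with_motif = if (!is.null(pas)) pas$frac_sites_with_motif
                                else NA_real_,
    n_multi_cs_utrs = length(apa$tables),
    n_significant = if (!is.null(apa$trend)) apa$trend$n_significant else NA_integer_,
    n_enhanced = if (!is.null(apa$trend)) apa$trend$n_enhanced else NA_integer_,
    n_reduced = if (!is.null(apa$trend)) apa$trend$n_reduced else NA_integer_,
    binomial_p_vs_half = if (!is.null(apa$trend)) apa$trend$binomial_p_vs_half
                         else NA_real_,
    paired_pui_test_p = if (!is.null(apa$trend)) apa$trend$paired_pui_test_p
                        else NA_real_,
    cs_recovery_rate = mean(!is.na(recov)),
    mean_abs_cs_error = if (any(!is.na(recov))) mean(recov, na.rm = TRUE)
                        else NA_real_,
    n_sites_at_decoys = n_at_decoy,
    unassigned_tailcalls = cs$unassigned,
    seed = config$seed)

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  writeLines(json, file.path(out_dir, "report.json"), sep = "\n")
  .write_manifest(out_dir, config,
                  files = c("genome.fa", "genes.gtf", "report.json"))
  invisible(report)
}

# One manifest per output directory: tool version, parameters, seed and
# input digests.
.write_manifest <- function(out_dir, config, files) {
  paths <- file.path(out_dir, files)
  manifest <- list(
    tool = "apaseq",
    version = as.character(utils::packageVersion("apaseq")),
    subcommand = "run-all",
    seed = config$seed,
    parameters = config[setdiff(names(config), "usage_props")],
    usage_props = lapply(config$usage_props, function(m) unname(m[1, ])),
    digests = as.list(tools::md5sum(paths[file.exists(paths)])),
    timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(NULL)
}
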