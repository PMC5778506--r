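#' Simulate auxiliary RNA-seq and IP-MS matrices with planted truth
#'
#' Generates (i) a gene x sample RNA-seq count matrix with gene lengths and
#' planted per-gene expression fold-changes between a control and a treated
#' sample, and (ii) a pair of protein x replicate log2-intensity matrices
#' (reference and control pulldown) with a planted interactor set whose
#' log2 difference exceeds 1 in all replicates. Ground truth (planted
#' fold-changes and interactors) is returned for parameter-recovery tests.
#'
#' @param n_genes number of genes (default 200).
#' @param n_proteins number of proteins (default 100).
#' @param n_reps IP-MS replicates (default 3).
#' @param frac_fc fraction of genes with a planted expression change
#'   (default 0.1).
#' @param planted_log2fc log2 fold-change planted in changed genes
#'   (default 2).
#' @param frac_interactors fraction of proteins planted as interactors
#'   (default 0.1).
#' @param interactor_shift planted log2 intensity difference for
#'   interactors (default 2).
#' @param noise_sd replicate noise sd on log2 intensities (default 0.2).
#' @param seed integer seed.
#' @return list with `rnaseq` (list: `counts`, `gene_lengths`,
#'   `fc_genes`) and `ipms` (list: `log2_ref`, `log2_ctl`, `interactors`).
#' @export
simulate_aux_matrices <- function(n_genes = 200L, n_proteins = 100L,
                                  n_reps = 3L, frac_fc = 0.1,
                                  planted_log2fc = 2,
                                  frac_interactors = 0.1,
                                  interactor_shift = 2, noise_sd = 0.2,
                                  seed = 1L) {
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  lens <- sample(500:5000, n_genes, replace = TRUE)
  base_expr <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 1)
  fc_genes <- sort(sample(gene_ids, round(frac_fc * n_genes)))
  lfc <- stats::setNames(rep(0, n_genes), gene_ids)
  lfc[fc_genes] <- planted_log2fc
  mu_ctl <- base_expr * lens / 1e3
  mu_trt <- mu_ctl * 2^lfc
  counts <- cbind(control = stats::rpois(n_genes, mu_ctl),
                  treated = stats::rpois(n_genes, mu_trt))
  rownames(counts) <- gene_ids

  prot_ids <- sprintf("P%04d", seq_len(n_proteins))
  interactors <- sort(sample(prot_ids, round(frac_interactors * n_proteins)))
  base_int <- stats::rnorm(n_proteins, 25, 2)
  shift <- stats::setNames(rep(0, n_proteins), prot_ids)
  shift[interactors] <- interactor_shift
  noise <- function() stats::rnorm(n_proteins * n_reps, 0, noise_sd)
  log2_ctl <- matrix(base_int, n_proteins, n_reps) + noise()
  log2_ref <- matrix(base_int + shift, n_proteins, n_reps) + noise()
  dimnames(log2_ctl) <- dimnames(log2_ref) <-
    list(prot_ids, paste0("rep", seq_len(n_reps)))

  list(rnaseq = list(counts = counts,
                     gene_lengths = stats::setNames(lens, gene_ids),
                     fc_genes = fc_genes,
                     planted_log2fc = planted_log2fc),
       ipms = list(log2_ref = log2_ref, log2_ctl = log2_ctl,
                   interactors = interactors))
}
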