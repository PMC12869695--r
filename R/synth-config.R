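#' Configuration for the synthetic drug-combination world
#'
#' The synthetic world is a pathway-structured generative model that stands in
#' for the real multi-omic inputs of a combination screen: genes are
#' partitioned into pathways, a protein-protein interaction (PPI) network is
#' denser within pathways than between them, each drug targets a few genes of
#' one pathway, and each sample (cell line or tumor) has a binary activity
#' state per pathway that drives its expression. Synergy is planted by a known
#' rule: a drug pair is synergistic in a sample when the two drugs target
#' *different* pathways and *both* pathways are active in that sample — a
#' signal that depends jointly on both drugs and the sample, so that
#' leave-drug-out generalization is a genuine test.
#'
#' @param n_pathways Number of pathways.
#' @param genes_per_pathway Genes per pathway; `n_genes = n_pathways *
#'   genes_per_pathway`.
#' @param n_samples Number of samples (cell lines / tumors).
#' @param n_drugs Number of drugs.
#' @param targets_per_drug Distinct target genes per drug, drawn from the
#'   drug's pathway.
#' @param ppi_p_within,ppi_p_between Edge probabilities inside / across
#'   pathways.
#' @param expr_baseline,expr_activity_effect,expr_noise_sd Expression model
#'   parameters on the log2(TPM+1) scale: `expr = baseline + effect *
#'   activity + N(0, noise_sd)`.
#' @param activity_prob Bernoulli probability that a pathway is active in a
#'   sample.
#' @param mutation_rate Per-gene background mutation probability.
#' @param sentinel_mutations If `TRUE`, the first gene of each pathway carries
#'   the pathway's activity state as its mutation status, making the mutation
#'   modality informative; by default mutations are independent noise.
#' @param dose_grid Ordered concentrations in micromolar, first element 0.
#'   Default is 0 plus five half-log steps (a 6x6 checkerboard).
#' @param synergy_bump_max Planted synergy amplitude (`%` inhibition) at the
#'   central well of the checkerboard.
#' @param response_noise_sd Well-level measurement noise (`%` inhibition).
#' @param potency_shift Fold-reduction of a drug's EC50 in samples where its
#'   pathway is active (active pathway = more potent drug).
#' @param seed Integer seed; the whole world is a pure function of the
#'   configuration including this seed.
#'
#' @return A `synth_config` list, validated against its invariants.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$n_genes
synth_config <- function(n_pathways = 12,
                         genes_per_pathway = 20,
                         n_samples = 40,
                         n_drugs = 30,
                         targets_per_drug = 3,
                         ppi_p_within = 0.3,
                         ppi_p_between = 0.01,
                         expr_baseline = 5,
                         expr_activity_effect = 2,
                         expr_noise_sd = 0.5,
                         activity_prob = 0.5,
                         mutation_rate = 0.05,
                         sentinel_mutations = FALSE,
                         dose_grid = c(0, 10^seq(-1, 1, by = 0.5)),
                         synergy_bump_max = 25,
                         response_noise_sd = 3,
                         potency_shift = 3,
                         seed = 1) {
  cfg <- list(
    n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
    n_genes = n_pathways * genes_per_pathway,
    n_samples = n_samples, n_drugs = n_drugs,
    targets_per_drug = targets_per_drug,
    ppi_p_within = ppi_p_within, ppi_p_between = ppi_p_between,
    expr_baseline = expr_baseline,
    expr_activity_effect = expr_activity_effect,
    expr_noise_sd = expr_noise_sd,
    activity_prob = activity_prob,
    mutation_rate = mutation_rate,
    sentinel_mutations = isTRUE(sentinel_mutations),
    dose_grid = as.numeric(dose_grid),
    synergy_bump_max = synergy_bump_max,
    response_noise_sd = response_noise_sd,
    potency_shift = potency_shift,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  for (fld in c("n_pathways", "genes_per_pathway", "n_samples", "n_drugs",
                "targets_per_drug")) {
    if (!is_count(cfg[[fld]])) {
      stopf("combisyn_config_error", "invalid config: `%s` must be a positive integer", fld)
    }
  }
  if (cfg$n_genes != cfg$n_pathways * cfg$genes_per_pathway) {
    stopf("combisyn_config_error",
          "invalid config: n_genes must equal n_pathways * genes_per_pathway")
  }
  if (cfg$targets_per_drug > cfg$genes_per_pathway) {
    stopf("combisyn_config_error",
          "invalid config: targets_per_drug exceeds genes_per_pathway")
  }
  for (fld in c("ppi_p_within", "ppi_p_between", "activity_prob", "mutation_rate")) {
    if (!is_prob(cfg[[fld]])) {
      stopf("combisyn_config_error", "invalid config: `%s` must be a probability in [0,1]", fld)
    }
  }
  dg <- cfg$dose_grid
  if (length(dg) < 2 || dg[1] != 0 || any(diff(dg) <= 0)) {
    stopf("combisyn_config_error",
          "invalid config: dose_grid must be strictly increasing with dose_grid[1] = 0")
  }
  if (!is.numeric(cfg$synergy_bump_max) || cfg$synergy_bump_max < 0) {
    stopf("combisyn_config_error", "invalid config: synergy_bump_max must be >= 0")
  }
  if (!is.numeric(cfg$response_noise_sd) || cfg$response_noise_sd < 0) {
    stopf("combisyn_config_error", "invalid config: response_noise_sd must be >= 0")
  }
  if (!is.numeric(cfg$expr_noise_sd) || cfg$expr_noise_sd < 0) {
    stopf("combisyn_config_error", "invalid config: expr_noise_sd must be >= 0")
  }
  if (!is.numeric(cfg$potency_shift) || cfg$potency_shift < 1) {
    stopf("combisyn_config_error", "invalid config: potency_shift must be >= 1")
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>",
      sprintf("%d genes in %d pathways x %d; %d samples, %d drugs (%d targets each)",
              x$n_genes, x$n_pathways, x$genes_per_pathway,
              x$n_samples, x$n_drugs, x$targets_per_drug),
      sprintf("dose grid: %s uM; bump %.1f%%, noise sd %.1f%%; seed %d",
              paste(signif(x$dose_grid, 3), collapse = ", "),
              x$synergy_bump_max, x$response_noise_sd, x$seed),
      sep = "\n")
  invisible(x)
}
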