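# Synthetic world generation: pathways, PPI, drugs, samples, expression,
# mutations, and the planted synergy rule.

# Fixed fragment table for deterministic, mutually distinct synthetic drug
# structures. These only need to parse as valid molecules and be pairwise
# different; they are deliberately uninformative about the planted synergy
# rule (which lives in the drug-target assignments, not the chemistry).
synth_smiles_table <- function() {
  c(
    "CCO", "CCN", "CCC", "CC(C)O", "CC(C)N", "CC(=O)O", "CC(=O)N",
    "CCOC", "CCCO", "CCCN", "CC(C)C", "CCOCC", "CC(=O)OC", "CC(=O)NC",
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
    "COc1ccccc1", "CC(=O)c1ccccc1", "OCc1ccccc1", "NCc1ccccc1",
    "Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1", "CCCl", "CCS", "CCSC",
    "C1CCCCC1", "CCBr", "CCCS", "OC1CCCCC1", "NC1CCCCC1",
    "CC1CCCCC1", "O=C1CCCCC1", "CCCCO", "CCCCN", "CCCCC", "CC(O)CO",
    "OCCO", "NCCN", "OCCN", "CC(C)(C)O", "CC(C)(C)C", "CCC(=O)O",
    "CCCC(=O)O", "CCOC(C)=O"
  )
}

# Deterministic SMILES for drug index i (1-based): curated table first, then
# distinct alcohol homologues of growing chain length.
synth_drug_smiles <- function(i) {
  tab <- synth_smiles_table()
  vapply(i, function(k) {
    if (k <= length(tab)) tab[[k]] else paste0(strrep("C", k - length(tab) + 4), "O")
  }, character(1))
}

#' Generate a synthetic drug-combination world
#'
#' Builds the full generative state described in [synth_config()]: a gene ->
#' pathway partition, a weighted PPI edge list sampled with `ppi_p_within`
#' inside pathways and `ppi_p_between` across, drugs each assigned one pathway
#' and `targets_per_drug` distinct target genes from it, a binary
#' sample-by-pathway activity matrix, a sample-by-gene expression matrix, an
#' (by default uninformative) binary mutation matrix, and per-drug monotherapy
#' Hill parameters. The planted synergy strength for a triplet is
#' `synergy_bump_max` when the two drugs sit in different pathways and both
#' pathways are active in the sample, else 0. Everything is a pure function of
#' the configuration (including its seed).
#'
#' @param cfg A [synth_config()].
#' @return A `synth_world` list with elements `cfg`, `genes` (tibble: gene,
#'   pathway), `ppi` (tibble: protein_a, protein_b, score in (0,1]), `drugs`
#'   (tibble: drug_id, pathway, smiles, e_max, h, ec50), `targets` (tibble:
#'   drug_id, gene), `activity` (samples x pathways, 0/1), `expression`
#'   (samples x genes, log2(TPM+1) scale), `mutation` (samples x genes, 0/1).
#' @export
#' @examples
#' w <- synth_world(synth_config(n_pathways = 3, genes_per_pathway = 4,
#'                               n_samples = 6, n_drugs = 5, seed = 1))
#' head(w$genes)
synth_world <- function(cfg) {
  validate_synth_config(cfg)
  with_seed(derive_seed(cfg$seed, "world"), {
    P <- cfg$n_pathways
    G <- cfg$n_genes
    genes <- sprintf("g%03d", seq_len(G))
    pathways <- sprintf("pw%02d", seq_len(P))
    pathway_of_gene <- rep(pathways, each = cfg$genes_per_pathway)
    names(pathway_of_gene) <- genes

    # PPI: Bernoulli edges over all gene pairs, block structure by pathway.
    pairs <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
    same <- pathway_of_gene[pairs[, 1]] == pathway_of_gene[pairs[, 2]]
    p_edge <- ifelse(same, cfg$ppi_p_within, cfg$ppi_p_between)
    keep <- runif(nrow(pairs)) < p_edge
    score <- ifelse(same[keep], runif(sum(keep), 0.6, 1.0),
                    runif(sum(keep), 0.15, 0.85))
    ppi <- tibble(
      protein_a = genes[pairs[keep, 1]],
      protein_b = genes[pairs[keep, 2]],
      score = score
    )

    drug_ids <- sprintf("D%02d", seq_len(cfg$n_drugs))
    drug_pathway <- sample(pathways, cfg$n_drugs, replace = TRUE)
    targets <- purrr::map2_dfr(drug_ids, drug_pathway, function(d, pw) {
      pool <- genes[pathway_of_gene == pw]
      tibble(drug_id = d, gene = sort(sample(pool, cfg$targets_per_drug)))
    })

    # Monotherapy Hill parameters, one draw per drug: E_max in [80,100]%,
    # slope in [1,2]. EC50 is log-uniform over the upper interior of the dose
    # grid (from potency_shift times the central dose up to the top dose) so
    # that the potency shift in active-pathway samples moves the EC50 into
    # the middle of the grid and the planted bump at the central well is
    # never saturated by the 100% response ceiling.
    dgi <- cfg$dose_grid[cfg$dose_grid > 0]
    d_center <- cfg$dose_grid[central_dose_index(cfg$dose_grid)]
    ec50_lo <- min(cfg$potency_shift * d_center, max(dgi) / 2)
    drugs <- tibble(
      drug_id = drug_ids,
      pathway = drug_pathway,
      smiles = synth_drug_smiles(seq_len(cfg$n_drugs)),
      e_max = runif(cfg$n_drugs, 80, 100),
      h = runif(cfg$n_drugs, 1, 2),
      ec50 = exp(runif(cfg$n_drugs, log(ec50_lo), log(max(dgi))))
    )

    sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
    activity <- matrix(rbinom(cfg$n_samples * P, 1, cfg$activity_prob),
                       nrow = cfg$n_samples,
                       dimnames = list(sample_ids, pathways))

    act_of_gene <- activity[, pathway_of_gene, drop = FALSE]
    expression <- cfg$expr_baseline + cfg$expr_activity_effect * act_of_gene +
      matrix(rnorm(cfg$n_samples * G, 0, cfg$expr_noise_sd),
             nrow = cfg$n_samples)
    dimnames(expression) <- list(sample_ids, genes)

    mutation <- matrix(rbinom(cfg$n_samples * G, 1, cfg$mutation_rate),
                       nrow = cfg$n_samples,
                       dimnames = list(sample_ids, genes))
    if (cfg$sentinel_mutations) {
      sentinel <- genes[match(pathways, pathway_of_gene)]
      mutation[, sentinel] <- activity[, pathways]
    }

    structure(
      list(cfg = cfg,
           genes = tibble(gene = genes, pathway = pathway_of_gene),
           ppi = ppi,
           drugs = drugs,
           targets = targets,
           activity = activity,
           expression = expression,
           mutation = mutation),
      class = "synth_world")
  })
}

#' @export
print.synth_world <- function(x, ...) {
  cat("<synth_world>",
      sprintf("%d genes / %d pathways, %d PPI edges, %d drugs, %d samples",
              nrow(x$genes), x$cfg$n_pathways, nrow(x$ppi),
              nrow(x$drugs), nrow(x$activity)),
      sep = "\n")
  invisible(x)
}

#' Planted synergy strength of drug-pair x sample triplets
#'
#' The planted rule: strength = `synergy_bump_max` when the two drugs target
#' different pathways and both pathways are active in the sample, else 0.
#' Symmetric in the drug pair and always non-negative.
#'
#' @param world A [synth_world()].
#' @param drug_a,drug_b,sample_id Vectors of ids (recycled to common length).
#' @return Numeric vector of synergy strengths (% inhibition).
#' @export
synth_truth_strength <- function(world, drug_a, drug_b, sample_id) {
  n <- max(length(drug_a), length(drug_b), length(sample_id))
  drug_a <- rep_len(drug_a, n); drug_b <- rep_len(drug_b, n)
  sample_id <- rep_len(sample_id, n)
  pw <- setNames(world$drugs$pathway, world$drugs$drug_id)
  pa <- pw[drug_a]; pb <- pw[drug_b]
  if (anyNA(pa) || anyNA(pb)) {
    bad <- unique(c(drug_a[is.na(pa)], drug_b[is.na(pb)]))
    stopf("combisyn_lookup_error", "unknown drug id(s): %s",
          paste(bad, collapse = ", "))
  }
  if (!all(sample_id %in% rownames(world$activity))) {
    stopf("combisyn_lookup_error", "unknown sample id(s): %s",
          paste(setdiff(sample_id, rownames(world$activity)), collapse = ", "))
  }
  act_a <- world$activity[cbind(sample_id, pa)]
  act_b <- world$activity[cbind(sample_id, pb)]
  world$cfg$synergy_bump_max * as.numeric(pa != pb & act_a == 1 & act_b == 1)
}

#' Enumerate all triplets of a synthetic world with their planted truth
#'
#' @param world A [synth_world()].
#' @return Tibble with `drug_a`, `drug_b` (canonical order), `sample_id`,
#'   `truth` (% inhibition) and `label` (1 if truth > 0).
#' @export
synth_truth <- function(world) {
  ids <- world$drugs$drug_id
  prs <- t(combn(ids, 2))
  out <- tidyr::expand_grid(
    pair = seq_len(nrow(prs)),
    sample_id = rownames(world$activity)
  )
  out <- tibble(
    drug_a = prs[out$pair, 1],
    drug_b = prs[out$pair, 2],
    sample_id = out$sample_id
  )
  out$truth <- synth_truth_strength(world, out$drug_a, out$drug_b, out$sample_id)
  out$label <- as.integer(out$truth > 0)
  out
}

#' Sample a triplet table from a synthetic world
#'
#' Draws `n` distinct (drug pair, sample) triplets uniformly at random with
#' their planted synergy strength and binary label — the synthetic analogue of
#' a curated screen triplet table.
#'
#' @param world A [synth_world()].
#' @param n Number of triplets (capped at the total number available).
#' @param seed Integer seed.
#' @return Tibble: `drug_a`, `drug_b`, `sample_id`, `truth`, `label`.
#' @export
synth_triplets <- function(world, n = 4000, seed = world$cfg$seed) {
  all <- synth_truth(world)
  n <- min(n, nrow(all))
  with_seed(derive_seed(seed, "triplets"), {
    all[sort(sample.int(nrow(all), n)), , drop = FALSE]
  })
}
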