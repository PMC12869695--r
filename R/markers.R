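# Marker-gene selection and binary mutation profiles.

#' Select marker genes for the expression branch
#'
#' Union of four sources with provenance tags: (i) a landmark gene list;
#' (ii) the top `variable_frac` of genes by expression variance; (iii) the
#' top `hub_n` genes by degree in the PPI restricted to high-confidence edges
#' (`score > score_threshold` on the 0-1 scale, i.e. > 700 on a 0-1000 file);
#' (iv) the drug-target universe. Deduplicated, sorted (deterministic order),
#' each gene tagged with every source that selected it.
#'
#' @param expression Sample x gene matrix (log2(TPM+1) scale), >= 2 samples.
#' @param landmark Character vector of landmark genes.
#' @param ppi PPI edge tibble (`protein_a`, `protein_b`, `score`).
#' @param dti_universe Character vector of drug-target genes.
#' @param variable_frac Fraction of most-variable genes to take (default 0.15).
#' @param hub_n Number of top-degree hub genes (default 1000, capped at the
#'   gene count).
#' @param score_threshold High-confidence edge cutoff on the 0-1 score scale.
#' @return A tibble (`marker_gene_set`): `gene` plus logical provenance
#'   columns `landmark`, `variable`, `hub`, `target`.
#' @export
select_marker_genes <- function(expression, landmark = character(),
                                ppi = NULL, dti_universe = character(),
                                variable_frac = 0.15, hub_n = 1000,
                                score_threshold = 0.7) {
  if (nrow(expression) < 2) {
    stopf("combisyn_config_error",
          "marker selection needs >= 2 samples, got %d", nrow(expression))
  }
  genes <- colnames(expression)

  variable <- character(0)
  if (length(genes) > 0 && variable_frac > 0) {
    v <- apply(expression, 2, var)
    n_var <- ceiling(variable_frac * length(genes))
    variable <- genes[order(-v, genes)][seq_len(n_var)]
  }

  hubs <- character(0)
  if (!is.null(ppi) && nrow(ppi)) {
    score <- ppi$score %||% rep(1, nrow(ppi))
    if (max(score) > 1.5) score <- score / 1000
    strong <- ppi[score > score_threshold, , drop = FALSE]
    if (nrow(strong)) {
      deg <- table(c(strong$protein_a, strong$protein_b))
      ids <- names(deg)
      n_hub <- min(hub_n, length(ids))
      hubs <- ids[order(-as.numeric(deg), ids)][seq_len(n_hub)]
    }
  }

  universe <- sort(unique(c(landmark, variable, hubs, dti_universe)))
  if (!length(universe)) {
    stopf("combisyn_config_error",
          "marker gene selection produced an empty union")
  }
  out <- tibble(
    gene = universe,
    landmark = universe %in% landmark,
    variable = universe %in% variable,
    hub = universe %in% hubs,
    target = universe %in% dti_universe
  )
  class(out) <- c("marker_gene_set", class(out))
  out
}

# The five qualifying nonsynonymous variant classes, normalized to
# lower-snake-case for matching.
MUTATION_CLASSES <- c("missense", "nonsense", "frameshift_insertion",
                      "frameshift_deletion", "splice_site")

normalize_variant_class <- function(x) {
  x <- tolower(gsub("[^[:alnum:]]+", "_", trimws(x)))
  x <- sub("_mutation$", "", x)
  x <- sub("^frame_shift", "frameshift", x)
  x <- sub("_ins$", "_insertion", x)
  x <- sub("_del$", "_deletion", x)
  x
}

#' Binary mutation profiles from variant calls
#'
#' A gene is 1 for a sample iff the sample has at least one call of a
#' qualifying nonsynonymous class (missense, nonsense, frameshift insertion
#' or deletion, splice site) in that gene; all other classes are ignored.
#' Unknown class strings are ignored with a warning, never fatal.
#'
#' @param calls Tibble with columns `sample_id`, `gene`, `variant_class`.
#' @param gene_set Genes forming the profile columns.
#' @param samples Sample ids forming the rows (default: those in `calls`).
#' @return Binary matrix samples x genes.
#' @export
mutation_profile <- function(calls, gene_set, samples = NULL) {
  samples <- samples %||% sort(unique(calls$sample_id))
  m <- matrix(0L, length(samples), length(gene_set),
              dimnames = list(samples, gene_set))
  if (nrow(calls)) {
    cls <- normalize_variant_class(calls$variant_class)
    qual <- cls %in% MUTATION_CLASSES
    known <- cls %in% c(MUTATION_CLASSES, "silent", "synonymous", "intron",
                        "utr_3", "utr_5", "igr", "rna", "nonstop")
    if (any(!known)) {
      warn(sprintf("%d call(s) with unrecognized variant class ignored",
                   sum(!known)))
    }
    hits <- calls[qual & calls$gene %in% gene_set &
                    calls$sample_id %in% samples, , drop = FALSE]
    if (nrow(hits)) m[cbind(hits$sample_id, hits$gene)] <- 1L
  }
  m
}
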