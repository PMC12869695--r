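# Feature-set assembly: the per-entity input matrices consumed by the fusion
# model (fingerprints, propagated target vectors, expression, mutations).

#' Assemble a feature set for the fusion model
#'
#' @param fingerprints Binary drugs x bits matrix (rownames = drug ids).
#' @param targets Drugs x genes matrix of (propagated) target weights.
#' @param expression Samples x gene matrix (marker genes, log2(TPM+1)).
#' @param mutation Optional binary samples x gene matrix.
#' @param encoder Optional pre-trained [pretrain_autoencoder()] encoder whose
#'   weights initialize the sample branch.
#' @return A `feature_set` list.
#' @export
feature_set <- function(fingerprints, targets, expression, mutation = NULL,
                        encoder = NULL) {
  stopifnot(identical(rownames(fingerprints), rownames(targets)))
  if (!is.null(mutation)) {
    stopifnot(identical(rownames(mutation), rownames(expression)))
  }
  structure(
    list(fingerprints = as.matrix(fingerprints), targets = as.matrix(targets),
         expression = as.matrix(expression), mutation = mutation,
         encoder = encoder,
         drug_ids = rownames(fingerprints),
         sample_ids = rownames(expression)),
    class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d drugs (fp %d bits, %d targets), %d samples (%d genes%s)\n",
              length(x$drug_ids), ncol(x$fingerprints), ncol(x$targets),
              length(x$sample_ids), ncol(x$expression),
              if (is.null(x$mutation)) "" else ", + mutations"))
  invisible(x)
}

#' Build the full feature set of a synthetic world
#'
#' Runs the standard feature pipeline on a [synth_world()]: Morgan
#' fingerprints of the synthetic structures, the binary drug-target matrix
#' propagated over the synthetic PPI by random walk with restart, marker-gene
#' expression (all world genes are markers at synthetic scale), a pre-trained
#' expression autoencoder, and the binary mutation matrix.
#'
#' @param world A [synth_world()].
#' @param alpha Restart probability for [rwr_propagate()].
#' @param n_bits Fingerprint length.
#' @param bottleneck,ae_hidden,ae_epochs Autoencoder geometry and training
#'   length at synthetic scale.
#' @param pretrain Set `FALSE` to skip autoencoder pre-training (the sample
#'   branch then starts from random weights).
#' @param seed Integer seed (defaults to the world's).
#' @return A [feature_set()].
#' @export
synth_features <- function(world, alpha = 0.5, n_bits = 2048,
                           bottleneck = 16, ae_hidden = 64, ae_epochs = 40,
                           pretrain = TRUE, seed = world$cfg$seed) {
  lib <- fingerprint_library(world$drugs, n_bits = n_bits)
  fp <- matrix(0, nrow(lib), n_bits, dimnames = list(lib$drug_id, NULL))
  for (i in seq_len(nrow(lib))) fp[i, lib$fp[[i]]$bits] <- 1

  dti <- build_dti_matrix(world$targets, universe = world$genes$gene)
  prop <- rwr_propagate(dti, world$ppi, alpha = alpha)

  expr <- world$expression
  enc <- NULL
  if (pretrain) {
    enc <- pretrain_autoencoder(expr, hidden = ae_hidden,
                                bottleneck = bottleneck, epochs = ae_epochs,
                                seed = derive_seed(seed, "ae"))
  }
  feature_set(fingerprints = fp, targets = prop, expression = expr,
              mutation = world$mutation, encoder = enc)
}
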