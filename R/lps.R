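# Linear predictor score (LPS) classifier: t-statistic gene weights, a
# weighted-sum score, and a two-Gaussian Bayes posterior.

# Vectorized Welch two-sample t statistics per gene (group1 minus group2).
welch_t <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2, var); v2 <- apply(X2, 2, var)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

#' Fit a linear-predictor-score classifier
#'
#' On a training portion of the samples, computes per-gene two-sample
#' (Welch) t-statistics between the two groups, keeps the `n_genes` genes
#' with the largest absolute t, and defines the linear predictor score
#' `LPS(x) = sum_j t_j x_j` over those genes. A Gaussian is fitted to the
#' training LPS of each group; classification is by Bayes posterior with the
#' empirical group proportions as priors.
#'
#' @param expression Samples x genes matrix.
#' @param labels Group label per sample (exactly two levels, >= 3 samples
#'   each).
#' @param n_genes Number of signature genes (default 50, capped).
#' @param train_frac Fraction used for fitting (default 0.7); the remainder
#'   estimates the validation accuracy.
#' @param seed Integer seed for the stratified split.
#' @return An `lps_model`: signature genes, t-statistic weights, group
#'   Gaussians, priors, and training/validation accuracy.
#' @export
fit_lps <- function(expression, labels, n_genes = 50, train_frac = 0.7,
                    seed = 1) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    stopf("combisyn_value_error", "LPS needs exactly two groups, got %d",
          length(lev))
  }
  if (any(table(labels) < 3)) {
    stopf("combisyn_value_error", "each group needs >= 3 samples")
  }
  n <- nrow(expression)
  tr <- with_seed(derive_seed(seed, "lps"), {
    unlist(lapply(lev, function(g) {
      idx <- which(labels == g)
      sort(sample(idx, max(3L, round(train_frac * length(idx)))))
    }))
  })
  va <- setdiff(seq_len(n), tr)

  Xtr <- expression[tr, , drop = FALSE]
  ytr <- labels[tr]
  t_stat <- welch_t(Xtr[ytr == lev[1], , drop = FALSE],
                    Xtr[ytr == lev[2], , drop = FALSE])
  t_stat[!is.finite(t_stat)] <- 0
  n_genes <- min(n_genes, ncol(expression))
  genes <- colnames(expression)[order(-abs(t_stat))][seq_len(n_genes)]
  w <- t_stat[match(genes, colnames(expression))]
  names(w) <- genes

  lps_tr <- as.vector(Xtr[, genes, drop = FALSE] %*% w)
  mu <- tapply(lps_tr, ytr, mean)
  sdev <- tapply(lps_tr, ytr, sd)
  sdev <- pmax(sdev, 1e-9)
  prior <- table(ytr) / length(ytr)

  model <- structure(
    list(genes = genes, weights = w, levels = lev,
         mean = as.numeric(mu[lev]), sd = as.numeric(sdev[lev]),
         prior = as.numeric(prior[lev]), seed = seed),
    class = "lps_model")

  model$train_accuracy <- mean(
    classify_lps(model, Xtr)$group == ytr)
  if (length(va) >= 1) {
    model$validation_accuracy <- mean(
      classify_lps(model, expression[va, , drop = FALSE])$group == labels[va])
  } else {
    model$validation_accuracy <- NA_real_
  }
  model
}

#' Classify samples with a fitted LPS model
#'
#' Posterior of group 1 by Bayes rule on the two fitted Gaussians; an exact
#' posterior tie (0.5) is broken toward the first group level.
#'
#' @param model An [fit_lps()] model.
#' @param profile A numeric vector over (at least) the model genes, or a
#'   samples x genes matrix.
#' @return Tibble `lps`, `posterior` (of the first group level), `group`.
#' @export
classify_lps <- function(model, profile) {
  X <- if (is.null(dim(profile))) matrix(profile, nrow = 1,
                                         dimnames = list(NULL, names(profile)))
       else as.matrix(profile)
  missing <- setdiff(model$genes, colnames(X))
  if (length(missing)) {
    stopf("combisyn_schema_error", "profile lacks model gene(s): %s",
          paste(missing, collapse = ", "))
  }
  lps <- as.vector(X[, model$genes, drop = FALSE] %*% model$weights)
  d1 <- dnorm(lps, model$mean[1], model$sd[1]) * model$prior[1]
  d2 <- dnorm(lps, model$mean[2], model$sd[2]) * model$prior[2]
  post <- ifelse(d1 + d2 == 0, model$prior[1], d1 / (d1 + d2))
  tibble(lps = lps, posterior = post,
         group = ifelse(post >= 0.5, model$levels[1], model$levels[2]))
}

#' @export
print.lps_model <- function(x, ...) {
  cat(sprintf("<lps_model> %d genes; groups %s/%s; train acc %.3f, val acc %.3f\n",
              length(x$genes), x$levels[1], x$levels[2],
              x$train_accuracy, x$validation_accuracy))
  invisible(x)
}

#' @rdname fit_lps
#' @param x An `lps_model`.
#' @param ... Unused.
#' @export
tidy.lps_model <- function(x, ...) {
  tibble(gene = x$genes, weight = unname(x$weights))
}

#' @rdname fit_lps
#' @export
glance.lps_model <- function(x, ...) {
  tibble(n_genes = length(x$genes),
         train_accuracy = x$train_accuracy,
         validation_accuracy = x$validation_accuracy)
}
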