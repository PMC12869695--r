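# Cross-validation driver: one model per fold, paper-style metric reporting
# (mean +/- sd across folds).

#' Cross-validated evaluation of the fusion model
#'
#' Builds the requested split plan, trains one model per fold on the fold's
#' training triplets (using the fold's carved validation set for epoch
#' selection), predicts the held-out test triplets and reports AUROC, AUPRC
#' and the Spearman correlation between predicted probabilities and the
#' continuous synergy score column. Folds with an empty or one-class test
#' set are reported as `NA` and excluded from the aggregate.
#'
#' @param triplets Tibble with `drug_a`, `drug_b`, `sample_id`, `label` and
#'   (for Spearman) a continuous score column.
#' @param features A [feature_set()].
#' @param strategy `"leave_combo_out"`, `"leave_drug_out"` or
#'   `"leave_sample_out"`.
#' @param k Folds (ignored by leave_sample_out, which has a single fold).
#' @param cfg A [synergy_net_config()].
#' @param seed Integer seed (drives the split and per-fold training seeds).
#' @param score_col Column with continuous synergy scores (default `truth`
#'   if present, else `score_loewe`, else the label).
#' @param drug_fingerprints Required for leave_drug_out; a
#'   [fingerprint_library()].
#' @return A `cv_result`: per-fold metrics tibble plus summary.
#' @export
cross_validate <- function(triplets, features,
                           strategy = c("leave_combo_out", "leave_drug_out",
                                        "leave_sample_out"),
                           k = 5, cfg = synergy_net_config(), seed = 1,
                           score_col = NULL, drug_fingerprints = NULL) {
  strategy <- match.arg(strategy)
  score_col <- score_col %||%
    intersect(c("truth", "score_loewe", "label"), names(triplets))[1]
  plan <- switch(strategy,
    leave_combo_out = split_leave_combo_out(triplets, k = k, seed = seed),
    leave_drug_out = {
      if (is.null(drug_fingerprints)) {
        stopf("combisyn_value_error",
              "leave_drug_out needs drug_fingerprints")
      }
      split_leave_drug_out(triplets, drug_fingerprints, k = k, seed = seed)
    },
    leave_sample_out = split_leave_sample_out(triplets,
                                              features$expression,
                                              seed = seed)
  )

  rows <- purrr::map_dfr(seq_along(plan$folds), function(f) {
    fold <- plan$folds[[f]]
    n_tr <- length(fold$train); n_va <- length(fold$val)
    n_te <- length(fold$test)
    out <- tibble(fold = f, n_train = n_tr, n_val = n_va, n_test = n_te,
                  auroc = NA_real_, auprc = NA_real_, spearman = NA_real_)
    ytest <- triplets$label[fold$test]
    if (length(fold$test) < 2 || length(unique(ytest)) < 2 ||
        length(unique(triplets$label[fold$train])) < 2) {
      return(out)
    }
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(seed, "fold", f)
    sub <- triplets[c(fold$train, fold$val), , drop = FALSE]
    model <- train_synergy_net(sub, features, fold_cfg,
                               val_ids = seq_along(fold$val) + length(fold$train))
    pred <- predict(model, triplets[fold$test, , drop = FALSE], features)
    out$auroc <- metric_auroc(ytest, pred$prob)
    out$auprc <- metric_auprc(ytest, pred$prob)
    if (!is.null(score_col) && length(fold$test) >= 3) {
      out$spearman <- metric_spearman(triplets[[score_col]][fold$test],
                                      pred$prob)
    }
    out
  })

  summary <- rows |>
    tidyr::pivot_longer(c("auroc", "auprc", "spearman"),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n_folds = sum(!is.na(.data$value)), .groups = "drop")

  structure(list(strategy = strategy, folds = rows, summary = summary,
                 plan = plan, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d fold(s)\n", x$strategy, nrow(x$folds)))
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    cat(sprintf("  %-9s %.3f+/-%.3f (n=%d)\n", r$metric, r$mean,
                ifelse(is.na(r$sd), 0, r$sd), r$n_folds))
  }
  invisible(x)
}

#' @rdname cross_validate
#' @param x,object A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname cross_validate
#' @export
glance.cv_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"), id_cols = NULL,
                             unused_fn = list(n_folds = max))
  dplyr::bind_cols(tibble(strategy = x$strategy), wide)
}

#' @rdname cross_validate
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, c("auroc", "auprc", "spearman"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, height = 0,
                         ggplot2::aes(color = factor(.data$fold))) +
    ggplot2::labs(color = "fold", y = "value",
                  title = sprintf("Cross-validation (%s)", object$strategy)) +
    ggplot2::theme_minimal()
}
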