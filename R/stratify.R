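# Patient-level downstream analyses: predicted-synergy matrices, two-group
# stratification, and survival comparison.

#' Predicted-synergy matrix of patients x partner drugs
#'
#' Applies a trained model to every (anchor + partner, patient) combination.
#' A combination is "effective" in a patient when its predicted synergy
#' probability exceeds 0.5; partners are ranked by their average predicted
#' synergy across patients.
#'
#' @param model A trained [train_synergy_net()] model.
#' @param features A [feature_set()] covering patients and drugs.
#' @param patients Character vector of patient/sample ids.
#' @param anchor The anchor drug id.
#' @param partners Character vector of partner drug ids.
#' @return A `prediction_matrix`: patients x partners matrix of
#'   probabilities in `[0, 1]`.
#' @export
predict_matrix <- function(model, features, patients, anchor, partners) {
  grid <- tidyr::expand_grid(sample_id = patients, partner = partners)
  trip <- tibble(drug_a = anchor, drug_b = grid$partner,
                 sample_id = grid$sample_id)
  pred <- predict(model, trip, features)
  m <- matrix(pred$prob, nrow = length(patients), byrow = FALSE,
              dimnames = list(NULL, NULL))
  # expand_grid varies `partner` fastest -> fill by row
  m <- matrix(pred$prob, nrow = length(patients), ncol = length(partners),
              byrow = TRUE, dimnames = list(patients, partners))
  structure(m, anchor = anchor, class = c("prediction_matrix", class(m)))
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("<prediction_matrix> %d patients x %d partners (anchor %s)\n",
              nrow(x), ncol(x), attr(x, "anchor") %||% "?"))
  invisible(x)
}

#' @rdname predict_matrix
#' @param x,object A `prediction_matrix`.
#' @param ... Unused.
#' @export
tidy.prediction_matrix <- function(x, ...) {
  as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    setNames(c("patient", "partner", "prob")) |>
    mutate(effective = .data$prob > 0.5)
}

#' @rdname predict_matrix
#' @export
autoplot.prediction_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$partner, .data$patient,
                                     fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P(synergy)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(title = sprintf("Predicted synergy (anchor %s)",
                                  attr(object, "anchor") %||% "?"))
}

#' Stratify patients into responsive / non-responsive groups
#'
#' Hierarchical clustering of the prediction-matrix rows (Euclidean
#' distance, average linkage) cut at two groups; the cluster with the higher
#' grand-mean probability is labeled `responsive`. The grouping depends only
#' on row geometry, so it is invariant under column permutations.
#'
#' @param matrix A [predict_matrix()] result (or any numeric matrix with
#'   patient rownames).
#' @param k Number of groups (default 2).
#' @return Tibble `sample_id`, `group` (`responsive` / `non_responsive`).
#' @export
stratify_patients <- function(matrix, k = 2) {
  m <- unclass(matrix)
  if (nrow(m) < 2) {
    stopf("combisyn_value_error", "stratification needs >= 2 patients")
  }
  if (max(dist(m)) < 1e-12) {
    stopf("combisyn_value_error",
          "all patient profiles are identical; no structure to stratify")
  }
  cl <- cutree(hclust(dist(m), method = "average"), k = k)
  grand <- tapply(rowMeans(m), cl, mean)
  responsive <- as.integer(names(grand)[which.max(grand)])
  tibble(
    sample_id = rownames(m),
    group = unname(ifelse(cl == responsive, "responsive", "non_responsive"))
  )
}

#' Two-group log-rank survival comparison
#'
#' Standard two-group log-rank statistic with a chi-squared (1 df) p-value,
#' via `survival::survdiff`.
#'
#' @param groups Tibble `sample_id`, `group` (exactly two groups).
#' @param survival_data Tibble `sample_id`, `time`, `event`.
#' @return Tibble `statistic`, `p_value`, `n`, `n_events`.
#' @export
logrank_compare <- function(groups, survival_data) {
  survival_data <- survival_data[, c("sample_id", "time", "event")]
  df <- dplyr::inner_join(groups[, c("sample_id", "group")], survival_data,
                          by = "sample_id")
  lev <- unique(df$group)
  if (length(lev) != 2) {
    stopf("combisyn_value_error",
          "log-rank comparison needs exactly two groups, got %d", length(lev))
  }
  ev <- tapply(df$event, df$group, sum)
  if (any(ev == 0)) {
    stopf("combisyn_value_error",
          "insufficient data: a group has no observed events")
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE)
  tibble(statistic = unname(fit$chisq), p_value = p,
         n = nrow(df), n_events = sum(df$event))
}
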