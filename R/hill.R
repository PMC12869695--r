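# Four-parameter Hill (log-logistic) monotherapy fits.

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `y = b + (e_max - b) * d^h / (ec50^h + d^h)` with the
#' baseline `b` fixed (0 unless `baseline_fixed` is given). Parameters are
#' bounded to `e_max` in `[0, 120]` % inhibition, `ec50 > 0`, `h` in
#' `(0.1, 10]`. When the optimizer fails — or the converged curve does not
#' positively track the data, as with inverted (decreasing) responses — a
#' median-interpolation fallback fit is returned with `converged = FALSE`
#' instead of raising.
#'
#' @param doses Concentrations (uM), may include 0; at least 3 distinct
#'   nonzero doses are required.
#' @param responses % inhibition at each dose.
#' @param baseline_fixed Optional fixed baseline (% inhibition); default 0.
#' @return A `hill_fit` object: `e_max`, `ec50`, `h`, `baseline`, `converged`.
#' @export
#' @examples
#' d <- c(0, 0.1, 0.3, 1, 3, 10)
#' y <- 90 * d^1.5 / (1^1.5 + d^1.5)
#' fit <- fit_hill(d, y)
#' tidy(fit)
fit_hill <- function(doses, responses, baseline_fixed = NULL) {
  b <- baseline_fixed %||% 0
  if (length(doses) != length(responses)) {
    stopf("combisyn_fit_error", "doses and responses must have equal length")
  }
  if (length(unique(doses[doses > 0])) < 3) {
    stopf("combisyn_fit_error",
          "Hill fit needs at least 3 distinct nonzero doses, got %d",
          length(unique(doses[doses > 0])))
  }
  dgi <- doses[doses > 0]

  # Degenerate flat data: constant at the baseline level is an exact fit with
  # zero span (predicted curve identically b).
  if (max(abs(responses - b)) < 1e-9) {
    return(new_hill_fit(e_max = b, ec50 = exp(mean(log(dgi))), h = 1,
                        baseline = b, converged = TRUE))
  }

  start <- list(
    e_max = clip(max(responses), b + 1e-3, 120),
    ec50 = hill_start_ec50(doses, responses, b),
    h = 1.5
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ b + (e_max - b) * ifelse(doses > 0, doses^h / (ec50^h + doses^h), 0),
      start = start,
      lower = c(e_max = 0, ec50 = min(dgi) * 1e-3, h = 0.101),
      upper = c(e_max = 120, ec50 = max(dgi) * 1e3, h = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    pred <- b + (cf[["e_max"]] - b) *
      ifelse(doses > 0, doses^cf[["h"]] / (cf[["ec50"]]^cf[["h"]] + doses^cf[["h"]]), 0)
    ok <- max(abs(pred - responses)) < 1e-6 ||
      (sd(pred) > 0 && sd(responses) > 0 && cor(pred, responses) > 0)
    if (ok) {
      return(new_hill_fit(cf[["e_max"]], cf[["ec50"]], cf[["h"]], b, TRUE))
    }
  }
  hill_fallback(doses, responses, b)
}

new_hill_fit <- function(e_max, ec50, h, baseline, converged) {
  structure(list(e_max = unname(e_max), ec50 = unname(ec50), h = unname(h),
                 baseline = unname(baseline), converged = converged),
            class = "hill_fit")
}

hill_start_ec50 <- function(doses, responses, b) {
  dgi <- sort(unique(doses[doses > 0]))
  span <- max(responses) - b
  if (span <= 0) return(exp(mean(log(dgi))))
  half <- b + span / 2
  ord <- order(doses)
  d <- doses[ord]; y <- responses[ord]
  above <- which(y >= half & d > 0)
  if (!length(above)) return(max(dgi))
  clip(d[above[1]], min(dgi), max(dgi))
}

# Median-interpolation fallback: e_max from the observed plateau, EC50 from
# the first linear-interpolation crossing of half-max, unit slope.
hill_fallback <- function(doses, responses, b) {
  dgi <- sort(unique(doses[doses > 0]))
  e_max <- clip(stats::median(utils::tail(sort(responses), 3)), 0, 120)
  new_hill_fit(e_max = e_max, ec50 = hill_start_ec50(doses, responses, b),
               h = 1, baseline = b, converged = FALSE)
}

#' Predicted response of a fitted Hill curve
#' @param fit A `hill_fit`.
#' @param d Doses (uM).
#' @return % inhibition.
#' @export
hill_predict <- function(fit, d) {
  ifelse(d <= 0, fit$baseline,
         fit$baseline + (fit$e_max - fit$baseline) *
           d^fit$h / (fit$ec50^fit$h + d^fit$h))
}

# Dose required to reach response y; Inf when y is at or beyond the plateau,
# 0 at or below baseline.
hill_inverse <- function(fit, y) {
  span <- fit$e_max - fit$baseline
  if (span <= 1e-9) return(ifelse(y > fit$baseline, Inf, 0))
  frac <- (y - fit$baseline) / span
  ifelse(frac <= 0, 0,
         ifelse(frac >= 1, Inf, fit$ec50 * (frac / (1 - frac))^(1 / fit$h)))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> e_max=%.2f ec50=%.4g h=%.3f baseline=%.2f converged=%s\n",
              x$e_max, x$ec50, x$h, x$baseline, x$converged))
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("e_max", "ec50", "h", "baseline"),
         estimate = c(x$e_max, x$ec50, x$h, x$baseline))
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(e_max = x$e_max, ec50 = x$ec50, h = x$h,
         baseline = x$baseline, converged = x$converged)
}
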