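# Synthetic dose-response checkerboards with a planted synergy bump.

# Four-parameter Hill response (baseline fixed at 0 for generation).
hill_response <- function(d, e_max, ec50, h) {
  ifelse(d <= 0, 0, e_max * d^h / (ec50^h + d^h))
}

# Unimodal bump kernel over 0-based grid indices 0..(m-1): 0 at the dose-0
# margin, 1 at the central index ceiling((m-1)/2), linear in between.
bump_kernel_weights <- function(m) {
  ic <- ceiling((m - 1) / 2)
  i <- seq_len(m) - 1
  pmax(0, 1 - abs(i - ic) / ic)
}

#' Index of the central well of a dose grid
#' @param dose_grid Ordered concentrations, first 0.
#' @return 1-based index of the central (peak-kernel) concentration.
#' @export
central_dose_index <- function(dose_grid) {
  ceiling((length(dose_grid) - 1) / 2) + 1L
}

#' Generate one dose-response checkerboard from the synthetic world
#'
#' Monotherapy margins follow each drug's four-parameter Hill curve, with the
#' EC50 divided by `potency_shift` when the drug's pathway is active in the
#' sample. Combination wells are the Bliss independence expectation of the two
#' monotherapy values plus `truth * k(d1, d2)`, where `k` is a unimodal kernel
#' equal to 1 at the grid's central well and 0 on the dose-0 margins, plus
#' Gaussian well noise; all responses are clipped to `[0, 100]`.
#'
#' @param world A [synth_world()].
#' @param drug_a,drug_b,sample_id Ids present in the world.
#' @param noise_sd Well noise sd (% inhibition); defaults to the config value.
#' @param seed Integer seed for the well noise.
#' @return A `dose_block` object (see [dose_block()]).
#' @export
synth_block <- function(world, drug_a, drug_b, sample_id,
                        noise_sd = world$cfg$response_noise_sd,
                        seed = world$cfg$seed) {
  drugs <- world$drugs
  if (!all(c(drug_a, drug_b) %in% drugs$drug_id)) {
    stopf("combisyn_lookup_error", "unknown drug id(s): %s",
          paste(setdiff(c(drug_a, drug_b), drugs$drug_id), collapse = ", "))
  }
  if (!sample_id %in% rownames(world$activity)) {
    stopf("combisyn_lookup_error", "unknown sample id: %s", sample_id)
  }
  cfg <- world$cfg
  dg <- cfg$dose_grid
  m <- length(dg)

  pars <- function(d) {
    row <- drugs[drugs$drug_id == d, ]
    active <- world$activity[sample_id, row$pathway] == 1
    list(e_max = row$e_max, h = row$h,
         ec50 = row$ec50 / ifelse(active, cfg$potency_shift, 1))
  }
  pa <- pars(drug_a); pb <- pars(drug_b)
  ya <- hill_response(dg, pa$e_max, pa$ec50, pa$h)
  yb <- hill_response(dg, pb$e_max, pb$ec50, pb$h)

  bliss <- outer(ya, yb, function(u, v) u + v - u * v / 100)
  # margins are pure monotherapy (the other drug at dose 0)
  bliss[, 1] <- ya
  bliss[1, ] <- yb
  bliss[1, 1] <- 0

  truth <- synth_truth_strength(world, drug_a, drug_b, sample_id)
  w <- bump_kernel_weights(m)
  bump <- truth * outer(w, w)
  bump[1, ] <- 0; bump[, 1] <- 0

  resp <- bliss + bump
  if (noise_sd > 0) {
    resp <- with_seed(derive_seed(seed, "block", drug_a, drug_b, sample_id), {
      resp + matrix(rnorm(m * m, 0, noise_sd), m, m)
    })
  }
  resp <- clip(resp, 0, 100)
  dose_block(drug_a = drug_a, drug_b = drug_b, sample_id = sample_id,
             conc_a = dg, conc_b = dg, response = resp)
}

#' Generate survival times for labeled sample groups
#'
#' Exponential event times whose hazard differs by `hazard_ratio` between the
#' two groups (the second group level carries the higher hazard), with
#' independent uniform censoring.
#'
#' @param groups Tibble with columns `sample_id` and `group` (exactly two
#'   distinct labels), or a named character/factor vector.
#' @param hazard_ratio Positive hazard ratio of group 2 relative to group 1.
#' @param seed Integer seed.
#' @param base_hazard Baseline event rate for group 1 (events per time unit).
#' @param censor_max Upper bound of the Uniform(0, censor_max) censoring time.
#' @return Tibble: `sample_id`, `group`, `time`, `event` (1 = observed).
#' @export
#' @examples
#' g <- tibble::tibble(sample_id = sprintf("S%02d", 1:20),
#'                     group = rep(c("a", "b"), each = 10))
#' surv <- synth_survival(g, hazard_ratio = 3, seed = 1)
synth_survival <- function(groups, hazard_ratio, seed = 1,
                           base_hazard = 0.1, censor_max = 30) {
  if (!is.data.frame(groups)) {
    groups <- tibble(sample_id = names(groups), group = as.character(groups))
  }
  if (!is.numeric(hazard_ratio) || length(hazard_ratio) != 1 ||
      !is.finite(hazard_ratio) || hazard_ratio <= 0) {
    stopf("combisyn_value_error", "hazard_ratio must be a positive number")
  }
  lev <- sort(unique(groups$group))
  if (length(lev) != 2) {
    stopf("combisyn_value_error",
          "groups must contain exactly two labels, got %d", length(lev))
  }
  with_seed(derive_seed(seed, "survival"), {
    rate <- base_hazard * ifelse(groups$group == lev[2], hazard_ratio, 1)
    t_event <- rexp(nrow(groups), rate)
    t_cens <- runif(nrow(groups), 0, censor_max)
    tibble(
      sample_id = groups$sample_id,
      group = groups$group,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}
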