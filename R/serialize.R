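# JSON serialization of split plans and LPS models.

#' Serialize a split plan or an LPS model to JSON
#'
#' `write_split_plan()` stores the strategy, provenance seed, dropped rows
#' and per-fold train/val/test triplet indices; `write_lps_model()` stores
#' the signature genes, t-statistic weights, group Gaussians and priors.
#' `read_lps_model()` restores a classifier usable with [classify_lps()].
#'
#' @param plan A `split_plan`.
#' @param model An `lps_model`.
#' @param path Output/input file path.
#' @return Invisibly, the path (writers); an `lps_model` (reader).
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(strategy = plan$strategy,
         seed = plan$provenance$seed,
         dropped = plan$dropped,
         folds = lapply(plan$folds, function(f) {
           list(train = f$train, val = f$val, test = f$test)
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
write_lps_model <- function(model, path) {
  jsonlite::write_json(
    list(genes = model$genes, weights = unname(model$weights),
         levels = model$levels, mean = model$mean, sd = model$sd,
         prior = model$prior, seed = model$seed,
         train_accuracy = model$train_accuracy,
         validation_accuracy = model$validation_accuracy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_lps_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(genes = x$genes, weights = setNames(x$weights, x$genes),
         levels = x$levels, mean = x$mean, sd = x$sd, prior = x$prior,
         seed = x$seed, train_accuracy = x$train_accuracy,
         validation_accuracy = x$validation_accuracy),
    class = "lps_model")
}
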