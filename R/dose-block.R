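# The dose-response checkerboard container and its long-format conversions.

#' Construct a dose-response block
#'
#' One drug-pair x sample checkerboard of % inhibition, with monotherapy
#' margins: `response[i, j]` is the well at `conc_a[i]` of drug A combined
#' with `conc_b[j]` of drug B; the first row/column (dose 0) are the
#' monotherapy margins and `response[1, 1]` is the untreated well.
#'
#' @param drug_a,drug_b,sample_id Identifiers.
#' @param conc_a,conc_b Ordered concentrations (uM), first element 0.
#' @param response Numeric matrix `length(conc_a) x length(conc_b)` of
#'   % inhibition; must be complete (no missing wells).
#' @return A `dose_block` object.
#' @export
dose_block <- function(drug_a, drug_b, sample_id, conc_a, conc_b, response) {
  response <- as.matrix(response)
  if (length(conc_a) < 2 || conc_a[1] != 0 || any(diff(conc_a) <= 0) ||
      length(conc_b) < 2 || conc_b[1] != 0 || any(diff(conc_b) <= 0)) {
    stopf("combisyn_input_error",
          "concentrations must be strictly increasing with first element 0")
  }
  if (!all(dim(response) == c(length(conc_a), length(conc_b)))) {
    stopf("combisyn_input_error",
          "response must be a %d x %d matrix", length(conc_a), length(conc_b))
  }
  if (anyNA(response)) {
    stopf("combisyn_input_error", "response matrix has missing wells")
  }
  structure(
    list(drug_a = drug_a, drug_b = drug_b, sample_id = sample_id,
         conc_a = as.numeric(conc_a), conc_b = as.numeric(conc_b),
         response = unname(response)),
    class = "dose_block")
}

#' @export
print.dose_block <- function(x, ...) {
  cat(sprintf("<dose_block> %s + %s in %s (%d x %d wells)\n",
              x$drug_a, x$drug_b, x$sample_id,
              length(x$conc_a), length(x$conc_b)))
  invisible(x)
}

# Transpose a block (swap drug roles); scoring is invariant under this.
transpose_block <- function(block) {
  dose_block(block$drug_b, block$drug_a, block$sample_id,
             block$conc_b, block$conc_a, t(block$response))
}

#' Convert a dose-response block to/from long format
#'
#' The long format matches the package's on-disk convention: one row per well
#' with columns `block_id`, `drug_row`, `drug_col`, `sample_id`, `conc_r`,
#' `conc_c`, `response` (% inhibition).
#'
#' @param block A [dose_block()].
#' @param block_id Identifier used in the long table.
#' @return `block_to_long()`: a tibble of wells. `blocks_from_long()`: a named
#'   list of `dose_block` objects, one per `block_id`.
#' @export
block_to_long <- function(block, block_id = triplet_key(block$drug_a, block$drug_b, block$sample_id)) {
  grid <- expand.grid(i = seq_along(block$conc_a), j = seq_along(block$conc_b))
  tibble(
    block_id = block_id,
    drug_row = block$drug_a,
    drug_col = block$drug_b,
    sample_id = block$sample_id,
    conc_r = block$conc_a[grid$i],
    conc_c = block$conc_b[grid$j],
    response = block$response[cbind(grid$i, grid$j)]
  )
}

#' @param wells Long-format tibble of wells (see `block_to_long()`).
#' @param viability If `TRUE`, responses are on a % viability scale and are
#'   converted to % inhibition as `100 - response`.
#' @rdname block_to_long
#' @export
blocks_from_long <- function(wells, viability = FALSE) {
  needed <- c("block_id", "drug_row", "drug_col", "sample_id",
              "conc_r", "conc_c", "response")
  missing <- setdiff(needed, names(wells))
  if (length(missing)) {
    stopf("combisyn_input_error", "long well table lacks column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (viability) wells$response <- 100 - wells$response
  split(wells, wells$block_id) |>
    purrr::map(function(df) {
      ca <- sort(unique(df$conc_r)); cb <- sort(unique(df$conc_c))
      resp <- matrix(NA_real_, length(ca), length(cb))
      resp[cbind(match(df$conc_r, ca), match(df$conc_c, cb))] <- df$response
      dose_block(df$drug_row[1], df$drug_col[1], df$sample_id[1], ca, cb, resp)
    })
}

#' @rdname block_to_long
#' @param object,... Passed through to ggplot2.
#' @export
autoplot.dose_block <- function(object, ...) {
  long <- block_to_long(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(signif(.data$conc_c, 3)),
    y = factor(signif(.data$conc_r, 3)),
    fill = .data$response)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% inhibition") +
    ggplot2::labs(
      x = sprintf("%s (uM)", object$drug_b),
      y = sprintf("%s (uM)", object$drug_a),
      title = sprintf("%s + %s in %s", object$drug_a, object$drug_b, object$sample_id)) +
    ggplot2::theme_minimal()
}
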