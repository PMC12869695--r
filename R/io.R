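# Readers and writers for the package's on-disk formats: SMILES-per-line
# drug files, target / PPI / expression / mutation TSVs, dose-response long
# CSVs and triplet CSVs.

#' Write a synthetic world to standard flat files
#'
#' Emits `drugs.smi` (SMILES and id per line), `targets.tsv` (drug_id, gene),
#' `ppi.tsv` (protein_a, protein_b, combined_score scaled 0-1000),
#' `expression.tsv` (genes x samples, log2(TPM+1)), `mutation.tsv`
#' (sample_id, gene, variant_class), and `triplets.csv` (the planted truth
#' table).
#'
#' @param world A [synth_world()].
#' @param dir Output directory (created if needed).
#' @param n_triplets Triplet-table size passed to [synth_triplets()].
#' @return Invisibly, the vector of files written.
#' @export
write_synth_world <- function(world, dir, n_triplets = 4000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- function(f) file.path(dir, f)

  writeLines(paste(world$drugs$smiles, world$drugs$drug_id), p("drugs.smi"))
  files <- c(files, p("drugs.smi"))

  readr::write_tsv(world$targets, p("targets.tsv"))
  files <- c(files, p("targets.tsv"))

  ppi <- world$ppi
  ppi$combined_score <- round(ppi$score * 1000)
  readr::write_tsv(ppi[, c("protein_a", "protein_b", "combined_score")],
                   p("ppi.tsv"))
  files <- c(files, p("ppi.tsv"))

  expr <- as_tibble(t(world$expression), rownames = "gene")
  readr::write_tsv(expr, p("expression.tsv"))
  files <- c(files, p("expression.tsv"))

  mut <- which(world$mutation == 1, arr.ind = TRUE)
  mut_df <- tibble(
    sample_id = rownames(world$mutation)[mut[, 1]],
    gene = colnames(world$mutation)[mut[, 2]],
    variant_class = "missense"
  )
  readr::write_tsv(mut_df, p("mutation.tsv"))
  files <- c(files, p("mutation.tsv"))

  readr::write_csv(synth_triplets(world, n = n_triplets), p("triplets.csv"))
  files <- c(files, p("triplets.csv"))

  invisible(files)
}

#' Read the package's flat-file formats
#'
#' @param path File path.
#' @return `read_smiles()`: tibble `drug_id`, `smiles`. `read_ppi()`: tibble
#'   `protein_a`, `protein_b`, `score` (0-1 scale). `read_expression()`:
#'   samples x genes matrix. `read_dose_blocks()`: long well tibble.
#'   `read_triplets()`: triplet tibble.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  tibble(
    drug_id = vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_,
                     character(1)),
    smiles = vapply(parts, `[[`, character(1), 1)
  )
}

#' @rdname read_smiles
#' @export
read_ppi <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  score_col <- intersect(c("combined_score", "score"), names(df))[1]
  score <- df[[score_col]] %||% rep(1, nrow(df))
  if (length(score) && max(score) > 1.5) score <- score / 1000
  tibble(protein_a = df$protein_a, protein_b = df$protein_b, score = score)
}

#' @rdname read_smiles
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- df[[1]]
  m <- t(as.matrix(df[, -1]))
  colnames(m) <- genes
  m
}

#' @rdname read_smiles
#' @param viability Convert % viability responses to % inhibition.
#' @export
read_dose_blocks <- function(path, viability = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (viability) df$response <- 100 - df$response
  df
}

#' @rdname read_smiles
#' @export
read_triplets <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
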