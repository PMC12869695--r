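# Morgan (circular-substructure) fingerprints, Tanimoto similarity, and
# fingerprint-based drug identity matching.
#
# The hashing is authored here because no installed R package exposes
# Morgan/ECFP fingerprints; SMILES parsing is delegated to ChemmineR. Atom
# identifiers are built from order-invariant invariants (element, heavy
# degree, formal charge, ring membership) and refined by hashing the sorted
# multiset of (bond order, neighbor identifier) pairs, so equivalent
# notations of the same molecule ("CCO" vs "OCC") produce identical bits.

MERSENNE31 <- 2147483647

hash_mix <- function(h, xs) {
  for (x in xs) h <- (h * 131071 + (x %% MERSENNE31) + 1) %% MERSENNE31
  h
}

#' Morgan fingerprint of a molecule
#'
#' Deterministic hashed circular-substructure fingerprint: atom environments
#' of radius 0..`radius` are hashed into a fixed-length bit vector.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood radius (default 2).
#' @param n_bits Fingerprint length (default 2048).
#' @return A `morgan_fp` object with fields `bits` (sorted positions of set
#'   bits, 1-based), `n_bits`, and `n_on`.
#' @export
#' @examples
#' \donttest{
#' fp <- morgan_fingerprint("CCO")
#' fp$n_on
#' tanimoto(fp, morgan_fingerprint("OCC"))  # 1: same molecule
#' }
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  mol <- parse_smiles(smiles)
  n <- length(mol$element)
  deg <- mol_degree(mol)
  ring_bond <- mol_ring_bonds(mol)
  in_ring <- rep(FALSE, n)
  if (any(ring_bond)) {
    in_ring[unique(unlist(mol$bonds[ring_bond, c("a1", "a2")]))] <- TRUE
  }
  elem_code <- vapply(mol$element, function(e) hash_mix(7, utf8ToInt(e)), numeric(1))

  ids <- vapply(seq_len(n), function(a) {
    hash_mix(17, c(elem_code[a], deg[a], mol$charge[a] + 8, as.numeric(in_ring[a])))
  }, numeric(1))

  nbrs <- lapply(seq_len(n), function(a) {
    k1 <- which(mol$bonds$a1 == a); k2 <- which(mol$bonds$a2 == a)
    list(atom = c(mol$bonds$a2[k1], mol$bonds$a1[k2]),
         order = c(mol$bonds$order[k1], mol$bonds$order[k2]))
  })

  all_ids <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(a) {
      nb <- nbrs[[a]]
      if (!length(nb$atom)) return(hash_mix(23 + r, ids[a]))
      enc <- nb$order * MERSENNE31 / 8 + ids[nb$atom]
      hash_mix(23 + r, c(ids[a], sort(enc)))
    }, numeric(1))
    all_ids <- c(all_ids, ids)
  }
  bits <- sort(unique(as.integer(all_ids %% n_bits) + 1L))
  new_morgan_fp(bits, n_bits, smiles = smiles)
}

new_morgan_fp <- function(bits, n_bits, smiles = NA_character_) {
  structure(list(bits = as.integer(bits), n_bits = as.integer(n_bits),
                 n_on = length(bits), smiles = smiles),
            class = "morgan_fp")
}

#' @export
print.morgan_fp <- function(x, ...) {
  cat(sprintf("<morgan_fp> %d/%d bits set (%s)\n", x$n_on, x$n_bits,
              x$smiles %||% "?"))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' Number of shared set bits divided by the size of their union; defined as 1
#' when both fingerprints are all-zero.
#'
#' @param a,b `morgan_fp` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (a$n_bits != b$n_bits) {
    stopf("combisyn_value_error",
          "fingerprint length mismatch: %d vs %d", a$n_bits, b$n_bits)
  }
  u <- length(union(a$bits, b$bits))
  if (u == 0) return(1)
  length(intersect(a$bits, b$bits)) / u
}

#' Build a fingerprint library from identified SMILES
#'
#' Unparseable SMILES are dropped (never abort a batch) and reported in the
#' `dropped` attribute.
#'
#' @param drugs Tibble with columns `drug_id` and `smiles`.
#' @param radius,n_bits Passed to [morgan_fingerprint()].
#' @return Tibble `drug_id`, `smiles`, `fp` (list column of `morgan_fp`),
#'   with attribute `dropped` (tibble of failures).
#' @export
fingerprint_library <- function(drugs, radius = 2, n_bits = 2048) {
  fps <- purrr::map(drugs$smiles, function(s) {
    tryCatch(morgan_fingerprint(s, radius, n_bits), error = function(e) NULL)
  })
  ok <- !vapply(fps, is.null, logical(1))
  out <- tibble(drug_id = drugs$drug_id[ok], smiles = drugs$smiles[ok],
                fp = fps[ok])
  attr(out, "dropped") <- tibble(drug_id = drugs$drug_id[!ok],
                                 smiles = drugs$smiles[!ok])
  out
}

#' Match a query structure against a reference fingerprint library
#'
#' Returns the maximum-similarity reference entry (ties broken by
#' lexicographic id) and the merge decision: structures merge only at
#' similarity exactly 1 (synonyms, not analogs).
#'
#' @param query A SMILES string or a `morgan_fp`.
#' @param reference A [fingerprint_library()] tibble (non-empty).
#' @param profile If `TRUE`, attach the full similarity profile.
#' @return One-row tibble `best_id`, `similarity`, `merge`; with
#'   `profile = TRUE`, attribute `profile` holds the per-reference tibble.
#' @export
match_drug <- function(query, reference, profile = FALSE) {
  if (!nrow(reference)) {
    stopf("combisyn_value_error", "reference library is empty")
  }
  qfp <- if (inherits(query, "morgan_fp")) query else morgan_fingerprint(query)
  sims <- vapply(reference$fp, function(f) tanimoto(qfp, f), numeric(1))
  ord <- order(-sims, reference$drug_id)
  best <- ord[1]
  out <- tibble(best_id = reference$drug_id[best],
                similarity = sims[best],
                merge = sims[best] == 1)
  if (profile) {
    attr(out, "profile") <- tibble(drug_id = reference$drug_id, similarity = sims) |>
      arrange(dplyr::desc(.data$similarity), .data$drug_id)
  }
  out
}
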