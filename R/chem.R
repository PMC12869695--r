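# SMILES parsing (via ChemmineR/OpenBabel) and the internal molecule
# representation used by fingerprints and molecular graphs.

# Parse one SMILES into atoms (element, charge) and bonds (a1, a2, order).
# Hydrogens are implicit; OpenBabel returns kekulized bond orders.
parse_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stopf("combisyn_parse_error", "ChemmineR is required for SMILES parsing")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) {
    stopf("combisyn_parse_error", "unparseable SMILES: '%s'", smiles)
  }
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0) {
    stopf("combisyn_parse_error", "unparseable SMILES: '%s'", smiles)
  }
  element <- sub("_.*$", "", rownames(ab))
  n <- length(element)
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  if (!is.null(bb) && !is.matrix(bb)) bb <- rbind(bb)
  bonds <- if (is.null(bb) || length(bb) == 0 || nrow(bb) == 0 || ncol(bb) < 3) {
    tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }
  charge <- rep(0L, n)
  txt <- tryCatch(as.character(ChemmineR::sdf2str(mol)), error = function(e) character())
  for (line in grep("^M  CHG", txt, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", line)), "\\s+")[[1]])
    if (length(flds) >= 2) {
      idx <- flds[seq(1, length(flds), by = 2)]
      val <- flds[seq(2, length(flds), by = 2)]
      charge[idx] <- val
    }
  }
  list(smiles = smiles, element = element, charge = charge, bonds = bonds)
}

# Heavy-atom degree per atom.
mol_degree <- function(mol) {
  deg <- rep(0L, length(mol$element))
  if (nrow(mol$bonds)) {
    t1 <- table(factor(mol$bonds$a1, levels = seq_along(deg)))
    t2 <- table(factor(mol$bonds$a2, levels = seq_along(deg)))
    deg <- as.integer(t1 + t2)
  }
  deg
}

# Bond-in-ring flags: a bond is in a ring iff its endpoints stay connected
# after the bond is removed.
mol_ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(
    as.matrix(mol$bonds[, c("a1", "a2")]), directed = FALSE)
  vapply(seq_len(nb), function(k) {
    g2 <- igraph::delete_edges(g, k)
    igraph::are_adjacent(g2, mol$bonds$a1[k], mol$bonds$a2[k]) ||
      !is.infinite(igraph::distances(g2, v = mol$bonds$a1[k])[mol$bonds$a2[k]])
  }, logical(1))
}

# Minimal aromaticity perception on the kekulized graph: a ring component is
# aromatic when every atom in it carries exactly one double bond among the
# ring bonds (an alternating Kekule pattern, e.g. benzene, pyridine). This is
# deliberately minimal chemistry - adequate for the synthetic fragment table.
mol_aromatic_atoms <- function(mol) {
  n <- length(mol$element)
  arom <- rep(FALSE, n)
  if (!nrow(mol$bonds)) return(arom)
  inring <- mol_ring_bonds(mol)
  rb <- mol$bonds[inring, , drop = FALSE]
  if (!nrow(rb)) return(arom)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rb$a1, to = rb$a2), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    atoms <- which(comp$membership == cid)
    if (length(atoms) < 5) next
    ndouble <- vapply(atoms, function(a) {
      sum(rb$order[(rb$a1 == a | rb$a2 == a)] == 2)
    }, numeric(1))
    if (all(ndouble == 1)) arom[atoms] <- TRUE
  }
  arom
}
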