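# Molecular graphs: per-atom feature vectors plus a symmetric adjacency
# matrix, the graph-shaped chemical input representation.

GRAPH_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")

#' Convert a SMILES string to a molecular graph
#'
#' One node per heavy atom (hydrogens implicit), one undirected edge per
#' bond. Atom features are an element one-hot (over C, N, O, S, P, F, Cl,
#' Br, I, other), heavy-atom degree, formal charge and an aromatic flag.
#'
#' @param smiles A single SMILES string.
#' @return A `molecular_graph` object: `atom_features` (atoms x features
#'   matrix) and `adjacency` (symmetric binary matrix, zero diagonal), plus
#'   a `bonds` tibble with bond orders.
#' @export
#' @examples
#' \donttest{
#' g <- smiles_to_graph("C1CC1")  # cyclopropane: 3 atoms, 3 edges
#' sum(g$adjacency) / 2
#' }
smiles_to_graph <- function(smiles) {
  mol <- parse_smiles(smiles)
  n <- length(mol$element)
  deg <- mol_degree(mol)
  arom <- mol_aromatic_atoms(mol)

  elem <- ifelse(mol$element %in% GRAPH_ELEMENTS, mol$element, "other")
  onehot <- matrix(0, n, length(GRAPH_ELEMENTS),
                   dimnames = list(NULL, paste0("elem_", GRAPH_ELEMENTS)))
  onehot[cbind(seq_len(n), match(elem, GRAPH_ELEMENTS))] <- 1

  feats <- cbind(onehot, degree = deg, charge = mol$charge,
                 aromatic = as.numeric(arom))
  adj <- matrix(0, n, n)
  if (nrow(mol$bonds)) {
    adj[cbind(mol$bonds$a1, mol$bonds$a2)] <- 1
    adj[cbind(mol$bonds$a2, mol$bonds$a1)] <- 1
  }
  structure(list(smiles = smiles, atom_features = feats, adjacency = adj,
                 bonds = mol$bonds),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d atoms, %d bonds, %d aromatic\n",
              x$smiles, nrow(x$atom_features), nrow(x$bonds),
              sum(x$atom_features[, "aromatic"])))
  invisible(x)
}
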