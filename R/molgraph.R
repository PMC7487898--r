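# Molecular featurization: 133-d atom and 14-d bond feature vectors, the
# directed-bond message-passing graph used by the property encoder, and the
# dense (A, E, F) state used by the construction environment.

#' Feature vector dimensions
#'
#' Atom features occupy 133 slots: atomic number one-hot (1..100 plus an
#' uncommon slot), degree (0..5 + uncommon), formal charge (-2..+2 + uncommon),
#' chiral tag (0..3 + uncommon), implicit hydrogen count (0..4 + uncommon),
#' hybridization (SP, SP2, SP3, SP3D, SP3D2 + uncommon), an aromaticity flag
#' and the atomic mass scaled by 0.01. Bond features occupy 14 slots: bond
#' present, bond order one-hot (single/double/triple), aromatic, conjugated,
#' in-ring, and a 7-slot stereo code. A directed bond's network input is the
#' 147-long concatenation of its source-atom features and its bond features.
#'
#' @name feature_dims
#' @format Integer constants `ATOM_FDIM` (133), `BOND_FDIM` (14),
#'   `BOND_INPUT_DIM` (147).
NULL

#' @rdname feature_dims
#' @export
ATOM_FDIM <- 133L

#' @rdname feature_dims
#' @export
BOND_FDIM <- 14L

#' @rdname feature_dims
#' @export
BOND_INPUT_DIM <- ATOM_FDIM + BOND_FDIM

# block start offsets (0-based index of first slot of each block)
.ATOM_BLOCKS <- list(
  z       = list(off = 0L,   size = 101L),  # values 1..100, last slot uncommon
  degree  = list(off = 101L, size = 7L),    # values 0..5,   last slot uncommon
  charge  = list(off = 108L, size = 6L),    # values -2..2,  last slot uncommon
  chiral  = list(off = 114L, size = 5L),    # values 0..3,   last slot uncommon
  n_h     = list(off = 119L, size = 6L),    # values 0..4,   last slot uncommon
  hybrid  = list(off = 125L, size = 6L)     # codes 1..5,    last slot uncommon
)

.one_hot_block <- function(vec, block, value, min_value) {
  pos <- value - min_value
  if (is.na(pos) || pos < 0 || pos >= block$size - 1L) pos <- block$size - 1L
  vec[block$off + pos + 1L] <- 1
  vec
}

#' Featurize an atom descriptor
#'
#' Lays out a single atom's descriptor into the 133-slot feature vector.
#' Values outside a block's covered range light that block's designated
#' "uncommon" slot, so no input can fail to featurize.
#'
#' @param atomic_num atomic number.
#' @param degree heavy-atom neighbour count.
#' @param formal_charge integer formal charge.
#' @param chiral_tag chirality code (0 = unspecified).
#' @param n_h implicit hydrogen count.
#' @param hybridization code 1..5 for SP, SP2, SP3, SP3D, SP3D2 (0 = other).
#' @param aromatic logical aromaticity flag.
#' @param mass atomic mass (amu); stored as `mass * 0.01`.
#' @return numeric vector of length 133.
#' @export
#' @examples
#' v <- featurize_atom(6, 2, 0, 0, 1, 2, TRUE, 12.011)
#' which(v != 0)
featurize_atom <- function(atomic_num, degree, formal_charge, chiral_tag,
                           n_h, hybridization, aromatic, mass) {
  v <- numeric(ATOM_FDIM)
  b <- .ATOM_BLOCKS
  v <- .one_hot_block(v, b$z, atomic_num, 1L)
  v <- .one_hot_block(v, b$degree, degree, 0L)
  v <- .one_hot_block(v, b$charge, formal_charge, -2L)
  v <- .one_hot_block(v, b$chiral, chiral_tag, 0L)
  v <- .one_hot_block(v, b$n_h, n_h, 0L)
  v <- .one_hot_block(v, b$hybrid, hybridization, 1L)
  v[132] <- as.numeric(isTRUE(aromatic) || (is.numeric(aromatic) && aromatic != 0))
  v[133] <- mass * 0.01
  v
}

#' Featurize a bond descriptor
#'
#' 14-slot bond feature vector: slot 1 flags a bond being present (the zero
#' vector is the "no bond" placeholder), slots 2-4 one-hot the kekulized bond
#' order, then aromatic / conjugated / in-ring flags and a 7-slot stereo code
#' (codes 0-5 plus an uncommon slot). A bond order outside 1..3 that is not
#' aromatic leaves the order block all zero and raises a warning.
#'
#' @param order kekulized bond order (1, 2, 3).
#' @param aromatic,conjugated,in_ring logical flags.
#' @param stereo stereo code 0..5 (0 = none).
#' @return numeric vector of length 14.
#' @export
featurize_bond <- function(order, aromatic = FALSE, conjugated = FALSE,
                           in_ring = FALSE, stereo = 0L) {
  v <- numeric(BOND_FDIM)
  v[1] <- 1
  if (order %in% 1:3) {
    v[1 + order] <- 1
  } else if (!isTRUE(aromatic)) {
    warning("unknown bond order ", order, "; bond-type block left all zero")
  }
  v[5] <- as.numeric(isTRUE(aromatic))
  v[6] <- as.numeric(isTRUE(conjugated))
  v[7] <- as.numeric(isTRUE(in_ring))
  pos <- if (is.na(stereo) || stereo < 0 || stereo > 5) 6L else as.integer(stereo)
  v[8 + pos] <- 1
  v
}

.atom_feature_matrix <- function(mol) {
  a <- mol$atoms
  t(vapply(seq_len(nrow(a)), function(i) {
    featurize_atom(a$z[i], a$degree[i], a$charge[i], a$chiral[i], a$n_h[i],
                   a$hybridization[i], a$aromatic[i], a$mass[i])
  }, numeric(ATOM_FDIM)))
}

#' Build the directed message-passing graph of a molecule
#'
#' Every chemical bond yields two directed bonds. Each directed bond carries a
#' 147-long network input: the feature vector of its source atom concatenated
#' with the bond's feature vector. `incoming[[a]]` lists the directed bonds
#' pointing into atom `a`; `reverse[b]` is the opposite-direction twin of
#' directed bond `b`.
#'
#' @param smiles a SMILES string, or a `mol` object.
#' @return an object of class `mol_graph` with fields `atom_features`
#'   (n x 133), `bond_src`, `bond_dst`, `bond_features` (2m x 14),
#'   `bond_inputs` (2m x 147), `incoming`, `reverse`, `n_atoms`, `n_bonds`,
#'   `mol`.
#' @export
#' @examples
#' g <- smiles_to_graph("CC")
#' g$n_bonds            # 2 directed bonds
#' ncol(g$bond_inputs)  # 147
smiles_to_graph <- function(smiles) {
  mol <- if (inherits(smiles, "mol")) smiles else parse_smiles(smiles)
  af <- .atom_feature_matrix(mol)
  m <- nrow(mol$bonds)
  nb <- 2L * m
  src <- integer(nb); dst <- integer(nb); rev <- integer(nb)
  bf <- matrix(0, nb, BOND_FDIM)
  if (m > 0) {
    for (k in seq_len(m)) {
      b <- mol$bonds[k, ]
      fv <- featurize_bond(b$order, b$aromatic, b$conjugated, b$in_ring, b$stereo)
      i1 <- 2L * k - 1L; i2 <- 2L * k
      src[i1] <- b$a1; dst[i1] <- b$a2
      src[i2] <- b$a2; dst[i2] <- b$a1
      bf[i1, ] <- fv; bf[i2, ] <- fv
      rev[i1] <- i2; rev[i2] <- i1
    }
  }
  bi <- if (nb > 0) cbind(af[src, , drop = FALSE], bf) else
    matrix(0, 0, BOND_INPUT_DIM)
  incoming <- lapply(seq_len(nrow(af)), function(a) which(dst == a))
  # precomputed bond->bond aggregation pairs (excluding the reverse twin),
  # so batching is a pure index shift
  agg_i <- integer(0); agg_j <- integer(0)
  if (nb > 0) {
    for (b in seq_len(nb)) {
      nbrs <- incoming[[src[b]]]
      nbrs <- nbrs[nbrs != rev[b]]
      if (length(nbrs)) {
        agg_i <- c(agg_i, rep.int(b, length(nbrs)))
        agg_j <- c(agg_j, nbrs)
      }
    }
  }
  structure(list(
    atom_features = af, bond_src = src, bond_dst = dst,
    bond_features = bf, bond_inputs = bi,
    incoming = incoming, reverse = rev, agg_i = agg_i, agg_j = agg_j,
    n_atoms = nrow(af), n_bonds = nb, mol = mol
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$n_atoms, " atoms, ", x$n_bonds, " directed bonds\n",
      sep = "")
  invisible(x)
}

# ---- dense (A, E, F) state -------------------------------------------------

#' Dense graph state for the construction environment
#'
#' The environment's molecule representation: adjacency `A` (n x n, 0/1),
#' edge-conditioned tensor `E` (3 x n x n; slices are single/double/triple;
#' aromatic systems are kekulized so that three slices suffice), node feature
#' matrix `F` (n x 133) and the element symbol of each node. `A[j,k] = 1`
#' exactly when some slice of `E` is set at (j,k), and at most one slice is
#' set per pair.
#'
#' @param x a SMILES string or `mol` object.
#' @return an object of class `dense_state` with fields `A`, `E`, `F`,
#'   `elements`, `n`.
#' @export
#' @examples
#' st <- as_dense_state("CCO")
#' st$n
as_dense_state <- function(x) {
  mol <- if (inherits(x, "mol")) x else parse_smiles(x)
  n <- nrow(mol$atoms)
  A <- matrix(0L, n, n)
  E <- array(0L, dim = c(3L, n, n))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      stopifnot(o %in% 1:3)
      A[a, b] <- A[b, a] <- 1L
      E[o, a, b] <- E[o, b, a] <- 1L
    }
  }
  structure(list(A = A, E = E, F = .atom_feature_matrix(mol),
                 elements = mol$atoms$element, n = n),
            class = "dense_state")
}

#' @export
print.dense_state <- function(x, ...) {
  cat("<dense_state> n = ", x$n, " (",
      paste(x$elements, collapse = ""), ")\n", sep = "")
  invisible(x)
}

# rebuild a mol (kekulized, neutral) from a dense state
.state_to_mol <- function(state) {
  stopifnot(inherits(state, "dense_state"))
  n <- state$n
  a1 <- integer(0); a2 <- integer(0); ord <- integer(0)
  if (n > 1) {
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      o <- which(state$E[, j, k] == 1L)
      if (length(o) > 1) stop("dense state has multiple bond orders at (",
                              j, ",", k, ")")
      if (length(o) == 1) { a1 <- c(a1, j); a2 <- c(a2, k); ord <- c(ord, o) }
    }
  }
  bonds <- tibble::tibble(a1 = a1, a2 = a2, order = ord,
                          aromatic = FALSE, conjugated = FALSE,
                          in_ring = FALSE, stereo = 0L)
  .finish_mol(state$elements, integer(n), bonds, integer(0))
}

#' Convert a dense state back to a molecule and canonical SMILES
#'
#' Inverse of [as_dense_state()]: rebuilds the kekulized bond graph encoded in
#' `E`, re-perceives aromaticity during SMILES generation, and returns the
#' canonical SMILES. Valence-violating states raise an error (unreachable when
#' states come from the environment, whose steps are valence-checked).
#'
#' @param state a `dense_state`.
#' @return list with elements `mol` and `smiles`.
#' @export
state_to_molecule <- function(state) {
  mol <- .state_to_mol(state)
  smi <- suppressWarnings(mol_to_smiles(mol))
  if (is.na(smi)) stop("dense state does not encode a convertible molecule")
  caps <- .element_row(mol$atoms$element)$max_valence
  bsum <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    bsum[mol$bonds$a1[k]] <- bsum[mol$bonds$a1[k]] + mol$bonds$order[k]
    bsum[mol$bonds$a2[k]] <- bsum[mol$bonds$a2[k]] + mol$bonds$order[k]
  }
  if (any(bsum > caps)) stop("dense state violates valence caps")
  list(mol = mol, smiles = smi)
}
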