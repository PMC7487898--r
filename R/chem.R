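# Internal chemistry layer: a light molecular-graph record ("mol") built on
# ChemmineR/ChemmineOB (Open Babel). All SMILES parsing, canonicalization and
# SDF text handling funnel through here.

# Element data for the species this package generates or commonly parses.
# default_valence: neutral-atom valence used to fill implicit hydrogens;
# max_valence: cap used by the construction environment's valency check.
.ELEMENTS <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  z      = c(1, 5, 6, 7, 8, 9, 14, 15, 16, 17, 35, 53),
  mass   = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 28.086, 30.974,
             32.06, 35.453, 79.904, 126.904),
  default_valence = c(1, 3, 4, 3, 2, 1, 4, 3, 2, 1, 1, 1),
  max_valence     = c(1, 3, 4, 3, 2, 1, 4, 5, 6, 1, 1, 1),
  stringsAsFactors = FALSE
)

.element_row <- function(symbol) {
  i <- match(symbol, .ELEMENTS$symbol)
  if (anyNA(i)) stop("unknown element symbol: ",
                     paste(unique(symbol[is.na(i)]), collapse = ", "))
  .ELEMENTS[i, , drop = FALSE]
}

.atomic_number <- function(symbol) .element_row(symbol)$z
.atomic_mass <- function(symbol) .element_row(symbol)$mass

#' @noRd
.mdl_charge_from_code <- function(code) {
  # MDL V2000 charge codes: 0 none, 1 +3, 2 +2, 3 +1, 4 radical, 5 -1, 6 -2, 7 -3
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0
  unname(out)
}

.mdl_code_from_charge <- function(q) {
  map <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6, `-3` = 7)
  out <- map[as.character(q)]
  out[is.na(out)] <- 0
  unname(out)
}

# Implicit hydrogen count from default valence, formal charge and total bond
# order. Charge shifts valence for N/P/O/S (protonation/deprotonation); carbon
# loses a slot either way (carbocation/carbanion).
.implicit_h <- function(symbol, charge, bond_order_sum) {
  v <- .element_row(symbol)$default_valence
  adj <- ifelse(symbol %in% c("N", "P", "O", "S"), charge,
                ifelse(symbol == "C", -abs(charge), 0))
  pmax(0L, as.integer(round(v + adj - bond_order_sum)))
}

# Hybridization code 1..5 = SP, SP2, SP3, SP3D, SP3D2; 0 = other/unknown.
# Rule-based perception: aromatic -> SP2; triple or cumulated double -> SP;
# one double -> SP2; else by total connection count (heavy neighbours + H).
.hybridization <- function(aromatic, n_double, n_triple, total_conn) {
  ifelse(total_conn >= 6, 6L,
  ifelse(total_conn == 5, 4L,
  ifelse(aromatic, 2L,
  ifelse(n_triple >= 1 | n_double >= 2, 1L,
  ifelse(n_double == 1, 2L, 3L)))))
}

#' Canonicalize SMILES strings
#'
#' Canonical SMILES via Open Babel's canonicalization. Unparsable inputs
#' produce an error naming the offending string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "C1=CC=CC=C1"))
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  out <- vapply(smiles, function(s) {
    res <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
      error = function(e) ""
    ))
    res <- sub("[\t\n ].*$", "", res)
    if (!nzchar(res)) stop("cannot parse SMILES: ", s, call. = FALSE)
    res
  }, character(1))
  unname(out)
}

# ---- mol construction ------------------------------------------------------

# A "mol" is a kekulized heavy-atom graph:
#   atoms: tibble(element, z, charge, aromatic, degree, n_h, hybridization,
#                 mass, chiral)
#   bonds: tibble(a1, a2, order, aromatic, conjugated, in_ring, stereo)
.new_mol <- function(atoms, bonds, smiles = NA_character_) {
  structure(list(atoms = atoms, bonds = bonds, smiles = smiles), class = "mol")
}

#' @export
print.mol <- function(x, ...) {
  cat("<mol> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds",
      if (!is.na(x$smiles)) paste0("  ", x$smiles), "\n", sep = "")
  invisible(x)
}

# Derive the perception-dependent atom columns once elements/charges and the
# kekulized bond list are known. ring_atoms/aromatic_* come from ring analysis.
.finish_mol <- function(element, charge, bonds, aromatic_atoms, chiral = NULL,
                        smiles = NA_character_) {
  n <- length(element)
  deg <- integer(n); bsum <- numeric(n); ndbl <- integer(n); ntrp <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]; o <- bonds$order[k]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bsum[a] <- bsum[a] + o; bsum[b] <- bsum[b] + o
      if (o == 2) { ndbl[a] <- ndbl[a] + 1L; ndbl[b] <- ndbl[b] + 1L }
      if (o == 3) { ntrp[a] <- ntrp[a] + 1L; ntrp[b] <- ntrp[b] + 1L }
    }
  }
  arom <- seq_len(n) %in% aromatic_atoms
  nh <- .implicit_h(element, charge, bsum)
  hyb <- .hybridization(arom, ndbl, ntrp, deg + nh)
  if (is.null(chiral)) chiral <- integer(n)
  atoms <- tibble::tibble(
    element = element, z = .atomic_number(element), charge = as.integer(charge),
    aromatic = arom, degree = deg, n_h = nh, hybridization = as.integer(hyb),
    mass = .atomic_mass(element), chiral = as.integer(chiral)
  )
  # conjugation heuristic: a bond is conjugated if it is aromatic, or if both
  # end atoms can take part in a pi system (carry a multiple bond, or are
  # N/O/S lone-pair donors) and at least one incident bond is a multiple bond
  pi_centre <- ndbl + ntrp > 0 | arom | element %in% c("N", "O", "S")
  if (nrow(bonds)) {
    has_multi <- function(a, b) (ndbl[a] + ntrp[a] + ndbl[b] + ntrp[b]) > 0
    conj <- logical(nrow(bonds))
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]
      conj[k] <- bonds$aromatic[k] ||
        (pi_centre[a] && pi_centre[b] && (has_multi(a, b) || bonds$aromatic[k]))
    }
    bonds$conjugated <- conj
  }
  .new_mol(atoms, bonds, smiles)
}

# Parse one V2000 molblock (as produced by Open Babel) that has no bonds.
# ChemmineR's SDF reader rejects bondless records, so this tiny fixed-format
# case is read directly.
.bondless_mol_from_molblock <- function(lines, smiles) {
  natoms <- as.integer(substr(lines[4], 1, 3))
  element <- character(natoms); charge <- integer(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4 + i]
    element[i] <- trimws(substr(ln, 32, 34))
    charge[i] <- .mdl_charge_from_code(as.integer(substr(ln, 37, 39)))
  }
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg) {
    v <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    nent <- v[1]
    for (j in seq_len(nent)) charge[v[2 * j]] <- v[2 * j + 1]
  }
  empty_bonds <- tibble::tibble(
    a1 = integer(), a2 = integer(), order = integer(), aromatic = logical(),
    conjugated = logical(), in_ring = logical(), stereo = integer()
  )
  .finish_mol(element, charge, empty_bonds, integer(0), smiles = smiles)
}

.mol_from_sdf_object <- function(sdf, smiles = NA_character_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  charge <- .mdl_charge_from_code(ab[, 5])
  chiral <- ab[, 6]
  chiral[!chiral %in% c(0, 1, 2)] <- 0
  nb <- nrow(bb)
  bonds <- tibble::tibble(
    a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
    order = as.integer(bb[, 3]),
    aromatic = FALSE, conjugated = FALSE, in_ring = FALSE,
    stereo = as.integer(ifelse(bb[, 4] == 0, 0L, 1L))
  )
  aromatic_atoms <- integer(0)
  if (nb > 0) {
    rr <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = NULL, AROMATIC = NULL))
    ring_list <- rr$RINGS
    if (!is.null(ring_list) && length(ring_list)) {
      bond_key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
      for (ri in seq_along(ring_list)) {
        idx <- as.integer(sub("^.*_", "", ring_list[[ri]]))
        pairs <- cbind(idx, c(idx[-1], idx[1]))
        keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
        hit <- bond_key %in% keys
        bonds$in_ring[hit] <- TRUE
        if (isTRUE(rr$AROMATIC[[ri]])) {
          bonds$aromatic[hit] <- TRUE
          aromatic_atoms <- union(aromatic_atoms, idx)
        }
      }
    }
  }
  .finish_mol(element, charge, bonds, aromatic_atoms, chiral = chiral,
              smiles = smiles)
}

#' Parse SMILES into molecular-graph records
#'
#' Converts SMILES to kekulized heavy-atom graph records with perceived
#' aromaticity, ring membership, implicit hydrogen counts and hybridization.
#' Parsing and ring/aromaticity perception are done by Open Babel through
#' ChemmineR; hydrogens are implicit throughout.
#'
#' @param smiles character vector of SMILES.
#' @return a list of `mol` objects (or a single `mol` when `length(smiles)==1`).
#' @export
#' @examples
#' m <- parse_smiles("c1ccccc1O")
#' m$atoms
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    txt <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(s, "\n")),
      error = function(e) ""
    ))
    if (!nzchar(txt)) stop("cannot parse SMILES: ", s, call. = FALSE)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
    nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
    if (is.na(natoms) || natoms == 0) stop("cannot parse SMILES: ", s, call. = FALSE)
    if (nbonds == 0) {
      out[[i]] <- .bondless_mol_from_molblock(lines, s)
    } else {
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(lines))
      out[[i]] <- .mol_from_sdf_object(sdfset[[1]], s)
    }
  }
  if (length(out) == 1) out[[1]] else out
}

# ---- mol -> SDF text / SMILES ---------------------------------------------

#' @noRd
mol_to_molblock <- function(mol) {
  n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  header <- c("", " molforge", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atoml <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, mol$atoms$element[i],
            .mdl_code_from_charge(mol$atoms$charge[i]))
  }, character(1))
  bondl <- if (nb) vapply(seq_len(nb), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1[k], mol$bonds$a2[k],
            mol$bonds$order[k])
  }, character(1)) else character(0)
  chg <- which(mol$atoms$charge != 0)
  chgl <- if (length(chg)) {
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, mol$atoms$charge[i]),
           character(1))
  } else character(0)
  paste(c(header, counts, atoml, bondl, chgl, "M  END", "$$$$"), collapse = "\n")
}

#' Canonical SMILES of a molecular-graph record
#'
#' Serializes the kekulized graph and lets Open Babel re-perceive aromaticity
#' and canonicalize. Returns `NA` (with a warning) if conversion fails, which
#' is how chemically unsound graphs surface.
#'
#' @param mol a `mol` object.
#' @return length-1 character (canonical SMILES) or `NA`.
#' @export
mol_to_smiles <- function(mol) {
  stopifnot(inherits(mol, "mol"))
  txt <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", mol_to_molblock(mol)),
    error = function(e) ""
  ))
  txt <- sub("[\t\n ].*$", "", txt)
  if (!nzchar(txt)) {
    warning("molecular graph could not be converted to SMILES")
    return(NA_character_)
  }
  txt
}

#' Check that a molecular graph is chemically valid
#'
#' A graph is sanitizable when every atom respects its valence cap (implicit
#' hydrogens filling the remainder) and the graph converts to a non-empty
#' canonical SMILES.
#'
#' @param mol a `mol` object.
#' @return logical flag.
#' @export
is_sanitizable <- function(mol) {
  stopifnot(inherits(mol, "mol"))
  bsum <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a1[k]] <- bsum[mol$bonds$a1[k]] + mol$bonds$order[k]
      bsum[mol$bonds$a2[k]] <- bsum[mol$bonds$a2[k]] + mol$bonds$order[k]
    }
  }
  caps <- .element_row(mol$atoms$element)$max_valence
  if (any(bsum > caps + mol$atoms$charge * 0)) return(FALSE)
  !is.na(suppressWarnings(mol_to_smiles(mol)))
}

#' Heavy-atom count of a molecular-graph record
#' @param mol a `mol` object.
#' @return integer count of non-hydrogen atoms.
#' @export
n_heavy_atoms <- function(mol) nrow(mol$atoms)
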