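# Synthetic fixtures: a deterministic pseudo-pKi oracle over interpretable
# graph descriptors, a labelled-dataset generator with heavy-tailed label
# contamination (emulating affinity data whose large-Ki entries are recorded
# as rough "~1000"-style caps), and a drug-like expert molecule set. These
# stand in for the binding-affinity and commercial-library inputs so every
# pipeline stage runs offline.

# A pool of small drug-like molecules (all <= 25 heavy atoms, all neutral and
# sanitizable; verified by the test suite). Datasets sample from this pool
# with random single-atom decorations, so generated sets are larger and more
# varied than the pool itself.
.FIXTURE_POOL <- c(
  "CC(=O)Oc1ccccc1C(=O)O",          # aspirin
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",     # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",             # paracetamol
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",     # caffeine
  "NC(=O)c1ccccc1",                 # benzamide
  "OC(=O)c1ccccc1O",                # salicylic acid
  "Clc1ccc(cc1)C(=O)NC1CC1",
  "O=C(NCc1ccccc1)C1CCNCC1",
  "COc1ccc(CCN)cc1",
  "NCCc1ccc(O)c(O)c1",              # dopamine
  "OCC(O)c1ccc(O)c(O)c1",
  "CNCC(O)c1ccc(O)c(O)c1",          # epinephrine-like
  "NCCc1c[nH]c2ccccc12",            # tryptamine
  "CN1CCC(CC1)Oc1ccccc1",
  "O=C(O)CCc1ccccc1",
  "CC(N)Cc1ccccc1",                 # amphetamine
  "CNC(C)Cc1ccccc1",                # methamphetamine-like
  "Fc1ccc(cc1)C(=O)CCCN1CCC(O)CC1",
  "CCN(CC)CCNC(=O)c1ccccc1",
  "COc1ccccc1OCCN",
  "CC1CCCCN1C",
  "O1CCN(CC1)c1ccccc1",
  "CN1CCN(CC1)c1ccccc1",
  "Clc1ccccc1CN1CCNCC1",
  "OC1CCN(CC1)Cc1ccccc1",
  "CC(=O)N1CCN(CC1)c1ccccc1",
  "c1ccc2[nH]ccc2c1",               # indole
  "c1ccc2ncccc2c1",                 # quinoline
  "c1ccc2[nH]cnc2c1",               # benzimidazole
  "Cc1ccccc1NC(=O)C",
  "CCOC(=O)c1ccccc1N",
  "NS(=O)(=O)c1ccccc1",
  "CC(C)NCC(O)c1ccccc1",
  "COC(=O)C1CCCCN1",
  "O=C1CCCN1c1ccccc1",
  "CC(C)(C)NCC(O)c1ccc(O)cc1",
  "Nc1ccc(cc1)S(=O)(=O)N",
  "OCc1ccc(O)cc1",
  "CCN1CCCC1CNC(=O)c1ccccc1",
  "Cc1cccc(C)c1NC(=O)CN",
  "COc1cc2CCNCc2cc1OC",
  "O=C(Nc1ccccc1)C1CC1",
  "CC(C)C(=O)NC1CCCCC1",
  "N#Cc1ccccc1N1CCCC1",
  "CSc1ccccc1C(=O)N",
  "Fc1ccc(F)cc1CNC",
  "Brc1ccc(cc1)C(=O)O",
  "Ic1ccccc1CO",
  "CCOc1ccc(cc1)C(C)=O",
  "CC1CC(C)CN(C1)C(C)=O",
  "O=S(=O)(N1CCCC1)c1ccccc1",
  "NC1CCC(CC1)c1ccccc1",
  "OC(c1ccccc1)C1CCNC1",
  "Cn1ccc2ccccc21",
  "CCC(CO)Nc1ccccn1",
  "O=C(OCC)C1CCN(C)CC1",
  "Cc1nc2ccccc2[nH]1",
  "CN(C)CCOC(c1ccccc1)c1ccccc1",
  "CC(O)c1ccc(C)cc1",
  "COc1ccc(cc1)N1CCOCC1",
  "CN1CCCC1c1cccnc1",               # nicotine
  "Oc1ccc2CC(N)Cc2c1",
  "CC(C)N1CCN(CC1)C(=O)C",
  "Clc1cccc(Cl)c1NC(=O)CN1CCCC1"
)

#' The built-in fixture molecule pool
#' @return character vector of SMILES (all valid, <= 25 heavy atoms).
#' @export
fixture_pool <- function() .FIXTURE_POOL

#' Toy property oracle parameters
#'
#' Weights over interpretable graph descriptors: ring count (cyclomatic),
#' aromatic ring count, heteroatom fraction, heavy-atom count (centred at 10)
#' and a hydrophobicity-like carbon-excess term `(nC - nHet)/n`. Output is
#' clamped to the pKi-like range `[2, 10]`. Defaults give pseudo-pKi values
#' spanning roughly 4-8 over the fixture pool.
#'
#' The default weights put most of the signal on graph-local structure
#' (rings, aromaticity, heteroatom composition), which a message-passing
#' encoder with mean pooling can represent; the extensive size term gets a
#' small weight because mean-pooled embeddings carry molecule size only
#' indirectly, and ring/aromatic-ring counts are likewise extensive, so the
#' heteroatom composition terms carry nearly all of the signal. The weights
#' are scaled so that scores over the fixture pool span a realistic affinity
#' range (mean ~6.6, sd ~1.0, range ~4.4-10 pseudo-pKi).
#' Note the hydrophobicity and heteroatom-fraction descriptors are exactly
#' collinear on heavy-atom graphs (`(nC - nHet)/n = 1 - 2 * het_frac`), so
#' their joint effect is the net of the two weights.
#'
#' @param ring,aromatic,het_frac,heavy,hydrophobic,bias numeric weights.
#' @param clamp length-2 output range.
#' @return a `toy_oracle_params` list.
#' @export
toy_oracle_params <- function(ring = 0.25, aromatic = 0.2, het_frac = 16,
                              heavy = 0.01, hydrophobic = 2.0, bias = 1.1,
                              clamp = c(2, 10)) {
  structure(list(ring = ring, aromatic = aromatic, het_frac = het_frac,
                 heavy = heavy, hydrophobic = hydrophobic, bias = bias,
                 clamp = clamp), class = "toy_oracle_params")
}

# interpretable descriptors used by the oracle, computed from the mol graph
.oracle_descriptors <- function(mol) {
  n <- nrow(mol$atoms); m <- nrow(mol$bonds)
  n_het <- sum(mol$atoms$element != "C")
  arom_bonds <- sum(mol$bonds$aromatic)
  list(
    ring = max(0L, m - n + 1L),             # cyclomatic number (connected)
    aromatic = arom_bonds %/% 6L + as.integer(arom_bonds %% 6L >= 5L),
    het_frac = n_het / n,
    heavy = n - 10,
    hydrophobic = (n - 2 * n_het) / n
  )
}

#' Deterministic pseudo-pKi oracle
#'
#' A smooth, bounded, deterministic score over graph descriptors, standing in
#' for a trained binding-affinity model when exercising the reward and
#' generation machinery.
#'
#' @param x SMILES character vector, `mol`, or list of `mol` objects.
#' @param params a [toy_oracle_params()].
#' @return numeric vector of pseudo-pKi scores in the clamp range.
#' @export
#' @examples
#' toy_oracle("c1ccccc1")  # differs from toy_oracle("C1CCCCC1") by the
#'                         # aromatic-ring weight exactly
toy_oracle <- function(x, params = toy_oracle_params()) {
  mols <- if (inherits(x, "mol")) list(x) else
    if (is.character(x)) {
      p <- parse_smiles(x); if (inherits(p, "mol")) list(p) else p
    } else x
  vapply(mols, function(mol) {
    d <- .oracle_descriptors(mol)
    raw <- params$bias + params$ring * d$ring + params$aromatic * d$aromatic +
      params$het_frac * d$het_frac + params$heavy * d$heavy +
      params$hydrophobic * d$hydrophobic
    min(max(raw, params$clamp[1]), params$clamp[2])
  }, numeric(1))
}

# Attach up to `k` random single atoms (from `menu`) to random atoms with
# free valence; returns a mol. Keeps the graph valid by construction.
.decorate_mol <- function(mol, k, menu = c("C", "C", "C", "N", "O", "F"),
                          max_heavy = 25L) {
  for (i in seq_len(k)) {
    n <- nrow(mol$atoms)
    if (n >= max_heavy) break
    bsum <- numeric(n)
    if (nrow(mol$bonds)) for (j in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a1[j]] <- bsum[mol$bonds$a1[j]] + mol$bonds$order[j]
      bsum[mol$bonds$a2[j]] <- bsum[mol$bonds$a2[j]] + mol$bonds$order[j]
    }
    free <- which(bsum + abs(mol$atoms$charge) <
                  .element_row(mol$atoms$element)$default_valence)
    if (!length(free)) break
    at <- if (length(free) == 1) free else sample(free, 1)
    el <- sample(menu, 1)
    bonds <- dplyr::bind_rows(mol$bonds, tibble::tibble(
      a1 = at, a2 = n + 1L, order = 1L, aromatic = FALSE, conjugated = FALSE,
      in_ring = FALSE, stereo = 0L))
    arom <- which(mol$atoms$aromatic)
    keep_ring <- bonds$in_ring
    mol <- .finish_mol(c(mol$atoms$element, el), c(mol$atoms$charge, 0L),
                       bonds, arom)
    mol$bonds$in_ring <- keep_ring
  }
  mol
}

.pool_sizes <- function() {
  if (is.null(.robust_cache$pool_sizes)) {
    .robust_cache$pool_sizes <- vapply(.FIXTURE_POOL, function(s) {
      n_heavy_atoms(parse_smiles(s))
    }, numeric(1))
  }
  .robust_cache$pool_sizes
}

.sample_fixture_mol <- function(max_heavy = 25L, decorate = 0:3) {
  eligible <- .FIXTURE_POOL[.pool_sizes() <= max_heavy]
  base <- sample(eligible, 1)
  mol <- parse_smiles(base)
  k <- sample(decorate, 1)
  if (k > 0) mol <- .decorate_mol(mol, k, max_heavy = max_heavy)
  mol
}

#' Generate a labelled property dataset with gross outliers
#'
#' Samples molecules from the fixture pool with random single-atom
#' decorations; labels each with the toy oracle plus Gaussian noise; then
#' shifts exactly `round(n * outlier_fraction)` labels by `outlier_shift`
#' (one-sided, mimicking affinity entries capped at rough values). Fully
#' reproducible for a given seed.
#'
#' @param n number of molecules (>= 10).
#' @param noise_sd Gaussian label noise standard deviation.
#' @param outlier_fraction fraction of gross outliers in `[0, 1]`.
#' @param outlier_shift additive label shift applied to outliers.
#' @param seed integer seed.
#' @param oracle a [toy_oracle_params()].
#' @return tibble with columns `smiles`, `target`, `oracle` (the noiseless
#'   score) and `is_outlier`.
#' @export
make_property_dataset <- function(n, noise_sd = 0.1, outlier_fraction = 0.1,
                                  outlier_shift = -3.0, seed = 1L,
                                  oracle = toy_oracle_params()) {
  stopifnot(n >= 10)
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    stop("outlier_fraction must be in [0, 1]")
  }
  set.seed(seed)
  # molecules are distinct (by canonical SMILES): a recovery benchmark with
  # duplicated molecules carrying contradictory labels would be ill-posed
  mols <- list(); smiles <- character(0); tries <- 0L
  while (length(mols) < n && tries < 40L * n) {
    tries <- tries + 1L
    mol <- .sample_fixture_mol()
    smi <- mol_to_smiles(mol)
    if (!smi %in% smiles) {
      mols[[length(mols) + 1L]] <- mol
      smiles <- c(smiles, smi)
    }
  }
  if (length(mols) < n) stop("could not draw ", n, " distinct molecules")
  clean <- toy_oracle(mols, oracle)
  target <- clean + stats::rnorm(n, 0, noise_sd)
  n_out <- round(n * outlier_fraction)
  is_out <- rep(FALSE, n)
  if (n_out > 0) {
    pick <- sample.int(n, n_out)
    target[pick] <- target[pick] + outlier_shift
    is_out[pick] <- TRUE
  }
  tibble::tibble(smiles = smiles, target = target, oracle = clean,
                 is_outlier = is_out)
}

#' Generate an expert molecule set
#'
#' Valid, drug-like fixture molecules (optionally decorated), capped at
#' `max_heavy` heavy atoms — the stand-in for a large commercial screening
#' library used as the "expert" reference for imitation and adversarial
#' training.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @param max_heavy heavy-atom cap per molecule.
#' @return character vector of canonical SMILES.
#' @export
make_expert_set <- function(n, seed = 1L, max_heavy = 25L) {
  stopifnot(n >= 1)
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    mol <- .sample_fixture_mol(max_heavy = max_heavy)
    mol_to_smiles(mol)
  }, character(1))
}

#' Convert Ki / IC50 values to pKi
#'
#' `pKi = 9 - log10(value in nM)` (so 1 nM -> 9, 1000 nM -> 6, 1 M -> 0).
#' IC50 values are treated interchangeably with Ki on this scale.
#'
#' @param value numeric vector of Ki or IC50 values.
#' @param unit `"nM"` (default) or `"M"`.
#' @return numeric vector of pKi values.
#' @export
ki_to_pki <- function(value, unit = c("nM", "M")) {
  unit <- match.arg(unit)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("Ki/IC50 values must be positive")
  }
  if (unit == "M") value <- value * 1e9
  9 - log10(value)
}
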