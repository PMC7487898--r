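# Molecular descriptors used by the reward: drug-likeness (QED), a synthetic
# accessibility heuristic on the 1-10 scale, substructure filter catalogs and
# a conformer-based steric-strain check. Bulk descriptors (MW, logP, TPSA,
# HBA, HBD) come from Open Babel's models; counts needing substructure logic
# use SMARTS matching; ring statistics use ring perception.

# published desirability-function parameters for the eight QED descriptors
# (asymmetric double sigmoids; columns a..f and the normalizing maximum)
.QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)
.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
                  ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  d <- p[1] +
    p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
  pmax(d / p[7], 1e-6)
}

.ROTB_SMARTS <- "[!$([NH]!@C(=O))&!D1&!$(*#*)]-&!@[!$([NH]!@C(=O))&!D1&!$(*#*)]"

# SDFset for a SMILES vector; NULL entries where the molecule has no bonds
# (ChemmineR cannot represent those) — callers fall back to table lookups.
.sdf_for <- function(smiles) {
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    s <- suppressWarnings(tryCatch(
      ChemmineR::smiles2sdf(stats::setNames(smiles[i], "m")),
      error = function(e) NULL))
    if (!is.null(s) && !all(suppressWarnings(ChemmineR::validSDF(s)))) {
      s <- NULL
    }
    out[i] <- list(s)
  }
  out
}

.ring_stats <- function(sdf) {
  if (is.null(sdf)) return(list(n_aromatic = 0L, sizes = integer(0)))
  rr <- tryCatch(ChemmineR::rings(sdf[[1]], type = "all", arom = TRUE),
                 error = function(e) list(RINGS = NULL, AROMATIC = NULL))
  if (is.null(rr$RINGS)) return(list(n_aromatic = 0L, sizes = integer(0)))
  list(n_aromatic = sum(unlist(rr$AROMATIC)),
       sizes = vapply(rr$RINGS, length, integer(1)))
}

#' Load a SMARTS pattern catalog
#'
#' Reads a tab-separated `name<TAB>SMARTS` file ('#' comments allowed) and
#' validates every pattern against a probe molecule; a malformed pattern
#' raises an error naming it.
#'
#' @param path file path; defaults to the filter catalog shipped with the
#'   package.
#' @return tibble with columns `name`, `smarts`.
#' @export
load_pattern_catalog <- function(path = system.file("extdata",
                                                    "zinc_filters.smarts",
                                                    package = "molforge")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed catalog line: ", lines[bad][1])
  cat <- tibble::tibble(name = vapply(parts, `[`, "", 1),
                        smarts = vapply(parts, `[`, "", 2))
  probe <- .sdf_for("CCO")[[1]]
  for (k in seq_len(nrow(cat))) {
    ok <- tryCatch({
      ChemmineR::smartsSearchOB(probe, cat$smarts[k], uniqueMatches = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("malformed SMARTS pattern '", cat$name[k], "': ",
                  cat$smarts[k])
  }
  cat
}

.count_smarts <- function(sdf, smarts) {
  if (is.null(sdf)) return(0L)
  as.integer(tryCatch(
    ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE),
    error = function(e) 0L))
}

#' Substructure filter check
#'
#' TRUE when no pattern of the catalog matches the molecule — the
#' "passes the functional-group filters" reward condition.
#'
#' @param smiles a SMILES string.
#' @param catalog a catalog tibble from [load_pattern_catalog()]; the shipped
#'   filter catalog by default. An empty catalog passes everything.
#' @return logical flag.
#' @export
zinc_filter_ok <- function(smiles, catalog = load_pattern_catalog()) {
  if (nrow(catalog) == 0) return(TRUE)
  sdf <- .sdf_for(smiles)[[1]]
  if (is.null(sdf)) return(TRUE)  # bondless: nothing to match
  for (k in seq_len(nrow(catalog))) {
    if (.count_smarts(sdf, catalog$smarts[k]) > 0) return(FALSE)
  }
  TRUE
}

# descriptor fallbacks for bondless single-atom molecules
.bondless_descriptors <- function(mol) {
  el <- mol$atoms$element[1]
  list(MW = mol$atoms$mass[1] + 1.008 * mol$atoms$n_h[1],
       ALOGP = if (el == "C") 0.6 else 0,
       HBA = as.integer(el %in% c("N", "O")),
       HBD = as.integer(el %in% c("N", "O")) * mol$atoms$n_h[1],
       PSA = if (el == "N") 26.0 else if (el == "O") 20.2 else 0)
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' The weighted-desirability QED composite over eight descriptors: molecular
#' weight, logP, hydrogen-bond acceptors and donors, polar surface area,
#' rotatable bonds, aromatic rings and structural alerts, each mapped through
#' its published desirability function and combined as a weighted geometric
#' mean. Bulk descriptors use Open Babel's models (logP in particular is Open
#' Babel's additive model), so values track but do not exactly equal other
#' toolkits' QED.
#'
#' @param smiles character vector of SMILES.
#' @param alerts a catalog tibble for the ALERTS descriptor, or `NULL` to
#'   count zero alerts (faster; used in reward loops).
#' @return numeric vector of QED values in `[0, 1]`.
#' @export
qed <- function(smiles, alerts = NULL) {
  stopifnot(is.character(smiles))
  sdfs <- .sdf_for(smiles)
  vapply(seq_along(smiles), function(i) {
    sdf <- sdfs[[i]]
    if (is.null(sdf)) {
      mol <- parse_smiles(smiles[i])
      d <- .bondless_descriptors(mol)
      rotb <- 0L; arom <- 0L
    } else {
      pr <- ChemmineR::propOB(sdf)
      d <- list(MW = pr$MW[1], ALOGP = pr$logP[1], HBA = pr$HBA1[1],
                HBD = pr$HBD[1], PSA = pr$TPSA[1])
      rotb <- .count_smarts(sdf, .ROTB_SMARTS)
      arom <- .ring_stats(sdf)$n_aromatic
    }
    nal <- if (is.null(alerts) || is.null(sdf)) 0L else
      sum(vapply(alerts$smarts, function(p) .count_smarts(sdf, p) > 0,
                 logical(1)))
    vals <- c(MW = d$MW, ALOGP = d$ALOGP, HBA = d$HBA, HBD = d$HBD,
              PSA = d$PSA, ROTB = rotb, AROM = arom, ALERTS = nal)
    ds <- vapply(names(vals), function(nm) .ads(vals[[nm]], .QED_ADS[[nm]]),
                 numeric(1))
    exp(sum(.QED_WEIGHTS * log(ds)) / sum(.QED_WEIGHTS))
  }, numeric(1))
}

#' Synthetic accessibility heuristic
#'
#' A 1 (easy) to 10 (hard) synthesizability score built from molecule size,
#' ring-system complexity (small, large and fused rings), branching and
#' heteroatom load. It follows the spirit of fragment-based accessibility
#' scores but replaces the corpus-derived fragment-frequency term with these
#' structural terms, so it is self-contained; the test suite pins its
#' behaviour (simple chains < decorated drug-like < caged/strained).
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of raw SA scores in `[1, 10]`.
#' @export
sa_score <- function(smiles) {
  stopifnot(is.character(smiles))
  sdfs <- .sdf_for(smiles)
  vapply(seq_along(smiles), function(i) {
    mol <- parse_smiles(smiles[i])
    n <- nrow(mol$atoms); m <- nrow(mol$bonds)
    rs <- .ring_stats(sdfs[[i]])
    sizes <- rs$sizes
    n_rings <- max(0L, m - n + 1L)
    small <- sum(sizes %in% c(3, 4))
    macro <- sum(sizes >= 8)
    # ring bonds shared by >1 ring indicate fusion/bridging: total ring-size
    # sum exceeds the number of distinct in-ring bonds by the shared count
    ring_bonds <- if (n_rings > 0) sum(mol$bonds$in_ring) else 0
    fusion <- max(0, sum(sizes) - ring_bonds)
    branch <- sum(pmax(0, mol$atoms$degree - 3))
    het <- sum(!mol$atoms$element %in% c("C", "H"))
    raw <- 1 +
      2.2 * (1 - exp(-pmax(0, n - 12) / 10)) +  # size, saturating
      0.9 * small +
      0.7 * macro +
      0.35 * pmax(0, fusion - 1) +
      0.4 * branch +
      0.25 * pmax(0, het - 4) +
      0.3 * pmax(0, n_rings - 3)
    min(max(raw, 1), 10)
  }, numeric(1))
}

#' Normalized synthetic accessibility
#'
#' `(10 - raw)/9`, mapped to `[0, 1]` with higher = easier to synthesize, the
#' orientation used in rewards and report filters.
#'
#' @inheritParams sa_score
#' @return numeric vector in `[0, 1]`.
#' @export
sa_norm <- function(smiles) (10 - sa_score(smiles)) / 9

# ---- steric strain ---------------------------------------------------------

# ideal bond angles (degrees) by hybridization code
.IDEAL_ANGLE <- c(`1` = 180, `2` = 120, `3` = 109.47, `4` = 109.47,
                  `5` = 90, `6` = 90)

#' Steric-strain check
#'
#' Embeds a 3-D conformer (Open Babel `--gen3d`, which includes a force-field
#' cleanup), measures every bond angle centred on a heavy atom against the
#' ideal angle for that atom's hybridization, and converts squared deviations
#' to an angle-bend energy (`k = 0.02` kcal/mol/deg^2). The molecule passes
#' when the mean angle energy per heavy atom stays below `threshold`
#' (kcal/mol/atom). If no conformer can be embedded the molecule passes with
#' a warning (configurable via `on_embed_failure`).
#'
#' @param smiles a SMILES string.
#' @param threshold mean angle-bend energy cutoff; `Inf` accepts everything.
#' @param on_embed_failure `"pass"` (default) or `"fail"`.
#' @return logical flag.
#' @export
strain_ok <- function(smiles, threshold = 0.82,
                      on_embed_failure = c("pass", "fail")) {
  on_embed_failure <- match.arg(on_embed_failure)
  if (!is.finite(threshold)) return(TRUE)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  status <- suppressWarnings(system2(
    "obabel", c(shQuote(paste0("-:", smiles)), "-osdf", "--gen3d",
                "-O", shQuote(tmp)),
    stdout = FALSE, stderr = FALSE))
  sdf <- tryCatch({
    s <- ChemmineR::read.SDFset(tmp)
    s[[1]]
  }, error = function(e) NULL, warning = function(w) NULL)
  if (status != 0 || is.null(sdf)) {
    warning("3-D embedding failed for ", smiles, "; strain check ",
            if (on_embed_failure == "pass") "passed" else "failed",
            " by policy")
    return(on_embed_failure == "pass")
  }
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  coords <- ab[, 1:3, drop = FALSE]
  el <- sub("_.*$", "", rownames(ab))
  heavy <- which(el != "H")
  nbrs <- lapply(seq_len(nrow(ab)), function(a) {
    c(bb[bb[, 1] == a, 2], bb[bb[, 2] == a, 1])
  })
  # hybridization of heavy centres from the embedded (kekulized) bond orders
  nd <- vapply(seq_len(nrow(ab)), function(a) {
    sum(bb[(bb[, 1] == a | bb[, 2] == a), 3] == 2)
  }, numeric(1))
  nt <- vapply(seq_len(nrow(ab)), function(a) {
    sum(bb[(bb[, 1] == a | bb[, 2] == a), 3] == 3)
  }, numeric(1))
  energy <- 0
  for (j in heavy) {
    nb <- nbrs[[j]]
    if (length(nb) < 2) next
    hyb <- .hybridization(FALSE, nd[j], nt[j], length(nb))
    theta0 <- .IDEAL_ANGLE[[as.character(hyb)]]
    prs <- utils::combn(nb, 2)
    for (q in seq_len(ncol(prs))) {
      v1 <- coords[prs[1, q], ] - coords[j, ]
      v2 <- coords[prs[2, q], ] - coords[j, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
      energy <- energy + 0.02 * (ang - theta0)^2
    }
  }
  (energy / length(heavy)) < threshold
}
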