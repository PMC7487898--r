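# Post-hoc analysis of generated molecules: binary fingerprints, Tanimoto
# similarity against a reference set, similarity distributions, Pareto-front
# extraction for multi-objective runs, and ranked top-k reports.

.FP_TYPES <- c(path = "FP2", fp3 = "FP3", fp4 = "FP4", maccs = "MACCS")

#' Binary molecular fingerprints
#'
#' Hashed binary fingerprints from Open Babel; the default `"path"` family
#' (FP2) hashes linear substructure fragments. Bondless molecules yield the
#' zero fingerprint.
#'
#' @param smiles character vector.
#' @param type `"path"` (default), `"fp3"`, `"fp4"` or `"maccs"`.
#' @return 0/1 numeric matrix, one row per molecule.
#' @export
fingerprints <- function(smiles, type = c("path", "fp3", "fp4", "maccs")) {
  type <- match.arg(type)
  sdfs <- .sdf_for(smiles)
  ok <- !vapply(sdfs, is.null, logical(1))
  width <- NULL
  rows <- vector("list", length(smiles))
  for (i in which(ok)) {
    fp <- ChemmineR::fingerprintOB(sdfs[[i]], .FP_TYPES[[type]])[[1]]
    rows[[i]] <- as.numeric(fp@fp)
    width <- length(fp@fp)
  }
  if (is.null(width)) width <- 1024L
  for (i in which(!ok)) rows[[i]] <- numeric(width)
  out <- do.call(rbind, rows)
  rownames(out) <- smiles
  out
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both fingerprints are empty.
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  un <- sum((a + b) > 0)
  if (un == 0) return(1)
  sum(a > 0 & b > 0) / un
}

#' Nearest reference molecule by Tanimoto similarity
#'
#' For each query molecule, the most similar molecule of a reference set
#' (ties broken by reference order).
#'
#' @param smiles character vector of query SMILES.
#' @param reference character vector of reference SMILES.
#' @param type fingerprint family (see [fingerprints()]).
#' @param ref_fps optional precomputed reference fingerprint matrix.
#' @return tibble with columns `smiles`, `nearest`, `similarity`.
#' @export
nearest_reference <- function(smiles, reference,
                              type = c("path", "fp3", "fp4", "maccs"),
                              ref_fps = NULL) {
  type <- match.arg(type)
  stopifnot(length(reference) >= 1)
  if (is.null(ref_fps)) ref_fps <- fingerprints(reference, type)
  qf <- fingerprints(smiles, type)
  # vectorized Tanimoto of each query row against all reference rows
  inter <- qf %*% t(ref_fps > 0)
  qsum <- rowSums(qf > 0)
  rsum <- rowSums(ref_fps > 0)
  un <- outer(qsum, rsum, `+`) - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1e-12))
  best <- apply(sim, 1, which.max)   # which.max takes the first on ties
  tibble::tibble(smiles = smiles, nearest = reference[best],
                 similarity = sim[cbind(seq_along(smiles), best)])
}

#' Distribution of nearest-reference similarities
#'
#' Histogram of the nearest-reference Tanimoto similarity over the `k`
#' top-ranked records. Counts always sum to `k`.
#'
#' @param smiles character vector of generated SMILES (already ranked; the
#'   first `k` are used).
#' @param reference character vector of reference SMILES.
#' @param k number of records to take (default min(500, length(smiles))).
#' @param breaks histogram break points on `[0, 1]`.
#' @inheritParams nearest_reference
#' @return tibble with columns `bin_low`, `bin_high`, `count`; the per-record
#'   similarities are attached as attribute `"nearest"`.
#' @export
similarity_distribution <- function(smiles, reference,
                                    k = min(500L, length(smiles)),
                                    breaks = seq(0, 1, by = 0.05),
                                    type = c("path", "fp3", "fp4", "maccs")) {
  type <- match.arg(type)
  if (k > length(smiles)) stop("k exceeds the number of records")
  take <- smiles[seq_len(k)]
  nr <- nearest_reference(take, reference, type)
  cut_idx <- cut(nr$similarity, breaks = breaks, include.lowest = TRUE)
  counts <- table(cut_idx)
  out <- tibble::tibble(bin_low = utils::head(breaks, -1),
                        bin_high = breaks[-1],
                        count = as.integer(counts))
  attr(out, "nearest") <- nr
  out
}

#' Pareto front of a set of objective tuples
#'
#' A point is retained when no other point is at least as good in every
#' objective and strictly better in one (after aligning senses so that
#' larger is better).
#'
#' @param points numeric matrix or data frame, one row per candidate, one
#'   column per objective.
#' @param senses character vector, `"max"` or `"min"` per objective.
#' @return integer vector of row indices on the front (in input order).
#' @export
pareto_front <- function(points, senses = rep("max", ncol(points))) {
  pts <- as.matrix(points)
  stopifnot(all(is.finite(pts)), length(senses) == ncol(pts),
            all(senses %in% c("max", "min")))
  for (j in seq_len(ncol(pts))) if (senses[j] == "min") pts[, j] <- -pts[, j]
  n <- nrow(pts)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    geq <- rowSums(pts >= matrix(pts[i, ], n, ncol(pts), byrow = TRUE)) ==
      ncol(pts)
    gt <- rowSums(pts > matrix(pts[i, ], n, ncol(pts), byrow = TRUE)) > 0
    if (any(geq & gt)) keep[i] <- FALSE
  }
  which(keep)
}

#' Ranked top-k report of generated molecules
#'
#' Deduplicates episode records by canonical SMILES (keeping each molecule's
#' best-ranked record), applies the drug-likeness and synthesizability
#' threshold filters, ranks by the requested column and returns the top `k`,
#' optionally annotated with the nearest reference molecule.
#'
#' @param records data frame with at least a `smiles` column and the ranking
#'   column (e.g. episode logs from [generate_molecules()] with rewards).
#' @param k rows to keep.
#' @param qed_min,sa_min threshold filters applied when the corresponding
#'   `qed` / `sa_norm` columns are present (set to 0 to disable).
#' @param rank_by column name to rank by (descending).
#' @param reference optional reference SMILES for nearest-neighbour columns.
#' @param type fingerprint family for the reference annotation.
#' @return tibble of at most `k` rows.
#' @export
topk_report <- function(records, k = 10L, qed_min = 0.8, sa_min = 0.8,
                        rank_by = "reward", reference = NULL,
                        type = c("path", "fp3", "fp4", "maccs")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(records), "smiles" %in% names(records),
            rank_by %in% names(records))
  out <- records
  out$.canonical <- vapply(out$smiles, function(s) {
    tryCatch(canonical_smiles(s), error = function(e) NA_character_)
  }, character(1))
  out <- out[!is.na(out$.canonical), , drop = FALSE]
  out <- out[order(-out[[rank_by]]), , drop = FALSE]
  out <- out[!duplicated(out$.canonical), , drop = FALSE]
  if ("qed" %in% names(out) && qed_min > 0) {
    out <- out[out$qed >= qed_min, , drop = FALSE]
  }
  if ("sa_norm" %in% names(out) && sa_min > 0) {
    out <- out[out$sa_norm >= sa_min, , drop = FALSE]
  }
  if (nrow(out) == 0) {
    warning("no records left after filters; returning an empty table")
    return(tibble::as_tibble(out[, setdiff(names(out), ".canonical")]))
  }
  out <- utils::head(out, k)
  if (!is.null(reference)) {
    nr <- nearest_reference(out$.canonical, reference, type)
    out$nearest <- nr$nearest
    out$nearest_similarity <- nr$similarity
  }
  tibble::as_tibble(out[, setdiff(names(out), ".canonical")])
}
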