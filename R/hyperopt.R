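# Hyperparameter optimization for the property model: k-fold cross-validated
# RMSE as the model score, minimized by sequential model-based (Bayesian)
# search — a Gaussian-process surrogate on the normalized 4-d space (encoder
# depth, message width, regressor depth, dropout) with expected improvement.

#' Cross-validation fold assignment
#'
#' Partitions `n` samples into `k` folds of near-equal size: every sample is
#' in exactly one validation fold.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels (1..k) of length `n`.
#' @export
cv_folds <- function(n, k = 10L, seed = 1L) {
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# mean k-fold RMSE of one configuration on the train+validation pool
.cv_score <- function(data, config, folds, train_cfg, loss) {
  k <- max(folds)
  rmses <- numeric(k)
  graphs <- lapply(data$smiles, smiles_to_graph)
  for (f in seq_len(k)) {
    tr <- which(folds != f); va <- which(folds == f)
    # train on the non-validation folds with an internal 90/10 split for
    # checkpoint selection
    sub <- data[tr, , drop = FALSE]
    cfg_f <- train_cfg
    cfg_f$split <- c(0.9, 0.1, 0.0)
    m <- train_property_model(sub, config, cfg_f, loss = loss)
    pred <- predict_property(graphs[va], m)
    rmses[f] <- sqrt(mean((pred - data$target[va])^2))
  }
  mean(rmses)
}

# GP posterior (RBF kernel on [0,1]^d, fixed length scale) and expected
# improvement for minimization
.gp_ei <- function(X, y, Xcand, ell = 0.5) {
  sf2 <- stats::var(y) + 1e-12
  sn2 <- 1e-6 + 0.05 * sf2
  K <- sf2 * exp(-as.matrix(stats::dist(X))^2 / (2 * ell^2)) +
    diag(sn2, nrow(X))
  d2 <- outer(rowSums(Xcand^2), rowSums(X^2), `+`) - 2 * Xcand %*% t(X)
  Ks <- sf2 * exp(-pmax(d2, 0) / (2 * ell^2))
  Kinv_y <- solve(K, y - mean(y))
  mu <- mean(y) + Ks %*% Kinv_y
  KinvKs <- solve(K, t(Ks))
  s2 <- pmax(sf2 - rowSums(t(KinvKs) * Ks), 1e-12)
  s <- sqrt(s2)
  best <- min(y)
  z <- (best - mu) / s
  (best - mu) * stats::pnorm(z) + s * stats::dnorm(z)
}

#' Bayesian hyperparameter search with k-fold cross-validation
#'
#' Holds out the test fraction first, then scores candidate configurations by
#' mean k-fold RMSE on the remaining data. After an initial random design,
#' candidates are proposed by maximizing expected improvement under a
#' Gaussian-process surrogate.
#'
#' @param data data frame with `smiles` and `target`.
#' @param search_space list with vectors `depth`, `hidden_dim`, `ffn_layers`
#'   (discrete values) and `dropout` (range or values).
#' @param budget total number of configurations to evaluate (>= 2).
#' @param folds number of CV folds.
#' @param train_cfg a [train_config()] used for every fold fit (reduce
#'   `epochs` for pilot-scale searches).
#' @param loss `"robust"` or `"l2"`.
#' @param seed integer seed.
#' @return list with `best_config` (an [mpnn_config()]), `best_score` (mean
#'   fold RMSE) and `history` (a tibble of evaluated configurations).
#' @export
hyperopt <- function(data,
                     search_space = list(depth = 1:5,
                                         hidden_dim = c(32L, 64L, 128L),
                                         ffn_layers = 1:3,
                                         dropout = c(0, 0.1, 0.2, 0.3)),
                     budget = 10L, folds = 10L,
                     train_cfg = train_config(), loss = c("robust", "l2"),
                     seed = 1L) {
  loss <- match.arg(loss)
  if (budget < 2) stop("budget must allow at least 2 evaluations")
  set.seed(seed)
  # test held out before CV
  n <- nrow(data)
  idx <- sample.int(n)
  n_test <- floor(train_cfg$split[3] * n)
  pool <- if (n_test > 0) data[idx[seq_len(n - n_test)], , drop = FALSE] else
    data[idx, , drop = FALSE]
  fold_id <- cv_folds(nrow(pool), folds, seed = seed)

  grid <- expand.grid(depth = search_space$depth,
                      hidden_dim = search_space$hidden_dim,
                      ffn_layers = search_space$ffn_layers,
                      dropout = search_space$dropout)
  budget <- min(budget, nrow(grid))
  # normalized coordinates for the surrogate
  norm01 <- function(v) {
    r <- range(v); if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  }
  Xall <- cbind(norm01(grid$depth), norm01(grid$hidden_dim),
                norm01(grid$ffn_layers), norm01(grid$dropout))

  n_init <- min(budget, max(2L, budget %/% 3L))
  tried <- sample.int(nrow(grid), n_init)
  scores <- vapply(tried, function(g) {
    .cv_score(pool, mpnn_config(grid$depth[g], grid$hidden_dim[g],
                                grid$ffn_layers[g], grid$dropout[g]),
              fold_id, train_cfg, loss)
  }, numeric(1))
  while (length(tried) < budget) {
    remaining <- setdiff(seq_len(nrow(grid)), tried)
    ei <- .gp_ei(Xall[tried, , drop = FALSE], scores,
                 Xall[remaining, , drop = FALSE])
    nxt <- remaining[which.max(ei)]
    sc <- .cv_score(pool, mpnn_config(grid$depth[nxt], grid$hidden_dim[nxt],
                                      grid$ffn_layers[nxt],
                                      grid$dropout[nxt]),
                    fold_id, train_cfg, loss)
    tried <- c(tried, nxt)
    scores <- c(scores, sc)
  }
  best <- which.min(scores)
  g <- tried[best]
  list(
    best_config = mpnn_config(grid$depth[g], grid$hidden_dim[g],
                              grid$ffn_layers[g], grid$dropout[g]),
    best_score = scores[best],
    history = tibble::tibble(
      depth = grid$depth[tried], hidden_dim = grid$hidden_dim[tried],
      ffn_layers = grid$ffn_layers[tried], dropout = grid$dropout[tried],
      cv_rmse = scores)
  )
}
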