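# Directed message-passing property model: bond-level message passing over
# the 147-d directed-bond inputs, atom-level readout, mean pooling, and a
# feed-forward regressor, trained under the adaptive robust NLL (or a plain
# squared loss for comparison). Forward/backward passes are explicit matrix
# code; aggregation uses sparse incidence matrices.

#' Encoder / regressor configuration
#'
#' @param depth message-passing depth N (>= 1): the bond messages are updated
#'   `depth - 1` times before the atom-level readout.
#' @param hidden_dim width of message vectors and hidden layers.
#' @param ffn_layers number of feed-forward layers in the regressor; 1 means a
#'   single affine map from the embedding to the score.
#' @param dropout dropout rate in `[0, 1)`, applied after each rectification
#'   during training and disabled at inference.
#' @return a `mpnn_config` list.
#' @export
mpnn_config <- function(depth = 3L, hidden_dim = 128L, ffn_layers = 2L,
                        dropout = 0.1) {
  stopifnot(depth >= 1, hidden_dim >= 1, ffn_layers >= 1,
            dropout >= 0, dropout < 1)
  structure(list(depth = as.integer(depth), hidden_dim = as.integer(hidden_dim),
                 ffn_layers = as.integer(ffn_layers), dropout = dropout),
            class = "mpnn_config")
}

#' Training configuration for the property model
#'
#' Defaults mirror the regression setup used throughout: batches of 50
#' molecules, 100 epochs, a 2-epoch linear warmup of the learning rate from
#' `lr_low` to `lr_high`, then exponential decay back to `lr_low` by the final
#' epoch, an 80/10/10 random split, and checkpointing on best validation RMSE.
#'
#' @param batch_size molecules per gradient step.
#' @param epochs training epochs.
#' @param warmup_epochs epochs of linear learning-rate warmup.
#' @param lr_low,lr_high learning-rate bounds.
#' @param split numeric length-3 train/validation/test fractions (sum 1).
#' @param loss_lr_mult learning-rate multiplier for the robust-loss shape and
#'   scale latents. The two loss parameters see far fewer effective updates
#'   than the network weights, so they get their own parameter-group rate;
#'   with the default 10 the shape can traverse its full range within a
#'   typical run, which is what lets the loss actually reject gross outliers.
#' @param loss_warmup_frac fraction of epochs during which the loss latents
#'   stay frozen at their initialization while only the network trains.
#'   Releasing the shape/scale after the model has fit the bulk of the signal
#'   is the stabilization recommended for adaptive robust losses: adapting
#'   them from the start lets the loss mistake early model error for label
#'   noise.
#' @param seed integer seed controlling the split, initialization and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 50L, epochs = 100L, warmup_epochs = 2L,
                         lr_low = 1e-4, lr_high = 1e-3,
                         split = c(0.8, 0.1, 0.1), loss_lr_mult = 10,
                         loss_warmup_frac = 0, seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, lr_low < lr_high, batch_size >= 1,
            epochs >= 1, loss_lr_mult > 0,
            loss_warmup_frac >= 0, loss_warmup_frac < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 lr_low = lr_low, lr_high = lr_high, split = split,
                 loss_lr_mult = loss_lr_mult,
                 loss_warmup_frac = loss_warmup_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

.xavier <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

#' Initialize a property model
#'
#' Xavier-initialized weights for the bond-input layer (147 -> hidden), the
#' per-depth hidden updates, the atom-level readout ((133 + hidden) -> hidden),
#' the feed-forward regressor, and — for the robust loss — the latent shape
#' and scale parameters (initialized at alpha ~ 1, c ~ 1).
#'
#' @param config an [mpnn_config()].
#' @param loss `"robust"` for the adaptive robust NLL, `"l2"` for squared loss.
#' @param seed integer seed for the weight draw.
#' @return object of class `property_model`.
#' @export
property_model_init <- function(config = mpnn_config(), loss = c("robust", "l2"),
                                seed = 1L) {
  loss <- match.arg(loss)
  set.seed(seed)
  h <- config$hidden_dim
  Wh <- if (config$depth > 1) {
    lapply(seq_len(config$depth - 1L), function(l) .xavier(h, h))
  } else list()
  Wf <- if (config$ffn_layers > 1) {
    lapply(seq_len(config$ffn_layers - 1L),
           function(j) list(W = .xavier(h, h), b = numeric(h)))
  } else list()
  structure(list(
    W0 = .xavier(BOND_INPUT_DIM, h), Wh = Wh,
    Wa = .xavier(ATOM_FDIM + h, h), Wf = Wf,
    w_out = .xavier(h, 1L), b_out = 0,
    loss = loss,
    loss_params = robust_loss_params(0, 0.541324),  # alpha ~ 1, c ~ 1
    config = config
  ), class = "property_model")
}

#' @export
print.property_model <- function(x, ...) {
  cat(sprintf("<property_model> depth %d, hidden %d, ffn %d, loss %s",
              x$config$depth, x$config$hidden_dim, x$config$ffn_layers, x$loss))
  if (x$loss == "robust") {
    cat(sprintf(" (alpha %.3f, c %.3f)", x$loss_params$alpha, x$loss_params$c))
  }
  if (!is.null(x$metrics)) {
    cat(sprintf("; best val RMSE %.4f (epoch %d)",
                min(x$metrics$val_rmse), x$best_epoch))
  }
  cat("\n"); invisible(x)
}

# ---- batching --------------------------------------------------------------

# Assemble a list of mol_graphs into one sparse-aggregation batch:
#   B    (nb x 147)  directed-bond inputs
#   Abb  (nb x nb)   bond->bond aggregation: incoming bonds of the source
#                    atom, excluding the reverse twin
#   Aab  (na x nb)   atom <- incoming-bond incidence
#   P    (nm x na)   per-molecule atom averaging
#   Xa   (na x 133)  atom features
.batch_graphs <- function(graphs, include_reverse = FALSE) {
  nb_each <- vapply(graphs, function(g) g$n_bonds, integer(1))
  na_each <- vapply(graphs, function(g) g$n_atoms, integer(1))
  boff <- cumsum(c(0L, nb_each))
  aoff <- cumsum(c(0L, na_each))
  nb <- sum(nb_each); na <- sum(na_each); nm <- length(graphs)
  bi <- bj <- vector("list", nm); ai <- aj <- vector("list", nm)
  pi_ <- pj <- px <- vector("list", nm)
  for (m in seq_len(nm)) {
    g <- graphs[[m]]
    if (g$n_bonds > 0) {
      ii <- g$agg_i; jj <- g$agg_j
      if (include_reverse) {
        ii <- c(ii, seq_len(g$n_bonds)); jj <- c(jj, g$reverse)
      }
      bi[[m]] <- ii + boff[m]; bj[[m]] <- jj + boff[m]
      ai[[m]] <- g$bond_dst + aoff[m]
      aj[[m]] <- seq_len(g$n_bonds) + boff[m]
    }
    pi_[[m]] <- rep(m, g$n_atoms)
    pj[[m]] <- seq_len(g$n_atoms) + aoff[m]
    px[[m]] <- rep(1 / g$n_atoms, g$n_atoms)
  }
  list(
    B = do.call(rbind, lapply(graphs, function(g) g$bond_inputs)),
    Abb = Matrix::sparseMatrix(i = unlist(bi), j = unlist(bj), x = 1,
                               dims = c(nb, nb)),
    Aab = Matrix::sparseMatrix(i = unlist(ai), j = unlist(aj), x = 1,
                               dims = c(na, nb)),
    P = Matrix::sparseMatrix(i = unlist(pi_), j = unlist(pj), x = unlist(px),
                             dims = c(nm, na)),
    Xa = do.call(rbind, lapply(graphs, function(g) g$atom_features)),
    n_mols = nm
  )
}

.dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1, 1 - p) / (1 - p), nr, nc)
}

# Forward pass over a batch. train = TRUE draws dropout masks (kept for the
# backward pass); train = FALSE is deterministic.
.mpnn_forward <- function(model, batch, train = FALSE) {
  cfg <- model$config; h <- cfg$hidden_dim; p <- if (train) cfg$dropout else 0
  nb <- nrow(batch$B); na <- nrow(batch$Xa)
  Pre0 <- batch$B %*% model$W0
  M0 <- pmax(Pre0, 0)
  M <- M0
  Pre_l <- list(); S_l <- list(); mask_l <- list(); M_l <- list()
  if (cfg$depth > 1) for (l in seq_len(cfg$depth - 1L)) {
    S <- as.matrix(batch$Abb %*% M)
    # depth-0 skip: the update re-injects the initial bond message, keeping
    # gradients alive through deep message passing
    Pre <- M0 + S %*% model$Wh[[l]]
    Ml <- pmax(Pre, 0)
    mk <- .dropout_mask(nrow(Ml), ncol(Ml), p)
    if (!is.null(mk)) Ml <- Ml * mk
    S_l[[l]] <- S; Pre_l[[l]] <- Pre; mask_l[l] <- list(mk); M_l[[l]] <- Ml
    M <- Ml
  }
  U <- if (nb > 0) as.matrix(batch$Aab %*% M) else matrix(0, na, h)
  XU <- cbind(batch$Xa, U)
  PreA <- XU %*% model$Wa
  Ha <- pmax(PreA, 0)
  maskA <- .dropout_mask(na, h, p)
  if (!is.null(maskA)) Ha <- Ha * maskA
  Emb <- as.matrix(batch$P %*% Ha)
  Z <- Emb; Zs <- list(Emb); PreF <- list(); maskF <- list()
  if (cfg$ffn_layers > 1) for (j in seq_len(cfg$ffn_layers - 1L)) {
    Pre <- sweep(Z %*% model$Wf[[j]]$W, 2, model$Wf[[j]]$b, `+`)
    Zj <- pmax(Pre, 0)
    mk <- .dropout_mask(nrow(Zj), ncol(Zj), p)
    if (!is.null(mk)) Zj <- Zj * mk
    PreF[[j]] <- Pre; maskF[j] <- list(mk); Z <- Zj; Zs[[j + 1]] <- Zj
  }
  y <- as.vector(Z %*% model$w_out + model$b_out)
  list(y = y, Pre0 = Pre0, M0 = M0, S_l = S_l, Pre_l = Pre_l,
       mask_l = mask_l, M_l = M_l, M = M, U = U, XU = XU, PreA = PreA,
       maskA = maskA, Ha = Ha, Emb = Emb, Zs = Zs, PreF = PreF,
       maskF = maskF, Z = Z)
}

# Backward pass: dY is dLoss/dy (length n_mols); returns gradients for every
# weight matrix, mirroring the model's field layout.
.mpnn_backward <- function(model, batch, fw, dY) {
  cfg <- model$config; h <- cfg$hidden_dim
  dZ <- outer(dY, as.vector(model$w_out))
  g <- list(w_out = crossprod(fw$Z, dY), b_out = sum(dY))
  if (cfg$ffn_layers > 1) {
    g$Wf <- vector("list", cfg$ffn_layers - 1L)
    for (j in rev(seq_len(cfg$ffn_layers - 1L))) {
      dPre <- dZ * (fw$PreF[[j]] > 0)
      if (!is.null(fw$maskF[[j]])) dPre <- dPre * fw$maskF[[j]]
      g$Wf[[j]] <- list(W = crossprod(fw$Zs[[j]], dPre), b = colSums(dPre))
      dZ <- dPre %*% t(model$Wf[[j]]$W)
    }
  }
  dEmb <- dZ
  dHa <- as.matrix(Matrix::crossprod(batch$P, dEmb))
  dPreA <- dHa * (fw$PreA > 0)
  if (!is.null(fw$maskA)) dPreA <- dPreA * fw$maskA
  g$Wa <- crossprod(fw$XU, dPreA)
  dU <- dPreA %*% t(model$Wa[ATOM_FDIM + seq_len(h), , drop = FALSE])
  dM <- if (nrow(batch$B) > 0) as.matrix(Matrix::crossprod(batch$Aab, dU)) else
    matrix(0, 0, h)
  dM0 <- matrix(0, nrow(dM), ncol(dM))
  if (cfg$depth > 1) {
    g$Wh <- vector("list", cfg$depth - 1L)
    for (l in rev(seq_len(cfg$depth - 1L))) {
      dPre <- dM * (fw$Pre_l[[l]] > 0)
      if (!is.null(fw$mask_l[[l]])) dPre <- dPre * fw$mask_l[[l]]
      g$Wh[[l]] <- crossprod(fw$S_l[[l]], dPre)
      dM0 <- dM0 + dPre   # depth-0 skip path
      dM <- as.matrix(Matrix::crossprod(batch$Abb, dPre %*% t(model$Wh[[l]])))
    }
  }
  dPre0 <- (dM + dM0) * (as.matrix(fw$Pre0) > 0)
  g$W0 <- if (nrow(batch$B) > 0) as.matrix(crossprod(batch$B, dPre0)) else
    matrix(0, BOND_INPUT_DIM, h)
  g
}

# ---- public encode / predict ----------------------------------------------

#' Encode molecules into graph embeddings
#'
#' Runs the message-passing encoder (no dropout) and returns the mean-pooled
#' depth-N atom messages, one embedding row per molecule. Bondless molecules
#' take the degenerate path: their atom readout sees a zero message sum next
#' to the atom features.
#'
#' @param graphs a `mol_graph`, a list of them, or a character vector of SMILES.
#' @param model a `property_model`.
#' @return numeric matrix, one row per molecule, `hidden_dim` columns.
#' @export
encode <- function(graphs, model) {
  graphs <- .as_graph_list(graphs)
  batch <- .batch_graphs(graphs)
  fw <- .mpnn_forward(model, batch, train = FALSE)
  fw$Emb
}

.as_graph_list <- function(graphs) {
  if (inherits(graphs, "mol_graph")) return(list(graphs))
  if (is.character(graphs)) return(lapply(graphs, smiles_to_graph))
  stopifnot(is.list(graphs))
  graphs
}

#' Predict property scores (pKi scale)
#'
#' @inheritParams encode
#' @return numeric vector of predicted scores.
#' @export
predict_property <- function(graphs, model) {
  graphs <- .as_graph_list(graphs)
  batch <- .batch_graphs(graphs)
  y <- .mpnn_forward(model, batch, train = FALSE)$y
  if (!is.null(model$target_scale)) {
    y <- y * model$target_scale$sd + model$target_scale$mu
  }
  y
}

#' @export
predict.property_model <- function(object, newdata, ...) {
  predict_property(newdata, object)
}

# ---- optimizer and schedule ------------------------------------------------

.adam_new <- function() list(t = 0, m = list(), v = list())

.adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  upd <- list()
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- 0 * gmat; state$v[[nm]] <- 0 * gmat }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    upd[[nm]] <- lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, update = upd)
}

# flatten model weights <-> named list of matrices for the optimizer
.pm_flatten <- function(model) {
  out <- list(W0 = model$W0, Wa = model$Wa, w_out = model$w_out,
              b_out = model$b_out)
  for (l in seq_along(model$Wh)) out[[paste0("Wh", l)]] <- model$Wh[[l]]
  for (j in seq_along(model$Wf)) {
    out[[paste0("WfW", j)]] <- model$Wf[[j]]$W
    out[[paste0("Wfb", j)]] <- model$Wf[[j]]$b
  }
  if (model$loss == "robust") {
    out$alpha_latent <- model$loss_params$alpha_latent
    out$scale_latent <- model$loss_params$scale_latent
  }
  out
}

.pm_unflatten <- function(model, flat) {
  model$W0 <- flat$W0; model$Wa <- flat$Wa
  model$w_out <- flat$w_out; model$b_out <- flat$b_out
  for (l in seq_along(model$Wh)) model$Wh[[l]] <- flat[[paste0("Wh", l)]]
  for (j in seq_along(model$Wf)) {
    model$Wf[[j]]$W <- flat[[paste0("WfW", j)]]
    model$Wf[[j]]$b <- flat[[paste0("Wfb", j)]]
  }
  if (model$loss == "robust") {
    model$loss_params <- robust_loss_params(flat$alpha_latent,
                                            flat$scale_latent,
                                            model$loss_params$scale_lo)
  }
  model
}

.grads_flatten <- function(model, g, extra = NULL) {
  out <- list(W0 = g$W0, Wa = g$Wa, w_out = g$w_out, b_out = g$b_out)
  for (l in seq_along(model$Wh)) out[[paste0("Wh", l)]] <- g$Wh[[l]]
  for (j in seq_along(model$Wf)) {
    out[[paste0("WfW", j)]] <- g$Wf[[j]]$W
    out[[paste0("Wfb", j)]] <- g$Wf[[j]]$b
  }
  if (!is.null(extra)) out <- c(out, extra)
  out
}

.lr_schedule <- function(step, steps_per_epoch, cfg) {
  warm <- cfg$warmup_epochs * steps_per_epoch
  total <- cfg$epochs * steps_per_epoch
  if (step <= warm) {
    cfg$lr_low + (cfg$lr_high - cfg$lr_low) * step / max(warm, 1)
  } else {
    decay <- (cfg$lr_low / cfg$lr_high)^(1 / max(total - warm, 1))
    cfg$lr_high * decay^(step - warm)
  }
}

# loss value + dY for one batch; robust loss also returns latent grads
.pm_loss <- function(model, y, targets) {
  r <- y - targets
  if (model$loss == "robust") {
    nb <- .robust_nll_batch(r, model$loss_params)
    list(value = nb$value, dY = nb$dx,
         extra = list(alpha_latent = nb$dalpha_latent,
                      scale_latent = nb$dscale_latent))
  } else {
    list(value = 0.5 * sum(r^2), dY = r, extra = NULL)
  }
}

.rmse <- function(model, graphs, targets) {
  if (!length(targets)) return(NA_real_)
  sqrt(mean((predict_property(graphs, model) - targets)^2))
}

#' Train a property model
#'
#' Featurizes the dataset, splits it randomly into train/validation/test by
#' the configured fractions and seed, then runs minibatch gradient training
#' (Adam) under the configured loss with the warmup-then-exponential-decay
#' learning-rate schedule. The model is checkpointed whenever the validation
#' RMSE improves and the checkpointed weights are returned.
#'
#' @param data a data frame with columns `smiles` and `target` (pKi scale).
#' @param config an [mpnn_config()].
#' @param train_cfg a [train_config()].
#' @param loss `"robust"` or `"l2"`.
#' @param verbose print per-epoch progress.
#' @return the best-validation `property_model`, with `$metrics` (a tibble of
#'   per-epoch train loss, val/test RMSE, learning rate, and — for the robust
#'   loss — the current alpha and c), `$best_epoch` and `$split` attached.
#' @export
train_property_model <- function(data, config = mpnn_config(),
                                 train_cfg = train_config(),
                                 loss = c("robust", "l2"), verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(is.data.frame(data), all(c("smiles", "target") %in% names(data)))
  if (nrow(data) < 10) stop("need at least 10 labelled molecules")
  if (!all(is.finite(data$target))) stop("labels must be finite")
  set.seed(train_cfg$seed)
  graphs <- lapply(data$smiles, smiles_to_graph)
  n <- nrow(data)
  idx <- sample.int(n)
  n_tr <- floor(train_cfg$split[1] * n)
  n_va <- floor(train_cfg$split[2] * n)
  tr <- idx[seq_len(n_tr)]
  va <- idx[n_tr + seq_len(n_va)]
  te <- idx[-seq_len(n_tr + n_va)]
  if (!length(tr) || !length(va)) stop("empty train or validation split")
  targets <- data$target
  # standardize targets on the training split; predictions are un-scaled, so
  # the robust loss sees residuals on the standardized scale
  t_mu <- mean(targets[tr]); t_sd <- stats::sd(targets[tr])
  if (!is.finite(t_sd) || t_sd < 1e-8) t_sd <- 1
  scaled <- (targets - t_mu) / t_sd

  model <- property_model_init(config, loss, seed = train_cfg$seed)
  model$target_scale <- list(mu = t_mu, sd = t_sd)
  adam <- .adam_new()
  steps_per_epoch <- max(1L, ceiling(length(tr) / train_cfg$batch_size))
  step <- 0L
  best <- list(val = Inf, model = model, epoch = 0L)
  hist <- vector("list", train_cfg$epochs)

  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample(tr)
    ep_loss <- 0
    for (bs in seq_len(steps_per_epoch)) {
      take <- ord[((bs - 1L) * train_cfg$batch_size + 1L):
                  min(bs * train_cfg$batch_size, length(ord))]
      take <- take[!is.na(take)]
      if (!length(take)) next
      batch <- .batch_graphs(graphs[take])
      fw <- .mpnn_forward(model, batch, train = TRUE)
      ls <- .pm_loss(model, fw$y, scaled[take])
      ep_loss <- ep_loss + ls$value
      g <- .mpnn_backward(model, batch, fw, ls$dY)
      step <- step + 1L
      lr <- .lr_schedule(step, steps_per_epoch, train_cfg)
      st <- .adam_step(adam, .grads_flatten(model, g, ls$extra), lr)
      adam <- st$state
      flat <- .pm_flatten(model)
      mult <- train_cfg$loss_lr_mult %||% 1
      frozen <- epoch <= (train_cfg$loss_warmup_frac %||% 0) * train_cfg$epochs
      for (nm in names(st$update)) {
        scale <- if (nm %in% c("alpha_latent", "scale_latent")) {
          if (frozen) 0 else mult
        } else 1
        flat[[nm]] <- flat[[nm]] - scale * st$update[[nm]]
      }
      model <- .pm_unflatten(model, flat)
    }
    val_rmse <- .rmse(model, graphs[va], targets[va])
    test_rmse <- .rmse(model, graphs[te], targets[te])
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = .lr_schedule(step, steps_per_epoch, train_cfg),
      train_loss = ep_loss / length(tr), val_rmse = val_rmse,
      test_rmse = test_rmse,
      alpha = if (loss == "robust") model$loss_params$alpha else NA_real_,
      c = if (loss == "robust") model$loss_params$c else NA_real_
    )
    if (is.finite(val_rmse) && val_rmse < best$val) {
      best <- list(val = val_rmse, model = model, epoch = epoch)
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f  test %.4f",
                      epoch, ep_loss / length(tr), val_rmse, test_rmse))
    }
  }
  out <- best$model
  out$metrics <- dplyr::bind_rows(hist)
  out$best_epoch <- best$epoch
  out$split <- list(train = tr, val = va, test = te)
  out$test_rmse <- .rmse(out, graphs[te], targets[te])
  out
}
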