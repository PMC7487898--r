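# Graph convolutional policy network. Node embeddings come from per-edge-type
# graph convolutions with renormalized adjacency (mean over the three bond
# types); four MLP heads read out the composite action (first atom, second
# atom, bond type, stop), an MLP value head scores the pooled state, and a
# structurally identical network with a terminal sigmoid serves as the
# adversarial discriminator. Backward passes are hand-derived; parameters
# live in nested lists walked by small tree utilities.

# ---- tree utilities (apply f leaf-wise over parallel nested lists) ---------
.tmap <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    out <- vector("list", length(xs[[1]]))
    names(out) <- names(xs[[1]])
    for (i in seq_along(xs[[1]])) {
      out[[i]] <- do.call(.tmap, c(list(f), lapply(xs, `[[`, i)))
    }
    out
  } else {
    do.call(f, xs)
  }
}

.tree_zero <- function(tree) .tmap(function(x) x * 0, tree)

# Adam over a parameter tree
.tree_adam_init <- function(params) {
  list(t = 0, m = .tree_zero(params), v = .tree_zero(params))
}

.tree_adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                            beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- .tmap(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tmap(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- .tmap(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  params, state$m, state$v)
  list(params = params, state = state)
}

# ---- two-layer rectified MLP head ------------------------------------------
.mlp2_init <- function(nin, nhid, nout) {
  list(W1 = .xavier(nin, nhid), b1 = numeric(nhid),
       W2 = .xavier(nhid, nout), b2 = numeric(nout))
}

.mlp2_forward <- function(h, X) {
  Pre <- sweep(X %*% h$W1, 2, h$b1, `+`)
  A <- pmax(Pre, 0)
  out <- sweep(A %*% h$W2, 2, h$b2, `+`)
  list(out = out, X = X, Pre = Pre, A = A)
}

.mlp2_backward <- function(h, cache, dOut) {
  gW2 <- crossprod(cache$A, dOut)
  gb2 <- colSums(dOut)
  dA <- dOut %*% t(h$W2)
  dPre <- dA * (cache$Pre > 0)
  gW1 <- crossprod(cache$X, dPre)
  gb1 <- colSums(dPre)
  dX <- dPre %*% t(h$W1)
  list(dX = dX, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

# ---- edge-type-sliced graph convolution ------------------------------------

#' One graph-convolution layer over edge-type slices
#'
#' For each bond-type slice `E_i` the adjacency is self-looped
#' (`Ehat_i = E_i + I`) and symmetrically renormalized by its degree matrix;
#' the layer output is the mean over the three slices of
#' `relu(Dhat^-1/2 Ehat Dhat^-1/2 H W_i)`.
#'
#' @param H node embedding matrix (p x d_in).
#' @param E edge tensor `3 x p x p` (zero-padded rows for edgeless nodes).
#' @param weights list of 3 matrices `W_i` (d_in x d_out).
#' @return list with `H` (p x d_out) and a `cache` for backpropagation.
#' @export
gcn_layer <- function(H, E, weights) {
  p <- nrow(H)
  stopifnot(length(weights) == 3, dim(E)[2] == p, dim(E)[3] == p,
            nrow(weights[[1]]) == ncol(H))
  out <- 0
  cache <- vector("list", 3)
  for (i in 1:3) {
    Ehat <- matrix(E[i, , ], p, p) + diag(p)
    dh <- 1 / sqrt(rowSums(Ehat))
    Nhat <- Ehat * outer(dh, dh)
    P <- Nhat %*% H
    Pre <- P %*% weights[[i]]
    out <- out + pmax(Pre, 0)
    cache[[i]] <- list(Nhat = Nhat, P = P, Pre = Pre)
  }
  list(H = out / 3, cache = cache)
}

.gcn_layer_backward <- function(weights, cache, dH) {
  g <- vector("list", 3)
  dHin <- 0
  for (i in 1:3) {
    dPre <- (dH / 3) * (cache[[i]]$Pre > 0)
    g[[i]] <- crossprod(cache[[i]]$P, dPre)
    dP <- dPre %*% t(weights[[i]])
    dHin <- dHin + cache[[i]]$Nhat %*% dP   # Nhat is symmetric
  }
  list(grads = g, dH = dHin)
}

.gcn_stack_forward <- function(Wg, X0, E) {
  H <- X0
  caches <- vector("list", length(Wg))
  Hs <- vector("list", length(Wg))
  for (l in seq_along(Wg)) {
    r <- gcn_layer(H, E, Wg[[l]])
    caches[[l]] <- r$cache
    H <- r$H
    Hs[[l]] <- H
  }
  list(H = H, caches = caches)
}

.gcn_stack_backward <- function(Wg, fw, dH) {
  g <- vector("list", length(Wg))
  for (l in rev(seq_along(Wg))) {
    r <- .gcn_layer_backward(Wg[[l]], fw$caches[[l]], dH)
    g[[l]] <- r$grads
    dH <- r$dH
  }
  g
}

# ---- policy object ---------------------------------------------------------

#' Initialize a graph convolutional policy
#'
#' @param embed_dim node embedding size d.
#' @param n_layers number of graph-convolution layers L.
#' @param atom_types addable atom-type menu (the candidate scaffold nodes).
#' @param seed integer seed for the Xavier draw.
#' @return a `gcpn_policy` with convolution weights (3 per layer), the four
#'   action heads, and the value head.
#' @export
gcpn_policy <- function(embed_dim = 128L, n_layers = 3L,
                        atom_types = c("C", "N", "O", "S", "F", "Cl",
                                       "Br", "I", "P"),
                        seed = 1L) {
  set.seed(seed)
  d <- as.integer(embed_dim)
  Wg <- lapply(seq_len(n_layers), function(l) {
    nin <- if (l == 1) ATOM_FDIM else d
    lapply(1:3, function(i) .xavier(nin, d))
  })
  structure(list(
    params = list(
      Wg = Wg,
      mf = .mlp2_init(d, d, 1L),
      ms = .mlp2_init(2L * d, d, 1L),
      me = .mlp2_init(2L * d, d, 3L),
      mt = .mlp2_init(d, d, 2L),
      vh = .mlp2_init(d, d, 1L)
    ),
    embed_dim = d, n_layers = as.integer(n_layers), atom_types = atom_types
  ), class = "gcpn_policy")
}

#' @export
print.gcpn_policy <- function(x, ...) {
  cat(sprintf("<gcpn_policy> d = %d, L = %d, %d atom types\n",
              x$embed_dim, x$n_layers, length(x$atom_types)))
  invisible(x)
}

# candidate scaffold-node features: one-hot element identity in the atomic
# number block, padded to the atom-feature width
.candidate_features <- function(atom_types) {
  t(vapply(atom_types, function(el) {
    v <- numeric(ATOM_FDIM)
    v[.atomic_number(el)] <- 1
    v
  }, numeric(ATOM_FDIM)))
}

.padded_E <- function(state, ct) {
  p <- state$n + ct
  E <- array(0L, dim = c(3L, p, p))
  E[, seq_len(state$n), seq_len(state$n)] <- state$E
  E
}

#' Embed an environment state
#'
#' Appends the edgeless candidate atom-type nodes below the molecule's atoms
#' and runs the L graph-convolution layers.
#'
#' @param state a `dense_state`.
#' @param policy a [gcpn_policy()].
#' @return embedding matrix with `n + c` rows.
#' @export
embed_state <- function(state, policy) {
  .policy_embed(state, policy)$H
}

.policy_embed <- function(state, policy) {
  X0 <- rbind(state$F, .candidate_features(policy$atom_types))
  E <- .padded_E(state, length(policy$atom_types))
  fw <- .gcn_stack_forward(policy$params$Wg, X0, E)
  c(fw, list(X0 = X0, E = E))
}

.log_softmax <- function(z) {
  z <- z - max(z)
  z - log(sum(exp(z)))
}

.softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# Forward evaluation of all four heads (and value) for a state; if `action`
# is supplied its log-probability is computed, otherwise an action is sampled
# ancestrally. Returns everything needed for the backward pass.
.policy_eval <- function(policy, state, action = NULL, max_resample = 10L) {
  n <- state$n; ct <- length(policy$atom_types)
  emb <- .policy_embed(state, policy)
  X <- emb$H
  pp <- policy$params

  cf <- .mlp2_forward(pp$mf, X[seq_len(n), , drop = FALSE])
  logp_f <- .log_softmax(as.vector(cf$out))
  first <- if (is.null(action)) {
    sample.int(n, 1, prob = exp(logp_f))
  } else action$first

  Xf <- X[first, ]
  Us <- cbind(matrix(Xf, n + ct, length(Xf), byrow = TRUE), X)
  cs <- .mlp2_forward(pp$ms, Us)
  logp_s <- .log_softmax(as.vector(cs$out))
  second <- if (is.null(action)) {
    sec <- NA_integer_
    for (k in seq_len(max_resample)) {
      cand <- sample.int(n + ct, 1, prob = exp(logp_s))
      if (cand != first) { sec <- cand; break }
    }
    if (is.na(sec)) sec <- first  # degenerate; environment rejects it
    sec
  } else action$second

  Ue <- matrix(c(Xf, X[second, ]), 1)
  ce <- .mlp2_forward(pp$me, Ue)
  logp_e <- .log_softmax(as.vector(ce$out))
  edge <- if (is.null(action)) {
    sample.int(3L, 1, prob = exp(logp_e))
  } else action$edge

  xbar <- matrix(colMeans(X), 1)
  ctp <- .mlp2_forward(pp$mt, xbar)
  logp_t <- .log_softmax(as.vector(ctp$out))
  stop_ <- if (is.null(action)) {
    sample.int(2L, 1, prob = exp(logp_t)) - 1L
  } else action$stop

  cv <- .mlp2_forward(pp$vh, xbar)

  act <- action_vector(first, second, edge, stop_)
  list(
    action = act,
    logp = logp_f[first] + logp_s[second] + logp_e[edge] + logp_t[stop_ + 1L],
    logp_parts = c(first = logp_f[first], second = logp_s[second],
                   edge = logp_e[edge], stop = logp_t[stop_ + 1L]),
    value = cv$out[1, 1],
    dists = list(first = c(exp(logp_f), numeric(ct)), second = exp(logp_s),
                 edge = exp(logp_e), stop = exp(logp_t)),
    emb = emb, X = X, n = n, ct = ct,
    cf = cf, cs = cs, ce = ce, ctp = ctp, cv = cv
  )
}

# Backward pass. Returns the gradient tree of
#   Loss = -coef_logp * logp(action|state) + (value term with dLoss/dV = dvalue)
# so descending the result raises the action's log-probability when
# coef_logp > 0 (the PPO surrogate coefficient).
.policy_backward <- function(policy, ev, coef_logp, dvalue = 0) {
  pp <- policy$params
  n <- ev$n; ct <- ev$ct
  d <- policy$embed_dim
  dX <- matrix(0, n + ct, d)
  a <- ev$action

  # categorical heads: dLoss/dlogits = coef * (p - onehot)
  g_f <- ev$dists$first[seq_len(n)]; g_f[a$first] <- g_f[a$first] - 1
  bf <- .mlp2_backward(pp$mf, ev$cf, matrix(coef_logp * g_f, ncol = 1))
  dX[seq_len(n), ] <- dX[seq_len(n), ] + bf$dX

  g_s <- ev$dists$second; g_s[a$second] <- g_s[a$second] - 1
  bs <- .mlp2_backward(pp$ms, ev$cs, matrix(coef_logp * g_s, ncol = 1))
  dX <- dX + bs$dX[, d + seq_len(d), drop = FALSE]
  dX[a$first, ] <- dX[a$first, ] + colSums(bs$dX[, seq_len(d), drop = FALSE])

  g_e <- ev$dists$edge; g_e[a$edge] <- g_e[a$edge] - 1
  be <- .mlp2_backward(pp$me, ev$ce, matrix(coef_logp * g_e, nrow = 1))
  dX[a$first, ] <- dX[a$first, ] + be$dX[1, seq_len(d)]
  dX[a$second, ] <- dX[a$second, ] + be$dX[1, d + seq_len(d)]

  g_t <- ev$dists$stop; g_t[a$stop + 1L] <- g_t[a$stop + 1L] - 1
  bt <- .mlp2_backward(pp$mt, ev$ctp, matrix(coef_logp * g_t, nrow = 1))
  dxbar <- bt$dX

  bv <- .mlp2_backward(pp$vh, ev$cv, matrix(dvalue, 1, 1))
  dxbar <- dxbar + bv$dX
  dX <- dX + matrix(rep(dxbar / (n + ct), each = n + ct), n + ct, d)

  gW <- .gcn_stack_backward(pp$Wg, ev$emb, dX)
  list(Wg = gW, mf = bf$grads, ms = bs$grads, me = be$grads, mt = bt$grads,
       vh = bv$grads)
}

#' Sample an action from the policy
#'
#' Ancestral sampling through the four heads: first atom (restricted to the
#' current molecule), second atom (molecule or candidate types; draws equal
#' to the first atom are rejected and resampled a bounded number of times),
#' bond type, stop flag.
#'
#' @param policy a `gcpn_policy`.
#' @param state a `dense_state`.
#' @return list with `action` (an [action_vector()]), its `logp` (sum of the
#'   four head log-probabilities), `value` (state-value estimate) and `dists`
#'   (the four categorical distributions; candidate slots of the first-atom
#'   distribution are structurally zero).
#' @export
policy_act <- function(policy, state) {
  ev <- .policy_eval(policy, state)
  list(action = ev$action, logp = ev$logp, value = ev$value, dists = ev$dists)
}

#' Log-probability of a composite action
#'
#' @inheritParams policy_act
#' @param action an [action_vector()].
#' @return scalar log-probability (sum of the four head terms).
#' @export
policy_logprob <- function(policy, state, action) {
  .policy_eval(policy, state, action)$logp
}

#' State-value estimate
#'
#' MLP readout of the mean-pooled node embedding.
#'
#' @inheritParams policy_act
#' @return scalar value estimate.
#' @export
policy_value <- function(policy, state) {
  .policy_eval(policy, state,
               action = action_vector(1L, 1L, 1L, 0L))$value
}

# ---- discriminator ---------------------------------------------------------

#' Initialize the adversarial discriminator
#'
#' Same per-edge-type graph convolution as the policy (over the molecule's
#' atoms only), mean pooling, and a two-layer head with terminal sigmoid
#' scoring the probability that a graph comes from the expert set.
#'
#' @inheritParams gcpn_policy
#' @return a `discriminator` object.
#' @export
discriminator_init <- function(embed_dim = 128L, n_layers = 3L, seed = 1L) {
  set.seed(seed)
  d <- as.integer(embed_dim)
  Wg <- lapply(seq_len(n_layers), function(l) {
    nin <- if (l == 1) ATOM_FDIM else d
    lapply(1:3, function(i) .xavier(nin, d))
  })
  structure(list(params = list(Wg = Wg, head = .mlp2_init(d, d, 1L)),
                 embed_dim = d, n_layers = as.integer(n_layers)),
            class = "discriminator")
}

.disc_eval <- function(disc, state) {
  fw <- .gcn_stack_forward(disc$params$Wg, state$F, state$E)
  xbar <- matrix(colMeans(fw$H), 1)
  ch <- .mlp2_forward(disc$params$head, xbar)
  logit <- ch$out[1, 1]
  list(p = .sigmoid(logit), logit = logit, fw = fw, ch = ch,
       n = state$n)
}

# dLoss/dlogit -> gradient tree
.disc_backward <- function(disc, ev, dlogit) {
  bh <- .mlp2_backward(disc$params$head, ev$ch, matrix(dlogit, 1, 1))
  dH <- matrix(rep(bh$dX / ev$n, each = ev$n), ev$n, disc$embed_dim)
  gW <- .gcn_stack_backward(disc$params$Wg, ev$fw, dH)
  list(Wg = gW, head = bh$grads)
}

#' Discriminator probability that a graph is from the expert data
#'
#' @param state a `dense_state`.
#' @param disc a `discriminator`.
#' @return probability in (0, 1).
#' @export
discriminate <- function(state, disc) {
  stopifnot(inherits(state, "dense_state"), inherits(disc, "discriminator"))
  .disc_eval(disc, state)$p
}
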