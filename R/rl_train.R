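# Policy-gradient training: proximal policy optimization with generalized
# advantage estimation, an adversarial reward from the expert discriminator,
# and expert imitation (subgraph/action pairs sampled from reference
# molecules). The policy and discriminator alternate updates each iteration.

#' Generalized advantage estimation
#'
#' `delta_t = R_t + gamma * V(S_{t+1}) - V(S_t)`;
#' `A_t = sum_k (gamma*lambda)^k delta_{t+k}`. With `lambda = 0` this
#' collapses to the one-step TD error; with `gamma = lambda = 1` it equals
#' the Monte-Carlo return minus the value baseline.
#'
#' @param rewards numeric vector of per-step rewards (length T).
#' @param values numeric vector of state values including the bootstrap for
#'   the post-terminal state (length T + 1; 0 for terminal episodes).
#' @param gamma discount factor.
#' @param lambda GAE mixing parameter.
#' @return numeric vector of advantage estimates (length T).
#' @export
gae <- function(rewards, values, gamma = 0.99, lambda = 0.95) {
  T_ <- length(rewards)
  if (length(values) != T_ + 1L) {
    stop("values must have length(rewards) + 1 (bootstrap included)")
  }
  deltas <- rewards + gamma * values[-1] - values[-(T_ + 1L)]
  adv <- numeric(T_)
  acc <- 0
  for (t in rev(seq_len(T_))) {
    acc <- deltas[t] + gamma * lambda * acc
    adv[t] <- acc
  }
  adv
}

#' PPO clipped surrogate objective
#'
#' `min(r * A, clip(r, 1 - eps, 1 + eps) * A)` with
#' `r = exp(logp_new - logp_old)`; the quantity to be maximized.
#'
#' @param logp_new,logp_old log-probabilities of the taken actions under the
#'   current and behaviour policies.
#' @param advantage advantage estimates.
#' @param eps clip radius.
#' @return numeric vector of per-step surrogate values.
#' @export
ppo_objective <- function(logp_new, logp_old, advantage, eps = 0.2) {
  stopifnot(eps > 0, eps < 1)
  r <- exp(logp_new - logp_old)
  pmin(r * advantage, pmin(pmax(r, 1 - eps), 1 + eps) * advantage)
}

#' Adversarial reward term
#'
#' The generator's reward from the discriminator: `-log(1 - D(x))`, monotone
#' increasing in `D(x)` (large when the molecule fools the discriminator).
#' `D` is clamped away from 0 and 1 before the logarithm.
#'
#' @param disc a `discriminator`.
#' @param state a `dense_state`.
#' @return scalar reward contribution.
#' @export
adversarial_term <- function(disc, state) {
  p <- min(max(discriminate(state, disc), 1e-6), 1 - 1e-6)
  -log(1 - p)
}

#' PPO training configuration
#'
#' @param clip PPO clip radius epsilon.
#' @param gamma discount factor.
#' @param lambda GAE parameter.
#' @param lr initial learning rate; decays linearly to 0 by
#'   `lr_decay_steps` environment steps.
#' @param lr_decay_steps horizon of the linear decay (the full-scale setting
#'   is 3e7 steps, under which toy runs see an almost constant rate).
#' @param episodes_per_iter trajectories collected per iteration.
#' @param ppo_epochs gradient passes over each collected batch.
#' @param value_coef weight of the squared-error value loss.
#' @param expert_weight initial weight of the expert imitation loss; decays
#'   linearly to 0 over `expert_horizon` iterations.
#' @param expert_horizon iterations over which the expert weight anneals.
#' @param expert_pairs_per_iter imitation pairs sampled per PPO epoch.
#' @param adv_norm normalize advantages per batch.
#' @param adv_guard abort when the mean absolute advantage exceeds this bound
#'   (divergence guard).
#' @param seed integer seed.
#' @return a `ppo_config` list.
#' @export
ppo_config <- function(clip = 0.2, gamma = 0.99, lambda = 0.95,
                       lr = 1e-3, lr_decay_steps = 3e7,
                       episodes_per_iter = 12L, ppo_epochs = 4L,
                       value_coef = 0.5,
                       expert_weight = 0, expert_horizon = 50L,
                       expert_pairs_per_iter = 8L,
                       adv_norm = TRUE, adv_guard = 1e3, seed = 1L) {
  stopifnot(clip > 0, clip < 1, gamma > 0, gamma <= 1, lambda >= 0,
            lambda <= 1)
  structure(list(clip = clip, gamma = gamma, lambda = lambda, lr = lr,
                 lr_decay_steps = lr_decay_steps,
                 episodes_per_iter = as.integer(episodes_per_iter),
                 ppo_epochs = as.integer(ppo_epochs),
                 value_coef = value_coef, expert_weight = expert_weight,
                 expert_horizon = as.integer(expert_horizon),
                 expert_pairs_per_iter = as.integer(expert_pairs_per_iter),
                 adv_norm = adv_norm, adv_guard = adv_guard,
                 seed = as.integer(seed)),
            class = "ppo_config")
}

# ---- expert pairs ----------------------------------------------------------

.mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  A <- matrix(0L, n, n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    A[mol$bonds$a1[k], mol$bonds$a2[k]] <- mol$bonds$order[k]
    A[mol$bonds$a2[k], mol$bonds$a1[k]] <- mol$bonds$order[k]
  }
  A
}

# dense state for an atom subset of a mol, with an optional internal bond
# removed; atom order = `keep` order
.subgraph_state <- function(mol, keep, drop_bond = NULL) {
  A <- .mol_adjacency(mol)
  n <- length(keep)
  sA <- matrix(0L, n, n); sE <- array(0L, dim = c(3L, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      o <- A[keep[i], keep[j]]
      if (!is.null(drop_bond) &&
          setequal(c(keep[i], keep[j]), drop_bond)) o <- 0L
      if (o > 0) {
        sA[i, j] <- sA[j, i] <- 1L
        sE[o, i, j] <- sE[o, j, i] <- 1L
      }
    }
  }
  st <- structure(list(A = sA, E = sE, F = NULL,
                       elements = mol$atoms$element[keep], n = n),
                  class = "dense_state")
  st$F <- .atom_feature_matrix(.state_to_mol(st))
  st
}

#' Sample an expert imitation pair
#'
#' Grows a random connected subgraph of the expert molecule as the state, and
#' picks a random single addition from the remainder adjacent to it as the
#' action: either a frontier atom (growth) or, occasionally, an omitted
#' internal ring-closing bond. Applying the action always yields a subgraph
#' of the expert molecule. Single-atom experts produce a stop-action pair.
#'
#' @param expert a SMILES string or `mol`.
#' @param atom_types the policy's addable-type menu (frontier atoms outside
#'   the menu are not proposed).
#' @param p_ring_closure probability of proposing an omitted ring bond when
#'   one exists.
#' @return list with `state` (a `dense_state`) and `action` (an
#'   [action_vector()] in the state's indexing), or `NULL` when the molecule
#'   offers no representable addition.
#' @export
sample_expert_pair <- function(expert,
                               atom_types = c("C", "N", "O", "S", "F", "Cl",
                                              "Br", "I", "P"),
                               p_ring_closure = 0.25) {
  mol <- if (inherits(expert, "mol")) expert else parse_smiles(expert)
  n <- nrow(mol$atoms)
  if (n < 2) {
    st <- as_dense_state(mol)
    return(list(state = st, action = action_vector(1L, 1L, 1L, 1L)))
  }
  A <- .mol_adjacency(mol)
  # subgraphs may span all atoms: the expert action is then a missing ring
  # bond, or "stop" when the molecule is already complete
  size <- sample.int(n, 1)
  keep <- sample.int(n, 1)
  while (length(keep) < size) {
    nb <- setdiff(which(rowSums(A[, keep, drop = FALSE] > 0) > 0), keep)
    if (!length(nb)) break
    keep <- c(keep, if (length(nb) == 1) nb else sample(nb, 1))
  }
  # candidate ring closures: internal bonds whose removal keeps the subgraph
  # connected (i.e. part of a cycle within the subgraph)
  closures <- NULL
  if (length(keep) >= 3) {
    subA <- A[keep, keep, drop = FALSE] > 0
    nb_cnt <- rowSums(subA)
    g_edges <- which(upper.tri(subA) & subA, arr.ind = TRUE)
    if (nrow(g_edges)) {
      in_cycle <- apply(g_edges, 1, function(e) {
        # connected after removing e?
        Ae <- subA; Ae[e[1], e[2]] <- Ae[e[2], e[1]] <- FALSE
        reach <- rep(FALSE, length(keep)); reach[1] <- TRUE
        repeat {
          new <- which(!reach & colSums(Ae[reach, , drop = FALSE]) > 0)
          if (!length(new)) break
          reach[new] <- TRUE
        }
        all(reach)
      })
      if (any(in_cycle)) closures <- g_edges[in_cycle, , drop = FALSE]
    }
  }
  if (!is.null(closures) &&
      (length(keep) == n || stats::runif(1) < p_ring_closure)) {
    pick <- closures[sample.int(nrow(closures), 1), ]
    drop_pair <- keep[pick]
    st <- .subgraph_state(mol, keep, drop_bond = drop_pair)
    o <- A[drop_pair[1], drop_pair[2]]
    return(list(state = st,
                action = action_vector(pick[1], pick[2], o, 0L)))
  }
  if (length(keep) == n) {
    # complete molecule reproduced: the expert signal is the stop action
    return(list(state = .subgraph_state(mol, keep),
                action = action_vector(1L, 1L, 1L, 1L)))
  }
  frontier <- which(rowSums(A[, keep, drop = FALSE] > 0) > 0)
  frontier <- setdiff(frontier, keep)
  frontier <- frontier[mol$atoms$element[frontier] %in% atom_types]
  if (!length(frontier)) {
    # fully grown (or unrepresentable frontier): the expert action is to stop
    st <- .subgraph_state(mol, keep)
    return(list(state = st, action = action_vector(1L, 1L, 1L, 1L)))
  }
  v <- if (length(frontier) == 1) frontier else sample(frontier, 1)
  anchors <- keep[A[v, keep] > 0]
  u <- if (length(anchors) == 1) anchors else sample(anchors, 1)
  st <- .subgraph_state(mol, keep)
  list(state = st,
       action = action_vector(
         first = match(u, keep),
         second = length(keep) + match(mol$atoms$element[v], atom_types),
         edge = A[u, v], stop = 0L))
}

#' Expert imitation loss
#'
#' Mean negative log-probability of the expert actions under the policy
#' (composite log-probability = sum of the four head terms). Log-probabilities
#' are clamped at -50 with a warning if an action is effectively impossible.
#'
#' @param policy a `gcpn_policy`.
#' @param pairs list of pairs from [sample_expert_pair()].
#' @return scalar loss (>= 0).
#' @export
expert_loss <- function(policy, pairs) {
  stopifnot(length(pairs) >= 1)
  lps <- vapply(pairs, function(pr) {
    policy_logprob(policy, pr$state, pr$action)
  }, numeric(1))
  if (any(lps < -50)) {
    warning("expert action(s) with vanishing probability; log clamped")
    lps <- pmax(lps, -50)
  }
  -mean(lps)
}

#' Expert pretraining
#'
#' Supervised warm-up of the policy on expert subgraph/action pairs only:
#' each update samples fresh pairs from the expert set and descends the mean
#' negative log-probability of the expert actions.
#'
#' @param policy a `gcpn_policy`.
#' @param expert_set character vector of expert SMILES.
#' @param updates gradient updates.
#' @param pairs_per_update imitation pairs per update.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @return list with the updated `policy` and a `log` tibble of the expert
#'   loss per update.
#' @export
pretrain_expert <- function(policy, expert_set, updates = 200L,
                            pairs_per_update = 8L, lr = 1e-3, seed = 1L) {
  set.seed(seed)
  expert_mols <- lapply(expert_set, parse_smiles)
  adam <- .tree_adam_init(policy$params)
  losses <- numeric(updates)
  for (u in seq_len(updates)) {
    pairs <- lapply(seq_len(pairs_per_update), function(k) {
      sample_expert_pair(expert_mols[[sample.int(length(expert_mols), 1)]],
                         atom_types = policy$atom_types)
    })
    grad <- .tree_zero(policy$params)
    el <- 0
    for (pr in pairs) {
      ev <- .policy_eval(policy, pr$state, pr$action)
      el <- el - ev$logp
      g <- .policy_backward(policy, ev, coef_logp = 1 / length(pairs),
                            dvalue = 0)
      grad <- .tmap(`+`, grad, g)
    }
    st <- .tree_adam_step(policy$params, grad, adam, lr)
    policy$params <- st$params; adam <- st$state
    losses[u] <- el / length(pairs)
  }
  list(policy = policy,
       log = tibble::tibble(update = seq_len(updates), expert_loss = losses))
}

# ---- episode collection ----------------------------------------------------

# roll out one episode; returns transitions plus the final breakdown
.collect_episode <- function(policy, config, discriminator = NULL,
                             init = "C") {
  env <- env_reset(init, config)
  states <- list(); actions <- list(); logps <- c(); rewards <- c(); values <- c()
  breakdown <- NULL
  repeat {
    act <- policy_act(policy, env$state)
    states[[length(states) + 1L]] <- env$state
    actions[[length(actions) + 1L]] <- act$action
    logps <- c(logps, act$logp)
    values <- c(values, act$value)
    stp <- env_step(env, act$action, config, discriminator)
    rewards <- c(rewards, stp$reward)
    env <- stp$env
    if (stp$done) { breakdown <- stp$breakdown; break }
  }
  list(states = states, actions = actions, logp_old = logps,
       rewards = rewards, values = values, breakdown = breakdown,
       final_state = env$state, steps = env$steps)
}

#' Generate molecules with a (possibly untrained) policy
#'
#' Rolls out construction episodes and returns one record per episode. All
#' emitted molecules come from valence-checked states, so they are valid by
#' construction; the `valid` column re-verifies this with the full
#' sanitization round trip.
#'
#' @param policy a `gcpn_policy`.
#' @param config a [reward_config()].
#' @param n_episodes number of episodes.
#' @param init initial state (`"C"` or a seed SMILES); may be a character
#'   vector to sample seeds from.
#' @param compute_reward also compute the final reward breakdown per episode
#'   (slower; off by default).
#' @param seed optional integer seed.
#' @return tibble with columns `smiles`, `n_atoms`, `steps`, `valid`, and the
#'   reward columns when `compute_reward = TRUE`.
#' @export
generate_molecules <- function(policy, config = reward_config(),
                               n_episodes = 100L, init = "C",
                               compute_reward = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_episodes)
  for (ep in seq_len(n_episodes)) {
    this_init <- if (length(init) > 1) sample(init, 1) else init
    cfg <- config
    if (!compute_reward) {
      cfg$qed_weight <- 0; cfg$sa_weight <- 0; cfg$strain_bonus <- 0
      cfg$filter_bonus <- 0; cfg$adversarial_weight <- 0
      cfg$property_weights <- numeric(0)
    }
    env <- env_reset(this_init, cfg)
    repeat {
      act <- policy_act(policy, env$state)
      stp <- env_step(env, act$action, cfg)
      env <- stp$env
      if (stp$done) break
    }
    smi <- state_to_molecule(env$state)$smiles
    valid <- !is.na(smi) &&
      is_sanitizable(tryCatch(parse_smiles(smi), error = function(e) {
        structure(list(atoms = tibble::tibble(element = "X"),
                       bonds = tibble::tibble()), class = "mol")
      }))
    row <- tibble::tibble(smiles = smi, n_atoms = env$state$n,
                          steps = env$steps, valid = valid)
    if (compute_reward) {
      bd <- stp$breakdown
      extra <- tibble::as_tibble(as.list(bd$parts))
      names(extra) <- paste0("part_", names(extra))
      row <- dplyr::bind_cols(row, extra, tibble::tibble(reward = bd$total))
      for (nm in names(bd$raw)) row[[nm]] <- bd$raw[[nm]]
      if (!is.null(bd$predictions)) {
        for (nm in names(bd$predictions)) {
          row[[paste0("pred_", nm)]] <- bd$predictions[[nm]]
        }
      }
    }
    rows[[ep]] <- row
  }
  dplyr::bind_rows(rows)
}

# ---- the training loop -----------------------------------------------------

#' Train the graph construction policy with PPO
#'
#' Each iteration: collect trajectories under the current policy; compute
#' itemized environment rewards (including the adversarial term when
#' configured); estimate advantages with GAE; run several PPO epochs on the
#' clipped surrogate plus value regression and (optionally) the expert
#' imitation loss; then update the discriminator on expert-vs-generated
#' batches. With `adversarial_weight = 0` and `expert_weight = 0` this is
#' plain PPO.
#'
#' @param policy a [gcpn_policy()].
#' @param config a [reward_config()].
#' @param ppo a [ppo_config()].
#' @param iterations training iterations.
#' @param expert_set character vector of expert SMILES (required when the
#'   expert loss or adversarial reward is active).
#' @param discriminator a [discriminator_init()] object; created on demand
#'   when the adversarial weight is nonzero.
#' @param init episode initialization (`"C"` or seed SMILES vector).
#' @param verbose print per-iteration summaries.
#' @return a `gcpn_run`: list with the trained `policy`, `discriminator`,
#'   per-iteration `log` tibble (mean reward, validity rate, losses) and the
#'   final-episode records.
#' @export
train_gcpn <- function(policy, config = reward_config(), ppo = ppo_config(),
                       iterations = 30L, expert_set = NULL,
                       discriminator = NULL, init = "C", verbose = FALSE) {
  set.seed(ppo$seed)
  needs_expert <- ppo$expert_weight > 0 || config$adversarial_weight != 0
  if (needs_expert && is.null(expert_set)) {
    stop("expert_set required when the expert loss or adversarial reward is on")
  }
  if (config$adversarial_weight != 0 && is.null(discriminator)) {
    discriminator <- discriminator_init(policy$embed_dim, policy$n_layers,
                                        seed = ppo$seed + 1L)
  }
  expert_mols <- if (needs_expert) lapply(expert_set, parse_smiles) else NULL
  adam_p <- .tree_adam_init(policy$params)
  adam_d <- if (!is.null(discriminator)) {
    .tree_adam_init(discriminator$params)
  } else NULL
  env_steps <- 0
  log_rows <- vector("list", iterations)
  last_eps <- NULL

  for (it in seq_len(iterations)) {
    eps <- lapply(seq_len(ppo$episodes_per_iter), function(e) {
      .collect_episode(policy, config, discriminator,
                       init = if (length(init) > 1) sample(init, 1) else init)
    })
    env_steps <- env_steps + sum(vapply(eps, function(e) e$steps, numeric(1)))
    # advantages and empirical returns per episode
    trans <- list()
    for (e in eps) {
      adv <- gae(e$rewards, c(e$values, 0), ppo$gamma, ppo$lambda)
      ret <- adv + e$values
      for (t in seq_along(e$rewards)) {
        trans[[length(trans) + 1L]] <- list(
          state = e$states[[t]], action = e$actions[[t]],
          logp_old = e$logp_old[t], adv = adv[t], ret = ret[t])
      }
    }
    advs <- vapply(trans, function(tr) tr$adv, numeric(1))
    if (mean(abs(advs)) > ppo$adv_guard) {
      stop("advantage estimates diverged (mean |A| = ",
           signif(mean(abs(advs)), 3), ")")
    }
    if (ppo$adv_norm && length(advs) > 1 && stats::sd(advs) > 1e-8) {
      advs <- (advs - mean(advs)) / stats::sd(advs)
      for (i in seq_along(trans)) trans[[i]]$adv <- advs[i]
    }
    lr_now <- ppo$lr * max(0, 1 - env_steps / ppo$lr_decay_steps)
    w_exp <- if (ppo$expert_weight > 0) {
      ppo$expert_weight * max(0, 1 - (it - 1) / ppo$expert_horizon)
    } else 0

    surr_val <- NA_real_; eloss_val <- NA_real_
    for (ppoe in seq_len(ppo$ppo_epochs)) {
      grad_acc <- .tree_zero(policy$params)
      surr_tot <- 0
      ntr <- length(trans)
      for (tr in trans) {
        ev <- .policy_eval(policy, tr$state, tr$action)
        ratio <- exp(ev$logp - tr$logp_old)
        clipped <- min(max(ratio, 1 - ppo$clip), 1 + ppo$clip)
        surr <- min(ratio * tr$adv, clipped * tr$adv)
        surr_tot <- surr_tot + surr
        # gradient of -surrogate wrt logp_new: active only on the unclipped
        # branch of the min
        coef <- if (ratio * tr$adv <= clipped * tr$adv) ratio * tr$adv else 0
        dv <- ppo$value_coef * (ev$value - tr$ret)
        g <- .policy_backward(policy, ev, coef_logp = coef / ntr,
                              dvalue = dv / ntr)
        grad_acc <- .tmap(`+`, grad_acc, g)
      }
      if (w_exp > 0) {
        pairs <- lapply(seq_len(ppo$expert_pairs_per_iter), function(k) {
          sample_expert_pair(expert_mols[[sample.int(length(expert_mols), 1)]],
                             atom_types = policy$atom_types)
        })
        el <- 0
        for (pr in pairs) {
          evp <- .policy_eval(policy, pr$state, pr$action)
          el <- el - evp$logp
          gp <- .policy_backward(policy, evp,
                                 coef_logp = w_exp / length(pairs),
                                 dvalue = 0)
          grad_acc <- .tmap(`+`, grad_acc, gp)
        }
        eloss_val <- el / length(pairs)
      }
      st <- .tree_adam_step(policy$params, grad_acc, adam_p, lr_now)
      policy$params <- st$params; adam_p <- st$state
      surr_val <- surr_tot / ntr
    }

    dloss_val <- NA_real_
    if (!is.null(discriminator) && config$adversarial_weight != 0) {
      gen_states <- lapply(eps, function(e) e$final_state)
      exp_states <- lapply(sample(expert_mols, min(length(gen_states),
                                                   length(expert_mols))),
                           as_dense_state)
      grad_d <- .tree_zero(discriminator$params)
      dl <- 0; npair <- length(gen_states) + length(exp_states)
      for (s in exp_states) {
        evd <- .disc_eval(discriminator, s)
        p <- min(max(evd$p, 1e-6), 1 - 1e-6)
        dl <- dl - log(p)
        gd <- .disc_backward(discriminator, evd, (evd$p - 1) / npair)
        grad_d <- .tmap(`+`, grad_d, gd)
      }
      for (s in gen_states) {
        evd <- .disc_eval(discriminator, s)
        p <- min(max(evd$p, 1e-6), 1 - 1e-6)
        dl <- dl - log(1 - p)
        gd <- .disc_backward(discriminator, evd, evd$p / npair)
        grad_d <- .tmap(`+`, grad_d, gd)
      }
      std <- .tree_adam_step(discriminator$params, grad_d, adam_d, lr_now)
      discriminator$params <- std$params; adam_d <- std$state
      dloss_val <- dl / npair
    }

    totals <- vapply(eps, function(e) sum(e$rewards), numeric(1))
    valid_rate <- mean(vapply(eps, function(e) {
      smi <- suppressWarnings(mol_to_smiles(.state_to_mol(e$final_state)))
      !is.na(smi)
    }, logical(1)))
    log_rows[[it]] <- tibble::tibble(
      iteration = it, mean_reward = mean(totals),
      mean_steps = mean(vapply(eps, function(e) e$steps, numeric(1))),
      validity = valid_rate, surrogate = surr_val,
      expert_loss = eloss_val, disc_loss = dloss_val, lr = lr_now,
      expert_weight = w_exp)
    last_eps <- eps
    if (verbose) {
      message(sprintf("iter %3d  reward %7.3f  valid %.2f  steps %.1f",
                      it, mean(totals), valid_rate,
                      mean(vapply(eps, function(e) e$steps, numeric(1)))))
    }
  }
  structure(list(policy = policy, discriminator = discriminator,
                 log = dplyr::bind_rows(log_rows),
                 final_episodes = tibble::tibble(
                   smiles = vapply(last_eps, function(e) {
                     state_to_molecule(e$final_state)$smiles
                   }, character(1)),
                   reward = vapply(last_eps, function(e) sum(e$rewards),
                                   numeric(1)))),
            class = "gcpn_run")
}

#' @export
print.gcpn_run <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<gcpn_run> %d iterations; mean reward %.3f -> %.3f; validity %.0f%%\n",
              n, x$log$mean_reward[1], x$log$mean_reward[n],
              100 * mean(x$log$validity)))
  invisible(x)
}
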