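# Molecule-construction Markov decision process. States are valence-respecting
# partial molecules (dense A/E/F graphs over heavy atoms); actions pick a
# first atom in the molecule, a second atom (existing -> ring closure, or one
# of the addable atom types -> growth), a bond order, and a stop flag. Invalid
# chemistry leaves the state unchanged; stepwise validity earns a small bonus
# and the final molecule earns the composed property/drug-likeness reward.

#' Action vector
#'
#' The composite action of the construction policy: four components.
#'
#' @param first index of the anchor atom (1..n, must be in the molecule).
#' @param second index of the partner: an existing atom (1..n, ring closure)
#'   or `n + k` for the k-th addable atom type (growth step).
#' @param edge bond order class, 1 = single, 2 = double, 3 = triple.
#' @param stop 0 to continue, 1 to finish the molecule.
#' @return an `action_vector` list.
#' @export
action_vector <- function(first, second, edge, stop = 0L) {
  structure(list(first = as.integer(first), second = as.integer(second),
                 edge = as.integer(edge), stop = as.integer(stop)),
            class = "action_vector")
}

#' Reward configuration
#'
#' Weights and caps composing the environment reward. The final reward is
#' `sum_k property_weights[k] * predicted_pKi_k + qed_weight * QED +
#' sa_weight * SA_norm + strain_bonus * [no steric strain] + filter_bonus *
#' [passes the filter catalog] + adversarial_weight * adversarial term`,
#' while every chemically valid growth step earns `step_valid_bonus`.
#' Components with zero weight are skipped entirely (their checks are not
#' run), which keeps toy reward settings fast.
#'
#' @param property_weights named numeric vector (e.g.
#'   `c(dopamine = 2, norepinephrine = -1)`); names must match
#'   `property_models`.
#' @param property_models named list of scorers: fitted `property_model`
#'   objects or plain functions of a SMILES string.
#' @param step_valid_bonus per-step validity bonus (small constant).
#' @param qed_weight,sa_weight,strain_bonus,filter_bonus,adversarial_weight
#'   weights of the final-reward components.
#' @param max_heavy_atoms heavy-atom cap (25 or 15 in the generation
#'   experiments).
#' @param atom_types addable element menu (the `c` candidate types).
#' @param filter_catalog pattern catalog for the filter term, or `NULL` to
#'   load the shipped one on first use.
#' @param strain_threshold mean angle-energy cutoff for the strain term.
#' @param invalid_penalty reward added on chemically invalid actions
#'   (default 0; set negative to punish).
#' @param max_steps episode step cap; default `10 * max_heavy_atoms`.
#' @return a `reward_config` list.
#' @export
reward_config <- function(property_weights = numeric(0),
                          property_models = list(),
                          step_valid_bonus = 0.05,
                          qed_weight = 1, sa_weight = 2,
                          strain_bonus = 1, filter_bonus = 1,
                          adversarial_weight = 0,
                          max_heavy_atoms = 25L,
                          atom_types = c("C", "N", "O", "S", "F", "Cl",
                                         "Br", "I", "P"),
                          filter_catalog = NULL,
                          strain_threshold = 0.82,
                          invalid_penalty = 0,
                          max_steps = NULL) {
  stopifnot(max_heavy_atoms >= 1, all(is.finite(property_weights)))
  if (length(property_weights) &&
      !all(names(property_weights) %in% names(property_models))) {
    stop("missing property model for weight(s): ",
         paste(setdiff(names(property_weights), names(property_models)),
               collapse = ", "))
  }
  structure(list(
    property_weights = property_weights, property_models = property_models,
    step_valid_bonus = step_valid_bonus, qed_weight = qed_weight,
    sa_weight = sa_weight, strain_bonus = strain_bonus,
    filter_bonus = filter_bonus, adversarial_weight = adversarial_weight,
    max_heavy_atoms = as.integer(max_heavy_atoms), atom_types = atom_types,
    filter_catalog = filter_catalog, strain_threshold = strain_threshold,
    invalid_penalty = invalid_penalty,
    max_steps = if (is.null(max_steps)) 10L * as.integer(max_heavy_atoms)
      else as.integer(max_steps)
  ), class = "reward_config")
}

# bond-order sum per atom (vectorized over the three slices)
.order_sums <- function(state) {
  if (state$n == 1) {
    return(sum(vapply(1:3, function(o) o * sum(state$E[o, , ]), numeric(1))))
  }
  o1 <- matrix(state$E[1, , ], state$n); o2 <- matrix(state$E[2, , ], state$n)
  o3 <- matrix(state$E[3, , ], state$n)
  rowSums(o1) + 2 * rowSums(o2) + 3 * rowSums(o3)
}

#' Valence check on a dense state
#'
#' TRUE when every atom's total bond order stays within its element's maximum
#' valence, implicit hydrogens filling the remainder.
#'
#' @param state a `dense_state`.
#' @return logical flag.
#' @export
valence_ok <- function(state) {
  stopifnot(inherits(state, "dense_state"))
  all(.order_sums(state) <= .element_row(state$elements)$max_valence)
}

#' Start a construction episode
#'
#' @param init `"C"` for the single-carbon start, or any seed SMILES (its
#'   kekulized graph becomes the initial state).
#' @param config a [reward_config()].
#' @return an `env_state` list: `state` (dense), `steps`, `done`,
#'   `seed_smiles`.
#' @export
env_reset <- function(init = "C", config = reward_config()) {
  state <- as_dense_state(init)   # errors on invalid seeds
  if (state$n > config$max_heavy_atoms) {
    stop("seed molecule exceeds max_heavy_atoms (", state$n, " > ",
         config$max_heavy_atoms, ")")
  }
  structure(list(state = state, steps = 0L, done = FALSE,
                 seed_smiles = if (is.character(init)) init else NA_character_),
            class = "env_state")
}

# apply a bond/atom addition to a dense state; returns NULL when the result
# would violate chemistry
.apply_action <- function(state, action, config) {
  n <- state$n
  ct <- length(config$atom_types)
  if (action$first < 1 || action$first > n) return(NULL)
  if (action$second < 1 || action$second > n + ct) return(NULL)
  if (!action$edge %in% 1:3) return(NULL)
  if (action$second <= n) {
    if (action$second == action$first) return(NULL)
    if (state$A[action$first, action$second] == 1L) return(NULL)  # bond exists
    elements <- state$elements
    j <- action$first; k <- action$second
    nn <- n
  } else {
    if (n + 1L > config$max_heavy_atoms) return(NULL)
    el_new <- config$atom_types[action$second - n]
    elements <- c(state$elements, el_new)
    j <- action$first; k <- n + 1L
    nn <- n + 1L
  }
  A <- matrix(0L, nn, nn); A[seq_len(n), seq_len(n)] <- state$A
  E <- array(0L, dim = c(3L, nn, nn))
  E[, seq_len(n), seq_len(n)] <- state$E
  A[j, k] <- A[k, j] <- 1L
  E[action$edge, j, k] <- E[action$edge, k, j] <- 1L
  cand <- structure(list(A = A, E = E, F = NULL, elements = elements, n = nn),
                    class = "dense_state")
  if (!valence_ok(cand)) return(NULL)
  # refresh node features from the updated graph
  mol <- .state_to_mol(cand)
  cand$F <- .atom_feature_matrix(mol)
  cand
}

#' Advance the environment by one action
#'
#' A stop action (or hitting the atom/step caps) ends the episode; a growth
#' or ring-closure action is applied only if the resulting molecule passes
#' the valence rules, otherwise the state is unchanged and no bonus is paid.
#' The transition depends only on the current state and action.
#'
#' @param env an `env_state`.
#' @param action an [action_vector()].
#' @param config a [reward_config()].
#' @param discriminator optional discriminator (see [discriminate()]) for the
#'   adversarial final-reward term.
#' @return list with `env` (next state), `reward` (step bonus, or the final
#'   total on termination), `done`, `valid` (was the action chemically
#'   applied), and on termination `breakdown` (a [reward_breakdown]).
#' @export
env_step <- function(env, action, config = reward_config(),
                     discriminator = NULL) {
  stopifnot(inherits(env, "env_state"), inherits(action, "action_vector"))
  if (env$done) stop("cannot step a finished episode")
  env$steps <- env$steps + 1L
  terminate <- action$stop == 1L
  valid <- FALSE
  reward <- 0
  if (!terminate) {
    nxt <- .apply_action(env$state, action, config)
    if (!is.null(nxt)) {
      env$state <- nxt
      valid <- TRUE
      reward <- config$step_valid_bonus
    } else {
      reward <- config$invalid_penalty
    }
    if (env$state$n >= config$max_heavy_atoms ||
        env$steps >= config$max_steps) {
      terminate <- TRUE  # cap reached: episode ends, final reward still paid
    }
  }
  breakdown <- NULL
  if (terminate) {
    env$done <- TRUE
    breakdown <- final_reward(env$state, config, discriminator)
    reward <- reward + breakdown$total
  }
  list(env = env, reward = reward, done = env$done, valid = valid,
       breakdown = breakdown)
}

#' Itemized final reward
#'
#' Composes the terminal reward of a finished molecule: weighted predicted
#' properties, drug-likeness, normalized synthetic accessibility, the strain
#' and filter bonuses, and the adversarial term `-log(1 - D(x))` when a
#' discriminator is supplied. Parts always sum to `total` exactly.
#'
#' @param x a `dense_state`, `mol`, or SMILES string.
#' @param config a [reward_config()].
#' @param discriminator optional `discriminator` object.
#' @return a `reward_breakdown`: list of named `parts` and their sum `total`.
#' @export
final_reward <- function(x, config = reward_config(), discriminator = NULL) {
  state <- NULL
  if (inherits(x, "dense_state")) {
    state <- x
    smiles <- state_to_molecule(x)$smiles
  } else if (inherits(x, "mol")) {
    smiles <- mol_to_smiles(x)
  } else {
    smiles <- x
  }
  parts <- c(property = 0)
  if (length(config$property_weights)) {
    preds <- vapply(names(config$property_weights), function(nm) {
      scorer <- config$property_models[[nm]]
      if (is.null(scorer)) stop("missing property model: ", nm)
      if (is.function(scorer)) scorer(smiles) else
        predict_property(smiles, scorer)
    }, numeric(1))
    parts["property"] <- sum(config$property_weights * preds)
    attr(parts, "predictions") <- preds
  }
  pred_attr <- attr(parts, "predictions")
  raw <- c()
  if (config$qed_weight != 0) {
    raw["qed"] <- qed(smiles, alerts = config$filter_catalog)
    parts["qed"] <- config$qed_weight * raw[["qed"]]
  } else parts["qed"] <- 0
  if (config$sa_weight != 0) {
    raw["sa_norm"] <- sa_norm(smiles)
    parts["sa"] <- config$sa_weight * raw[["sa_norm"]]
  } else parts["sa"] <- 0
  if (config$strain_bonus != 0) {
    raw["strain_ok"] <- as.numeric(strain_ok(smiles, config$strain_threshold))
    parts["strain"] <- config$strain_bonus * raw[["strain_ok"]]
  } else parts["strain"] <- 0
  if (config$filter_bonus != 0) {
    catalog <- config$filter_catalog
    if (is.null(catalog)) catalog <- load_pattern_catalog()
    raw["filter_ok"] <- as.numeric(zinc_filter_ok(smiles, catalog))
    parts["filter"] <- config$filter_bonus * raw[["filter_ok"]]
  } else parts["filter"] <- 0
  parts["adversarial"] <- if (config$adversarial_weight != 0 &&
                              !is.null(discriminator)) {
    if (is.null(state)) state <- as_dense_state(smiles)
    config$adversarial_weight * adversarial_term(discriminator, state)
  } else 0
  attributes(parts) <- list(names = names(parts))
  structure(list(smiles = smiles, parts = parts, total = sum(parts),
                 predictions = pred_attr, raw = raw),
            class = "reward_breakdown")
}

#' @export
print.reward_breakdown <- function(x, ...) {
  cat("<reward_breakdown> ", x$smiles, "\n", sep = "")
  for (nm in names(x$parts)) cat(sprintf("  %-12s %8.4f\n", nm, x$parts[nm]))
  cat(sprintf("  %-12s %8.4f\n", "total", x$total))
  invisible(x)
}
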