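# PPO machinery: advantage estimation, the clipped surrogate, adversarial
# terms, expert imitation, and the training loop's contracts

test_that("GAE collapses to the TD error at lambda = 0", {
  set.seed(1)
  r <- rnorm(8); v <- rnorm(9)
  deltas <- r + 0.9 * v[-1] - v[-9]
  expect_equal(gae(r, v, gamma = 0.9, lambda = 0), deltas)
})

test_that("GAE at gamma = lambda = 1 telescopes to return minus baseline", {
  set.seed(2)
  r <- rnorm(6); v <- c(rnorm(6), 0)
  adv <- gae(r, v, gamma = 1, lambda = 1)
  oracle <- vapply(1:6, function(t) sum(r[t:6]) - v[t], numeric(1))
  expect_equal(adv, oracle, tolerance = 1e-12)
})

test_that("GAE equals the brute-force double sum", {
  brute <- function(r, v, g, l) {
    T_ <- length(r)
    d <- r + g * v[-1] - v[-(T_ + 1)]
    vapply(1:T_, function(t) sum((g * l)^(0:(T_ - t)) * d[t:T_]), numeric(1))
  }
  expect_equal(gae(c(1, 1), c(0, 0, 0), 0.5, 0.5),
               brute(c(1, 1), c(0, 0, 0), 0.5, 0.5))
  set.seed(3)
  for (i in 1:10) {
    r <- rnorm(10); v <- rnorm(11)
    expect_equal(gae(r, v, 0.99, 0.95), brute(r, v, 0.99, 0.95),
                 tolerance = 1e-10)
  }
  expect_error(gae(1:3, 1:3), "length")
})

test_that("the PPO surrogate evaluates its clip branches correctly", {
  expect_equal(ppo_objective(0, 0, 2.5), 2.5)                     # r = 1
  eps <- 0.2
  expect_equal(ppo_objective(log(1 + 2 * eps), 0, 1, eps), 1 + eps)
  expect_equal(ppo_objective(log(1 - 2 * eps) - log(1), 0, -1, eps),
               -(1 - eps))
  # the surrogate is flat in logp_new inside the clipped region
  h <- 1e-6
  base <- log(1 + 2 * eps)
  grad <- (ppo_objective(base + h, 0, 1, eps) -
           ppo_objective(base - h, 0, 1, eps)) / (2 * h)
  expect_equal(grad, 0)
})

test_that("the adversarial reward is -log(1 - D) and monotone in D", {
  disc <- discriminator_init(8, 2, seed = 1)
  for (w in names(disc$params$head)) disc$params$head[[w]][] <- 0   # D = 0.5
  st <- as_dense_state("CCO")
  expect_equal(adversarial_term(disc, st), -log(0.5), tolerance = 1e-10)
  # monotonicity via the closed form with clamping
  ds <- seq(0.05, 0.95, by = 0.05)
  vals <- -log(1 - ds)
  expect_true(all(diff(vals) > 0))
  # discriminator batch loss at D = 0.5 is log 4 per real+fake pair
  expect_equal(-log(0.5) - log(1 - 0.5), log(4), tolerance = 1e-12)
})

test_that("expert pairs always apply to reproduce part of the parent", {
  set.seed(5)
  cfg <- toy_reward_cfg(max_heavy = 25)
  # ethane: the only growth pair is carbon + add-carbon-with-single-bond
  # (the other possible pair is the complete molecule with a stop action)
  repeat {
    pr <- sample_expert_pair("CC")
    if (pr$action$stop == 0) break
  }
  expect_equal(pr$state$n, 1)
  expect_equal(pr$action$second, 1 + 1)   # first candidate type, carbon
  expect_equal(pr$action$edge, 1)
  # butane: every sampled pair must rebuild a fragment of butane
  subgraphs <- c("C", "CC", "CCC", "CCCC")
  subgraphs <- vapply(subgraphs, canonical_smiles, character(1))
  for (i in 1:40) {
    pr <- sample_expert_pair("CCCC")
    if (pr$action$stop == 1) next
    nxt <- molforge:::.apply_action(pr$state, pr$action, cfg)
    expect_false(is.null(nxt))
    expect_true(state_to_molecule(nxt)$smiles %in% subgraphs)
  }
})

test_that("expert pair sampling covers every frontier of a path graph", {
  set.seed(6)
  seen_sizes <- integer(0)
  for (i in 1:200) {
    pr <- sample_expert_pair("CCCC")
    seen_sizes <- c(seen_sizes, pr$state$n)
  }
  # growing states of every size appear (4 = complete molecule, stop pair)
  expect_true(all(1:3 %in% seen_sizes))
})

test_that("single-atom experts produce a stop pair; ring bonds can be the action", {
  pr <- sample_expert_pair("C")
  expect_equal(pr$action$stop, 1)
  set.seed(7)
  found_ring <- FALSE
  for (i in 1:100) {
    pr <- sample_expert_pair("C1CC1", p_ring_closure = 0.9)
    if (pr$action$stop == 0 && pr$action$second <= pr$state$n) {
      found_ring <- TRUE
      cfg <- toy_reward_cfg()
      nxt <- molforge:::.apply_action(pr$state, pr$action, cfg)
      expect_false(is.null(nxt))
    }
  }
  expect_true(found_ring)
})

test_that("expert loss is nonnegative and exact for a uniform policy", {
  pol <- tiny_policy(seed = 11)
  for (nm in c("mf", "ms", "me", "mt")) {
    for (w in names(pol$params[[nm]])) pol$params[[nm]][[w]][] <- 0
  }
  set.seed(12)
  pr <- sample_expert_pair("CC")
  el <- expert_loss(pol, list(pr))
  ct <- length(pol$atom_types)
  n <- pr$state$n
  # under a uniform policy the composite log-probability factorizes over the
  # four heads regardless of which action was sampled
  expect_equal(el, -(log(1 / n) + log(1 / (n + ct)) + log(1 / 3) +
                     log(1 / 2)),
               tolerance = 1e-10)
  set.seed(13)
  pairs <- lapply(1:5, function(i) sample_expert_pair("CC(=O)NC"))
  expect_gte(expert_loss(tiny_policy(seed = 14), pairs), 0)
})

test_that("expert pretraining drives the imitation loss well below start", {
  # the loss floor is the entropy of the expert action distribution (many
  # valid growth actions per state), so the check is a large relative drop
  set.seed(15)
  expert <- fixture_pool()[1:20]
  pol <- tiny_policy(seed = 15)
  res <- pretrain_expert(pol, expert, updates = 300, pairs_per_update = 8,
                         seed = 15)
  early <- mean(res$log$expert_loss[1:10])
  late <- mean(utils::tail(res$log$expert_loss, 10))
  expect_lt(late, 0.6 * early)
})

test_that("plain PPO runs with adversarial and expert terms disabled", {
  cfg <- toy_reward_cfg(max_heavy = 8)
  run <- train_gcpn(tiny_policy(seed = 16), cfg,
                    ppo_config(episodes_per_iter = 4, ppo_epochs = 1,
                               seed = 16),
                    iterations = 2)
  expect_s3_class(run$log, "tbl_df")
  expect_equal(nrow(run$log), 2)
  expect_true(all(is.na(run$log$expert_loss)))
  expect_true(all(is.na(run$log$disc_loss)))
  expect_true(all(run$log$validity == 1))
  expect_s3_class(glance(run), "tbl_df")
  expect_s3_class(autoplot(run), "ggplot")
})

test_that("the adversarial + expert pathway trains end to end", {
  cfg <- toy_reward_cfg(max_heavy = 8, adversarial_weight = 0.5)
  expert <- fixture_pool()[1:10]
  run <- train_gcpn(tiny_policy(seed = 17), cfg,
                    ppo_config(episodes_per_iter = 4, ppo_epochs = 1,
                               expert_weight = 1, expert_horizon = 10,
                               expert_pairs_per_iter = 3, seed = 17),
                    iterations = 2, expert_set = expert)
  expect_true(all(is.finite(run$log$disc_loss)))
  expect_true(all(is.finite(run$log$expert_loss)))
  expect_false(is.null(run$discriminator))
  expect_error(train_gcpn(tiny_policy(), cfg,
                          ppo_config(episodes_per_iter = 2, seed = 1),
                          iterations = 1),
               "expert_set")
})

test_that("the divergence guard aborts on exploding advantages", {
  cfg <- toy_reward_cfg(max_heavy = 6)
  cfg$step_valid_bonus <- 1e6
  expect_error(
    train_gcpn(tiny_policy(seed = 18), cfg,
               ppo_config(episodes_per_iter = 2, adv_guard = 1, seed = 18),
               iterations = 1),
    "diverged")
})

test_that("every molecule in the episode logs is sanitizable", {
  cfg <- toy_reward_cfg(max_heavy = 10)
  recs <- generate_molecules(tiny_policy(seed = 19), cfg, n_episodes = 25,
                             seed = 19)
  expect_equal(nrow(recs), 25)
  expect_true(all(recs$valid))
  expect_true(all(recs$n_atoms <= 10))
  for (s in recs$smiles) {
    expect_true(is_sanitizable(parse_smiles(s)))
  }
})
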