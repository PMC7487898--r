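# The molecule-construction MDP: reset, valence-checked steps, termination,
# and the itemized reward

test_that("reset supports single-carbon and seed-molecule initialization", {
  cfg <- toy_reward_cfg()
  env <- env_reset("C", cfg)
  expect_equal(env$state$n, 1)
  expect_equal(env$steps, 0)
  expect_false(env$done)
  env6 <- env_reset("c1ccccc1", cfg)
  expect_equal(env6$state$n, 6)
  # kekulized: three single + three double slices
  expect_equal(sum(env6$state$E[1, , ]) / 2, 3)
  expect_equal(sum(env6$state$E[2, , ]) / 2, 3)
  expect_error(env_reset("not_smiles", cfg), "cannot parse")
  small <- reward_config(max_heavy_atoms = 3, qed_weight = 0, sa_weight = 0,
                         strain_bonus = 0, filter_bonus = 0)
  expect_error(env_reset("c1ccccc1", small), "max_heavy_atoms")
})

test_that("valid growth steps extend the molecule and pay the step bonus", {
  cfg <- toy_reward_cfg()
  env <- env_reset("C", cfg)
  st <- env_step(env, action_vector(1, env$state$n + 1, 1, 0), cfg)
  expect_true(st$valid)
  expect_equal(st$env$state$n, 2)
  expect_equal(st$reward, cfg$step_valid_bonus)
  expect_equal(state_to_molecule(st$env$state)$smiles, "CC")
})

test_that("chemically invalid actions leave the state unchanged with no bonus", {
  cfg <- toy_reward_cfg()
  env <- env_reset("C", cfg)
  for (i in 1:4) {
    env <- env_step(env, action_vector(1, env$state$n + 1, 1, 0), cfg)$env
  }
  expect_equal(env$state$n, 5)   # neopentane skeleton: carbon 1 is saturated
  before <- env$state
  st <- env_step(env, action_vector(1, env$state$n + 1, 1, 0), cfg)
  expect_false(st$valid)
  expect_equal(st$reward, 0)
  expect_equal(st$env$state$A, before$A)
  expect_equal(st$env$state$E, before$E)
  # a duplicate bond and a self-bond are also rejected
  st2 <- env_step(st$env, action_vector(1, 2, 1, 0), cfg)
  expect_false(st2$valid)
  st3 <- env_step(st2$env, action_vector(2, 2, 1, 0), cfg)
  expect_false(st3$valid)
})

test_that("the stop action terminates and triggers the final reward", {
  cfg <- toy_reward_cfg()
  env <- env_reset("C", cfg)
  st <- env_step(env, action_vector(1, 1, 1, 1), cfg)
  expect_true(st$done)
  expect_s3_class(st$breakdown, "reward_breakdown")
  expect_equal(sum(st$breakdown$parts), st$breakdown$total)
  expect_error(env_step(st$env, action_vector(1, 2, 1, 0), cfg),
               "finished")
})

test_that("hitting the atom cap terminates with the final reward still paid", {
  cfg <- toy_reward_cfg(max_heavy = 3)
  env <- env_reset("C", cfg)
  st <- env_step(env, action_vector(1, 2, 1, 0), cfg)
  expect_false(st$done)
  st <- env_step(st$env, action_vector(2, 3, 1, 0), cfg)
  expect_true(st$done)
  expect_s3_class(st$breakdown, "reward_breakdown")
  expect_equal(st$env$state$n, 3)
})

test_that("valence_ok applies the element valence table", {
  expect_true(valence_ok(as_dense_state("CC")))
  expect_true(valence_ok(as_dense_state("N(C)(C)C")))   # trivalent N
  expect_true(valence_ok(as_dense_state("C(=O)O")))
  # hand-built pentavalent carbon
  E <- array(0L, dim = c(3, 6, 6))
  for (k in 2:6) { E[1, 1, k] <- E[1, k, 1] <- 1L }
  A <- matrix(0L, 6, 6); A[1, 2:6] <- A[2:6, 1] <- 1L
  bad <- structure(list(A = A, E = E, F = NULL, elements = rep("C", 6),
                        n = 6L), class = "dense_state")
  expect_false(valence_ok(bad))
})

test_that("the Markov transition is a pure function of state and action", {
  cfg <- toy_reward_cfg()
  env <- env_reset("C", cfg)
  env <- env_step(env, action_vector(1, 2, 1, 0), cfg)$env
  a <- action_vector(2, 3, 1, 0)
  s1 <- env_step(env, a, cfg)
  s2 <- env_step(env, a, cfg)
  expect_equal(s1$env$state, s2$env$state)
  expect_equal(s1$reward, s2$reward)
})

test_that("steric strain passes relaxed molecules and fails strained cages", {
  expect_true(strain_ok("CCO"))
  expect_false(strain_ok("C1CC12CC2"))   # spiro-fused cyclopropanes
  expect_true(strain_ok("C1CC12CC2", threshold = Inf))
})

test_that("the substructure filter catalog behaves and validates", {
  catalog <- load_pattern_catalog(filter_catalog_path())
  expect_true(zinc_filter_ok("CC", catalog))
  expect_false(zinc_filter_ok("CC(=O)Cl", catalog))       # acyl halide
  expect_true(zinc_filter_ok("CC(=O)Cl", catalog[0, ]))   # empty catalog
  bad <- tempfile(fileext = ".smarts")
  writeLines("broken\t[[invalid", bad)
  expect_error(load_pattern_catalog(bad), "broken")
})

test_that("the final reward composes its parts exactly", {
  # all property weights zero, strain and filter on: QED + 2*SA_norm + 2
  cfg <- reward_config(max_heavy_atoms = 25)
  bd <- final_reward("CCO", cfg)
  expect_equal(bd$total,
               qed("CCO") + 2 * sa_norm("CCO") + 1 + 1,
               tolerance = 1e-10)
  expect_equal(sum(bd$parts), bd$total)
  # dual-target weighting with toy oracles
  oracle1 <- function(s) toy_oracle(s)
  oracle2 <- function(s) toy_oracle(s, toy_oracle_params(bias = 3))
  cfg2 <- reward_config(
    property_weights = c(a = 2, b = -1),
    property_models = list(a = oracle1, b = oracle2),
    qed_weight = 0, sa_weight = 0, strain_bonus = 0, filter_bonus = 0)
  bd2 <- final_reward("c1ccccc1", cfg2)
  expect_equal(bd2$parts[["property"]],
               2 * oracle1("c1ccccc1") - oracle2("c1ccccc1"))
  expect_equal(sum(bd2$parts), bd2$total)
  # a named weight without a model is a configuration error
  expect_error(reward_config(property_weights = c(x = 1)), "missing")
})

test_that("random rollouts never exceed the atom cap and stay sanitizable", {
  cfg <- toy_reward_cfg(max_heavy = 15)
  pol <- tiny_policy(seed = 8)
  set.seed(99)
  for (i in 1:15) {
    env <- roll_episode(pol, cfg)
    expect_lte(env$state$n, 15)
    out <- state_to_molecule(env$state)
    expect_true(is_sanitizable(out$mol))
  }
})
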