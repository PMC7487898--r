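# shared fixtures for the suite: tiny configurations and a quiet toy reward
# (no strain/filter/descriptor calls) for fast environment rollouts

toy_reward_cfg <- function(max_heavy = 12L, ...) {
  reward_config(qed_weight = 0, sa_weight = 0, strain_bonus = 0,
                filter_bonus = 0, max_heavy_atoms = max_heavy, ...)
}

tiny_policy <- function(seed = 1L, d = 16L, L = 2L) {
  gcpn_policy(embed_dim = d, n_layers = L, seed = seed)
}

# roll one episode under a policy, returning the final env state
roll_episode <- function(policy, cfg) {
  env <- env_reset("C", cfg)
  repeat {
    act <- policy_act(policy, env$state)
    stp <- env_step(env, act$action, cfg)
    env <- stp$env
    if (stp$done) return(env)
  }
}

filter_catalog_path <- function() {
  system.file("extdata", "zinc_filters.smarts", package = "molforge")
}
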