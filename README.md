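# molforge

Computational design of small molecules with desired binding profiles, for
cheminformatics and drug-discovery researchers. The package couples two
models around a molecule-construction environment:

1. **Property prediction.** A directed message-passing neural network
   (D-MPNN) encodes a molecule's graph — 133-dimensional atom features and
   14-dimensional bond features, messages living on directed bonds — and a
   feed-forward head regresses a binding affinity on the pKi scale
   (`pKi = 9 − log10(Ki in nM)`). Because experimental affinity labels
   contain gross errors (entries recorded as rough cut-offs), training
   minimizes the negative log-likelihood of the **general adaptive robust
   loss**

   f(x, α, c) = (|α−2|/α) · [((x/c)² / |α−2| + 1)^(α/2) − 1],

   whose shape `α ∈ (0,2]` (L2 at 2, Charbonnier at 1, Cauchy at 0) and
   scale `c` are *trained jointly with the network* through the partition
   function `Z(α)`, instead of being hand-tuned.

2. **Molecule generation.** A graph convolutional policy network (GCPN)
   builds molecules one bond at a time in a valence-checked environment —
   every emitted molecule is chemically valid by construction. The policy's
   four heads pick (first atom, second atom, bond type, stop) from node
   embeddings computed by per-bond-type graph convolutions; training is
   proximal policy optimization (PPO) with generalized advantage estimation
   against a reward combining predicted affinities (with arbitrary weights,
   e.g. `+2·pKi(target A) − 1·pKi(target B)` for dual-target design),
   drug-likeness (QED), synthetic accessibility, steric-strain and
   functional-group-filter bonuses, and an optional adversarial term from a
   discriminator trained against an expert molecule set, plus expert
   imitation pretraining.

Evaluation utilities cover Tanimoto similarity to a reference set
(path-based fingerprints), similarity distributions, ranked top-k reports
and Pareto-front extraction for multi-objective runs. Synthetic-data
generators (a deterministic pseudo-pKi oracle, contaminated labelled
datasets, an expert set) make the whole pipeline runnable offline; chemistry
primitives come from ChemmineR/ChemmineOB (Open Babel).

## Worked example

Train a robust property model on a contaminated synthetic dataset and
compare it with a squared-loss twin:

```r
library(molforge)

data <- make_property_dataset(400, noise_sd = 0.1, outlier_fraction = 0.1,
                              outlier_shift = -3, seed = 1)
fit  <- train_property_model(data, mpnn_config(depth = 3, hidden_dim = 64,
                                               ffn_layers = 2, dropout = 0),
                             train_config(epochs = 100, seed = 1))
glance(fit)
```

```
#>   depth hidden_dim ffn_layers dropout   loss best_epoch val_rmse test_rmse alpha     c
#> 1     3         64          2       0 robust         46    0.922     0.756     1 0.348
```

`val_rmse`/`test_rmse` are computed over the *contaminated* held-out labels
(the planted outliers dominate them by construction); the fitted scale
`c ≈ 0.35` tightened from its initialization near 1 as the model's genuine
residuals shrank. On the clean test points only:

```r
te    <- fit$split$test
clean <- te[!data$is_outlier[te]]
sqrt(mean((predict_property(data$smiles[clean], fit) - data$target[clean])^2))
#> [1] 0.3724917
```

while the identically configured squared-loss twin (`loss = "l2"`) reaches
0.4635 on the same split — the practical argument for the adaptive loss in
one pair of numbers. (Across seeds 1-5 the medians are 0.336 for the robust
loss against 0.392 for L2; the acceptance suite recomputes exactly this
experiment.)

Generate molecules with a policy and score them:

```r
cfg  <- reward_config(max_heavy_atoms = 25)
pol  <- gcpn_policy(embed_dim = 32, n_layers = 3, seed = 1)
recs <- generate_molecules(pol, cfg, n_episodes = 50, seed = 1)
mean(recs$valid)
#> [1] 1
```

Policy improvement on a drug-likeness reward, and reporting:

```r
run <- train_gcpn(pol, reward_config(qed_weight = 1, sa_weight = 0,
                                     strain_bonus = 0, filter_bonus = 0,
                                     max_heavy_atoms = 15),
                  ppo_config(episodes_per_iter = 16, seed = 1),
                  iterations = 30)
glance(run)          # mean episode reward, first vs last iteration
autoplot(run)        # reward curve

report <- topk_report(generate_molecules(run$policy, cfg, 100,
                                         compute_reward = TRUE, seed = 2),
                      k = 10, qed_min = 0.8, sa_min = 0.8,
                      reference = make_expert_set(100, seed = 3))
```

A thin command-line front end over the same functions lives at
`inst/cli/molforge.R` (`make-fixtures`, `train-prop`, `hyperopt`,
`generate`, `evaluate`).

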