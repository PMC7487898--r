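# Featurization layout, directed-graph structure, and dense-state round trips

test_that("atom featurization follows the documented block layout", {
  # neutral aromatic carbon, degree 2, one H, sp2
  v <- featurize_atom(6, 2, 0, 0, 1, 2, TRUE, 12.011)
  expect_length(v, 133)
  expect_equal(which(v[1:101] != 0), 6)          # atomic number 6
  expect_equal(v[132], 1)                        # aromatic flag
  expect_equal(v[133], 0.12011)                  # mass * 0.01
  # hypothetical element 105 lands in the uncommon slot of its block only
  v2 <- featurize_atom(105, 0, 0, 0, 0, 3, FALSE, 262)
  expect_equal(which(v2[1:101] != 0), 101)
})

test_that("every categorical block sets exactly one slot", {
  blocks <- list(1:101, 102:108, 109:114, 115:119, 120:125, 126:131)
  set.seed(7)
  for (i in 1:25) {
    v <- featurize_atom(sample(-5:120, 1), sample(-1:8, 1), sample(-4:4, 1),
                        sample(-1:6, 1), sample(-1:7, 1), sample(0:7, 1),
                        sample(c(TRUE, FALSE), 1), runif(1, 1, 300))
    for (b in blocks) expect_equal(sum(v[b] != 0), 1)
  }
})

test_that("bond featurization covers the 14 slots", {
  v <- featurize_bond(1, aromatic = FALSE, in_ring = TRUE)
  expect_length(v, 14)
  expect_equal(v[1], 1)                # bond present
  expect_equal(v[2], 1)                # single
  expect_equal(v[7], 1)                # in ring
  expect_equal(v[5], 0)
  v2 <- featurize_bond(1, aromatic = TRUE, conjugated = TRUE)
  expect_equal(v2[5], 1); expect_equal(v2[6], 1)
  # the all-zero vector is the "no bond" placeholder; real bonds always set
  # slot 1, and an unknown non-aromatic order leaves the type block empty
  expect_warning(v3 <- featurize_bond(5), "unknown bond order")
  expect_equal(sum(v3[2:4]), 0)
  expect_equal(v3[1], 1)
})

test_that("smiles_to_graph builds the directed-bond structure", {
  g <- smiles_to_graph("CC")
  expect_equal(g$n_atoms, 2)
  expect_equal(g$n_bonds, 2)                         # 2 directed bonds
  expect_equal(dim(g$bond_inputs), c(2L, 147L))
  g1 <- smiles_to_graph("C")
  expect_equal(g1$n_atoms, 1)
  expect_equal(g1$n_bonds, 0)
  expect_error(smiles_to_graph("not_smiles"), "cannot parse SMILES")
})

test_that("directed bonds come in reverse pairs and 147-long inputs", {
  for (s in c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1")) {
    g <- smiles_to_graph(s)
    expect_equal(g$n_bonds, 2 * nrow(g$mol$bonds))
    expect_equal(g$reverse[g$reverse], seq_len(g$n_bonds))  # involution
    expect_equal(ncol(g$bond_inputs), 147)
    # bond input = [source atom features || bond features]
    for (b in seq_len(g$n_bonds)) {
      expect_equal(g$bond_inputs[b, 1:133],
                   g$atom_features[g$bond_src[b], ])
      expect_equal(g$bond_inputs[b, 134:147], g$bond_features[b, ])
    }
    # incoming map is consistent with bond_dst
    for (a in seq_len(g$n_atoms)) {
      expect_setequal(g$incoming[[a]], which(g$bond_dst == a))
    }
  }
})

test_that("atom relabelling permutes feature rows but not their multiset", {
  g1 <- smiles_to_graph("CCO")
  g2 <- smiles_to_graph("OCC")
  key <- function(g) sort(apply(g$atom_features, 1, paste, collapse = ","))
  expect_equal(key(g1), key(g2))
})

test_that("dense states satisfy their structural invariants", {
  st <- as_dense_state("c1ccccc1O")
  expect_equal(st$n, 7)
  expect_true(all(st$A == t(st$A)))
  expect_true(all(diag(st$A) == 0))
  for (j in 1:st$n) for (k in 1:st$n) {
    expect_equal(st$A[j, k], as.integer(sum(st$E[, j, k]) > 0))
    expect_lte(sum(st$E[, j, k]), 1)   # at most one order per pair
  }
  for (o in 1:3) {
    expect_true(all(st$E[o, , ] == t(st$E[o, , ])))
  }
})

test_that("smiles -> dense state -> smiles preserves the molecule", {
  set.seed(31)
  pool <- fixture_pool()
  smis <- c(pool, make_expert_set(100 - length(pool), seed = 31))
  for (s in smis) {
    st <- as_dense_state(s)
    back <- state_to_molecule(st)$smiles
    expect_equal(back, canonical_smiles(s))
  }
})

test_that("tiny state conversions work, and bad states error", {
  st <- as_dense_state("C")
  expect_equal(state_to_molecule(st)$smiles, "C")
  # hand-built two-carbon single bond
  E <- array(0L, dim = c(3, 2, 2)); E[1, 1, 2] <- E[1, 2, 1] <- 1L
  st2 <- structure(list(A = matrix(c(0L, 1L, 1L, 0L), 2), E = E,
                        F = NULL, elements = c("C", "C"), n = 2L),
                   class = "dense_state")
  expect_equal(state_to_molecule(st2)$smiles, "CC")
  # five bonds on a carbon violates its valence cap
  E5 <- array(0L, dim = c(3, 6, 6))
  for (k in 2:6) { E5[1, 1, k] <- E5[1, k, 1] <- 1L }
  A5 <- matrix(0L, 6, 6); A5[1, 2:6] <- A5[2:6, 1] <- 1L
  st5 <- structure(list(A = A5, E = E5, F = NULL,
                        elements = rep("C", 6), n = 6L),
                   class = "dense_state")
  expect_error(state_to_molecule(st5))
})
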