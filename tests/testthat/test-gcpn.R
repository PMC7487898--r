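# Policy network: the sliced graph convolution, the four heads, value head
# and discriminator

test_that("gcn_layer handles the single-node identity case", {
  H <- matrix(c(-1, 2), 1)
  E <- array(0L, dim = c(3, 1, 1))
  W <- lapply(1:3, function(i) diag(2))
  out <- gcn_layer(H, E, W)$H
  # self-loop normalization is 1; each slice contributes relu(H)
  expect_equal(out, pmax(H, 0))
})

test_that("gcn_layer matches the dense renormalized-adjacency formula", {
  # two nodes, one single bond, identity weights and features
  H <- diag(2)
  E <- array(0L, dim = c(3, 2, 2)); E[1, 1, 2] <- E[1, 2, 1] <- 1L
  W <- lapply(1:3, function(i) diag(2))
  out <- gcn_layer(H, E, W)$H
  # bonded slice: Ehat = ones(2,2), Dhat = 2 -> all entries 0.5;
  # the two empty slices pass relu(H) through
  expect_equal(out, (matrix(0.5, 2, 2) + diag(2) + diag(2)) / 3)
})

test_that("gcn_layer agrees with an explicit per-slice oracle on small graphs", {
  oracle_layer <- function(H, E, W) {
    p <- nrow(H); acc <- matrix(0, p, ncol(W[[1]]))
    for (i in 1:3) {
      Ehat <- matrix(E[i, , ], p, p) + diag(p)
      D <- diag(1 / sqrt(rowSums(Ehat)))
      acc <- acc + pmax(D %*% Ehat %*% D %*% H %*% W[[i]], 0)
    }
    acc / 3
  }
  set.seed(21)
  for (rep in 1:5) {
    p <- sample(2:5, 1)
    H <- matrix(rnorm(p * 4), p, 4)
    E <- array(0L, dim = c(3, p, p))
    for (q in seq_len(p - 1)) {
      o <- sample(1:3, 1)
      E[o, q, q + 1] <- E[o, q + 1, q] <- 1L
    }
    W <- lapply(1:3, function(i) matrix(rnorm(4 * 3), 4, 3))
    expect_equal(gcn_layer(H, E, W)$H, oracle_layer(H, E, W),
                 tolerance = 1e-8)
  }
})

test_that("gcn_layer is permutation-equivariant", {
  set.seed(22)
  p <- 5
  H <- matrix(rnorm(p * 4), p, 4)
  E <- array(0L, dim = c(3, p, p))
  E[1, 1, 2] <- E[1, 2, 1] <- 1L; E[2, 2, 3] <- E[2, 3, 2] <- 1L
  E[1, 4, 5] <- E[1, 5, 4] <- 1L
  W <- lapply(1:3, function(i) matrix(rnorm(4 * 4), 4, 4))
  perm <- sample(p)
  Ep <- E[, perm, perm, drop = FALSE]
  out <- gcn_layer(H, E, W)$H
  outp <- gcn_layer(H[perm, ], Ep, W)$H
  expect_equal(outp, out[perm, ], tolerance = 1e-10)
})

test_that("embed_state appends the candidate atom-type rows", {
  pol <- tiny_policy(seed = 1)
  st <- as_dense_state("C")
  X <- embed_state(st, pol)
  expect_equal(nrow(X), 1 + length(pol$atom_types))   # 1 + 9
  expect_equal(ncol(X), pol$embed_dim)
  expect_equal(X, embed_state(st, pol))               # deterministic
})

test_that("action distributions are proper and masked", {
  pol <- tiny_policy(seed = 2)
  st <- as_dense_state("CCO")
  set.seed(1)
  out <- policy_act(pol, st)
  for (d in out$dists) expect_equal(sum(d), 1, tolerance = 1e-6)
  expect_length(out$dists$second, st$n + length(pol$atom_types))
  expect_length(out$dists$edge, 3)
  expect_length(out$dists$stop, 2)
  # candidate slots of the first-atom distribution carry zero mass
  expect_equal(out$dists$first[(st$n + 1):length(out$dists$first)],
               rep(0, length(pol$atom_types)))
})

test_that("sampled actions satisfy the action-vector invariants", {
  pol <- tiny_policy(seed = 3)
  st <- as_dense_state("CCO")
  ct <- length(pol$atom_types)
  set.seed(4)
  for (i in 1:100) {
    a <- policy_act(pol, st)$action
    expect_true(a$first >= 1 && a$first <= st$n)
    expect_true(a$second >= 1 && a$second <= st$n + ct)
    expect_true(a$edge %in% 1:3)
    expect_true(a$stop %in% 0:1)
  }
})

test_that("the composite log-probability is the sum of the head terms", {
  pol <- tiny_policy(seed = 5)
  st <- as_dense_state("CCO")
  set.seed(6)
  out <- policy_act(pol, st)
  a <- out$action
  manual <- log(out$dists$first[a$first]) + log(out$dists$second[a$second]) +
    log(out$dists$edge[a$edge]) + log(out$dists$stop[a$stop + 1])
  expect_equal(out$logp, manual, tolerance = 1e-10)
  expect_equal(policy_logprob(pol, st, a), out$logp, tolerance = 1e-10)
})

test_that("zeroed heads give uniform distributions and zero value", {
  pol <- tiny_policy(seed = 7)
  for (nm in c("mf", "ms", "me", "mt", "vh")) {
    for (w in names(pol$params[[nm]])) pol$params[[nm]][[w]][] <- 0
  }
  st <- as_dense_state("CCO")
  set.seed(8)
  out <- policy_act(pol, st)
  expect_equal(out$dists$first[1:3], rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(out$dists$second, rep(1 / 12, 12), tolerance = 1e-12)
  expect_equal(out$dists$edge, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(out$dists$stop, rep(1 / 2, 2), tolerance = 1e-12)
  expect_equal(out$value, 0)
  expect_equal(policy_value(pol, st), 0)
})

test_that("the discriminator is bounded, centred and permutation-invariant", {
  disc <- discriminator_init(16, 2, seed = 9)
  p1 <- discriminate(as_dense_state("CCO"), disc)
  expect_true(p1 > 0 && p1 < 1)
  expect_equal(discriminate(as_dense_state("OCC"), disc), p1,
               tolerance = 1e-10)
  disc0 <- disc
  for (w in names(disc0$params$head)) disc0$params$head[[w]][] <- 0
  expect_equal(discriminate(as_dense_state("c1ccccc1"), disc0), 0.5)
})
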