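# Message-passing encoder, regressor, and the training loop

small_cfg <- mpnn_config(depth = 2, hidden_dim = 8, ffn_layers = 2,
                         dropout = 0)

test_that("encode produces one embedding row per molecule", {
  m <- property_model_init(small_cfg, "robust", seed = 2)
  e <- encode(c("CCO", "c1ccccc1"), m)
  expect_equal(dim(e), c(2L, 8L))
  expect_true(all(is.finite(e)))
})

test_that("embedding is invariant to atom relabelling and deterministic", {
  m <- property_model_init(small_cfg, "robust", seed = 2)
  expect_equal(encode("OCC", m), encode("CCO", m))
  expect_equal(encode("c1ccccc1O", m), encode("c1ccccc1O", m))
})

test_that("a bondless molecule takes the zero-augmented readout path", {
  m <- property_model_init(small_cfg, "robust", seed = 3)
  g <- smiles_to_graph("C")
  emb <- encode(g, m)
  manual <- pmax(cbind(g$atom_features, matrix(0, 1, 8)) %*% m$Wa, 0)
  expect_equal(emb, manual, ignore_attr = TRUE)
})

test_that("encoder matches a hand-rolled dense message-passing oracle", {
  # independent oracle: explicit loops over directed bonds
  oracle_encode <- function(g, m) {
    nb <- g$n_bonds
    M0 <- matrix(0, nb, ncol(m$W0))
    for (b in seq_len(nb)) M0[b, ] <- pmax(g$bond_inputs[b, ] %*% m$W0, 0)
    M <- M0
    for (l in seq_along(m$Wh)) {
      S <- matrix(0, nb, ncol(M))
      for (b in seq_len(nb)) {
        nbrs <- setdiff(g$incoming[[g$bond_src[b]]], g$reverse[b])
        if (length(nbrs)) S[b, ] <- colSums(M[nbrs, , drop = FALSE])
      }
      M <- pmax(M0 + S %*% m$Wh[[l]], 0)   # depth-0 skip
    }
    H <- matrix(0, g$n_atoms, ncol(M))
    for (a in seq_len(g$n_atoms)) {
      inc <- g$incoming[[a]]
      u <- if (length(inc)) colSums(M[inc, , drop = FALSE]) else
        numeric(ncol(M))
      H[a, ] <- pmax(c(g$atom_features[a, ], u) %*% m$Wa, 0)
    }
    matrix(colMeans(H), 1)
  }
  m <- property_model_init(mpnn_config(3, 6, 1, 0), "l2", seed = 9)
  for (s in c("CC", "CCO", "c1ccccc1", "CC(=O)N")) {
    g <- smiles_to_graph(s)
    expect_equal(encode(g, m), oracle_encode(g, m), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("a 1-layer regressor is a single affine map of the embedding", {
  m <- property_model_init(mpnn_config(2, 8, 1, 0), "l2", seed = 4)
  g <- smiles_to_graph("CCO")
  emb <- encode(g, m)
  expect_equal(predict_property(g, m),
               as.vector(emb %*% m$w_out + m$b_out))
  # zero output weights and bias give exactly zero
  m$w_out[] <- 0; m$b_out <- 0
  expect_equal(predict_property(g, m), 0)
})

test_that("analytic gradients match central differences on a 2-molecule batch", {
  graphs <- lapply(c("CCO", "c1ccccc1"), smiles_to_graph)
  targets <- c(5.1, 6.3)
  m <- property_model_init(small_cfg, "robust", seed = 2)
  batch <- molforge:::.batch_graphs(graphs)
  fw <- molforge:::.mpnn_forward(m, batch, train = FALSE)
  ls <- molforge:::.pm_loss(m, fw$y, targets)
  gr <- molforge:::.mpnn_backward(m, batch, fw, ls$dY)
  flat <- molforge:::.pm_flatten(m)
  gflat <- molforge:::.grads_flatten(m, gr, ls$extra)
  lossfun <- function(mm) {
    f <- molforge:::.mpnn_forward(mm, batch, train = FALSE)
    molforge:::.pm_loss(mm, f$y, targets)$value
  }
  h <- 1e-5
  set.seed(11)
  for (nm in names(gflat)) {
    pick <- sample(length(flat[[nm]]), min(3, length(flat[[nm]])))
    for (ix in pick) {
      f2 <- flat; f2[[nm]][ix] <- f2[[nm]][ix] + h
      lp <- lossfun(molforge:::.pm_unflatten(m, f2))
      f2[[nm]][ix] <- f2[[nm]][ix] - 2 * h
      lm <- lossfun(molforge:::.pm_unflatten(m, f2))
      num <- (lp - lm) / (2 * h)
      an <- gflat[[nm]][ix]
      expect_equal(an, num, tolerance = 1e-4)
    }
  }
})

test_that("the learning-rate schedule warms up then decays to the floor", {
  cfg <- train_config(epochs = 100, warmup_epochs = 2)
  spe <- 8
  lrs <- vapply(seq_len(100 * spe), molforge:::.lr_schedule, numeric(1),
                steps_per_epoch = spe, cfg = cfg)
  expect_lt(lrs[1], cfg$lr_high)
  expect_equal(lrs[2 * spe], cfg$lr_high, tolerance = 1e-12)
  expect_true(all(diff(lrs[1:(2 * spe)]) > 0))
  expect_true(all(diff(lrs[(2 * spe):(100 * spe)]) < 0))
  expect_equal(lrs[100 * spe], cfg$lr_low, tolerance = 1e-9)
})

test_that("training is deterministic, improves, and checkpoints on validation", {
  d <- make_property_dataset(60, 0, 0, 0, seed = 5)
  tc <- train_config(batch_size = 16, epochs = 12, seed = 5)
  m1 <- train_property_model(d, small_cfg, tc, loss = "robust")
  m2 <- train_property_model(d, small_cfg, tc, loss = "robust")
  expect_equal(m1$metrics$train_loss[1], m2$metrics$train_loss[1])
  expect_lt(utils::tail(m1$metrics$train_loss, 1), m1$metrics$train_loss[1])
  expect_equal(min(m1$metrics$val_rmse),
               m1$metrics$val_rmse[m1$best_epoch])
  expect_error(train_property_model(d[1:5, ], small_cfg, tc), "at least 10")
  bad <- d; bad$target[1] <- NA
  expect_error(train_property_model(bad, small_cfg, tc), "finite")
})

test_that("the fitted shape parameter drifts up under Gaussian label noise", {
  # labels are drawn from the alpha = 2 member; the adaptive NLL should pull
  # alpha above its initialization at ~1 (median over 5 seeds)
  alphas <- vapply(1:5, function(seed) {
    d <- make_property_dataset(80, 0.25, 0, 0, seed = seed)
    m <- train_property_model(
      d, mpnn_config(2, 12, 1, 0),
      train_config(batch_size = 20, epochs = 25, seed = seed),
      loss = "robust")
    m$metrics$alpha[nrow(m$metrics)]
  }, numeric(1))
  expect_gt(median(alphas), 1.0)
})

test_that("tidy and glance expose the training history", {
  d <- make_property_dataset(40, 0, 0, 0, seed = 6)
  m <- train_property_model(d, small_cfg,
                            train_config(batch_size = 16, epochs = 3, seed = 6))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(m)
  expect_equal(gl$depth, 2)
  expect_true(is.finite(gl$val_rmse))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
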