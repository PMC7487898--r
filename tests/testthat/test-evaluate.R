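# Similarity, Pareto and reporting utilities

test_that("tanimoto follows the set-arithmetic definition", {
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)       # disjoint
  expect_equal(tanimoto(numeric(4), numeric(4)), 1) # both empty
  expect_equal(tanimoto(c(1, 1, 1, 1), c(1, 1, 0, 0)), 0.5)  # |I|=2 |U|=4
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("tanimoto on real fingerprints is symmetric with unit diagonal", {
  smis <- fixture_pool()[1:8]
  fp <- fingerprints(smis)
  expect_equal(nrow(fp), 8)
  for (i in 1:8) expect_equal(tanimoto(fp[i, ], fp[i, ]), 1)
  for (i in 1:4) {
    j <- i + 4
    expect_equal(tanimoto(fp[i, ], fp[j, ]), tanimoto(fp[j, ], fp[i, ]))
  }
})

test_that("nearest_reference finds exact members and matches a brute scan", {
  ref <- fixture_pool()[1:20]
  # a molecule present in the reference scores similarity 1
  nr <- nearest_reference(ref[3], ref)
  expect_equal(nr$similarity, 1)
  # singleton reference returns that molecule
  nr1 <- nearest_reference("CCO", ref[1])
  expect_equal(nr1$nearest, ref[1])
  # brute-force scan oracle over a batch of queries
  queries <- make_expert_set(15, seed = 44)
  got <- nearest_reference(queries, ref)
  fq <- fingerprints(queries); fr <- fingerprints(ref)
  for (i in seq_along(queries)) {
    sims <- vapply(seq_along(ref),
                   function(j) tanimoto(fq[i, ], fr[j, ]), numeric(1))
    expect_equal(got$similarity[i], max(sims), tolerance = 1e-12)
    expect_equal(got$nearest[i], ref[which.max(sims)])
  }
})

test_that("similarity distributions conserve counts", {
  ref <- fixture_pool()[1:10]
  smis <- rep("CCO", 7)
  d <- similarity_distribution(smis, ref, k = 7)
  expect_equal(sum(d$count), 7)
  expect_equal(sum(d$count > 0), 1)        # identical molecules: one bin
  gen <- make_expert_set(20, seed = 45)
  d2 <- similarity_distribution(gen, ref, k = 20)
  expect_equal(sum(d2$count), 20)
  nearest <- attr(d2, "nearest")
  again <- nearest_reference(gen, ref)
  expect_equal(nearest$similarity, again$similarity)
  expect_error(similarity_distribution(gen, ref, k = 50), "exceeds")
})

test_that("pareto_front retains exactly the non-dominated points", {
  expect_equal(pareto_front(matrix(c(1, 2), 1)), 1)             # singleton
  expect_equal(pareto_front(rbind(c(1, 1), c(2, 2))), 2)
  curve <- cbind(1:10, 10:1)                                    # trade-off
  expect_equal(pareto_front(curve), 1:10)
  # sense alignment: minimizing both flips the dominance
  expect_equal(pareto_front(rbind(c(1, 1), c(2, 2)),
                            senses = c("min", "min")), 1)
  expect_error(pareto_front(matrix(c(1, NA), 1)))
})

test_that("pareto_front equals the O(n^2) dominance oracle on random sets", {
  oracle <- function(pts) {
    n <- nrow(pts)
    keep <- logical(n)
    for (i in 1:n) {
      dominated <- FALSE
      for (j in 1:n) {
        if (j != i && all(pts[j, ] >= pts[i, ]) && any(pts[j, ] > pts[i, ])) {
          dominated <- TRUE; break
        }
      }
      keep[i] <- !dominated
    }
    which(keep)
  }
  set.seed(46)
  for (rep in 1:3) {
    pts <- matrix(rnorm(200 * 2), 200, 2)
    expect_equal(pareto_front(pts), oracle(pts))
  }
  pts3 <- matrix(rnorm(60 * 3), 60, 3)
  expect_equal(pareto_front(pts3), oracle(pts3))
})

test_that("topk_report deduplicates, filters and ranks", {
  recs <- tibble::tibble(
    smiles = c("CCO", "OCC", "c1ccccc1", "CCN", "CCC"),
    reward = c(5, 7, 6, 4, 3),
    qed = c(0.9, 0.9, 0.5, 0.85, 0.95),
    sa_norm = c(0.9, 0.9, 0.9, 0.7, 0.95))
  out <- topk_report(recs, k = 10, qed_min = 0.8, sa_min = 0.8)
  # CCO/OCC collapse to one molecule (best record kept); benzene fails the
  # QED filter; CCN fails the SA filter
  expect_equal(nrow(out), 2)
  expect_equal(out$reward, c(7, 3))
  # thresholds 0: rank-only behaviour over unique molecules
  all4 <- topk_report(recs, k = 10, qed_min = 0, sa_min = 0)
  expect_equal(nrow(all4), 4)
  expect_equal(all4$reward, sort(all4$reward, decreasing = TRUE))
  expect_equal(nrow(topk_report(recs, k = 2, qed_min = 0, sa_min = 0)), 2)
  # brute-force recount of the filters
  brute <- sum(recs$qed[!duplicated(vapply(recs$smiles, canonical_smiles,
                                           ""))] >= 0.8 &
               recs$sa_norm[!duplicated(vapply(recs$smiles, canonical_smiles,
                                               ""))] >= 0.8)
  expect_equal(nrow(out), brute)
  # empty post-filter set warns and returns an empty table
  expect_warning(empty <- topk_report(recs, k = 5, qed_min = 0.99),
                 "empty")
  expect_equal(nrow(empty), 0)
  # nearest-reference annotation
  ann <- topk_report(recs, k = 2, qed_min = 0, sa_min = 0,
                     reference = c("CCO", "CCCC"))
  expect_true(all(c("nearest", "nearest_similarity") %in% names(ann)))
})
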