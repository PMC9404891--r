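test_that("DAI follows the simple-ratio formula and its bounds", {
  ros <- tiny_roster(c("A", "B", "C"))
  # D_ab = 10, D_a = D_b = 100 -> 10 / 190
  rec <- rbind(prox_rec("A", "B", "sA", 100, 10),
               prox_rec("B", "A", "sB", 100, 0))
  dai <- compute_dai(rec, ros)
  expect_equal(dai["A", "B"], 10 / 190)
  expect_equal(dai["B", "A"], 10 / 190)
  expect_equal(dai["A", "C"], 0) # never recorded together
  expect_equal(diag(unclass(dai)), setNames(c(0, 0, 0), c("A", "B", "C")))
  # full-overlap bound: D_ab = D_a = D_b -> 1
  rec2 <- prox_rec("A", "B", "sA", 100, 100)
  expect_equal(compute_dai(rec2, ros)["A", "B"], 1)
  # two-individual troop always within 1 m from both perspectives -> 1
  ros2 <- tiny_roster(c("A", "B"))
  rec3 <- rbind(prox_rec("A", "B", "sA", 50, 50),
                prox_rec("B", "A", "sB", 50, 50))
  expect_equal(compute_dai(rec3, ros2)["A", "B"], 1)
})

test_that("DAI is invariant to record order and session splitting", {
  ros <- tiny_roster(c("A", "B", "C"))
  rec <- rbind(prox_rec("A", "B", "s1", 100, 30),
               prox_rec("A", "C", "s1", 100, 10),
               prox_rec("B", "C", "s2", 80, 20),
               prox_rec("B", "A", "s2", 80, 15))
  base <- compute_dai(rec, ros)
  shuffled <- compute_dai(rec[c(3, 1, 4, 2), ], ros)
  expect_equal(unclass(base), unclass(shuffled))
  # split A's single session into two with the same totals
  split <- rbind(prox_rec("A", "B", "s1a", 60, 20),
                 prox_rec("A", "B", "s1b", 40, 10),
                 prox_rec("A", "C", "s1a", 60, 10),
                 prox_rec("A", "C", "s1b", 40, 0),
                 prox_rec("B", "C", "s2", 80, 20),
                 prox_rec("B", "A", "s2", 80, 15))
  expect_equal(unclass(compute_dai(split, ros)), unclass(base))
})

test_that("DAI validates its inputs", {
  ros <- tiny_roster(c("A", "B"))
  expect_error(compute_dai(prox_rec("A", "Z", "s", 10, 1), ros), "Z")
  expect_error(compute_dai(prox_rec("A", "B", "s", 10, -1), ros), "negative")
  expect_error(compute_dai(prox_rec("A", "B", "s", 10, 11), ros), "exceeds")
})

test_that("eigenvector centrality matches closed forms and dense eigen", {
  # complete graph with equal weights: uniform scores
  n <- 5
  cg <- matrix(1, n, n); diag(cg) <- 0
  expect_equal(as.numeric(eigenvector_centrality(cg)), rep(1 / sqrt(n), n),
               tolerance = 1e-9)
  # star K1,3: center / leaf ratio = sqrt(3)
  st <- matrix(0, 4, 4); st[1, 2:4] <- 1; st[2:4, 1] <- 1
  ec <- eigenvector_centrality(st)
  expect_equal(ec[[1]] / ec[[2]], sqrt(3), tolerance = 1e-9)
  # random symmetric 27x27 vs dense eigendecomposition
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(runif(27 * 27), 27)
    a <- (a + t(a)) / 2; diag(a) <- 0
    ec <- eigenvector_centrality(a)
    ev <- abs(eigen(a, symmetric = TRUE)$vectors[, 1])
    expect_lt(max(abs(as.numeric(ec) - ev)), 1e-8)
    # eigen-residual contract
    lam <- attr(ec, "eigenvalue")
    expect_lt(max(abs(a %*% as.numeric(ec) - lam * as.numeric(ec))), 1e-8)
  }
})

test_that("centrality handles disconnected and degenerate matrices", {
  # two components: the larger carries the scores, the smaller gets zeros
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1 # component {1,2,3}
  a[4, 5] <- a[5, 4] <- 1                       # component {4,5}
  ec <- eigenvector_centrality(a)
  expect_true(all(ec[4:5] == 0))
  expect_true(all(ec[1:3] > 0))
  expect_equal(sum(ec^2), 1)
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "all-zero")
  expect_error(eigenvector_centrality(matrix(1:9, 3)), "symmetric")
})

test_that("David's Score: hand cases, conservation, and dij correction", {
  ros <- tiny_roster(c("A", "B"))
  bouts <- data.frame(actor_id = rep("A", 5), receiver_id = rep("B", 5))
  ds <- davids_score(bouts, ros, correction = "pij")
  expect_equal(ds$ds, c(1, -1))
  expect_equal(ds$rank, c(1L, 2L))
  # dij: P_AB = 1 - 0.5/6, then DS_A = w + w2 - l - l2 computed by hand
  p_ab <- 1 - (1 - 0.5) / (5 + 1)
  p_ba <- 0 - (0 - 0.5) / (5 + 1)
  ds_a <- p_ab + p_ab * p_ba - p_ba - p_ab * p_ba
  dsd <- davids_score(bouts, ros, correction = "dij")
  expect_equal(dsd$ds[1], ds_a)
  expect_equal(sum(dsd$ds), 0, tolerance = 1e-12)
  # perfectly balanced round robin: all scores zero
  ros3 <- tiny_roster(c("A", "B", "C"))
  rr <- data.frame(
    actor_id = c("A", "B", "A", "C", "B", "C"),
    receiver_id = c("B", "A", "C", "A", "C", "B"))
  expect_equal(davids_score(rr, ros3)$ds, c(0, 0, 0))
  # random tournaments: conservation and agreement with the matrix oracle
  for (s in 1:5) {
    set.seed(s)
    ids <- tiny_roster(LETTERS[1:6])
    k <- 60
    i <- sample(6, k, replace = TRUE)
    j <- sample(6, k, replace = TRUE)
    keep <- i != j
    bt <- data.frame(actor_id = LETTERS[i[keep]],
                     receiver_id = LETTERS[j[keep]])
    ds <- davids_score(bt, ids)
    expect_equal(sum(ds$ds), 0, tolerance = 1e-9)
    wins <- matrix(0, 6, 6)
    for (r in seq_len(nrow(bt))) {
      a <- match(bt$actor_id[r], LETTERS)
      b <- match(bt$receiver_id[r], LETTERS)
      wins[a, b] <- wins[a, b] + 1
    }
    expect_equal(ds$ds, ds_matrix_oracle(wins), tolerance = 1e-12)
  }
  expect_error(davids_score(data.frame(actor_id = "A", receiver_id = "Q"),
                            ros), "Q")
})

test_that("relative counts come from matriline sizes", {
  t1 <- read_table1_roster()
  rel <- count_relatives(t1)
  expect_equal(unname(rel[t1$id == "YXK"]), 6L) # 7-member matriline
  expect_equal(unname(rel[t1$id == "YL"]), 0L)  # immigrant male
  expect_identical(unname(rel), t1$n_relatives) # matches the printed column
  singleton <- tiny_roster(c("A", "B"), matriline = c("m1", NA))
  expect_equal(unname(count_relatives(singleton)), c(0L, 0L))
})
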