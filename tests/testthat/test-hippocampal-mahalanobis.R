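# Independent Ledoit-Wolf + explicit-inverse oracle, written against the
# estimator's definition rather than the package implementation.
oracle_lw_mahal <- function(s, X) {
  m <- nrow(X); k <- ncol(X)
  mu <- colMeans(X)
  Xc <- X - matrix(mu, m, k, byrow = TRUE)
  S <- t(Xc) %*% Xc / m
  mu_t <- mean(diag(S))
  d2 <- sum((S - diag(mu_t, k))^2)
  if (d2 <= .Machine$double.eps) {
    C <- diag(mu_t, k)
  } else {
    b2bar <- 0
    for (i in seq_len(m))
      b2bar <- b2bar + sum((Xc[i, ] %o% Xc[i, ] - S)^2)
    b2bar <- b2bar / m^2
    rho <- min(b2bar, d2) / d2
    C <- rho * diag(mu_t, k) + (1 - rho) * S
  }
  drop(t(s - mu) %*% solve(C) %*% (s - mu))
}

test_that("Mahalanobis deviation reproduces hand-computable cases", {
  # patient at the control mean
  X <- matrix(stats::rnorm(50 * 4), 50, 4)
  expect_equal(mahalanobis_dist(colMeans(X), X), 0, tolerance = 1e-12)

  # forced identity covariance: unit shift gives M = 1
  expect_equal(mahalanobis_dist(c(1, 0, 0), cov = diag(3),
                                center = c(0, 0, 0)), 1)

  # 2x2 closed form with unit variances and r = 0.74 at (2, -1):
  # (4 + 1 + 2 * 0.74 * 2) / (1 - 0.74^2)
  C2 <- matrix(c(1, 0.74, 0.74, 1), 2)
  expect_equal(mahalanobis_dist(c(2, -1), cov = C2, center = c(0, 0)),
               (4 + 1 + 2 * 0.74 * 2) / (1 - 0.74^2), tolerance = 1e-12)

  # Euclidean distance of (2, -1) from the origin is 2.2 to one decimal
  expect_equal(round(mahalanobis_dist(c(2, -1), cov = diag(2),
                                      center = c(0, 0), squared = FALSE), 1),
               2.2)
})

test_that("shrinkage Mahalanobis matches a brute-force oracle", {
  set.seed(12)
  for (rep in 1:200) {
    k <- sample(1:10, 1)
    m <- sample((k + 2):60, 1)
    X <- matrix(stats::rnorm(m * k, sd = stats::runif(1, 0.5, 3)), m, k)
    s <- stats::rnorm(k, sd = 2)
    expect_equal(mahalanobis_dist(s, X, "ledoit-wolf"),
                 oracle_lw_mahal(s, X), tolerance = 1e-10)
  }
})

test_that("M is invariant to edge permutation and per-edge shifts", {
  set.seed(13)
  X <- matrix(stats::rnorm(40 * 7), 40, 7)
  s <- stats::rnorm(7)
  M0 <- mahalanobis_dist(s, X)
  perm <- sample(7)
  expect_equal(mahalanobis_dist(s[perm], X[, perm]), M0, tolerance = 1e-10)
  shift <- stats::rnorm(7)
  expect_equal(mahalanobis_dist(s + shift,
                                X + matrix(shift, 40, 7, byrow = TRUE)),
               M0, tolerance = 1e-10)
  # square root relation
  expect_equal(mahalanobis_dist(s, X, squared = FALSE), sqrt(M0))
})

test_that("shrunk covariance is positive definite at n = 50, k = 7", {
  set.seed(14)
  for (rep in 1:20) {
    X <- matrix(stats::rnorm(50 * 7), 50, 7)
    C <- shrink_cov(X)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_gt(attr(C, "intensity"), 0)
    expect_lte(attr(C, "intensity"), 1)
  }
})

test_that("the permutation kernel matches the scalar path and keeps books", {
  set.seed(15)
  n_ctrl <- 30; n_pat <- 5; n_edges <- 12; k <- 4
  Ce <- matrix(stats::rnorm(n_ctrl * n_edges), n_ctrl, n_edges)
  Pe <- matrix(stats::rnorm(n_pat * n_edges), n_pat, n_edges)
  no <- 6; ni <- 4
  es <- t(replicate(no, sample.int(n_edges, k)))
  cs <- t(replicate(no * ni, sample.int(n_ctrl, 20)))
  out <- netprog:::cpp_perm_mahal(Ce, Pe, es, cs, ni, 18L, 0L, 0.2, TRUE)
  # no missing edges: full bookkeeping
  expect_equal(out$n_pairs, rep(no * ni, n_pat))
  expect_equal(out$n_outer_skipped, rep(0L, n_pat))
  expect_equal(out$n_inner_discarded, 0L)
  # recompute one patient's pooled mean through the scalar path
  for (p in 1:2) {
    Ms <- numeric(0)
    for (o in seq_len(no)) for (i in seq_len(ni)) {
      Xs <- Ce[cs[(o - 1) * ni + i, ], es[o, ]]
      Ms <- c(Ms, mahalanobis_dist(Pe[p, es[o, ]], Xs, "ledoit-wolf"))
    }
    expect_equal(out$M[p], mean(Ms), tolerance = 1e-10)
    expect_equal(out$M_outer[p],
                 mean(colMeans(matrix(Ms, ni, no))), tolerance = 1e-10)
  }
})

test_that("missing edges trigger the documented discard rules", {
  set.seed(16)
  n_ctrl <- 20; n_edges <- 6; k <- 3
  Ce <- matrix(stats::rnorm(n_ctrl * n_edges), n_ctrl, n_edges)
  Ce[1:10, 1] <- NA  # half the controls miss edge 1
  Pe <- matrix(stats::rnorm(2 * n_edges), 2, n_edges)
  Pe[2, 2] <- NA     # patient 2 misses edge 2
  es <- rbind(c(1, 3, 4), c(2, 5, 6))
  cs <- t(replicate(2 * 3, sample.int(n_ctrl, 15)))
  # min_complete 12: draws containing edge 1 usually keep < 12 controls
  out <- netprog:::cpp_perm_mahal(Ce, Pe, es, cs, 3L, 12L, 0L, 0.2, TRUE)
  expect_gt(out$n_inner_discarded, 0)
  # patient 2 skips the outer draw containing edge 2
  expect_equal(out$n_outer_skipped[2], 1L)
  expect_equal(out$n_outer_skipped[1], 0L)

  # a patient sitting on the control means scores 0 in every retained
  # pair once each draw spans the full (complete) control set
  Ce2 <- matrix(stats::rnorm(n_ctrl * n_edges), n_ctrl, n_edges)
  Pe0 <- rbind(colMeans(Ce2))
  cs_full <- t(replicate(2 * 3, sample.int(n_ctrl, n_ctrl)))
  out0 <- netprog:::cpp_perm_mahal(Ce2, Pe0, es, cs_full, 3L, n_ctrl, 0L,
                                   0.2, TRUE)
  expect_lt(out0$M[1], 1e-18)
})

test_that("patient at control means gives M = 0 in every bin end to end", {
  atlas <- mini_atlas()
  n <- nrow(atlas)
  ne <- n * (n - 1) / 2
  set.seed(17)
  nc <- 20
  ids <- c(sprintf("c%02d", 1:nc), "p1")
  FCres <- matrix(stats::rnorm((nc + 1) * ne), nc + 1, ne)
  FCres[nc + 1, ] <- colMeans(FCres[1:nc, ])
  rownames(FCres) <- ids
  LEN <- matrix(rep(abs(stats::rnorm(ne)) + 1, each = nc + 1), nc + 1, ne)
  rownames(LEN) <- ids
  subjects <- data.frame(
    subject_id = ids, group = c(rep("control", nc), "patient"),
    age = rep(40, nc + 1),
    duration = c(rep(NA, nc), 10),
    focus_side = c(rep(NA, nc), "left"), stringsAsFactors = FALSE)
  coh <- cohort(atlas, subjects, list(FC_res = FCres, LEN = LEN))
  topo <- build_topology(coh, "LEN")
  b <- hippocampal_binnings(topo, atlas, 3)
  cfg <- mahal_config(k_subset = 4, n_edge_permutations = 10,
                      n_control_permutations = 10, n_controls_drawn = nc,
                      min_controls_complete = nc, seed = 9)
  prof <- hippocampal_profiles(coh, b, "FC", cfg)
  ipsi <- prof[prof$side == "ipsi", ]
  expect_equal(nrow(ipsi), 3)
  expect_true(all(ipsi$M < 1e-18))
  expect_true(all(ipsi$n_pairs == 100))
})
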