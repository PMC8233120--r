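test_that("joint matrix concatenates FC and SC edges with provenance", {
  sim <- null_cohort_fc_sc()
  coh <- normalize_cohort(sim$cohort)
  joint <- build_joint_matrix(coh, max_missing_fraction = 0.1)
  np <- sum(coh$subjects$group == "patient")
  expect_equal(nrow(joint$X), np)
  expect_equal(sum(joint$edge_map$modality == "FC"), 5886)
  # cross-hemisphere SC edges (40% missing) are dropped at the 10% rule;
  # within-hemisphere SC edges (all present) are kept
  expect_equal(sum(joint$edge_map$modality == "SC"), 5886 - 54 * 54)
  expect_false(anyNA(joint$X))
  expect_equal(nrow(joint$edge_map), ncol(joint$X))

  # with no missing edges the full 2 x 5886 = 11772 columns survive
  cfg0 <- sim_config(seed = 31, n_controls = 3, n_patients = 4,
                     n_right_focus = 2,
                     missing_fraction_cross_hemisphere = 0)
  sim0 <- simulate_cohort(cfg0)
  coh0 <- normalize_cohort(sim0$cohort)
  joint0 <- build_joint_matrix(coh0)
  expect_equal(ncol(joint0$X), 11772)
})

test_that("ICA recovers planted orthogonal non-Gaussian sources exactly", {
  set.seed(32)
  n_edges <- 3000; n_sub <- 24
  s1 <- stats::rbinom(n_edges, 1, 0.1) * stats::rnorm(n_edges, 3)
  s2 <- stats::rbinom(n_edges, 1, 0.1) * stats::rnorm(n_edges, -3)
  a1 <- stats::rnorm(n_sub); a2 <- stats::rnorm(n_sub)
  X <- outer(a1, s1) + outer(a2, s2)
  joint <- list(X = X,
                edge_map = data.frame(modality = "FC",
                                      i = rep(1, n_edges),
                                      j = seq_len(n_edges) + 1,
                                      col = seq_len(n_edges)),
                patients = data.frame(subject_id = as.character(seq_len(n_sub)),
                                      duration = stats::runif(n_sub, 2, 50)))
  runs <- run_hybrid_ica(joint, ica_config(n_runs = 2, pca_variance = 0.99,
                                           seed = 5))
  expect_equal(runs$n_comp, 2)
  cors <- abs(stats::cor(runs$components[, 1:2], cbind(s1, s2)))
  expect_true(all(apply(cors, 2, max) >= 0.99))

  # pca_variance = 1 on full-rank input retains min(n - 1, p) components
  Xf <- X + matrix(stats::rnorm(n_sub * n_edges, 0, 0.5), n_sub, n_edges)
  jf <- joint; jf$X <- Xf
  runs_f <- run_hybrid_ica(jf, ica_config(n_runs = 1, pca_variance = 1,
                                          seed = 5))
  expect_equal(runs_f$n_comp, n_sub - 1)

  # identical seed, identical output
  runs2 <- run_hybrid_ica(joint, ica_config(n_runs = 2, pca_variance = 0.99,
                                            seed = 5))
  expect_identical(runs$components, runs2$components)
})

test_that("merging pools duplicated components and tracks frequency", {
  set.seed(33)
  s <- stats::rnorm(500)
  noise <- matrix(stats::rnorm(500 * 2, sd = 3), 500, 2)
  comps <- cbind(s, -s + stats::rnorm(500, 0, 0.01), noise)
  w <- matrix(stats::rnorm(10 * 4), 10, 4)
  runs <- structure(list(components = comps, weights = w,
                         run = c(1, 2, 1, 2), n_comp = 2, n_runs = 2,
                         n_runs_failed = 0, edge_map = NULL,
                         patients = NULL), class = "ica_runs")
  merged <- merge_components(runs, 0.8)
  expect_equal(ncol(merged$components), 3)
  # the duplicated (sign-flipped) pair merged into one with frequency 1
  ix <- which(merged$n_members == 2)
  expect_length(ix, 1)
  expect_equal(merged$frequency[ix], 1)
  # sign alignment: the merged component still correlates with s
  expect_gt(abs(stats::cor(merged$components[, ix], s)), 0.99)
  # merged set is pairwise below the threshold
  R <- abs(stats::cor(merged$components))
  expect_true(all(R[upper.tri(R)] <= 0.8))
})

test_that("duration selection flips signs and respects significance", {
  set.seed(34)
  dur <- stats::runif(30, 2, 50)
  comps <- matrix(stats::rnorm(200 * 3), 200, 3)
  w <- cbind(-rank(dur), stats::rnorm(30), stats::rnorm(30))
  res <- structure(list(components = comps, weights = w,
                        frequency = rep(1, 3), n_members = rep(1L, 3),
                        contributing_runs = list(1, 1, 1),
                        edge_map = NULL,
                        patients = data.frame(subject_id = as.character(1:30),
                                              duration = dur)),
                   class = "ica_result")
  out <- select_duration_component(res)
  # perfect monotone weights: rho = 1 after the sign flip
  expect_equal(out$duration_rho[1], 1)
  expect_equal(out$primary, 1L)
  expect_true(1 %in% out$selected)
})

test_that("degree projection matches hand computation and density rules", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.6
  m[1, 3] <- m[3, 1] <- -0.6
  m[2, 3] <- m[3, 2] <- 0.1
  v <- edge_vector(m)
  em <- data.frame(modality = rep(c("FC", "SC"), each = 3),
                   i = rep(c(1, 1, 2), 2), j = rep(c(2, 3, 3), 2),
                   col = 1:6)
  res <- structure(list(components = cbind(c(v, v)), weights = NULL,
                        edge_map = em), class = "ica_result")
  proj <- degree_projection(res, 1, fc_threshold = 0.55, sc_threshold = 0.55)
  expect_equal(proj$fc_degree, c(0, 0.6, -0.6))
  expect_equal(proj$fc_density, 2 / 3)
  # threshold 0: plain signed weighted degree
  proj0 <- degree_projection(res, 1, fc_threshold = 1e-12,
                             sc_threshold = 1e-12)
  expect_equal(proj0$fc_degree, rowSums(m))
  # threshold above the largest value: all zero, density 0
  projL <- degree_projection(res, 1, fc_threshold = 10, sc_threshold = 10)
  expect_equal(projL$fc_degree, c(0, 0, 0))
  expect_equal(projL$fc_density, 0)
  # density is non-increasing in the threshold
  dens <- vapply(c(0.05, 0.175, 0.55, 0.7),
                 function(t) degree_projection(res, 1, t, t)$fc_density, 0)
  expect_true(all(diff(dens) <= 0))
  # absolute-degree option
  projA <- degree_projection(res, 1, 0.55, 0.55, degree = "absolute")
  expect_equal(projA$fc_degree, c(1.2, 0.6, 0.6))

  # density-targeted threshold mode hits the requested density
  set.seed(41)
  nE <- 400
  emb <- data.frame(modality = "FC", i = 1, j = 2, col = seq_len(nE))
  resb <- structure(list(components = cbind(stats::rnorm(nE)),
                         edge_map = emb), class = "ica_result")
  thr <- density_threshold(resb, 1, "FC", density = 0.2)
  expect_equal(mean(abs(resb$components[, 1]) >= thr), 0.2, tolerance = 0.01)
})

test_that("model correlations use the documented methods and exclusions", {
  coh <- shared_cohort()$norm
  atlas <- coh$atlas
  topos <- list(LEN = build_topology(coh, "LEN"),
                RSN = build_topology(coh, "RSN"))
  md <- model_distance_by_region(topos$LEN, atlas)
  # seed slots excluded, everything else defined
  expect_true(all(is.na(md[atlas$is_anterior_hippocampus])))
  expect_equal(sum(is.na(md)), 2)
  # homotopic slots share one hemisphere-averaged distance
  pairs <- region_pairs(atlas)
  expect_equal(md[pairs$left_id + 1], md[pairs$right_id + 1])

  # a degree vector proportional to the model distances correlates at 1
  deg <- md * 2.5
  deg[is.na(deg)] <- 0
  out <- correlate_with_models(deg, topos["LEN"], atlas)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$method, "pearson")
  expect_equal(out$n, 107)

  # RSN model uses Spearman; a zero degree vector is reported undefined
  out2 <- correlate_with_models(rep(0, 109), topos, atlas)
  expect_true(all(is.na(out2$r)))
  expect_equal(out2$method[out2$model == "RSN"], "spearman")
})
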