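test_that("same seed gives bitwise-identical cohorts", {
  a <- simulate_cohort(sim_config(seed = 5, n_controls = 8, n_patients = 4,
                                  n_right_focus = 3))
  b <- simulate_cohort(sim_config(seed = 5, n_controls = 8, n_patients = 4,
                                  n_right_focus = 3))
  expect_identical(a$cohort$edges, b$cohort$edges)
  expect_identical(a$cohort$subjects, b$cohort$subjects)
  expect_identical(a$truth$len_base, b$truth$len_base)
})

test_that("modalities realized separately match the full simulation", {
  full <- simulate_cohort(sim_config(seed = 9, n_controls = 6, n_patients = 3,
                                     n_right_focus = 2))
  fc_only <- simulate_cohort(sim_config(seed = 9, n_controls = 6,
                                        n_patients = 3, n_right_focus = 2),
                             modalities = "FC")
  expect_identical(fc_only$cohort$edges$FC, full$cohort$edges$FC)
  expect_identical(fc_only$cohort$subjects, full$cohort$subjects)
})

test_that("generated connectomes satisfy their domain constraints", {
  sim <- shared_cohort()$sim
  coh <- sim$cohort
  expect_true(all(coh$edges$SC >= 0, na.rm = TRUE))
  expect_true(all(coh$edges$LEN > 0, na.rm = TRUE))
  # SC and LEN share the missing mask; FC has none
  expect_identical(is.na(coh$edges$SC), is.na(coh$edges$LEN))
  expect_false(anyNA(coh$edges$FC))
  # missingness is confined to cross-hemisphere edges
  atlas <- coh$atlas
  emap <- edge_index_map(nrow(atlas))
  cross <- (atlas$hemisphere[emap$i] == "left" &
              atlas$hemisphere[emap$j] == "right") |
           (atlas$hemisphere[emap$i] == "right" &
              atlas$hemisphere[emap$j] == "left")
  expect_true(all(!is.na(coh$edges$SC[, !cross])))
  frac <- mean(is.na(coh$edges$SC[, cross]))
  expect_gt(frac, 0.3); expect_lt(frac, 0.5)
})

test_that("latent streamline lengths are near-metric", {
  truth <- shared_cohort()$sim$truth
  D <- edges_to_matrix(truth$len_base, 109)
  set.seed(1)
  viol <- 0; total <- 2000
  for (rep in seq_len(total)) {
    ijk <- sample(109, 3)
    if (D[ijk[1], ijk[2]] > D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-9)
      viol <- viol + 1
  }
  expect_lt(viol / total, 0.01)
})

test_that("null effect profile makes patients exchangeable with controls", {
  ps <- vapply(1:5, function(s) {
    sim <- simulate_cohort(sim_config(seed = 300 + s,
                                      effect_profile = rep(0, 5)),
                           modalities = "FC")
    coh <- sim$cohort
    ctrl <- coh$edges$FC[coh$subjects$group == "control", ]
    pat <- coh$edges$FC[coh$subjects$group == "patient", ]
    set.seed(s)
    cols <- sample(ncol(ctrl), 300)
    suppressWarnings(stats::ks.test(as.numeric(ctrl[, cols]),
                                    as.numeric(pat[, cols]))$p.value)
  }, 0)
  expect_gt(stats::median(ps), 0.01)
})

test_that("planted per-bin effects produce a decreasing |FC_corr| gradient", {
  cfg <- sim_config(seed = 77, duration_mean = 30, duration_sd = 0,
                    effect_profile = c(3, 2.25, 1.5, 0.75, 0))
  sim <- simulate_cohort(cfg, modalities = "FC")
  coh <- normalize_cohort(sim$cohort, "FC")
  pats <- cohort_subjects(coh, "patient")
  corr <- coh$edges$FC_corr[pats$subject_id, ]
  bin_means <- vapply(1:5, function(b) {
    vals <- vapply(seq_len(nrow(pats)), function(p) {
      pb <- sim$truth$bins[[pats$focus_side[p]]]
      mean(abs(corr[p, pb$edge_col[pb$bin == b]]))
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(bin_means) < 0))
})

test_that("planted ICA loading hits its target Spearman correlation", {
  sim <- simulate_cohort(sim_config(seed = 42, n_controls = 6,
                                    n_patients = 40, n_right_focus = 29),
                         modalities = c("FC", "SC"))
  # exact construction at rho = 1
  pl <- plant_ica_component(sim$cohort, loading_vs_duration_rho = 1,
                            amplitude = 1, seed = 1)
  expect_equal(pl$truth$realized_rho, 1)

  # amplitude 0 leaves the cohort untouched; negative amplitude errors
  pl0 <- plant_ica_component(sim$cohort, amplitude = 0, seed = 1)
  expect_identical(pl0$cohort$edges, sim$cohort$edges)
  expect_error(plant_ica_component(sim$cohort, amplitude = -1), "amplitude")

  # stochastic construction lands near the target (median over seeds)
  err <- vapply(1:5, function(s) {
    pl <- plant_ica_component(sim$cohort, loading_vs_duration_rho = 0.6,
                              amplitude = 1, seed = s)
    abs(pl$truth$realized_rho - 0.6)
  }, 0)
  expect_lt(stats::median(err), 0.1)
})

test_that("planted effect sizes are recoverable from group statistics", {
  # (patient mean - control mean) / control SD at duration 30 on planted
  # edges approximates the configured profile
  cfg <- sim_config(seed = 55, n_controls = 300, n_patients = 60,
                    n_right_focus = 30, duration_mean = 30, duration_sd = 0,
                    effect_profile = c(3, 2.25, 1.5, 0.75, 0))
  sim <- simulate_cohort(cfg, modalities = "FC")
  coh <- sim$cohort
  ctrl <- coh$edges$FC[coh$subjects$group == "control", ]
  pats <- cohort_subjects(coh, "patient")
  pat_e <- coh$edges$FC[pats$subject_id, ]
  est <- vapply(1:5, function(b) {
    vals <- vapply(seq_len(nrow(pats)), function(p) {
      pb <- sim$truth$bins[[pats$focus_side[p]]]
      cols <- pb$edge_col[pb$bin == b]
      mean((pat_e[p, cols] - colMeans(ctrl[, cols])) /
             apply(ctrl[, cols], 2, stats::sd))
    }, 0)
    mean(vals)
  }, 0)
  expect_equal(abs(est[1:4]), cfg$effect_profile[1:4], tolerance = 0.15)
  expect_lt(abs(est[5]), 0.2)
})
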