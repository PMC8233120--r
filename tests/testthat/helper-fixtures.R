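# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A compact atlas satisfying all atlas invariants: 21 region pairs
# (hippocampus pair + 5 pairs per resting-state network) plus brainstem.
mini_atlas <- function() {
  base <- c("ant_hippocampus",
            paste0("dmn_", 1:5), paste0("att_", 1:5),
            paste0("vis_", 1:5), paste0("mot_", 1:5))
  rsn <- c(0L, rep(1L, 5), rep(2L, 5), rep(3L, 5), rep(4L, 5))
  n_pair <- length(base)
  data.frame(
    region_id = 0:(2 * n_pair),
    name = c(paste0(base, "_L"), paste0(base, "_R"), "brainstem"),
    hemisphere = c(rep("left", n_pair), rep("right", n_pair), "bilateral"),
    rsn_label = c(rsn, rsn, 0L),
    is_anterior_hippocampus = c(base == "ant_hippocampus",
                                base == "ant_hippocampus", FALSE),
    stringsAsFactors = FALSE
  )
}

# Random symmetric matrix with zero diagonal.
rand_sym <- function(n, missing = 0) {
  v <- stats::rnorm(n * (n - 1) / 2)
  if (missing > 0) v[sample(length(v), missing)] <- NA
  edges_to_matrix(v, n)
}

# Default-condition simulated cohort (FC/SC/LEN), age-normalized, shared
# across test files.
shared_cohort <- function() {
  cached("shared_cohort", {
    sim <- simulate_cohort(sim_config(seed = 101))
    list(sim = sim, norm = normalize_cohort(sim$cohort))
  })
}

# Hippocampal-null cohort used by the ICA tests.
null_cohort_fc_sc <- function() {
  cached("null_cohort_fc_sc", {
    simulate_cohort(sim_config(seed = 202, effect_profile = rep(0, 5)))
  })
}

# 200 null-cohort replicates of the ipsilateral M_FC patients-by-bins
# matrix at 50 x 50 permutations, shared by the calibration tests.
null_M_replicates <- function(n_rep = 200) {
  cached("null_M_replicates", {
    lapply(seq_len(n_rep), function(s) {
      sim <- simulate_cohort(sim_config(seed = 9000 + s,
                                        effect_profile = rep(0, 5)),
                             modalities = c("FC", "LEN"))
      coh <- normalize_cohort(sim$cohort, "FC")
      b <- hippocampal_binnings(build_topology(coh, "LEN"), coh$atlas, 5)
      cfg <- mahal_config(n_edge_permutations = 50,
                          n_control_permutations = 50, seed = s)
      profiles_matrix(hippocampal_profiles(coh, b, "FC", cfg), "ipsi")
    })
  })
}
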