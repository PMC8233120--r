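#' Simulation configuration
#'
#' Default parameters mirror the study cohort: 70 controls and 40 patients
#' (29 right-sided, 11 left-sided focus), ages 18-71 years, epilepsy
#' duration with mean 21 and SD 15 years truncated to [2, 50]. Remaining
#' parameters set the generative model the analysis assumes: mean
#' functional connectivity (Fisher z) decays exponentially with streamline
#' length, mean log structural connectivity decays linearly with length,
#' every edge has its own linear age trend, cross-hemisphere structural
#' edges are frequently undetected, and patient alterations are planted on
#' edges of the ipsilateral anterior hippocampus with per-bin magnitudes
#' (in control-SD units) that scale with duration of disease.
#'
#' @param n_controls,n_patients Cohort sizes.
#' @param n_right_focus Number of patients with right-sided focus.
#' @param age_range Years, sampled uniformly.
#' @param duration_mean,duration_sd,duration_range Patient duration of
#'   disease (years), normal truncated to the range.
#' @param fc_base,fc_lambda Fisher-z FC mean at zero length and its
#'   exponential decay constant (mm).
#' @param fc_edge_sd SD of the per-edge FC intercept around the decay curve.
#' @param fc_noise_sd Within-edge between-subject FC noise SD (Fisher-z).
#' @param sc_log0,sc_decay Log-SC mean at zero length and linear decay per mm.
#' @param sc_edge_sd SD of the per-edge log-SC intercept.
#' @param sc_dispersion Within-edge between-subject log-SC noise SD.
#' @param age_slope_sd_fc,age_slope_sd_sc SD of per-edge linear age slopes
#'   (Fisher-z per year; log-SC per year).
#' @param len_jitter_sd Log-scale per-subject jitter of streamline length.
#' @param tortuosity Streamline length = tortuosity x Euclidean distance.
#' @param mirror_jitter_sd Coordinate jitter (mm) between mirrored
#'   left/right region positions.
#' @param missing_fraction_cross_hemisphere Probability that a
#'   cross-hemisphere SC/LEN edge is undetected in a given subject.
#' @param effect_profile Planted per-bin alteration magnitudes in
#'   control-SD units (bin 1 first); its length sets the number of planted
#'   bins.
#' @param effect_duration_exponent Effect scales with
#'   `(duration / 30)^exponent`.
#' @param effect_direction +1 or -1: direction of the planted shift.
#' @param onset_duration_correlation Optional target correlation between
#'   age of onset and duration (e.g. -0.59); `NULL` leaves age and
#'   duration independent.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_controls = 70, n_patients = 40, n_right_focus = 29,
                       age_range = c(18, 71),
                       duration_mean = 21, duration_sd = 15,
                       duration_range = c(2, 50),
                       fc_base = 0.8, fc_lambda = 60, fc_edge_sd = 0.1,
                       fc_noise_sd = 0.15,
                       sc_log0 = 0, sc_decay = 0.03, sc_edge_sd = 0.5,
                       sc_dispersion = 0.4,
                       age_slope_sd_fc = 0.002, age_slope_sd_sc = 0.004,
                       len_jitter_sd = 0.03, tortuosity = 1.2,
                       mirror_jitter_sd = 1,
                       missing_fraction_cross_hemisphere = 0.4,
                       effect_profile = c(3, 2.25, 1.5, 0.75, 0),
                       effect_duration_exponent = 1,
                       effect_direction = -1,
                       onset_duration_correlation = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_controls > 0, cfg$n_patients > 0,
            cfg$n_right_focus >= 0, cfg$n_right_focus <= cfg$n_patients,
            all(cfg$effect_profile >= 0),
            cfg$missing_fraction_cross_hemisphere >= 0,
            cfg$missing_fraction_cross_hemisphere <= 1,
            cfg$effect_direction %in% c(-1, 1))
  structure(cfg, class = "sim_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# Mirrored 3-D region coordinates (mm). Left regions uniform in a
# hemisphere-sized box, right regions mirrored across x = 0 with jitter,
# bilateral regions on the midline.
simulate_coordinates <- function(atlas, mirror_jitter_sd) {
  n <- nrow(atlas)
  coords <- matrix(NA_real_, n, 3)
  pairs <- region_pairs(atlas)
  nl <- nrow(pairs)
  left <- cbind(stats::runif(nl, -70, -8), stats::runif(nl, -95, 60),
                stats::runif(nl, -45, 70))
  coords[pairs$left_id + 1L, ] <- left
  right <- left
  right[, 1] <- -right[, 1]
  right <- right + matrix(stats::rnorm(3 * nl, 0, mirror_jitter_sd), nl, 3)
  coords[pairs$right_id + 1L, ] <- right
  bil <- which(atlas$hemisphere == "bilateral")
  if (length(bil))
    coords[bil, ] <- cbind(0, seq(-30, -40, length.out = length(bil)), -30)
  coords
}

# Planted bin assignment: edges from the anterior hippocampus of one
# hemisphere to the other regions of that hemisphere (plus bilateral),
# ranked by latent streamline length, chunked into near-equal bins.
planted_bins <- function(atlas, len_base_edges, side, n_bins) {
  n <- nrow(atlas)
  seed_id <- anterior_hippocampus(atlas, side)
  others <- setdiff(hemisphere_regions(atlas, side), seed_id)
  cols <- edge_column(seed_id + 1L, others + 1L, n)
  lens <- len_base_edges[cols]
  ord <- order(lens, others)
  sizes <- chunk_sizes(length(cols), n_bins)
  bin <- integer(length(cols))
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  data.frame(region_id = others, edge_col = cols, len = lens, bin = bin)
}

#' Simulate a control/patient connectome cohort with planted ground truth
#'
#' Generates FC, SC and LEN connectomes for controls and patients under
#' the generative model described in [sim_config()]. Patient alterations
#' are planted on edges incident to the ipsilateral anterior hippocampus:
#' edges are ranked by latent streamline length into `length(effect_profile)`
#' bins, and FC (and log-SC) values are shifted by
#' `effect_direction * effect_profile[bin] * (duration/30)^exponent`
#' control SDs. The generator is fully determined by `config$seed`.
#'
#' @param config A [sim_config()].
#' @param atlas A region atlas (default [mtle_atlas()]).
#' @param modalities Modalities to realize (subsets skip unneeded noise
#'   generation; the latent structure and subject tables are identical
#'   for a given seed regardless).
#' @return A list with elements `cohort` (a [cohort()]) and `truth`
#'   (planted coordinates, latent lengths, per-edge age slopes, per-bin
#'   edge assignments per hemisphere, per-patient effect multipliers).
#' @export
simulate_cohort <- function(config = sim_config(), atlas = mtle_atlas(),
                            modalities = c("FC", "SC", "LEN")) {
  stopifnot(inherits(config, "sim_config"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  n <- nrow(atlas)
  emap <- edge_index_map(n)
  ne <- nrow(emap)

  # mirror-symmetrized per-edge noise: homotopic edge pairs share their
  # intercept/slope perturbations (bilaterally symmetric connectivity),
  # with marginal SD preserved
  mirror_perm <- edge_permutation(ipsi_contra_permutation(atlas, "right"), n)
  sym_edge_noise <- function(sd) {
    eps <- stats::rnorm(ne, 0, sd)
    out <- (eps + eps[mirror_perm]) / sqrt(2)
    self <- mirror_perm == seq_len(ne)
    out[self] <- eps[self]
    out
  }

  # latent structure and subject tables: one RNG stream, so they are
  # identical for a given seed regardless of which modalities are realized
  latent <- with_rng_seed(derive_seed(config$seed, "latent"), {
    coords <- simulate_coordinates(atlas, config$mirror_jitter_sd)
    len_base <- config$tortuosity *
      as.numeric(edge_vector(as.matrix(stats::dist(coords))))
    mu_fc <- config$fc_base * exp(-len_base / config$fc_lambda) +
      sym_edge_noise(config$fc_edge_sd)
    slope_fc <- sym_edge_noise(config$age_slope_sd_fc)
    mu_sc <- config$sc_log0 - config$sc_decay * len_base +
      sym_edge_noise(config$sc_edge_sd)
    slope_sc <- sym_edge_noise(config$age_slope_sd_sc)

    nc <- config$n_controls; np <- config$n_patients
    ids <- c(sprintf("ctrl_%03d", seq_len(nc)),
             sprintf("pat_%03d", seq_len(np)))
    dur <- rtrunc_norm(np, config$duration_mean, config$duration_sd,
                       config$duration_range[1], config$duration_range[2])
    lo <- config$age_range[1]; hi <- config$age_range[2]
    if (is.null(config$onset_duration_correlation)) {
      ages_c <- stats::runif(nc, lo, hi)
      ages_p <- pmin(hi, pmax(dur + 1, stats::runif(np, lo, hi)))
    } else {
      rho <- config$onset_duration_correlation
      zd <- scale(dur)[, 1]
      onset <- 28 + 12 * (rho * zd +
                            sqrt(max(0, 1 - rho^2)) * stats::rnorm(np))
      ages_c <- stats::runif(nc, lo, hi)
      ages_p <- pmin(hi, pmax(lo, pmax(onset, 1) + dur))
    }
    focus <- c(rep(NA_character_, nc),
               sample(c(rep("right", config$n_right_focus),
                        rep("left", np - config$n_right_focus))))
    list(coords = coords, len_base = len_base, mu_fc = mu_fc,
         slope_fc = slope_fc, mu_sc = mu_sc, slope_sc = slope_sc,
         ids = ids, dur = dur, ages = c(ages_c, ages_p), focus = focus)
  })

  nc <- config$n_controls; np <- config$n_patients
  ns <- nc + np
  subjects <- data.frame(
    subject_id = latent$ids,
    group = c(rep("control", nc), rep("patient", np)),
    age = latent$ages,
    duration = c(rep(NA_real_, nc), latent$dur),
    focus_side = latent$focus,
    stringsAsFactors = FALSE
  )
  dage <- latent$ages - 40
  hemi <- atlas$hemisphere
  cross <- (hemi[emap$i] == "left" & hemi[emap$j] == "right") |
    (hemi[emap$i] == "right" & hemi[emap$j] == "left")
  nb <- length(config$effect_profile)
  bins <- list(left = planted_bins(atlas, latent$len_base, "left", nb),
               right = planted_bins(atlas, latent$len_base, "right", nb))
  mult <- (latent$dur / 30)^config$effect_duration_exponent
  dirn <- config$effect_direction

  plant <- function(M, scale) {
    for (p in seq_len(np)) {
      row <- nc + p
      pb <- bins[[latent$focus[row]]]
      shift <- config$effect_profile[pb$bin] * mult[p]
      M[row, pb$edge_col] <- M[row, pb$edge_col] + dirn * shift * scale
    }
    M
  }
  missing_mask <- function() {
    if (config$missing_fraction_cross_hemisphere <= 0 || !any(cross))
      return(NULL)
    with_rng_seed(derive_seed(config$seed, "missing"), {
      matrix(stats::runif(ns * sum(cross)) <
               config$missing_fraction_cross_hemisphere, ns, sum(cross))
    })
  }
  drop_mask <- NULL

  edges <- list()
  if ("FC" %in% modalities) {
    FC <- with_rng_seed(derive_seed(config$seed, "FC"), {
      matrix(latent$mu_fc, ns, ne, byrow = TRUE) +
        outer(dage, latent$slope_fc) +
        matrix(stats::rnorm(ns * ne, 0, config$fc_noise_sd), ns, ne)
    })
    FC <- plant(FC, config$fc_noise_sd)
    rownames(FC) <- latent$ids
    edges$FC <- FC
  }
  if ("SC" %in% modalities) {
    LSC <- with_rng_seed(derive_seed(config$seed, "SC"), {
      matrix(latent$mu_sc, ns, ne, byrow = TRUE) +
        outer(dage, latent$slope_sc) +
        matrix(stats::rnorm(ns * ne, 0, config$sc_dispersion), ns, ne)
    })
    LSC <- plant(LSC, config$sc_dispersion)
    SC <- exp(LSC)
    if (is.null(drop_mask)) drop_mask <- missing_mask()
    if (!is.null(drop_mask)) SC[, cross][drop_mask] <- NA
    rownames(SC) <- latent$ids
    edges$SC <- SC
  }
  if ("LEN" %in% modalities) {
    LEN <- with_rng_seed(derive_seed(config$seed, "LEN"), {
      matrix(latent$len_base, ns, ne, byrow = TRUE) *
        exp(matrix(stats::rnorm(ns * ne, 0, config$len_jitter_sd), ns, ne))
    })
    if (is.null(drop_mask)) drop_mask <- missing_mask()
    if (!is.null(drop_mask)) LEN[, cross][drop_mask] <- NA
    rownames(LEN) <- latent$ids
    edges$LEN <- LEN
  }

  coh <- cohort(atlas, subjects, edges)
  truth <- list(
    coordinates = latent$coords,
    len_base = latent$len_base,
    fc_mu = latent$mu_fc, fc_slope = latent$slope_fc,
    sc_mu = latent$mu_sc, sc_slope = latent$slope_sc,
    bins = bins,
    effect_profile = config$effect_profile,
    effect_direction = dirn,
    patient_multiplier = stats::setNames(mult, latent$ids[nc + seq_len(np)]),
    config = config
  )
  list(cohort = coh, truth = truth)
}

#' Plant a rank-1 duration-linked component into a cohort
#'
#' Adds a sparse, sign-consistent edge pattern spanning the FC and SC
#' blocks, scaled per patient by a loading constructed (via a Gaussian
#' copula on duration ranks) to have Spearman correlation close to
#' `loading_vs_duration_rho` with duration of disease. This is the ground
#' truth against which the hybrid ICA stage is tested.
#'
#' @param cohort A [cohort()] containing patients with durations.
#' @param pattern_sparsity Fraction of FC and SC edges in the support.
#' @param loading_vs_duration_rho Target Spearman correlation with
#'   duration; `1` (or `-1`) makes the loading a monotone function of
#'   duration so the realized correlation is exact.
#' @param amplitude Pattern amplitude in control-SD units; `0` leaves the
#'   cohort unchanged, negative values are an error.
#' @param fc_noise_sd,sc_dispersion Control noise SDs used to convert
#'   amplitude to raw units (defaults match [sim_config()]).
#' @param seed Integer seed.
#' @return List with `cohort` (modified) and `truth` (pattern over FC and
#'   SC edges, per-patient loading, realized Spearman correlation).
#' @export
plant_ica_component <- function(cohort, pattern_sparsity = 0.05,
                                loading_vs_duration_rho = 0.6,
                                amplitude = 1,
                                fc_noise_sd = 0.15, sc_dispersion = 0.4,
                                seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  pat <- cohort_subjects(cohort, "patient")
  if (nrow(pat) < 2) stop("cohort must contain patients with durations")
  with_rng_seed(derive_seed(seed, "plant-ica"), {
    ne <- ncol(cohort$edges$FC)
    k <- max(1L, round(pattern_sparsity * ne))
    sup_fc <- sample.int(ne, k)
    sup_sc <- sample.int(ne, k)
    pat_fc <- numeric(ne); pat_sc <- numeric(ne)
    pat_fc[sup_fc] <- stats::rnorm(k)
    pat_sc[sup_sc] <- stats::rnorm(k)

    dur <- pat$duration
    npat <- length(dur)
    rho <- loading_vs_duration_rho
    zd <- stats::qnorm((rank(dur, ties.method = "average") - 0.375) /
                         (npat + 0.25))
    if (abs(rho) >= 1) {
      loading <- sign(rho) * zd
    } else {
      loading <- rho * zd + sqrt(1 - rho^2) * stats::rnorm(npat)
    }
    loading <- as.numeric(scale(loading))
    realized <- suppressWarnings(
      stats::cor(loading, dur, method = "spearman"))

    if (amplitude > 0) {
      # the pattern lives in ipsi/contra space: right-focus patients
      # receive it through the (involutory) left/right edge swap so the
      # pattern aligns across patients after the ipsi/contra transform
      n <- nrow(cohort$atlas)
      swap <- edge_permutation(ipsi_contra_permutation(cohort$atlas, "right"),
                               n)
      rows <- match(pat$subject_id, rownames(cohort$edges$FC))
      for (ix in seq_along(rows)) {
        pfc <- if (pat$focus_side[ix] == "right") pat_fc[swap] else pat_fc
        psc <- if (pat$focus_side[ix] == "right") pat_sc[swap] else pat_sc
        r <- rows[ix]
        cohort$edges$FC[r, ] <- cohort$edges$FC[r, ] +
          amplitude * fc_noise_sd * loading[ix] * pfc
        if (!is.null(cohort$edges$SC))
          cohort$edges$SC[r, ] <- cohort$edges$SC[r, ] *
            exp(amplitude * sc_dispersion * loading[ix] * psc)
      }
    }
    truth <- list(pattern_fc = pat_fc, pattern_sc = pat_sc,
                  loading = stats::setNames(loading, pat$subject_id),
                  target_rho = rho, realized_rho = realized,
                  amplitude = amplitude)
    list(cohort = cohort, truth = truth)
  })
}
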