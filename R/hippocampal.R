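#' Configuration for the permutation-subsampled Mahalanobis statistic
#'
#' Full-scale defaults: within each bin, 500 random
#' subsets of 7 edges (out of the ~10-11 in the bin), each crossed with
#' 500 random subsets of 50 of the 70 controls; a control subset is
#' discarded when fewer than 45 controls have all seven edges, and an
#' edge subset is skipped for a patient missing any of the seven edges.
#' The final statistic is the mean over retained pairs. For desk-scale
#' testing, reduced counts (e.g. 100 x 100) give the same group-level
#' behavior at a fraction of the cost.
#'
#' @param k_subset Edges drawn per permutation.
#' @param n_edge_permutations Outer loop count.
#' @param n_control_permutations Inner loop count.
#' @param n_controls_drawn Controls drawn per inner permutation.
#' @param min_controls_complete Minimum complete controls to retain a draw.
#' @param shrinkage `"ledoit-wolf"` or `"fixed"`.
#' @param lambda Fixed shrinkage intensity (used when `shrinkage = "fixed"`).
#' @param squared Report the quadratic form (default) or its square root.
#' @param seed Integer seed; permutation draws derive deterministically
#'   from `(seed, modality, hemisphere, bin)` and are shared across
#'   patients.
#' @return A list of class `mahal_config`.
#' @export
mahal_config <- function(k_subset = 7, n_edge_permutations = 500,
                         n_control_permutations = 500,
                         n_controls_drawn = 50, min_controls_complete = 45,
                         shrinkage = c("ledoit-wolf", "fixed"),
                         lambda = 0.2, squared = TRUE, seed = 1) {
  shrinkage <- match.arg(shrinkage)
  stopifnot(k_subset >= 1, n_edge_permutations >= 1,
            n_control_permutations >= 1,
            min_controls_complete <= n_controls_drawn)
  structure(list(k_subset = k_subset,
                 n_edge_permutations = n_edge_permutations,
                 n_control_permutations = n_control_permutations,
                 n_controls_drawn = n_controls_drawn,
                 min_controls_complete = min_controls_complete,
                 shrinkage = shrinkage, lambda = lambda,
                 squared = squared, seed = seed),
            class = "mahal_config")
}

# Gather the (seed region, other region) edge values for a set of regions
# from an edge-major value matrix. Returns subjects x regions matrix.
seed_edge_values <- function(edges, seed_region, regions, n_regions) {
  cols <- edge_column(seed_region + 1L, regions + 1L, n_regions)
  out <- edges[, cols, drop = FALSE]
  colnames(out) <- regions
  out
}

#' Per-patient, per-bin Mahalanobis deviation of hippocampal networks
#'
#' For each hemisphere, takes the age-regressed (`_res`) edge values
#' between that hemisphere's anterior hippocampus and the binned regions,
#' and computes each patient's permutation-subsampled Mahalanobis
#' deviation from the controls, bin by bin. Left/right results are then
#' labeled ipsilateral/contralateral according to each patient's focus
#' side. Controls always enter in native left/right orientation.
#'
#' @param cohort An age-normalized [cohort()] (see [normalize_cohort()]).
#' @param binnings Named list with `left` and `right` [bin_edges()]
#'   results (e.g. from [hippocampal_binnings()]).
#' @param modality `"FC"` or `"SC"` (the `_res` modality is used).
#' @param config A [mahal_config()].
#' @return An object of class `mahal_profiles`: a data frame with columns
#'   `patient_id`, `modality`, `side` (`ipsi`/`contra`), `bin`, `M`
#'   (pooled mean over retained pairs), `M_outer` (mean of per-edge-subset
#'   means), `n_pairs`, `n_outer_used`, `n_outer_skipped`, plus attribute
#'   `n_inner_discarded` (per hemisphere/bin control-side discards).
#' @export
hippocampal_profiles <- function(cohort, binnings, modality = c("FC", "SC"),
                                 config = mahal_config()) {
  modality <- match.arg(modality)
  stopifnot(inherits(cohort, "cohort"), inherits(config, "mahal_config"))
  res_mod <- paste0(modality, "_res")
  if (is.null(cohort$edges[[res_mod]]))
    stop("cohort lacks ", res_mod, "; run normalize_cohort() first")
  atlas <- cohort$atlas
  n <- nrow(atlas)
  ctrl <- cohort_subjects(cohort, "control")
  pats <- cohort_subjects(cohort, "patient")
  E <- cohort$edges[[res_mod]]
  rows <- list()
  discards <- list()
  for (side in c("left", "right")) {
    binning <- binnings[[side]]
    seed_region <- anterior_hippocampus(atlas, side)
    for (b in seq_along(binning)) {
      regions <- binning[[b]]
      if (length(regions) < config$k_subset)
        stop("bin ", b, " has fewer regions than k_subset")
      C <- seed_edge_values(E[ctrl$subject_id, , drop = FALSE],
                            seed_region, regions, n)
      P <- seed_edge_values(E[pats$subject_id, , drop = FALSE],
                            seed_region, regions, n)
      no <- config$n_edge_permutations
      ni <- config$n_control_permutations
      draws <- with_rng_seed(
        derive_seed(config$seed, modality, side, b), {
          es <- t(replicate(no, sample.int(length(regions),
                                           config$k_subset)))
          cs <- t(replicate(no * ni, sample.int(nrow(C),
                                                config$n_controls_drawn)))
          list(es = es, cs = cs)
        })
      out <- cpp_perm_mahal(C, P, draws$es, draws$cs, ni,
                            config$min_controls_complete,
                            if (config$shrinkage == "ledoit-wolf") 0L else 1L,
                            config$lambda, config$squared)
      hemi_side <- ifelse(pats$focus_side == side, "ipsi", "contra")
      rows[[paste(side, b)]] <- data.frame(
        patient_id = pats$subject_id, modality = modality,
        side = hemi_side, bin = b,
        M = out$M, M_outer = out$M_outer,
        n_pairs = out$n_pairs, n_outer_used = out$n_outer_used,
        n_outer_skipped = out$n_outer_skipped,
        stringsAsFactors = FALSE)
      discards[[paste(side, b)]] <- out$n_inner_discarded
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_inner_discarded = unlist(discards),
            class = c("mahal_profiles", "data.frame"))
}

#' Patients-by-bins matrix of M values from a profiles data frame
#'
#' @param profiles A [hippocampal_profiles()] result.
#' @param side `"ipsi"` or `"contra"`.
#' @param statistic `"M"` (pooled mean) or `"M_outer"`.
#' @return Numeric matrix, rows = patients, columns = bins.
#' @export
profiles_matrix <- function(profiles, side = c("ipsi", "contra"),
                            statistic = c("M", "M_outer")) {
  side <- match.arg(side)
  statistic <- match.arg(statistic)
  d <- profiles[profiles$side == side, ]
  ids <- unique(d$patient_id)
  bins <- sort(unique(d$bin))
  m <- matrix(NA_real_, length(ids), length(bins),
              dimnames = list(ids, paste0("bin", bins)))
  m[cbind(match(d$patient_id, ids), match(d$bin, bins))] <- d[[statistic]]
  m
}

rm_anova <- function(M) {
  np <- nrow(M); nb <- ncol(M)
  d <- data.frame(M = as.vector(M),
                  bin = factor(rep(seq_len(nb), each = np)),
                  subject = factor(rep(seq_len(np), nb)))
  fit <- stats::aov(M ~ bin + Error(subject / bin), data = d)
  tab <- summary(fit)[["Error: subject:bin"]][[1]]
  rn <- trimws(rownames(tab))
  list(F = tab[rn == "bin", "F value"], df1 = tab[rn == "bin", "Df"],
       df2 = tab[rn == "Residuals", "Df"], p = tab[rn == "bin", "Pr(>F)"])
}

#' Three-criterion distance-gradient hypothesis test
#'
#' Tests whether the per-patient deviation M decreases across
#' distance-ranked bins (bin 1 > bin 2 > ...): (1) a one-way repeated
#' measures ANOVA with bin as the within-subject factor must reach the
#' stated significance threshold; (2) the group means must decrease
#' monotonically from bin 1 to the last bin; (3) uncorrected two-sided
#' paired t tests must show no higher-index bin significantly greater
#' than a lower-index bin at 0.05. The verdict is true only if all three
#' hold.
#'
#' @param M Patients-by-bins matrix of deviation values (or a
#'   [hippocampal_profiles()] object, in which case the ipsilateral pooled
#'   M matrix is used). Patients with undefined bins are dropped with a
#'   warning; at least 3 complete patients are required.
#' @param alpha Repeated-measures ANOVA significance threshold
#'   (Bonferroni over topologies: 0.0125 for a four-topology family,
#'   0.0167 for three).
#' @return An object of class `gradient_test`: ANOVA F/df/p, per-bin
#'   means, `monotone_decrease`, the pairwise paired-t p matrix
#'   (uncorrected), the mean-difference sign matrix, and `verdict`.
#' @export
gradient_test <- function(M, alpha = 0.0125) {
  if (inherits(M, "mahal_profiles")) M <- profiles_matrix(M, "ipsi")
  M <- as.matrix(M)
  complete <- stats::complete.cases(M)
  if (any(!complete)) {
    warning(sum(!complete), " patient(s) with undefined bins dropped")
    M <- M[complete, , drop = FALSE]
  }
  if (nrow(M) < 3) stop("need at least 3 complete patients")
  nb <- ncol(M)
  anova_res <- rm_anova(M)
  means <- colMeans(M)
  monotone <- all(diff(means) < 0)
  pmat <- matrix(NA_real_, nb, nb)
  violation <- FALSE
  for (a in seq_len(nb - 1)) {
    for (b in (a + 1):nb) {
      tt <- stats::t.test(M[, a], M[, b], paired = TRUE)
      pmat[a, b] <- pmat[b, a] <- tt$p.value
      if (!is.na(tt$p.value) && tt$p.value < 0.05 && means[b] > means[a])
        violation <- TRUE
    }
  }
  verdict <- !is.na(anova_res$p) && anova_res$p <= alpha &&
    monotone && !violation
  structure(list(F = anova_res$F, df1 = anova_res$df1, df2 = anova_res$df2,
                 p = anova_res$p, bin_means = means,
                 monotone_decrease = monotone, pairwise_p = pmat,
                 higher_bin_greater = violation, alpha = alpha,
                 n_patients = nrow(M), verdict = verdict),
            class = "gradient_test")
}

#' @export
print.gradient_test <- function(x, ...) {
  cat(sprintf("<gradient_test> F(%d, %d) = %.3f, p = %.4g (alpha %.4g)\n",
              x$df1, x$df2, x$F, x$p, x$alpha))
  cat(" bin means:", paste(sprintf("%.3f", x$bin_means), collapse = ", "), "\n")
  cat(" monotone decrease:", x$monotone_decrease,
      "| verdict:", x$verdict, "\n")
  invisible(x)
}

mixed_anova_interaction <- function(M, group) {
  np <- nrow(M); nb <- ncol(M)
  d <- data.frame(M = as.vector(M),
                  bin = factor(rep(seq_len(nb), each = np)),
                  subject = factor(rep(seq_len(np), nb)),
                  group = factor(rep(group, nb)))
  fit <- stats::aov(M ~ group * bin + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(tab))
  ix <- which(rn == "group:bin")
  list(F = tab[ix, "F value"], df1 = tab[ix, "Df"],
       df2 = tab[rn == "Residuals", "Df"], p = tab[ix, "Pr(>F)"])
}

#' Duration-group analysis of the deviation gradient
#'
#' Splits patients into duration-of-disease groups at the stated
#' boundaries (defaults: short <= 10 years, medium 11-30, long > 30),
#' runs the [gradient_test()] within each group with at least 3 complete
#' patients (empty/small groups are skipped with a warning), and reports
#' the bin-by-group interaction from a mixed ANOVA with group as
#' between-subject factor.
#'
#' @param M Patients-by-bins matrix (rows named by patient id).
#' @param durations Numeric vector of durations, aligned with rows of `M`.
#' @param boundaries Two increasing group boundaries in years.
#' @param alpha Per-group ANOVA threshold.
#' @return List with `groups` (factor), `per_group` (named list of
#'   [gradient_test()] results), and `interaction` (mixed-ANOVA F, dfs, p).
#' @export
duration_group_analysis <- function(M, durations, boundaries = c(10, 30),
                                    alpha = 0.05) {
  M <- as.matrix(M)
  stopifnot(length(durations) == nrow(M), length(boundaries) == 2,
            boundaries[1] < boundaries[2])
  groups <- cut(durations, c(-Inf, boundaries, Inf),
                labels = c("short", "medium", "long"))
  per_group <- list()
  for (g in levels(groups)) {
    Mg <- M[groups == g, , drop = FALSE]
    Mg <- Mg[stats::complete.cases(Mg), , drop = FALSE]
    if (nrow(Mg) < 3) {
      warning("duration group '", g, "' has fewer than 3 patients; skipped")
      next
    }
    per_group[[g]] <- gradient_test(Mg, alpha = alpha)
  }
  complete <- stats::complete.cases(M)
  interaction <- if (nlevels(droplevels(groups[complete])) >= 2)
    mixed_anova_interaction(M[complete, , drop = FALSE], groups[complete])
  else NULL
  list(groups = groups, boundaries = boundaries,
       per_group = per_group, interaction = interaction)
}
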