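#' Configuration for the hybrid FC-SC connectome ICA
#'
#' Defaults: PCA retaining 90% of
#' variance, FastICA run 40 times, components from different runs merged
#' when their Pearson correlation exceeds 0.8, component weights compared
#' to duration of disease by Spearman correlation, and component
#' connectomes thresholded at +/-0.55 (FC) and +/-0.175 (SC) before the
#' weighted-degree projection.
#'
#' @param n_runs Number of FastICA restarts.
#' @param merge_r_threshold Pearson threshold for merging components.
#' @param pca_variance Fraction of variance the PCA must retain.
#' @param fc_threshold,sc_threshold Component thresholds before degree.
#' @param max_missing_fraction SC edge columns missing in more than this
#'   fraction of patients are dropped from the joint matrix.
#' @param min_frequency Only merged components identified in at least this
#'   fraction of runs are eligible for duration selection; components seen
#'   in a single run are dominated by the rotational ambiguity of the
#'   near-Gaussian directions and are not replicable signal.
#' @param seed Integer seed; run `r` uses the stream `(seed, "ica", r)`.
#' @return A list of class `ica_config`.
#' @export
ica_config <- function(n_runs = 40, merge_r_threshold = 0.8,
                       pca_variance = 0.90, fc_threshold = 0.55,
                       sc_threshold = 0.175, max_missing_fraction = 0.1,
                       min_frequency = 0.5, seed = 1) {
  stopifnot(n_runs >= 1, merge_r_threshold > 0, merge_r_threshold <= 1,
            pca_variance > 0, pca_variance <= 1,
            fc_threshold > 0, sc_threshold > 0,
            min_frequency >= 0, min_frequency <= 1)
  structure(list(n_runs = n_runs, merge_r_threshold = merge_r_threshold,
                 pca_variance = pca_variance, fc_threshold = fc_threshold,
                 sc_threshold = sc_threshold,
                 max_missing_fraction = max_missing_fraction,
                 min_frequency = min_frequency, seed = seed),
            class = "ica_config")
}

#' Joint patients-by-edges FC/SC matrix in ipsi/contra orientation
#'
#' Concatenates each patient's `FC_corr` and `SC_corr` edge vectors (in
#' SD units from age-matched controls) after transforming left/right to
#' ipsilateral/contralateral with respect to the seizure focus. SC edges
#' missing in more than `max_missing_fraction` of patients are dropped;
#' remaining missing entries are imputed as 0 (the age-expected control
#' level).
#'
#' @param cohort An age-normalized [cohort()].
#' @param max_missing_fraction Column drop threshold for SC edges.
#' @return List with `X` (patients x columns matrix) and `edge_map`
#'   (data frame: `col`, `modality`, `i`, `j` -- 1-based ipsi/contra
#'   region indices).
#' @export
build_joint_matrix <- function(cohort, max_missing_fraction = 0.1) {
  stopifnot(inherits(cohort, "cohort"))
  for (mod in c("FC_corr", "SC_corr"))
    if (is.null(cohort$edges[[mod]]))
      stop("cohort lacks ", mod, "; run normalize_cohort() first")
  pats <- cohort_subjects(cohort, "patient")
  if (nrow(pats) == 0) stop("cohort has no patients")
  n <- nrow(cohort$atlas)
  swap <- edge_permutation(ipsi_contra_permutation(cohort$atlas, "right"), n)
  gather <- function(mod) {
    E <- cohort$edges[[mod]][pats$subject_id, , drop = FALSE]
    flip <- pats$focus_side == "right"
    E[flip, ] <- E[flip, swap, drop = FALSE]
    E
  }
  FCm <- gather("FC_corr")
  SCm <- gather("SC_corr")
  keep_sc <- colMeans(is.na(SCm)) <= max_missing_fraction
  SCm <- SCm[, keep_sc, drop = FALSE]
  SCm[is.na(SCm)] <- 0
  FCm[is.na(FCm)] <- 0
  emap <- edge_index_map(n)
  edge_map <- rbind(
    data.frame(modality = "FC", i = emap$i, j = emap$j),
    data.frame(modality = "SC", i = emap$i[keep_sc], j = emap$j[keep_sc]))
  edge_map$col <- seq_len(nrow(edge_map))
  X <- cbind(FCm, SCm)
  colnames(X) <- NULL
  list(X = X, edge_map = edge_map, patients = pats)
}

# FastICA (symmetric orthogonalization, logcosh contrast) on whitened
# data Z (observations x q). Directions dominated by near-Gaussian noise
# have no stable optimum, so like the reference implementations the
# estimate at the iteration cap is returned when the tolerance is not
# reached earlier; NULL is returned only on numerical failure.
fastica_core <- function(Z, maxit = 200, tol = 1e-4) {
  q <- ncol(Z)
  N <- nrow(Z)
  W <- qr.Q(qr(matrix(stats::rnorm(q * q), q, q)))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), q) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(maxit)) {
    WX <- Z %*% t(W)
    G <- tanh(WX)
    gprime <- colMeans(1 - G^2)
    W1 <- t(crossprod(Z, G) / N) - diag(gprime, q) %*% W
    if (!all(is.finite(W1))) return(NULL)
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Run the hybrid connectome ICA
#'
#' Centers the joint matrix column-wise, reduces dimensionality by PCA to
#' the smallest number of components whose cumulative explained variance
#' reaches `pca_variance`, and runs FastICA that many times with
#' different seeded initializations. Components are returned in edge
#' space (unit variance over edges) with least-squares patient weights.
#' Non-convergent runs are dropped with a warning.
#'
#' @param joint A [build_joint_matrix()] result.
#' @param config An [ica_config()].
#' @return An object of class `ica_runs`: list with `components` (edges x
#'   component matrix, runs concatenated), `weights` (patients x
#'   component), `run` (run index per component), `n_comp` (PCA
#'   dimension), `n_runs_failed`.
#' @export
run_hybrid_ica <- function(joint, config = ica_config()) {
  X <- joint$X
  if (nrow(X) < 3) stop("need at least 3 patients")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  q <- which(cumsum(ev) / sum(ev) >= config$pca_variance)[1]
  q <- max(2L, min(q, nrow(X) - 1L))
  # edge-space principal coordinates, whitened (rows = edges)
  P <- sv$v[, seq_len(q), drop = FALSE] %*% diag(sv$d[seq_len(q)], q)
  Pc <- sweep(P, 2, colMeans(P))
  ew <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  Z <- Pc %*% ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-12)), q)

  comps <- list(); wts <- list(); run_ix <- integer(0)
  failed <- 0L
  for (r in seq_len(config$n_runs)) {
    W <- with_rng_seed(derive_seed(config$seed, "ica", r),
                       fastica_core(Z))
    if (is.null(W)) {
      warning("FastICA run ", r, " failed numerically; dropped")
      failed <- failed + 1L
      next
    }
    S <- Z %*% t(W)                         # edges x q, unit variance
    A <- Xc %*% S %*% solve(crossprod(S))   # patients x q weights
    # scale convention: weights have unit SD across patients, so component
    # values are in data units (control SDs) per 1-SD weight variation
    sdA <- apply(A, 2, stats::sd)
    sdA[sdA == 0] <- 1
    S <- S * rep(sdA, each = nrow(S))
    A <- sweep(A, 2, sdA, "/")
    comps[[length(comps) + 1L]] <- S
    wts[[length(wts) + 1L]] <- A
    run_ix <- c(run_ix, rep(r, q))
  }
  if (!length(comps)) stop("all FastICA runs failed to converge")
  structure(list(components = do.call(cbind, comps),
                 weights = do.call(cbind, wts),
                 run = run_ix, n_comp = q,
                 n_runs = config$n_runs, n_runs_failed = failed,
                 edge_map = joint$edge_map, patients = joint$patients),
            class = "ica_runs")
}

#' Merge ICA components across runs
#'
#' Components are sign-aligned and grouped by connected components of the
#' graph linking any two with absolute Pearson correlation above the
#' threshold (an order-independent version of pairwise merging); each
#' group is averaged in edge space and weight space. Grouping is repeated
#' on the merged set until no pair exceeds the threshold, so the merged
#' components are pairwise below it by construction. Identification
#' frequency is the number of distinct runs contributing to a group
#' divided by the configured number of runs.
#'
#' @param runs An [run_hybrid_ica()] result.
#' @param r_threshold Merge threshold (Pearson r).
#' @return An object of class `ica_result`: `components` (edges x merged),
#'   `weights` (patients x merged), `frequency` (per merged component),
#'   `n_members`, plus the edge map and patient table.
#' @export
merge_components <- function(runs, r_threshold = 0.8) {
  S <- runs$components
  A <- runs$weights
  run_of <- runs$run
  repeat {
    R <- suppressWarnings(stats::cor(S))
    R[is.na(R)] <- 0
    adj <- abs(R) > r_threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    if (max(memb) == ncol(S)) break  # no merges left
    newS <- matrix(0, nrow(S), max(memb))
    newA <- matrix(0, nrow(A), max(memb))
    new_runs <- vector("list", max(memb))
    for (gix in seq_len(max(memb))) {
      members <- which(memb == gix)
      ref <- members[1]
      sgn <- sign(R[ref, members]); sgn[sgn == 0] <- 1
      newS[, gix] <- rowMeans(S[, members, drop = FALSE] *
                                rep(sgn, each = nrow(S)))
      newA[, gix] <- rowMeans(A[, members, drop = FALSE] *
                                rep(sgn, each = nrow(A)))
      new_runs[[gix]] <- unique(unlist(run_of[members]))
    }
    S <- newS; A <- newA; run_of <- new_runs
    if (ncol(S) == 1) break
  }
  if (!is.list(run_of)) run_of <- as.list(run_of)
  frequency <- vapply(run_of, function(r) length(unique(r)), 0L) /
    runs$n_runs
  structure(list(components = S, weights = A, frequency = frequency,
                 n_members = vapply(run_of, length, 0L),
                 contributing_runs = run_of,
                 edge_map = runs$edge_map, patients = runs$patients),
            class = "ica_result")
}

#' Identify duration-related components
#'
#' Spearman-correlates each merged component's patient weights with
#' duration of disease. Only components identified in at least
#' `min_frequency` of the runs are eligible: a component seen in a single
#' run reflects the rotational ambiguity of near-Gaussian directions
#' rather than replicable structure, and testing every singleton would
#' guarantee spurious selections. Components (and weights) are
#' sign-flipped so the correlation is non-negative (the ICA sign is
#' unidentifiable). Eligible components are selected at the
#' Bonferroni-corrected level `alpha / n_eligible`, so the family-wise
#' false-selection rate stays near `alpha` however many replicable
#' components a decomposition yields; the primary component is the
#' selected one with the largest correlation.
#'
#' @param result An [merge_components()] result.
#' @param durations Numeric vector aligned with the patient table (default
#'   taken from it).
#' @param min_frequency Minimum identification frequency for eligibility.
#' @param alpha Family-wise selection level.
#' @return The `ica_result` with added fields `duration_rho`,
#'   `duration_p` (`NA` for ineligible components), `selected` (indices,
#'   possibly empty) and `primary` (index or `NA`).
#' @export
select_duration_component <- function(result, durations = NULL,
                                      min_frequency = 0.5, alpha = 0.05) {
  stopifnot(inherits(result, "ica_result"))
  if (is.null(durations)) durations <- result$patients$duration
  if (sum(!is.na(durations)) < 5) stop("need at least 5 patients with durations")
  k <- ncol(result$weights)
  rho <- p <- rep(NA_real_, k)
  eligible <- result$frequency >= min_frequency
  for (ix in which(eligible)) {
    ct <- suppressWarnings(stats::cor.test(result$weights[, ix], durations,
                                           method = "spearman", exact = FALSE))
    if (!is.na(ct$estimate) && ct$estimate < 0) {
      result$weights[, ix] <- -result$weights[, ix]
      result$components[, ix] <- -result$components[, ix]
      ct$estimate <- -ct$estimate
    }
    rho[ix] <- ct$estimate
    p[ix] <- ct$p.value
  }
  selected <- which(!is.na(p) & p < alpha / max(1L, sum(eligible)))
  result$duration_rho <- rho
  result$duration_p <- p
  result$selected <- selected
  result$primary <- if (length(selected)) selected[which.max(rho[selected])]
                    else NA_integer_
  result
}

#' Thresholded weighted-degree projection of a component
#'
#' Reshapes a component's FC and SC blocks into symmetric region-by-region
#' matrices, zeroes entries below the modality threshold in absolute
#' value, and computes each region's weighted degree: the signed sum of
#' surviving incident edge values ("net connectivity"; an absolute-value
#' variant is available). Achieved edge density after thresholding is
#' reported.
#'
#' @param result An `ica_result`.
#' @param component Component index (default the primary selected one).
#' @param fc_threshold,sc_threshold Absolute-value thresholds.
#' @param degree `"signed"` (net connectivity) or `"absolute"`.
#' @return List with `fc_degree`, `sc_degree` (length-N vectors in
#'   ipsi/contra region order), `fc_density`, `sc_density`, and the
#'   thresholded matrices.
#' @export
degree_projection <- function(result, component = result$primary,
                              fc_threshold = 0.55, sc_threshold = 0.175,
                              degree = c("signed", "absolute")) {
  degree <- match.arg(degree)
  stopifnot(inherits(result, "ica_result"), !is.na(component))
  v <- result$components[, component]
  em <- result$edge_map
  n <- max(em$j)
  mats <- list()
  dens <- list()
  for (mod in c("FC", "SC")) {
    thr <- if (mod == "FC") fc_threshold else sc_threshold
    sel <- em$modality == mod
    m <- matrix(0, n, n)
    m[cbind(em$i[sel], em$j[sel])] <- v[em$col[sel]]
    m <- m + t(m)
    m[abs(m) < thr] <- 0
    mats[[mod]] <- m
    dens[[mod]] <- sum(m[upper.tri(m)] != 0) / (n * (n - 1) / 2)
  }
  deg <- function(m) if (degree == "signed") rowSums(m) else rowSums(abs(m))
  list(fc_degree = deg(mats$FC), sc_degree = deg(mats$SC),
       fc_density = dens$FC, sc_density = dens$SC,
       fc_matrix = mats$FC, sc_matrix = mats$SC)
}

#' Threshold achieving a target edge density for a component block
#'
#' Alternative to the fixed absolute thresholds: returns the
#' absolute-value cutoff at which the requested fraction of a
#' component's FC or SC edges survives, so
#' `degree_projection(..., fc_threshold = density_threshold(...))`
#' realizes an approximate target density (e.g. 20%).
#'
#' @param result An `ica_result`.
#' @param component Component index.
#' @param modality `"FC"` or `"SC"`.
#' @param density Target fraction of surviving edges.
#' @return A positive scalar threshold.
#' @export
density_threshold <- function(result, component, modality = c("FC", "SC"),
                              density = 0.2) {
  modality <- match.arg(modality)
  stopifnot(density > 0, density < 1)
  em <- result$edge_map
  v <- abs(result$components[em$col[em$modality == modality], component])
  as.numeric(stats::quantile(v, 1 - density, names = FALSE))
}

#' Hemisphere-averaged model distances for ipsi/contra regions
#'
#' The ICA degree vectors live in ipsi/contra region order while the
#' healthy-brain models are built in native left/right hemispheres; each
#' region therefore receives the average of its left- and
#' right-hemisphere distances to the anterior hippocampus. The seed
#' region slots themselves get `NA`.
#'
#' @param topology A [build_topology()] result.
#' @param atlas The region atlas.
#' @return Numeric vector of length N (model distance per region slot).
#' @export
model_distance_by_region <- function(topology, atlas) {
  n <- nrow(atlas)
  out <- rep(NA_real_, n)
  if (topology$kind == "RSN") {
    out <- as.numeric(topology$membership)
    out[atlas$is_anterior_hippocampus] <- NA
    return(out)
  }
  mvl <- model_vector(topology, anterior_hippocampus(atlas, "left"))
  mvr <- model_vector(topology, anterior_hippocampus(atlas, "right"))
  pairs <- region_pairs(atlas)
  base_by_id <- rep(NA_character_, n)
  base_by_id[pairs$left_id + 1L] <- pairs$base
  base_by_id[pairs$right_id + 1L] <- pairs$base
  bil <- atlas$hemisphere == "bilateral"
  base_by_id[bil] <- atlas$name[bil]
  val_l <- stats::setNames(mvl$value, base_by_id[mvl$region_id + 1L])
  val_r <- stats::setNames(mvr$value, base_by_id[mvr$region_id + 1L])
  for (rix in seq_len(n)) {
    if (atlas$is_anterior_hippocampus[rix]) next
    base <- base_by_id[rix]
    vals <- c(val_l[names(val_l) == base], val_r[names(val_r) == base])
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[rix] <- mean(vals)
  }
  out
}

#' Correlate a degree vector with the healthy-brain distance models
#'
#' Pearson correlation for the matrix-valued models (`LEN`, `SC`, `FC`)
#' and Spearman for the ordinal `RSN` model; regions with undefined model
#' distance are excluded pairwise. The Bonferroni threshold for the
#' four-model family (0.0125) is recorded alongside each p value.
#'
#' @param degree Length-N numeric vector in ipsi/contra region order.
#' @param topologies Named list of [build_topology()] results.
#' @param atlas The region atlas.
#' @param alpha Family-corrected significance threshold.
#' @return Data frame with columns `model`, `method`, `n`, `r`, `p`,
#'   `significant`.
#' @export
correlate_with_models <- function(degree, topologies, atlas, alpha = 0.0125) {
  rows <- lapply(names(topologies), function(kind) {
    md <- model_distance_by_region(topologies[[kind]], atlas)
    ok <- !is.na(md) & !is.na(degree)
    if (sum(ok) < 5) stop("fewer than 5 paired regions for model ", kind)
    method <- if (topologies[[kind]]$kind == "RSN") "spearman" else "pearson"
    if (stats::sd(degree[ok]) == 0) {
      data.frame(model = kind, method = method, n = sum(ok),
                 r = NA_real_, p = NA_real_, significant = NA)
    } else {
      ct <- suppressWarnings(stats::cor.test(degree[ok], md[ok],
                                             method = method, exact = FALSE))
      data.frame(model = kind, method = method, n = sum(ok),
                 r = unname(ct$estimate), p = ct$p.value,
                 significant = ct$p.value < alpha)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' End-to-end whole-brain ICA analysis
#'
#' Convenience wrapper: joint matrix, ICA runs, merging, duration
#' selection, degree projection of the primary component (if any), and
#' model correlations.
#'
#' @param cohort An age-normalized [cohort()].
#' @param topologies Named list of topologies (for model correlations).
#' @param config An [ica_config()].
#' @return List with `result` (selected `ica_result`), `degree`
#'   (projection or `NULL`), `model_correlations` (FC and SC data frames
#'   or `NULL` when no component is selected).
#' @export
wholebrain_analysis <- function(cohort, topologies, config = ica_config()) {
  joint <- build_joint_matrix(cohort, config$max_missing_fraction)
  runs <- run_hybrid_ica(joint, config)
  merged <- merge_components(runs, config$merge_r_threshold)
  merged <- select_duration_component(merged,
                                      min_frequency = config$min_frequency)
  if (is.na(merged$primary))
    return(list(result = merged, degree = NULL, model_correlations = NULL))
  proj <- degree_projection(merged, merged$primary,
                            config$fc_threshold, config$sc_threshold)
  list(result = merged, degree = proj,
       model_correlations = list(
         FC = correlate_with_models(proj$fc_degree, topologies, cohort$atlas),
         SC = correlate_with_models(proj$sc_degree, topologies, cohort$atlas)))
}
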