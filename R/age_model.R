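#' Fit the edge-wise linear age model on controls
#'
#' For every edge, ordinary least squares of the edge value against age is
#' fitted across the control subjects in which the edge is present. For
#' `SC` the values are natural-log transformed first (zeros/undetected
#' edges stay missing rather than receiving a pseudocount). The root mean
#' squared error of each fit is stored for SD-standardization; by default
#' it uses the biased 1/n denominator (switchable to 1/(n-2)).
#'
#' Edges present in fewer than 3 controls are flagged unfittable; edges
#' whose fit is exact (RMSE 0) are flagged degenerate and cannot be
#' standardized.
#'
#' @param cohort A [cohort()]; only its controls are used.
#' @param modality `"FC"` or `"SC"`.
#' @param rmse_denominator `"n"` (default) or `"n-2"`.
#' @return An object of class `edge_age_model` with per-edge `slope`,
#'   `intercept`, `rmse`, `n` (controls used), and logical flags
#'   `unfittable` and `degenerate`.
#' @export
fit_age_model <- function(cohort, modality = c("FC", "SC"),
                          rmse_denominator = c("n", "n-2")) {
  modality <- match.arg(modality)
  rmse_denominator <- match.arg(rmse_denominator)
  stopifnot(inherits(cohort, "cohort"))
  ctrl <- cohort_subjects(cohort, "control")
  if (nrow(ctrl) < 3) stop("need at least 3 controls")
  Y <- cohort$edges[[modality]][ctrl$subject_id, , drop = FALSE]
  if (modality == "SC") Y <- log(Y)
  age <- ctrl$age
  if (stats::sd(age) == 0) stop("zero age variance in controls")

  present <- !is.na(Y)
  Y0 <- Y; Y0[!present] <- 0
  A <- matrix(age, nrow(Y), ncol(Y))
  A0 <- A * present
  n_e <- colSums(present)
  s_a <- colSums(A0)
  s_aa <- colSums(A0 * A)
  s_y <- colSums(Y0)
  s_yy <- colSums(Y0 * Y0)
  s_ay <- colSums(A0 * Y0)
  den <- n_e * s_aa - s_a^2
  slope <- (n_e * s_ay - s_a * s_y) / den
  intercept <- (s_y - slope * s_a) / n_e
  unfittable <- n_e < 3 | den <= 0
  slope[unfittable] <- NA
  intercept[unfittable] <- NA

  R <- Y - (A * matrix(slope, nrow(Y), ncol(Y), byrow = TRUE) +
              matrix(intercept, nrow(Y), ncol(Y), byrow = TRUE))
  R[!present] <- 0
  denom <- if (rmse_denominator == "n") n_e else pmax(n_e - 2, 1)
  rmse <- sqrt(colSums(R^2) / denom)
  rmse[unfittable] <- NA
  # exact fits (up to rounding relative to the data spread) cannot be
  # standardized
  sd_y <- sqrt(pmax(s_yy / n_e - (s_y / n_e)^2, 0))
  degenerate <- !unfittable & rmse <= 1e-10 * pmax(sd_y, 1e-12)

  structure(list(modality = modality, slope = slope, intercept = intercept,
                 rmse = rmse, n = n_e, unfittable = unfittable,
                 degenerate = degenerate,
                 rmse_denominator = rmse_denominator,
                 controls_used = ctrl$subject_id),
            class = "edge_age_model")
}

#' @export
print.edge_age_model <- function(x, ...) {
  cat("<edge_age_model>", x$modality, "edges:", length(x$slope),
      "unfittable:", sum(x$unfittable), "degenerate:", sum(x$degenerate),
      "controls:", length(x$controls_used), "\n")
  invisible(x)
}

#' Apply the age correction to one subject's connectome
#'
#' Returns the residual connectome (`_res`: value minus the control-fitted
#' line at the subject's age; `SC` on the log scale) and the standardized
#' connectome (`_corr`: residual divided by the control fit's RMSE, i.e.
#' deviation in SD units from age-matched controls). The correction is
#' applied in native left/right orientation. Missing, unfittable and
#' degenerate edges propagate as missing.
#'
#' @param x A `connectome` of the model's raw modality.
#' @param age Subject age in years.
#' @param model An [fit_age_model()] result for the same modality/atlas.
#' @return List with elements `res` and `corr` (both `connectome`s).
#' @export
apply_age_correction <- function(x, age, model) {
  stopifnot(inherits(x, "connectome"), inherits(model, "edge_age_model"))
  if (x$modality != model$modality)
    stop("modality mismatch between connectome and age model")
  v <- edge_vector(x$matrix)
  if (length(v) != length(model$slope))
    stop("connectome dimension does not match age model")
  if (model$modality == "SC") v <- log(v)
  res <- v - (model$slope * age + model$intercept)
  res[model$unfittable] <- NA
  corr <- res / model$rmse
  corr[model$degenerate] <- NA
  n <- nrow(x$matrix)
  list(res = connectome(x$subject_id, paste0(model$modality, "_res"),
                        edges_to_matrix(res, n)),
       corr = connectome(x$subject_id, paste0(model$modality, "_corr"),
                         edges_to_matrix(corr, n)))
}

# Edge-matrix version of apply_age_correction for a whole cohort.
correct_edges <- function(Y, ages, model) {
  if (model$modality == "SC") Y <- log(Y)
  pred <- outer(ages, model$slope) +
    matrix(model$intercept, nrow(Y), ncol(Y), byrow = TRUE)
  res <- Y - pred
  res[, model$unfittable] <- NA
  corr <- res / matrix(model$rmse, nrow(Y), ncol(Y), byrow = TRUE)
  corr[, model$degenerate] <- NA
  list(res = res, corr = corr)
}

#' Age-normalize a whole cohort
#'
#' Fits the edge-wise age models on the cohort's controls (FC, and SC on
#' the log scale) and applies them to every subject, adding `FC_res`,
#' `FC_corr`, `SC_res` and `SC_corr` modalities to the cohort. Controls
#' are corrected with the model fitted on all controls.
#'
#' @param cohort A [cohort()] with `FC` and/or `SC` modalities.
#' @param modalities Raw modalities to normalize.
#' @param rmse_denominator Passed to [fit_age_model()].
#' @return The cohort with derived modalities added; the fitted models are
#'   attached as attribute `"age_models"`.
#' @export
normalize_cohort <- function(cohort, modalities = c("FC", "SC"),
                             rmse_denominator = "n") {
  stopifnot(inherits(cohort, "cohort"))
  models <- list()
  for (mod in intersect(modalities, names(cohort$edges))) {
    model <- fit_age_model(cohort, mod, rmse_denominator)
    out <- correct_edges(cohort$edges[[mod]], cohort$subjects$age, model)
    rownames(out$res) <- rownames(out$corr) <- rownames(cohort$edges[[mod]])
    cohort$edges[[paste0(mod, "_res")]] <- out$res
    cohort$edges[[paste0(mod, "_corr")]] <- out$corr
    models[[mod]] <- model
  }
  attr(cohort, "age_models") <- models
  cohort
}
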