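#' Build a healthy-brain topology model
#'
#' For the matrix kinds (`LEN`, `SC`, `FC`) the designated raw connectomes
#' are averaged element-wise across all controls, separately per
#' hemisphere (the 54 hemisphere regions plus the brainstem; 55 x 55 for
#' the default atlas). Missing edges are excluded from the mean; an edge
#' missing in every control is missing in the topology. Cross-hemisphere
#' connections are not part of the matrix models. The `RSN` kind is read
#' directly from the atlas: a length-N membership vector with values 0-4
#' ordered along the transmodal-to-unimodal gradient (1 = default mode,
#' 2 = attention, 3 = primary visual, 4 = motor/sensorimotor).
#'
#' @param cohort A [cohort()]; only controls enter the averages.
#' @param kind One of `"LEN"`, `"SC"`, `"FC"`, `"RSN"`.
#' @return An object of class `topology_model`: for matrix kinds, fields
#'   `left`/`right` (within-hemisphere matrices with 0-based region ids as
#'   dimnames) and `regions_left`/`regions_right`; for `RSN`, field
#'   `membership` (length-N integer vector).
#' @export
build_topology <- function(cohort, kind = c("LEN", "SC", "FC", "RSN")) {
  kind <- match.arg(kind)
  stopifnot(inherits(cohort, "cohort"))
  atlas <- cohort$atlas
  if (kind == "RSN") {
    if (!"rsn_label" %in% names(atlas) || all(atlas$rsn_label == 0))
      stop("atlas lacks rsn labels")
    return(structure(list(kind = "RSN",
                          membership = stats::setNames(atlas$rsn_label,
                                                       atlas$region_id),
                          controls_used = cohort_subjects(cohort, "control")$subject_id),
                     class = "topology_model"))
  }
  ctrl <- cohort_subjects(cohort, "control")
  if (nrow(ctrl) < 2) stop("need at least 2 controls")
  E <- cohort$edges[[kind]][ctrl$subject_id, , drop = FALSE]
  n <- nrow(atlas)
  present <- !is.na(E)
  E0 <- E; E0[!present] <- 0
  mean_e <- colSums(E0) / colSums(present)
  mean_e[colSums(present) == 0] <- NA
  Tfull <- edges_to_matrix(mean_e, n)
  out <- list(kind = kind, controls_used = ctrl$subject_id)
  for (side in c("left", "right")) {
    regions <- hemisphere_regions(atlas, side)
    Ts <- Tfull[regions + 1L, regions + 1L, drop = FALSE]
    dimnames(Ts) <- list(regions, regions)
    out[[side]] <- Ts
    out[[paste0("regions_", side)]] <- regions
  }
  structure(out, class = "topology_model")
}

#' @export
print.topology_model <- function(x, ...) {
  cat("<topology_model>", x$kind,
      if (x$kind == "RSN") paste(length(x$membership), "regions")
      else paste(nrow(x$left), "x", ncol(x$left), "per hemisphere"), "\n")
  invisible(x)
}

#' Model distance vector from a seed region
#'
#' Reads the modeled distance from the seed region to each other region
#' under the topology: the seed's row of the hemisphere topology matrix
#' for `LEN`/`SC`/`FC`, or the membership vector (independent of the seed)
#' for `RSN`. The seed region itself is excluded.
#'
#' @param topology A [build_topology()] result.
#' @param seed 0-based region id of the seed (for matrix kinds it must lie
#'   in one hemisphere's region set).
#' @return An object of class `model_vector`: data frame with columns
#'   `region_id` and `value`, plus attributes `kind` and `seed`.
#' @export
model_vector <- function(topology, seed) {
  stopifnot(inherits(topology, "topology_model"))
  if (topology$kind == "RSN") {
    ids <- as.integer(names(topology$membership))
    keep <- ids != seed
    out <- data.frame(region_id = ids[keep],
                      value = as.numeric(topology$membership[keep]))
  } else {
    side <- if (seed %in% topology$regions_left) "left"
            else if (seed %in% topology$regions_right) "right"
            else stop("seed region not in either hemisphere block")
    Ts <- topology[[side]]
    ids <- topology[[paste0("regions_", side)]]
    row <- Ts[as.character(seed), ]
    keep <- ids != seed
    out <- data.frame(region_id = ids[keep], value = as.numeric(row[keep]))
  }
  structure(out, kind = topology$kind, seed = seed, class = c("model_vector",
                                                              "data.frame"))
}

#' Partition seed edges into distance-ranked bins
#'
#' Ranks the model vector per the topology's convention -- `LEN`
#' ascending (bin 1 = shortest), `FC` descending by absolute value,
#' `SC` descending, edges missing from the topology excluded before
#' binning -- and chunks the ranked edges into contiguous bins as equal
#' in size as possible, earlier bins receiving the extra edge. For `RSN`
#' the bins are the four membership classes in gradient order (bin index =
#' label); regions with label 0 are not binned. Ties are broken by region
#' id (stable order).
#'
#' @param mv A [model_vector()].
#' @param n_bins Number of bins (ignored for `RSN`, which always has 4).
#' @return An object of class `edge_binning`: list of integer vectors of
#'   0-based region ids (bin 1 first), with attributes `kind` and `seed`.
#' @export
bin_edges <- function(mv, n_bins = 5) {
  stopifnot(inherits(mv, "model_vector"))
  kind <- attr(mv, "kind")
  if (kind == "RSN") {
    elig <- mv[mv$value %in% 1:4, ]
    bins <- lapply(1:4, function(b) sort(elig$region_id[elig$value == b]))
  } else {
    elig <- mv[!is.na(mv$value), ]
    key <- switch(kind,
                  LEN = elig$value,
                  FC = -abs(elig$value),
                  SC = -elig$value)
    ord <- order(key, elig$region_id)
    sizes <- chunk_sizes(nrow(elig), n_bins)
    lab <- rep(seq_len(n_bins), times = sizes)
    bins <- lapply(seq_len(n_bins),
                   function(b) elig$region_id[ord][lab == b])
  }
  structure(bins, kind = kind, seed = attr(mv, "seed"),
            class = "edge_binning")
}

#' @export
print.edge_binning <- function(x, ...) {
  cat("<edge_binning>", attr(x, "kind"), "seed region", attr(x, "seed"),
      "bin sizes:", paste(lengths(x), collapse = ", "), "\n")
  invisible(x)
}

#' Seed-edge binnings for both hemispheres
#'
#' Convenience wrapper: builds the model vector from the anterior
#' hippocampus of each hemisphere and bins it.
#'
#' @param topology A [build_topology()] result.
#' @param atlas The region atlas.
#' @param n_bins Number of bins for matrix kinds.
#' @return Named list with `left` and `right` [bin_edges()] results.
#' @export
hippocampal_binnings <- function(topology, atlas, n_bins = 5) {
  lapply(stats::setNames(c("left", "right"), c("left", "right")),
         function(side) {
           seed <- anterior_hippocampus(atlas, side)
           bin_edges(model_vector(topology, seed), n_bins)
         })
}
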