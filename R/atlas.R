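#' Default 109-region study atlas
#'
#' Builds the region atlas used throughout the package: 54 regions per
#' hemisphere plus the bilateral brainstem (109 in total). One region per
#' hemisphere is flagged as the anterior hippocampus (the presumed seizure
#' focus in unilateral mesial temporal lobe epilepsy). Twenty bilateral
#' region pairs carry a resting-state-network label ordered along the
#' transmodal-to-unimodal functional gradient: 1 = default mode,
#' 2 = attention, 3 = primary visual, 4 = motor/sensorimotor; five pairs
#' per network. All other regions (including the brainstem) carry label 0.
#'
#' @return A data frame with columns `region_id` (0-based integer), `name`,
#'   `hemisphere` (`"left"`, `"right"` or `"bilateral"`), `rsn_label`
#'   (integer 0-4) and `is_anterior_hippocampus` (logical).
#' @examples
#' atlas <- mtle_atlas()
#' table(atlas$hemisphere)
#' @export
mtle_atlas <- function() {
  base <- c(
    "ant_hippocampus", "post_hippocampus",
    paste0("dmn_", 1:5), paste0("att_", 1:5),
    paste0("vis_", 1:5), paste0("mot_", 1:5),
    sprintf("ctx_%02d", 1:32)
  )
  rsn <- c(0L, 0L, rep(1L, 5), rep(2L, 5), rep(3L, 5), rep(4L, 5), rep(0L, 32))
  atlas <- data.frame(
    region_id = 0:108,
    name = c(paste0(base, "_L"), paste0(base, "_R"), "brainstem"),
    hemisphere = c(rep("left", 54), rep("right", 54), "bilateral"),
    rsn_label = c(rsn, rsn, 0L),
    is_anterior_hippocampus = c(base == "ant_hippocampus",
                                base == "ant_hippocampus", FALSE),
    stringsAsFactors = FALSE
  )
  validate_atlas(atlas)
  atlas
}

#' Validate a region atlas
#'
#' Checks the structural invariants every atlas must satisfy: contiguous
#' 0-based region ids, exactly one anterior hippocampus per hemisphere
#' (never a bilateral region), matched left/right name pairs, and each
#' non-zero resting-state-network label carried by exactly five bilateral
#' region pairs.
#'
#' @param atlas A data frame as returned by [mtle_atlas()].
#' @return The atlas, invisibly. Errors on violation.
#' @export
validate_atlas <- function(atlas) {
  req <- c("region_id", "name", "hemisphere", "rsn_label",
           "is_anterior_hippocampus")
  if (!all(req %in% names(atlas)))
    stop("atlas must have columns: ", paste(req, collapse = ", "))
  n <- nrow(atlas)
  if (!identical(as.integer(atlas$region_id), 0:(n - 1L)))
    stop("atlas region_id must be 0-based and contiguous in row order")
  if (!all(atlas$hemisphere %in% c("left", "right", "bilateral")))
    stop("atlas hemisphere must be left/right/bilateral")
  if (anyDuplicated(atlas$name)) stop("atlas region names must be unique")
  for (h in c("left", "right")) {
    ah <- atlas$is_anterior_hippocampus & atlas$hemisphere == h
    if (sum(ah) != 1L)
      stop("atlas must flag exactly one anterior hippocampus in ", h,
           " hemisphere")
  }
  if (any(atlas$is_anterior_hippocampus & atlas$hemisphere == "bilateral"))
    stop("bilateral regions cannot be the anterior hippocampus")
  pairs <- region_pairs(atlas)
  for (lab in 1:4) {
    ids <- atlas$region_id[atlas$rsn_label == lab]
    if (length(ids) %% 2L != 0L)
      stop("rsn_label ", lab, " is not carried by bilateral pairs")
    lab_pairs <- pairs[pairs$left_id %in% ids & pairs$right_id %in% ids, ]
    if (nrow(lab_pairs) * 2L != length(ids))
      stop("rsn_label ", lab, " is not carried by matched left/right pairs")
    if (nrow(lab_pairs) != 5L)
      stop("rsn_label ", lab, " must be carried by exactly five region pairs")
  }
  invisible(atlas)
}

#' Matched left/right region pairs of an atlas
#'
#' Pairs are matched by base name: `<base>_L` with `<base>_R`.
#'
#' @param atlas A region atlas.
#' @return Data frame with columns `base`, `left_id`, `right_id` (0-based).
#' @export
region_pairs <- function(atlas) {
  left <- atlas[atlas$hemisphere == "left", ]
  right <- atlas[atlas$hemisphere == "right", ]
  strip <- function(x) sub("_[LR]$", "", x)
  lb <- strip(left$name)
  rb <- strip(right$name)
  if (!setequal(lb, rb) || anyDuplicated(lb) || anyDuplicated(rb))
    stop("left/right region names do not form matched pairs")
  m <- match(lb, rb)
  data.frame(base = lb, left_id = left$region_id,
             right_id = right$region_id[m], stringsAsFactors = FALSE)
}

#' Region ids of one hemisphere plus bilateral regions
#'
#' @param atlas A region atlas.
#' @param side `"left"` or `"right"`.
#' @return Integer vector of 0-based region ids (hemisphere regions in atlas
#'   order, then bilateral regions).
#' @export
hemisphere_regions <- function(atlas, side) {
  side <- match.arg(side, c("left", "right"))
  c(atlas$region_id[atlas$hemisphere == side],
    atlas$region_id[atlas$hemisphere == "bilateral"])
}

#' Anterior hippocampus region id for one hemisphere
#' @param atlas A region atlas.
#' @param side `"left"` or `"right"`.
#' @return A single 0-based region id.
#' @export
anterior_hippocampus <- function(atlas, side) {
  side <- match.arg(side, c("left", "right"))
  atlas$region_id[atlas$is_anterior_hippocampus & atlas$hemisphere == side]
}
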