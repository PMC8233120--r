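#' Construct a connectome object
#'
#' A connectome is one subject's region-by-region matrix for one modality:
#' `FC` (functional connectivity, Fisher-z scale), `SC` (structural
#' connectivity, volume-scaled streamline counts, non-negative) or `LEN`
#' (mean streamline length, positive where present). Missing edges (an SC
#' or LEN edge with no streamlines) are stored as `NA`; the diagonal is
#' undefined and stored as zero. Derived modalities produced by age
#' normalization (`FC_res`, `FC_corr`, `SC_res`, `SC_corr`) are also
#' accepted.
#'
#' @param subject_id Subject identifier string.
#' @param modality One of `"FC"`, `"SC"`, `"LEN"`, `"FC_res"`, `"FC_corr"`,
#'   `"SC_res"`, `"SC_corr"`.
#' @param matrix Square symmetric numeric matrix; `NA` = missing edge.
#' @param sym_tol Maximum tolerated absolute asymmetry; beyond it the
#'   matrix is rejected, below it values are symmetrized by averaging.
#' @return An object of class `connectome` with fields `subject_id`,
#'   `modality` and `matrix`.
#' @export
connectome <- function(subject_id, modality, matrix, sym_tol = 1e-8) {
  modality <- match.arg(modality, c("FC", "SC", "LEN",
                                    "FC_res", "FC_corr", "SC_res", "SC_corr"))
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("connectome matrix must be square")
  asym <- abs(m - t(m))
  asym[is.na(asym)] <- if (any(xor(is.na(m), is.na(t(m))))) Inf else 0
  if (max(asym) > sym_tol)
    stop("connectome matrix asymmetric beyond tolerance (max |a_ij - a_ji| = ",
         format(max(asym)), ")")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (modality == "SC" && any(m < 0, na.rm = TRUE))
    stop("SC values must be non-negative")
  if (modality == "LEN" && any(m <= 0 & upper.tri(m), na.rm = TRUE))
    stop("LEN values must be positive where present")
  structure(list(subject_id = as.character(subject_id),
                 modality = modality, matrix = m),
            class = "connectome")
}

#' Missing-edge mask of a connectome
#' @param x A `connectome`.
#' @return Logical matrix, `TRUE` where the edge is not detected.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "connectome"))
  mm <- is.na(x$matrix)
  diag(mm) <- FALSE
  mm
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> subject", x$subject_id, "modality", x$modality,
      "regions", nrow(x$matrix),
      "missing edges", sum(is.na(x$matrix[upper.tri(x$matrix)])), "\n")
  invisible(x)
}

# Region permutation mapping native left/right slots to ipsi/contra slots
# for a given focus side. perm[slot] = source region index (1-based).
# focus left: identity (ipsilateral occupies the left-hemisphere slots);
# focus right: left and right partners swap; bilateral regions are fixed.
ipsi_contra_permutation <- function(atlas, focus_side) {
  focus_side <- match.arg(focus_side, c("left", "right"))
  n <- nrow(atlas)
  perm <- seq_len(n)
  if (focus_side == "right") {
    pairs <- region_pairs(atlas)
    perm[pairs$left_id + 1L] <- pairs$right_id + 1L
    perm[pairs$right_id + 1L] <- pairs$left_id + 1L
  }
  perm
}

#' Transform a connectome to ipsilateral/contralateral orientation
#'
#' Patients with different seizure-focus sides are pooled by permuting
#' rows/columns so that the focus hemisphere occupies the canonical
#' "ipsilateral" block (the left-hemisphere slots). For a left focus the
#' permutation is the identity; for a right focus left/right partner
#' regions swap. Bilateral regions are fixed points, and applying the
#' transform twice with the same side restores the original matrix.
#'
#' @param x A `connectome`.
#' @param focus_side `"left"` or `"right"`.
#' @param atlas The region atlas (must have matched left/right pairs).
#' @return A `connectome` in ipsi/contra orientation.
#' @export
to_ipsi_contra <- function(x, focus_side, atlas) {
  stopifnot(inherits(x, "connectome"))
  if (nrow(x$matrix) != nrow(atlas))
    stop("connectome dimension does not match atlas")
  perm <- ipsi_contra_permutation(atlas, focus_side)
  out <- x
  out$matrix <- x$matrix[perm, perm, drop = FALSE]
  out
}
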