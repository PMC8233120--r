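#' Construct a cohort
#'
#' A cohort ties a region atlas, a subject manifest and per-subject
#' connectomes together. Internally connectomes are held edge-major: one
#' `n_subjects x n_edges` matrix per modality (canonical edge order of
#' [edge_index_map()]), with `NA` marking missing edges. This is the
#' layout every downstream stage (age normalization, topology averaging,
#' Mahalanobis permutations, ICA) consumes directly.
#'
#' @param atlas Region atlas data frame (validated).
#' @param subjects Data frame with columns `subject_id`, `group`
#'   (`"control"`/`"patient"`), `age`, `duration`, `focus_side`; `duration`
#'   and `focus_side` must be defined iff the subject is a patient.
#' @param connectomes Either a list of `connectome` objects, or a named
#'   list of edge matrices (one per modality, rows named by subject).
#' @return An object of class `cohort`.
#' @export
cohort <- function(atlas, subjects, connectomes) {
  validate_atlas(atlas)
  subjects <- validate_subjects(subjects)
  n <- nrow(atlas)
  ne <- n * (n - 1L) %/% 2L
  if (length(connectomes) && inherits(connectomes[[1]], "connectome")) {
    mods <- unique(vapply(connectomes, function(x) x$modality, ""))
    edges <- list()
    lin <- edge_linear_index(n)
    for (mod in mods) {
      cs <- Filter(function(x) x$modality == mod, connectomes)
      ids <- vapply(cs, function(x) x$subject_id, "")
      em <- t(vapply(cs, function(x) {
        if (nrow(x$matrix) != n) stop("connectome dimension mismatch with atlas")
        x$matrix[lin]
      }, numeric(ne)))
      rownames(em) <- ids
      edges[[mod]] <- em
    }
  } else {
    edges <- connectomes
    for (mod in names(edges)) {
      if (ncol(edges[[mod]]) != ne) stop("edge matrix width mismatch with atlas")
      if (is.null(rownames(edges[[mod]]))) stop("edge matrices need subject rownames")
    }
  }
  for (mod in names(edges)) {
    miss <- setdiff(subjects$subject_id, rownames(edges[[mod]]))
    if (length(miss))
      stop("subjects missing ", mod, " connectome: ", paste(miss, collapse = ", "))
    edges[[mod]] <- edges[[mod]][subjects$subject_id, , drop = FALSE]
  }
  structure(list(atlas = atlas, subjects = subjects, edges = edges),
            class = "cohort")
}

validate_subjects <- function(subjects) {
  req <- c("subject_id", "group", "age")
  if (!all(req %in% names(subjects)))
    stop("subject manifest must have columns subject_id, group, age")
  if (!"duration" %in% names(subjects)) subjects$duration <- NA_real_
  if (!"focus_side" %in% names(subjects)) subjects$focus_side <- NA_character_
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$focus_side[!is.na(subjects$focus_side) & subjects$focus_side == ""] <-
    NA_character_
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids")
  if (!all(subjects$group %in% c("control", "patient")))
    stop("group must be control or patient")
  pat <- subjects$group == "patient"
  if (any(pat & (is.na(subjects$duration) | is.na(subjects$focus_side))))
    stop("patients must have duration and focus_side")
  if (any(!pat & (!is.na(subjects$duration) | !is.na(subjects$focus_side))))
    stop("controls must not have duration or focus_side")
  if (any(!is.na(subjects$focus_side) &
          !subjects$focus_side %in% c("left", "right")))
    stop("focus_side must be left or right")
  d <- subjects$duration[pat]
  if (any(d < 0) || any(d > subjects$age[pat]))
    stop("duration must satisfy 0 <= duration <= age")
  subjects
}

#' Extract one subject's connectome from a cohort
#' @param x A `cohort`.
#' @param subject_id Subject identifier.
#' @param modality Modality name present in the cohort.
#' @return A `connectome` object.
#' @export
get_connectome <- function(x, subject_id, modality) {
  stopifnot(inherits(x, "cohort"))
  em <- x$edges[[modality]]
  if (is.null(em)) stop("modality not in cohort: ", modality)
  if (!subject_id %in% rownames(em)) stop("unknown subject: ", subject_id)
  m <- edges_to_matrix(em[subject_id, ], nrow(x$atlas))
  connectome(subject_id, modality, m)
}

#' Subjects of one group
#' @param x A `cohort`.
#' @param group `"control"` or `"patient"`.
#' @return Data frame of subject records.
#' @export
cohort_subjects <- function(x, group = c("control", "patient")) {
  group <- match.arg(group)
  x$subjects[x$subjects$group == group, , drop = FALSE]
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$atlas), "regions;",
      sum(x$subjects$group == "control"), "controls,",
      sum(x$subjects$group == "patient"), "patients; modalities:",
      paste(names(x$edges), collapse = ", "), "\n")
  invisible(x)
}

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_matrix_tsv <- function(m, region_ids, path) {
  n <- nrow(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region_id", region_ids), collapse = "\t"), con)
  for (r in seq_len(n)) {
    writeLines(paste(c(region_ids[r], fmt17(m[r, ])), collapse = "\t"), con)
  }
  invisible(path)
}

read_matrix_tsv <- function(path, region_ids) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!identical(as.integer(tab[[1]]), as.integer(region_ids)) ||
      !identical(as.integer(colnames(tab)[-1]), as.integer(region_ids)))
    stop("matrix file ", basename(path), " does not match atlas region ids")
  as.matrix(tab[, -1, drop = FALSE])
}

#' Write a cohort to disk
#'
#' Writes `atlas.csv`, `manifest.csv` and one tab-separated matrix file per
#' subject and modality (`<subject_id>.<modality>.tsv`, region ids in the
#' first row and column, 17 significant digits so round trips are
#' bit-exact). Missing SC/LEN edges are written as 0, the on-disk
#' convention for "no streamlines detected".
#'
#' @param x A `cohort`.
#' @param dir Output directory (created if needed).
#' @param modalities Modalities to write (default: all in the cohort).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(x, dir, modalities = names(x$edges)) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$atlas, file.path(dir, "atlas.csv"), row.names = FALSE)
  man <- x$subjects
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   na = "")
  n <- nrow(x$atlas)
  for (mod in modalities) {
    em <- x$edges[[mod]]
    for (id in rownames(em)) {
      v <- em[id, ]
      if (mod %in% c("SC", "LEN")) v[is.na(v)] <- 0
      write_matrix_tsv(edges_to_matrix(v, n), x$atlas$region_id,
                       file.path(dir, paste0(id, ".", mod, ".tsv")))
    }
  }
  invisible(dir)
}

#' Load a cohort from disk
#'
#' Reads the manifest, atlas and per-subject matrix files written by
#' [save_cohort()] (or prepared externally in the same layout). SC/LEN
#' entries equal to zero are converted to missing edges. Validation is
#' strict: dimensions must match the atlas, matrices must be symmetric
#' within `1e-8`, and every patient must carry `duration` and
#' `focus_side`.
#'
#' @param manifest_path CSV with header
#'   `subject_id,group,age,duration,focus_side`.
#' @param atlas_path CSV with header
#'   `region_id,name,hemisphere,rsn_label,is_anterior_hippocampus`.
#' @param matrix_dir Directory holding `<subject_id>.<modality>.tsv` files.
#' @param modalities Modalities to load.
#' @return A `cohort`.
#' @export
load_cohort <- function(manifest_path, atlas_path, matrix_dir,
                        modalities = c("FC", "SC", "LEN")) {
  atlas <- utils::read.csv(atlas_path, stringsAsFactors = FALSE)
  atlas$is_anterior_hippocampus <- as.logical(atlas$is_anterior_hippocampus)
  validate_atlas(atlas)
  subjects <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
  conns <- list()
  for (id in subjects$subject_id) {
    for (mod in modalities) {
      path <- file.path(matrix_dir, paste0(id, ".", mod, ".tsv"))
      if (!file.exists(path)) stop("missing matrix file: ", path)
      m <- read_matrix_tsv(path, atlas$region_id)
      if (mod %in% c("SC", "LEN")) m[m == 0] <- NA
      diag(m) <- 0
      conns[[paste(id, mod)]] <- connectome(id, mod, m)
    }
  }
  cohort(atlas, subjects, conns)
}
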