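#' Validate a single-subject connectivity matrix
#'
#' A connectivity matrix is the unit of analysis: a symmetric nonnegative
#' N x N matrix of fractional-anisotropy-weighted connections with an exact
#' zero diagonal.  Validation enforces these invariants and then symmetrises
#' the matrix (average of `W` and `t(W)`) so that downstream code can rely on
#' exact symmetry; asymmetries beyond `tol` are an error, not silently fixed.
#'
#' @param weights Numeric square matrix.
#' @param subject_id Subject identifier used in error messages.
#' @param tol Maximum tolerated absolute asymmetry (default `1e-9`).
#' @return The validated, symmetrised matrix.
#' @export
validate_connectivity_matrix <- function(weights, subject_id = "<subject>",
                                         tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights) ||
      nrow(weights) != ncol(weights)) {
    abort(sprintf("Subject %s: weights must be a square numeric matrix.",
                  subject_id),
          class = "wm_validation_error")
  }
  if (any(!is.finite(weights))) {
    abort(sprintf("Subject %s: non-finite entries in connectivity matrix.",
                  subject_id),
          class = "wm_validation_error")
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    abort(sprintf(
      "Subject %s: connectivity matrix is not symmetric (max asymmetry %.3g > tol %.3g).",
      subject_id, asym, tol
    ), class = "wm_validation_error")
  }
  if (any(weights < 0)) {
    abort(sprintf("Subject %s: negative connection weights.", subject_id),
          class = "wm_validation_error")
  }
  if (any(diag(weights) != 0)) {
    abort(sprintf("Subject %s: diagonal must be exactly zero.", subject_id),
          class = "wm_validation_error")
  }
  (weights + t(weights)) / 2
}

required_metadata_cols <- c("subject_id", "group", "age", "sex")
patient_metadata_cols <- c("duration_months", "alsfrs_r",
                           "bulbar", "motor", "respiratory")

validate_metadata <- function(metadata) {
  metadata <- as_tibble(metadata)
  missing <- setdiff(required_metadata_cols, names(metadata))
  if (length(missing)) {
    abort(paste0("Metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "wm_validation_error")
  }
  if (anyDuplicated(metadata$subject_id)) {
    abort("Duplicate subject_id in metadata.", class = "wm_validation_error")
  }
  bad_group <- setdiff(unique(metadata$group), c("patient", "control"))
  if (length(bad_group)) {
    abort(paste0("group must be 'patient' or 'control'; found: ",
                 paste(bad_group, collapse = ", ")),
          class = "wm_validation_error")
  }
  if (!all(metadata$sex %in% c(0, 1))) {
    abort("sex must be coded 0/1.", class = "wm_validation_error")
  }
  pats <- metadata[metadata$group == "patient", , drop = FALSE]
  if (nrow(pats) && "duration_months" %in% names(pats)) {
    if (any(!is.finite(pats$duration_months) | pats$duration_months <= 0)) {
      abort("duration_months must be > 0 for every patient.",
            class = "wm_validation_error")
    }
  }
  sub_cols <- c("alsfrs_r", "bulbar", "motor", "respiratory")
  if (all(sub_cols %in% names(pats)) && nrow(pats)) {
    ok <- is.na(pats$alsfrs_r) | is.na(pats$bulbar) | is.na(pats$motor) |
      is.na(pats$respiratory) |
      pats$alsfrs_r == pats$bulbar + pats$motor + pats$respiratory
    if (!all(ok)) {
      abort(paste0(
        "ALSFRS-R total must equal bulbar + motor + respiratory for subject(s): ",
        paste(pats$subject_id[!ok], collapse = ", ")
      ), class = "wm_validation_error")
    }
  }
  metadata
}

#' Assemble a cohort
#'
#' A cohort bundles an atlas, one connectivity matrix per subject and the
#' subject metadata table.  Every metadata row must have a matrix (matched by
#' `subject_id`) and vice versa, and all matrices must share the atlas
#' dimension.
#'
#' @param atlas A [node_atlas()].
#' @param matrices Named list of square numeric matrices (names are subject
#'   ids).
#' @param metadata Data frame with at least `subject_id`, `group`
#'   (`"patient"`/`"control"`), `age`, `sex` (0/1); patients additionally
#'   carry `duration_months`, `alsfrs_r` and the `bulbar`/`motor`/
#'   `respiratory` subscores.
#' @param tol Symmetry tolerance passed to [validate_connectivity_matrix()].
#' @return An object of class `wm_cohort` (list with elements `atlas`,
#'   `matrices`, `metadata`).
#' @export
wm_cohort <- function(atlas, matrices, metadata, tol = 1e-9) {
  stopifnot(inherits(atlas, "wm_atlas"))
  metadata <- validate_metadata(metadata)
  if (is.null(names(matrices)) || anyDuplicated(names(matrices))) {
    abort("matrices must be a uniquely named list keyed by subject_id.",
          class = "wm_validation_error")
  }
  missing_mat <- setdiff(metadata$subject_id, names(matrices))
  if (length(missing_mat)) {
    abort(paste0("No connectivity matrix for subject(s): ",
                 paste(missing_mat, collapse = ", ")),
          class = "wm_missing_matrix_error")
  }
  extra <- setdiff(names(matrices), metadata$subject_id)
  if (length(extra)) {
    abort(paste0("Matrix present without metadata row: ",
                 paste(extra, collapse = ", ")),
          class = "wm_validation_error")
  }
  n <- length(atlas)
  matrices <- matrices[metadata$subject_id]
  matrices <- lapply(metadata$subject_id, function(id) {
    w <- matrices[[id]]
    if (nrow(w) != n) {
      abort(sprintf("Subject %s: matrix is %dx%d but atlas has %d regions.",
                    id, nrow(w), ncol(w), n),
            class = "wm_validation_error")
    }
    validate_connectivity_matrix(w, id, tol = tol)
  })
  names(matrices) <- metadata$subject_id
  structure(list(atlas = atlas, matrices = matrices, metadata = metadata),
            class = "wm_cohort")
}

#' @export
print.wm_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat("<wm_cohort> ", nrow(x$metadata), " subjects (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "), ", length(x$atlas), "-region atlas\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `wm_cohort`.
#' @return Integer subject count.
#' @export
n_subjects <- function(cohort) nrow(cohort$metadata)

#' Restrict a cohort to a subset of subjects
#'
#' @param cohort A `wm_cohort`.
#' @param subject_ids Character vector of subject ids to keep.
#' @return A `wm_cohort` with only those subjects, in the requested order.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  missing <- setdiff(subject_ids, cohort$metadata$subject_id)
  if (length(missing)) {
    abort(paste0("Unknown subject id(s): ", paste(missing, collapse = ", ")),
          class = "wm_validation_error")
  }
  meta <- cohort$metadata[match(subject_ids, cohort$metadata$subject_id), ]
  wm_cohort(cohort$atlas, cohort$matrices[subject_ids], meta)
}
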