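#' Read one connectivity-matrix file
#'
#' Matrix files are plain delimited text without a header: one row per atlas
#' region, comma- or whitespace-separated (autodetected).  This matches the
#' export format of the common connectome toolboxes.
#'
#' @param path Path to the matrix file.
#' @param subject_id Subject id for error messages; defaults to the file
#'   name without extension.
#' @return A numeric square matrix (not yet validated).
#' @export
read_connectivity_matrix <- function(path,
                                     subject_id = sub("\\.[^.]*$", "",
                                                      basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  delim <- if (any(grepl(",", lines))) "," else "\\s+"
  rows <- lapply(seq_along(lines), function(i) {
    cells <- strsplit(trimws(lines[[i]]), delim)[[1]]
    cells <- cells[nzchar(cells)]
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals) & !cells %in% "NA")) {
      bad <- which(is.na(vals))[1]
      abort(sprintf("%s: non-numeric cell '%s' at line %d, field %d.",
                    path, cells[bad], i, bad),
            class = "wm_parse_error")
    }
    vals
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L || lens[1] != length(rows)) {
    abort(sprintf("%s: not a square numeric grid (%d rows, widths %s).",
                  path, length(rows),
                  paste(unique(lens), collapse = "/")),
          class = "wm_parse_error")
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- NULL
  m
}

#' Read a cohort from disk
#'
#' Expects one matrix file per subject named `<subject_id>.txt` in
#' `matrix_dir`, a delimited metadata table with a header, and an atlas file
#' with one region name per line.  A metadata row without a matrix file is an
#' error, never a silent drop.
#'
#' @param matrix_dir Directory of per-subject matrix files.
#' @param metadata_path Path to the metadata TSV/CSV.
#' @param atlas_path Path to the atlas label file.
#' @param tol Symmetry tolerance.
#' @return A validated [wm_cohort()].
#' @export
read_cohort <- function(matrix_dir, metadata_path, atlas_path, tol = 1e-9) {
  atlas <- read_atlas(atlas_path)
  metadata <- read_table_auto(metadata_path)
  metadata <- validate_metadata(metadata)
  paths <- file.path(matrix_dir, paste0(metadata$subject_id, ".txt"))
  missing <- metadata$subject_id[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("Missing matrix file for subject(s): ",
                 paste(missing, collapse = ", "), " in ", matrix_dir),
          class = "wm_missing_matrix_error")
  }
  matrices <- lapply(seq_along(paths), function(i) {
    read_connectivity_matrix(paths[i], metadata$subject_id[i])
  })
  names(matrices) <- metadata$subject_id
  wm_cohort(atlas, matrices, metadata, tol = tol)
}

read_table_auto <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Write a cohort to a directory
#'
#' Inverse of [read_cohort()]: writes `matrices/<subject_id>.txt` (space
#' delimited, full precision), `metadata.tsv` and `atlas.txt` under `dir`.
#'
#' @param cohort A `wm_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  mat_dir <- file.path(dir, "matrices")
  dir.create(mat_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in cohort$metadata$subject_id) {
    write_matrix_txt(cohort$matrices[[id]],
                     file.path(mat_dir, paste0(id, ".txt")))
  }
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"),
                   progress = FALSE)
  writeLines(unclass(cohort$atlas), file.path(dir, "atlas.txt"))
  invisible(dir)
}

write_matrix_txt <- function(m, path) {
  txt <- apply(m, 1L, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")
  })
  writeLines(txt, path)
}

#' Write a result table
#'
#' Tabular results are written as TSV with full numeric precision so that
#' `read_result_table(write_result_table(x))` reproduces `x` exactly.  An
#' empty table yields a header-only file.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a structured result as JSON
#'
#' Used for results that are not flat tables (NBS components, prediction
#' reports).  Numbers are written at full precision.
#'
#' @param x A list-like result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
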