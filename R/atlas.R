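#' Node atlas
#'
#' An atlas is the ordered set of region labels that index the rows and
#' columns of every connectivity matrix in an analysis.  The order is fixed
#' for the life of the analysis; all matrices of a cohort must share it.
#'
#' @param names Character vector of unique region labels (length >= 3).
#' @return An object of class `wm_atlas`: a character vector with an `n`
#'   attribute.
#' @examples
#' atlas <- node_atlas(c("A", "B", "C", "D"))
#' length(atlas)
#' @export
node_atlas <- function(names) {
  names <- as.character(names)
  if (length(names) < 3) {
    abort("An atlas needs at least 3 regions.", class = "wm_validation_error")
  }
  if (anyDuplicated(names)) {
    abort(
      paste0(
        "Atlas region names must be unique; duplicated: ",
        paste(unique(names[duplicated(names)]), collapse = ", ")
      ),
      class = "wm_validation_error"
    )
  }
  structure(names, class = "wm_atlas", n = length(names))
}

#' @export
print.wm_atlas <- function(x, ...) {
  cat("<wm_atlas> ", length(x), " regions: ",
      paste(head(unclass(x), 3), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' Read an atlas file (one region label per line)
#'
#' @param path Path to a plain-text file with one region name per line.
#' @return A [node_atlas()].
#' @export
read_atlas <- function(path) {
  names <- readLines(path, warn = FALSE)
  names <- names[nzchar(trimws(names))]
  node_atlas(trimws(names))
}

#' The 90-region AAL atlas
#'
#' Region labels of the automated anatomical labeling (AAL) atlas restricted
#' to its 90 cortical and subcortical regions (cerebellum excluded), in the
#' conventional left/right interleaved order.  This is the parcellation most
#' commonly used for 90-node structural brain networks.
#'
#' @return A [node_atlas()] of length 90.
#' @examples
#' aal90_atlas()
#' @export
aal90_atlas <- function() {
  read_atlas(system.file("extdata", "aal90_labels.txt",
                         package = "wmconnect", mustWork = TRUE))
}
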