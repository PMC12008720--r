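#' Electrode montages and reduced electrode subsets
#'
#' The full cap is a 128-channel layout following the extended international
#' 10-5 nomenclature; the reduced 64/32/24 sets are standard 10-10 caps as used
#' in hospital settings, each a strict subset of the 128-channel montage. The
#' label lists ship as editable plain-text files (one label per line) under
#' `inst/extdata/` and can be replaced by the user's own cap definition.
#'
#' @param n Montage size: one of 128, 64, 32, 24.
#' @return Character vector of channel labels.
#' @examples
#' length(montage_labels(128))
#' all(montage_labels(64) %in% montage_labels(128))
#' @export
montage_labels <- function(n = 128) {
  n <- as.integer(n)
  if (!n %in% c(128L, 64L, 32L, 24L)) {
    stop("montage size must be one of 128, 64, 32, 24")
  }
  file <- if (n == 128L) "montage_128.txt" else sprintf("subset_%d.txt", n)
  path <- system.file("extdata", file, package = "taugraph")
  if (path == "") stop("montage file not found: ", file)
  labels <- readLines(path)
  labels <- labels[nzchar(labels)]
  if (length(labels) != n) {
    stop("montage file ", file, " holds ", length(labels),
         " labels, expected ", n)
  }
  labels
}

#' Electrode subset definition
#'
#' Validates a reduced electrode set against a full montage and returns the
#' subset object used by [subset_metrics()].
#'
#' @param size Subset size (64, 32 or 24) to load from the shipped defaults,
#'   or ignored when `labels` is given.
#' @param labels Optional explicit label vector replacing the shipped set.
#' @param montage Full montage the subset must live in (default: the shipped
#'   128-channel labels).
#' @return An object of class `electrode_subset` with fields `name` and
#'   `labels`.
#' @export
electrode_subset <- function(size = 64, labels = NULL,
                             montage = montage_labels(128)) {
  if (is.null(labels)) labels <- montage_labels(size)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("subset labels must be unique")
  missing <- setdiff(labels, montage)
  if (length(missing) > 0) {
    stop("subset labels absent from montage: ",
         paste(missing, collapse = ", "))
  }
  structure(list(name = as.character(length(labels)), labels = labels),
            class = "electrode_subset")
}
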