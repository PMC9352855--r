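#' Define a set of regions of interest with subnetwork membership
#'
#' An ROI set fixes the node set of every network in an analysis: the
#' ordered ROI labels, the assignment of each ROI to the putative mental
#' rotations network (`"MRN"`) or the default mode network (`"DMN"`), and
#' optional 3-d coordinates in millimetres.
#'
#' @param labels Character vector of unique ROI labels. Column order of all
#'   time-series matrices must follow this order.
#' @param membership Named character vector (or unnamed, parallel to
#'   `labels`) with values `"MRN"` or `"DMN"`.
#' @param coordinates Optional numeric matrix with one row per ROI and
#'   three columns (x, y, z in mm).
#'
#' @return An object of class `roi_set`.
#' @seealso [default_roi_set()]
#' @export
roi_set <- function(labels, membership, coordinates = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) input_error("ROI labels must be unique")
  if (length(labels) < 2L) input_error("an ROI set needs at least 2 labels")
  if (!is.null(names(membership))) {
    if (!setequal(names(membership), labels)) {
      input_error("membership names must match the ROI labels")
    }
    membership <- membership[labels]
  } else if (length(membership) != length(labels)) {
    input_error("membership must have one entry per ROI label")
  } else {
    names(membership) <- labels
  }
  membership <- as.character(membership)
  names(membership) <- labels
  if (!all(membership %in% c("MRN", "DMN"))) {
    input_error("membership values must be 'MRN' or 'DMN'")
  }
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != length(labels) || ncol(coordinates) != 3L) {
      input_error("coordinates must be a length(labels) x 3 matrix")
    }
    rownames(coordinates) <- labels
  }
  structure(
    list(labels = labels, membership = membership, coordinates = coordinates),
    class = "roi_set"
  )
}

#' Default 10-ROI set: 6 MRN + 4 DMN regions
#'
#' The default node set used throughout the package: six regions forming a
#' putative mental rotations network (bilateral inferior frontal gyrus,
#' parietal, and superior parietal cortex) and four default mode network
#' regions (medial prefrontal cortex, posterior cingulate cortex, and
#' bilateral lateral parietal cortex). Labels are placeholders for the
#' 10 mm spherical ROIs of the study design; coordinates can be supplied
#' through [roi_set()] when available.
#'
#' @return An object of class `roi_set` with 10 labels.
#' @export
#' @examples
#' default_roi_set()
default_roi_set <- function() {
  mrn <- c("R_IFG", "L_IFG", "R_Par", "L_Par", "R_sPar", "L_sPar")
  dmn <- c("MPFC", "PCC", "R_LP", "L_LP")
  roi_set(
    labels = c(mrn, dmn),
    membership = c(rep("MRN", length(mrn)), rep("DMN", length(dmn)))
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf(
    "ROI set: %d regions (%d MRN, %d DMN)\n",
    length(x$labels), sum(x$membership == "MRN"), sum(x$membership == "DMN")
  ))
  cat("  MRN:", paste(x$labels[x$membership == "MRN"], collapse = ", "), "\n")
  cat("  DMN:", paste(x$labels[x$membership == "DMN"], collapse = ", "), "\n")
  invisible(x)
}

roi_labels <- function(rois) {
  if (inherits(rois, "roi_set")) rois$labels else as.character(rois)
}
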