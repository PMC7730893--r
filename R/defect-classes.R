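#' Defect classes of the green-plum grading scheme
#'
#' Five surface-condition classes are distinguished: `rot`, `spot` (rain
#' spot), `scar`, `crack` and `normal`. All confusion matrices and reports
#' in the package use the canonical order `rot, spot, scar, crack, normal`.
#'
#' @return Character vector of the five class names in canonical order.
#' @export
#' @examples
#' defect_classes()
defect_classes <- function() {
  c("rot", "spot", "scar", "crack", "normal")
}

#' Severity ranks of the defect classes
#'
#' When several defects co-occur on one fruit the image is labelled with the
#' most severe one. Decay (rot) outranks cracks, which outrank scars, which
#' outrank rain spots; a defect-free fruit is `normal`.
#'
#' @return Named integer vector mapping class name to severity rank
#'   (higher = more severe).
#' @export
severity_ranks <- function() {
  c(rot = 4L, crack = 3L, scar = 2L, spot = 1L, normal = 0L)
}

#' Label an image by its most severe defect
#'
#' @param defects_present Character vector (possibly empty) of defect names
#'   observed on the fruit; a subset of `rot`, `crack`, `scar`, `spot`.
#' @return A single class name: the highest-severity member, or `"normal"`
#'   for an empty set.
#' @export
#' @examples
#' assign_label(c("crack", "rot")) # "rot": decay outranks cracks
#' assign_label(character())       # "normal"
assign_label <- function(defects_present) {
  defects_present <- unique(as.character(defects_present))
  if (length(defects_present) == 0) {
    return("normal")
  }
  ranks <- severity_ranks()
  bad <- setdiff(defects_present, setdiff(names(ranks), "normal"))
  if (length(bad) > 0) {
    stop("unknown defect name(s): ", paste(bad, collapse = ", "))
  }
  names(which.max(ranks[defects_present]))
}

#' Coerce labels to a factor in canonical class order
#'
#' @param x Character or factor vector of class labels.
#' @return Factor with levels `defect_classes()`.
#' @export
as_defect_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), defect_classes())
  if (length(bad) > 0) {
    stop("labels outside the five defect classes: ", paste(bad, collapse = ", "))
  }
  factor(x, levels = defect_classes())
}
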