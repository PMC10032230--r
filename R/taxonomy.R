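#' Reserved label for out-of-distribution (non-exercise) data
#'
#' Windows or samples that do not belong to any exercise class carry this
#' reserved label: rest periods, activities of daily living, and any segment
#' outside a labelled exercise interval.
#'
#' @return A length-one character string.
#' @export
ood_label <- function() "OOD"

#' Shoulder physiotherapy exercise taxonomy
#'
#' The 18 rotator-cuff rehabilitation exercises the pipeline recognises, each
#' with its motion, simple-motion and body-position attributes. Exercises that
#' share a name but differ in position (e.g. assisted shoulder flexion
#' performed upright vs. lying) are disambiguated with a parenthesised
#' position suffix so that exercise names are unique.
#'
#' @return A tibble with columns `exercise`, `motion`, `simple_motion`,
#'   `position`; 18 rows spanning 6 distinct simple-motion groups.
#' @examples
#' taxonomy()
#' dplyr::count(taxonomy(), simple_motion)
#' @export
taxonomy <- function() {
  tibble::tribble(
    ~exercise, ~motion, ~simple_motion, ~position,
    "Active shoulder flexion", "Flexion", "Elevation", "Upright",
    "Active shoulder abduction", "Abduction", "Elevation", "Upright",
    "Assisted shoulder flexion", "Flexion", "Elevation", "Upright",
    "Assisted shoulder flexion (lying)", "Flexion", "Elevation", "Lying",
    "Shoulder girdle stabilization with elevation", "Flexion", "Elevation", "Upright",
    "Assisted shoulder external rotation", "External rotation", "Rotation", "Upright",
    "Assisted shoulder internal rotation", "Internal rotation", "Rotation", "Upright",
    "Assisted shoulder internal rotation (side-lying)", "Internal rotation", "Rotation", "Side-lying",
    "Resisted shoulder internal rotation", "Internal rotation", "Rotation", "Upright, adducted",
    "Resisted shoulder external rotation", "External rotation", "Rotation", "Upright, adducted",
    "Resisted shoulder external rotation (abducted)", "External rotation", "Rotation", "Upright, abducted",
    "Resisted row", "Row", "Row", "Bent over",
    "Resisted triceps pull down", "Elbow-extension", "Elbow-flexion", "Upright",
    "Resisted lat pull down", "Pull down", "Pull down", "Upright",
    "Resisted lat pull down (external rotation)", "Pull down", "Pull down", "Upright",
    "Press up against wall", "Press up", "Press up", "Upright",
    "Resisted seratus anterior", "Press up", "Press up", "Upright",
    "Push up", "Press up", "Press up", "Prone"
  )
}

#' Grouping levels for exercise labels
#'
#' @return Character vector of the five supported grouping levels, from finest
#'   (`exercise`) to the coarser motion-type groupings.
#' @export
grouping_levels <- function() {
  c("exercise", "motion", "motion_position", "simple_motion",
    "simple_motion_position")
}

#' Map exercise-level labels to a coarser grouping
#'
#' Many-to-one relabelling of exercise classes by motion type, optionally
#' composed with body position (e.g. "Elevation-Upright"). The reserved
#' out-of-distribution label maps to itself at every level, and
#' `level = "exercise"` is the identity.
#'
#' @param labels Character vector of exercise-level labels (taxonomy names or
#'   [ood_label()]).
#' @param level One of [grouping_levels()].
#' @param tax Taxonomy tibble, by default [taxonomy()].
#' @return Character vector of the same length, relabelled.
#' @examples
#' apply_grouping("Active shoulder flexion", "simple_motion_position")
#' @export
apply_grouping <- function(labels, level = "exercise", tax = taxonomy()) {
  level <- match.arg(level, grouping_levels())
  labels <- as.character(labels)
  if (level == "exercise") {
    unknown <- setdiff(labels, c(tax$exercise, ood_label()))
    if (length(unknown) > 0L) {
      stop("unknown exercise label(s): ", paste(unique(unknown), collapse = ", "))
    }
    return(labels)
  }
  map <- switch(level,
    motion = tax$motion,
    simple_motion = tax$simple_motion,
    motion_position = paste(tax$motion, tax$position, sep = "-"),
    simple_motion_position = paste(tax$simple_motion, tax$position, sep = "-")
  )
  names(map) <- tax$exercise
  out <- character(length(labels))
  is_ood <- labels == ood_label()
  out[is_ood] <- ood_label()
  unknown <- setdiff(labels[!is_ood], tax$exercise)
  if (length(unknown) > 0L) {
    stop("unknown exercise label(s): ", paste(unique(unknown), collapse = ", "))
  }
  out[!is_ood] <- unname(map[labels[!is_ood]])
  out
}
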