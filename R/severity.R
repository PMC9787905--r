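# MDS-UPDRS Part III scoring structures and severity binning.

.SEVERITY_BREAKS <- c(0, 8, 32, 58, 132)
.SEVERITY_LEVELS <- c("normal", "mild", "moderate", "severe")

#' Severity cut-off intervals on the MDS-UPDRS Part III total
#'
#' The four-level scale used throughout the package: normal 0-8, mild 9-32,
#' moderate 33-58, severe 59-132. Intervals are contiguous, disjoint and
#' cover 0..132.
#'
#' @return A `data.frame` with columns `level`, `lower`, `upper`.
#' @export
severityScale <- function() {
  data.frame(level = .SEVERITY_LEVELS,
             lower = .SEVERITY_BREAKS[-5] + c(0, 1, 1, 1),
             upper = .SEVERITY_BREAKS[-1])
}

#' Bin an MDS-UPDRS Part III total score into a severity level
#'
#' @param part3Total Integer score(s) in 0..132.
#' @return Ordered factor with levels normal < mild < moderate < severe.
#' @examples
#' binSeverity(c(8, 9, 42))   # normal, mild, moderate
#' @export
binSeverity <- function(part3Total) {
  if (length(part3Total) == 0)
    return(factor(character(), levels = .SEVERITY_LEVELS, ordered = TRUE))
  if (anyNA(part3Total))
    stop("validation error: score is NA", call. = FALSE)
  if (!is.numeric(part3Total) || any(part3Total != round(part3Total)))
    stop("validation error: MDS-UPDRS Part III totals are integer-valued",
         call. = FALSE)
  if (any(part3Total < 0 | part3Total > 132))
    stop("validation error: score out of range 0..132", call. = FALSE)
  cut(part3Total, breaks = .SEVERITY_BREAKS + c(-1, 0, 0, 0, 0),
      labels = .SEVERITY_LEVELS, ordered_result = TRUE)
}

#' Total the six-item Control Subset
#'
#' Sums the six lower-extremity items of MDS-UPDRS Part III (3.9 arising
#' from chair, 3.10 gait, 3.11 freezing of gait, 3.12 postural stability,
#' 3.13 posture, 3.14 global spontaneity of movement), each rated 0..4;
#' maximum attainable total 24.
#'
#' @param items Integer vector of exactly 6 item scores in 0..4.
#' @return Integer total in 0..24.
#' @examples
#' controlSubsetTotal(c(1, 1, 0, 0, 0, 0))
#' @export
controlSubsetTotal <- function(items) {
  if (length(items) != 6L)
    stop("validation error: the Control Subset has exactly 6 items",
         call. = FALSE)
  if (anyNA(items) || !is.numeric(items) || any(items != round(items)) ||
      any(items < 0 | items > 4))
    stop("validation error: items must be integers in 0..4", call. = FALSE)
  as.integer(sum(items))
}

#' Validate a full MDS-UPDRS Part III score set
#'
#' @param part3Items Integer vector of 33 item scores, each 0..4, or `NULL`
#'   if only the total is known.
#' @param part3Total Integer total in 0..132; when `part3Items` is supplied
#'   it must equal their sum (default: computed from the items).
#' @param controlSubsetItems Optional integer vector of the six Control
#'   Subset items, each 0..4.
#' @return A list with `part3_items`, `part3_total`, `severity_level`,
#'   `control_subset_items`, `control_subset_total`.
#' @examples
#' clinicalScores(part3Total = 42)$severity_level
#' @export
clinicalScores <- function(part3Items = NULL, part3Total = NULL,
                           controlSubsetItems = NULL) {
  if (!is.null(part3Items)) {
    if (length(part3Items) != 33L)
      stop("validation error: MDS-UPDRS Part III has 33 items", call. = FALSE)
    if (anyNA(part3Items) || any(part3Items != round(part3Items)) ||
        any(part3Items < 0 | part3Items > 4))
      stop("validation error: items must be integers in 0..4", call. = FALSE)
    total <- as.integer(sum(part3Items))
    if (!is.null(part3Total) && part3Total != total)
      stop("validation error: part3Total does not equal the item sum",
           call. = FALSE)
    part3Total <- total
  }
  if (is.null(part3Total))
    stop("validation error: supply part3Items or part3Total", call. = FALSE)
  sev <- binSeverity(part3Total)
  cs <- if (!is.null(controlSubsetItems))
    controlSubsetTotal(controlSubsetItems) else NA_integer_
  list(part3_items = part3Items, part3_total = as.integer(part3Total),
       severity_level = sev,
       control_subset_items = controlSubsetItems, control_subset_total = cs)
}
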