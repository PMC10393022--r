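#' Significance thresholds for class admission
#'
#' Class 2 (increased) and Class 3 (decreased) proteins are admitted below
#' \code{class23_alpha} (study default 0.1). Class 1 proteins -- detected only
#' in the oocyte extract and on treated sperm -- are admitted at the loosened
#' \code{class1_alpha} (study default 0.2), because their all-zero control
#' vectors make the presence/absence pattern itself informative.
#'
#' @param class23_alpha p-value threshold for Classes 2 and 3 (default 0.1).
#' @param class1_alpha p-value threshold for Class 1 (default 0.2).
#' @return list of class \code{"significance_thresholds"}.
#' @export
significance_thresholds <- function(class23_alpha = 0.1, class1_alpha = 0.2) {
  if (!(class23_alpha > 0 && class23_alpha <= class1_alpha && class1_alpha < 1))
    stopf("need 0 < class23_alpha <= class1_alpha < 1")
  structure(list(class23_alpha = class23_alpha, class1_alpha = class1_alpha),
            class = "significance_thresholds")
}

#' Per-condition detection patterns at one timepoint
#'
#' A protein counts as "in" a condition when it is detected in at least
#' \code{presence_min} of that condition's replicates at the timepoint.
#' Extract and vehicle-control samples stamped timepoint \code{"na"} in the
#' sheet apply to every timepoint.
#'
#' @param dm a \code{detection_matrix}.
#' @param sheet a \code{\link{sample_sheet}}.
#' @param timepoint \code{"4h"} or \code{"24h"}.
#' @param presence_min minimum number of replicates (default 1).
#' @return data.frame: \code{protein_id}, \code{in_vehicle_control},
#'   \code{in_primed_control}, \code{in_extract}, \code{in_treated}.
#' @export
detection_pattern <- function(dm, sheet, timepoint, presence_min = 1L) {
  det <- dm$detected
  cols <- lapply(sheet_conditions, function(cond) {
    ids <- samples_of(sheet, cond, timepoint)
    if (!length(ids)) stopf("condition '%s' absent from sheet at timepoint '%s'",
                            cond, timepoint)
    if (presence_min < 1L || presence_min > length(ids))
      stopf("presence_min must lie in 1..%d for condition '%s'", length(ids), cond)
    rowSums(det[, ids, drop = FALSE]) >= presence_min
  })
  names(cols) <- paste0("in_", sheet_conditions)
  data.frame(protein_id = rownames(det), cols, stringsAsFactors = FALSE,
             row.names = NULL)
}

# class label for one protein given its pattern booleans, direction and p
class_rule <- function(in_vc, in_pc, in_ex, in_tr, direction, p, th) {
  if (!in_vc && !in_pc && in_ex && in_tr && p < th$class1_alpha)
    return(c("class1", th$class1_alpha))
  if (in_pc && direction == "increase" && p < th$class23_alpha)
    return(c("class2", th$class23_alpha))
  if (in_pc && direction == "decrease" && p < th$class23_alpha)
    return(c("class3", th$class23_alpha))
  c("unclassified", NA)
}

#' Classify one protein from its detection pattern and paired test
#'
#' Class 1: absent from both sperm controls, present in the extract and on
#' treated sperm (an extract-derived binder), p below the Class-1 threshold.
#' Class 2: present in primed-control sperm and significantly increased.
#' Class 3: present in primed-control sperm (with or without the extract,
#' i.e. "both gametes or only the spermatozoa") and significantly decreased.
#' Anything else is unclassified. At most one class can apply.
#'
#' @param pattern one-row data.frame from \code{\link{detection_pattern}}.
#' @param result one-row data.frame from \code{\link{run_differential}} (or a
#'   \code{"paired_t"} object plus matching protein).
#' @param thresholds a \code{\link{significance_thresholds}} object.
#' @return one-row data.frame: \code{protein_id}, \code{timepoint},
#'   \code{klass}, \code{p_value}, \code{direction}, \code{admitted_alpha}.
#' @export
assign_class <- function(pattern, result, thresholds = significance_thresholds()) {
  if (!identical(pattern$protein_id, result$protein_id))
    stopf("pattern/result protein mismatch: '%s' vs '%s'",
          pattern$protein_id, result$protein_id)
  cl <- class_rule(pattern$in_vehicle_control, pattern$in_primed_control,
                   pattern$in_extract, pattern$in_treated,
                   result$direction, result$p_value, thresholds)
  data.frame(protein_id = result$protein_id, timepoint = result$timepoint,
             klass = cl[1L], p_value = result$p_value,
             direction = result$direction,
             admitted_alpha = as.numeric(cl[2L]), stringsAsFactors = FALSE)
}

#' Classify every tested protein of one trial
#'
#' Vectorized \code{\link{assign_class}} over the test table; patterns are
#' matched to results by accession.
#'
#' @param patterns data.frame from \code{\link{detection_pattern}}.
#' @param results data.frame from \code{\link{run_differential}}.
#' @param thresholds a \code{\link{significance_thresholds}} object.
#' @return data.frame with one row per tested protein (columns as
#'   \code{\link{assign_class}}), carrying the thresholds as attribute
#'   \code{"thresholds"}.
#' @export
assign_classes <- function(patterns, results,
                           thresholds = significance_thresholds()) {
  idx <- match(results$protein_id, patterns$protein_id)
  if (anyNA(idx))
    stopf("pattern missing for protein(s): %s",
          paste(results$protein_id[is.na(idx)], collapse = ", "))
  pat <- patterns[idx, , drop = FALSE]
  cls <- character(nrow(results))
  alpha <- numeric(nrow(results))
  for (i in seq_len(nrow(results))) {
    cl <- class_rule(pat$in_vehicle_control[i], pat$in_primed_control[i],
                     pat$in_extract[i], pat$in_treated[i],
                     results$direction[i], results$p_value[i], thresholds)
    cls[i] <- cl[1L]
    alpha[i] <- as.numeric(cl[2L])
  }
  out <- data.frame(protein_id = results$protein_id,
                    timepoint = results$timepoint, klass = cls,
                    p_value = results$p_value, direction = results$direction,
                    admitted_alpha = alpha, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}
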