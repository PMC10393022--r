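#' Default outer-dense-fiber reference accessions
#'
#' ODF1, ODF2 and ODF3 are structural proteins of the sperm flagellum's outer
#' dense fibers. Their summed spectral counts act as a sperm-load anchor:
#' scaling sperm samples so that the anchors agree removes differences in the
#' number of spermatozoa entering each sample.
#'
#' @return character vector of the default reference accessions.
#' @export
odf_reference <- function() c("ODF1", "ODF2", "ODF3")

new_scale_factors <- function(f, stage, reference_value) {
  if (any(!is.finite(f)) || any(f <= 0))
    stopf("scale factors must be positive and finite")
  structure(f, stage = stage, reference_value = reference_value,
            class = "scale_factors")
}

#' @export
print.scale_factors <- function(x, ...) {
  cat(sprintf("Scale factors (stage: %s, reference value %.4g)\n",
              attr(x, "stage"), attr(x, "reference_value")))
  print(round(unclass(x), 4))
  invisible(x)
}

# pull a plain numeric matrix out of any of the containers upstream stages emit
as_count_matrix <- function(m) {
  if (inherits(m, "detection_matrix")) return(m$censored_counts)
  if (is.matrix(m)) return(unclass(m))
  stopf("expected a count matrix or detection_matrix")
}

#' Reference-protein (ODF) scale factors
#'
#' Computes one multiplicative factor per target sample so that the summed
#' spectral counts of the reference accessions become equal across the target
#' samples, anchored at the arithmetic mean of the per-sample reference sums.
#' Samples outside the target set receive factor 1.
#'
#' @param m count matrix or \code{detection_matrix} (censored counts are used).
#' @param reference character vector of reference accessions
#'   (default \code{\link{odf_reference}()}).
#' @param target_samples sample ids to scale (default: all columns).
#' @return a \code{"scale_factors"} object: named factor vector with
#'   attributes \code{stage = "odf"} and \code{reference_value}.
#' @export
odf_scale_factors <- function(m, reference = odf_reference(),
                              target_samples = NULL) {
  mm <- as_count_matrix(m)
  target_samples <- target_samples %||% colnames(mm)
  if (!length(reference)) stopf("reference set is empty")
  miss <- setdiff(reference, rownames(mm))
  if (length(miss))
    stopf("reference accession(s) absent from matrix: %s", paste(miss, collapse = ", "))
  miss <- setdiff(target_samples, colnames(mm))
  if (length(miss))
    stopf("target sample(s) absent from matrix: %s", paste(miss, collapse = ", "))
  totals <- colSums(mm[reference, target_samples, drop = FALSE])
  zero <- names(totals)[totals <= 0]
  if (length(zero))
    stopf("zero reference counts in target sample(s): %s", paste(zero, collapse = ", "))
  ref_value <- mean(totals)
  f <- stats::setNames(rep(1, ncol(mm)), colnames(mm))
  f[target_samples] <- ref_value / totals
  new_scale_factors(f, "odf", ref_value)
}

#' Mean scale factors
#'
#' Second normalization stage: scales each target sample so that its mean
#' value over a chosen protein set equals the grand mean of those per-sample
#' means, reducing residual batch variance. With \code{shared_only = TRUE}
#' the means run over proteins observed (value > 0) in every target sample,
#' so presence/absence differences cannot dominate the scaling.
#'
#' @param m count matrix, \code{detection_matrix}, or normalized matrix.
#' @param target_samples sample ids to scale (default: all columns).
#' @param shared_only use only proteins present in all target samples
#'   (default \code{TRUE}).
#' @return a \code{"scale_factors"} object with \code{stage = "mean"}.
#' @export
mean_scale_factors <- function(m, target_samples = NULL, shared_only = TRUE) {
  mm <- as_count_matrix(m)
  target_samples <- target_samples %||% colnames(mm)
  miss <- setdiff(target_samples, colnames(mm))
  if (length(miss))
    stopf("target sample(s) absent from matrix: %s", paste(miss, collapse = ", "))
  sub <- mm[, target_samples, drop = FALSE]
  if (shared_only) {
    keep <- rowSums(sub > 0) == ncol(sub)
    if (!any(keep)) stopf("no protein is present in every target sample")
    sub <- sub[keep, , drop = FALSE]
  }
  means <- colMeans(sub)
  zero <- names(means)[means <= 0]
  if (length(zero))
    stopf("zero sample mean in target sample(s): %s", paste(zero, collapse = ", "))
  grand <- mean(means)
  f <- stats::setNames(rep(1, ncol(mm)), colnames(mm))
  f[target_samples] <- grand / means
  new_scale_factors(f, "mean", grand)
}

#' Apply per-sample scale factors
#'
#' Multiplies each sample column by its factor; samples without a factor keep
#' factor 1. The applied stage is appended to the matrix's provenance so a
#' normalized matrix records the ordered list of scalings that produced it.
#'
#' @param m count matrix, \code{detection_matrix}, or normalized matrix.
#' @param f a \code{"scale_factors"} object (or named positive numeric).
#' @return a \code{"normalized_counts"} matrix with attribute
#'   \code{provenance} (list of applied scale-factor stages, in order).
#' @export
apply_scaling <- function(m, f) {
  mm <- as_count_matrix(m)
  if (is.null(names(f))) stopf("scale factors must be named by sample id")
  if (any(!is.finite(f)) || any(f <= 0)) stopf("scale factors must be positive and finite")
  ff <- stats::setNames(rep(1, ncol(mm)), colnames(mm))
  ff[intersect(names(f), colnames(mm))] <- f[intersect(names(f), colnames(mm))]
  out <- sweep(mm, 2L, ff, `*`)
  prov <- c(attr(m, "provenance") %||% list(), list(f))
  structure(out, provenance = prov, class = c("normalized_counts", class(matrix())))
}

#' @export
print.normalized_counts <- function(x, ...) {
  stages <- vapply(attr(x, "provenance"), function(s) attr(s, "stage") %||% "?", "")
  cat(sprintf("Normalized counts: %d proteins x %d samples (stages: %s)\n",
              nrow(x), ncol(x), paste(stages, collapse = " -> ")))
  invisible(x)
}

#' Two-stage normalization of one co-incubation trial
#'
#' Convenience wrapper applying the study's normalization order within one
#' timepoint batch: first reference (ODF) scaling of the sperm-containing
#' samples, then mean scaling across the batch. Oocyte-extract samples carry
#' no sperm flagellum and are excluded from the reference stage.
#'
#' @param dm a \code{detection_matrix} (censored counts are normalized).
#' @param sheet a \code{\link{sample_sheet}}.
#' @param timepoint \code{"4h"} or \code{"24h"}.
#' @param reference reference accessions (default \code{\link{odf_reference}()}).
#' @param shared_only passed to \code{\link{mean_scale_factors}}.
#' @param odf_conditions conditions whose samples are reference-scaled
#'   (default: the three sperm-containing conditions).
#' @param mean_conditions conditions entering the mean stage (default: all
#'   four, i.e. extract samples are mean-normalized too).
#' @return list with \code{normalized} (the batch's normalized matrix, columns
#'   restricted to the batch samples) and \code{factors} (list of the two
#'   \code{"scale_factors"} stages).
#' @export
normalize_counts <- function(dm, sheet, timepoint,
                             reference = odf_reference(), shared_only = TRUE,
                             odf_conditions = c("vehicle_control",
                                                "primed_control", "treated"),
                             mean_conditions = c("vehicle_control",
                                                 "primed_control", "extract",
                                                 "treated")) {
  batch <- unlist(lapply(unique(c(odf_conditions, mean_conditions)),
                         samples_of, sheet = sheet, timepoint = timepoint))
  batch <- intersect(colnames(as_count_matrix(dm)), unique(batch))
  if (!length(batch)) stopf("no samples at timepoint '%s'", timepoint)
  mm <- as_count_matrix(dm)[, batch, drop = FALSE]

  odf_targets <- intersect(batch, unlist(lapply(odf_conditions, samples_of,
                                                sheet = sheet, timepoint = timepoint)))
  f_odf <- odf_scale_factors(mm, reference, odf_targets)
  step1 <- apply_scaling(mm, f_odf)

  mean_targets <- intersect(batch, unlist(lapply(mean_conditions, samples_of,
                                                 sheet = sheet, timepoint = timepoint)))
  f_mean <- mean_scale_factors(unclass(step1), mean_targets, shared_only = shared_only)
  normalized <- apply_scaling(step1, f_mean)

  list(normalized = normalized, factors = list(odf = f_odf, mean = f_mean))
}
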