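#' Fit the cell-free screening model to one co-incubation trial
#'
#' The main fitting function: runs the whole per-timepoint procedure on a raw
#' spectral-count matrix -- per-sample detection filtering, two-stage
#' normalization (reference/ODF scaling of sperm samples, then mean scaling),
#' per-protein paired t-tests of primed-control vs treated sperm, and
#' presence/absence classification into Classes 1-3.
#'
#' @param counts a \code{\link{spectral_counts}} matrix (or path to one).
#' @param sheet a \code{\link{sample_sheet}} (or path).
#' @param timepoint trial to analyse, \code{"4h"} or \code{"24h"}.
#' @param min_spectra detection floor (default 4 spectra per protein per
#'   sample).
#' @param reference reference accessions for the first normalization stage
#'   (default \code{\link{odf_reference}()}).
#' @param presence_min replicates required to call a protein present in a
#'   condition (default 1).
#' @param thresholds a \code{\link{significance_thresholds}} object.
#' @param shared_only mean-normalize over shared proteins only (default TRUE).
#' @param normalized optionally, an already-normalized matrix (the
#'   "from-normalized" entry mode, e.g. values recomputed elsewhere); when
#'   given, the filtering and normalization stages are skipped and zeros in
#'   this matrix encode non-detection.
#' @return object of class \code{"cellfree_screen"}: list with
#'   \code{detection}, \code{factors}, \code{normalized}, \code{tests},
#'   \code{patterns}, \code{assignments}, \code{params}.
#' @seealso \code{\link{build_inventory}} to merge two trials,
#'   \code{\link{truth_confusion}} to score simulated data.
#' @export
cellfree_screen <- function(counts, sheet, timepoint,
                            min_spectra = 4L, reference = odf_reference(),
                            presence_min = 1L,
                            thresholds = significance_thresholds(),
                            shared_only = TRUE, normalized = NULL) {
  if (is.character(counts)) counts <- read_spectral_counts(counts)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  stopifnot(inherits(sheet, "sample_sheet"))

  if (is.null(normalized)) {
    dm <- apply_detection_filter(counts, min_spectra)
    norm <- normalize_counts(dm, sheet, timepoint, reference = reference,
                             shared_only = shared_only)
    normalized <- norm$normalized
    factors <- norm$factors
  } else {
    # from-normalized mode: treat positive normalized values as detections
    mm <- as_count_matrix(normalized)
    dm <- structure(list(detected = mm > 0, censored_counts = mm,
                         min_spectra = NA_integer_),
                    class = "detection_matrix")
    factors <- list()
  }
  tests <- run_differential(normalized, sheet, timepoint)
  patterns <- detection_pattern(dm, sheet, timepoint, presence_min)
  assignments <- assign_classes(patterns, tests, thresholds)
  structure(list(timepoint = timepoint, detection = dm, factors = factors,
                 normalized = normalized, tests = tests, patterns = patterns,
                 assignments = assignments,
                 params = list(min_spectra = min_spectra,
                               reference = reference,
                               presence_min = presence_min,
                               thresholds = thresholds,
                               shared_only = shared_only)),
            class = "cellfree_screen")
}

#' @export
print.cellfree_screen <- function(x, ...) {
  tab <- table(factor(x$assignments$klass,
                      c("class1", "class2", "class3", "unclassified")))
  cat(sprintf("Cell-free screen, %s trial\n", x$timepoint))
  cat(sprintf("  proteins tested: %d\n", nrow(x$tests)))
  cat(sprintf("  class1 (extract-derived binders): %d\n", tab["class1"]))
  cat(sprintf("  class2 (increased on sperm):      %d\n", tab["class2"]))
  cat(sprintf("  class3 (degraded from sperm):     %d\n", tab["class3"]))
  cat(sprintf("  unclassified:                     %d\n", tab["unclassified"]))
  invisible(x)
}

#' Summarize a fitted cell-free screen
#'
#' @param object a \code{"cellfree_screen"}.
#' @param n number of top candidates (smallest p) to list per class.
#' @param ... unused.
#' @return object of class \code{"summary.cellfree_screen"}.
#' @export
summary.cellfree_screen <- function(object, n = 5L, ...) {
  a <- object$assignments
  top <- lapply(c("class1", "class2", "class3"), function(k) {
    sel <- a[a$klass == k, , drop = FALSE]
    utils::head(sel[order(sel$p_value), ], n)
  })
  names(top) <- c("class1", "class2", "class3")
  structure(list(timepoint = object$timepoint, n_tested = nrow(object$tests),
                 class_counts = table(a$klass), top = top,
                 thresholds = object$params$thresholds),
            class = "summary.cellfree_screen")
}

#' @export
print.summary.cellfree_screen <- function(x, ...) {
  cat(sprintf("Cell-free screen summary (%s trial): %d proteins tested\n",
              x$timepoint, x$n_tested))
  cat(sprintf("  thresholds: p < %g (class 2/3), p < %g (class 1)\n",
              x$thresholds$class23_alpha, x$thresholds$class1_alpha))
  for (k in names(x$top)) {
    cat(sprintf("-- %s top candidates --\n", k))
    if (nrow(x$top[[k]])) print(x$top[[k]], row.names = FALSE)
    else cat("  (none)\n")
  }
  invisible(x)
}

#' Plot per-class candidate counts of a fitted screen
#'
#' @param x a \code{"cellfree_screen"}.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.cellfree_screen <- function(x, ...) {
  tab <- table(factor(x$assignments$klass,
                      c("class1", "class2", "class3", "unclassified")))
  graphics::barplot(tab, ylab = "proteins",
                    main = sprintf("%s trial classification", x$timepoint), ...)
  invisible(x)
}

#' Read an already-normalized abundance matrix
#'
#' Entry point for the "from-normalized" mode: a delimited table whose first
#' column is the accession and whose remaining columns are per-sample
#' normalized abundances (non-negative reals; zeros encode non-detection).
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} auto-detects.
#' @return a numeric matrix with accession rownames.
#' @export
read_normalized_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  acc <- as.character(df[[1L]])
  if (anyDuplicated(acc))
    stopf("duplicate accession(s) in %s", path)
  m <- as.matrix(df[-1L])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0))
    stopf("normalized values must be non-negative numbers: %s", path)
  rownames(m) <- acc
  m
}
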