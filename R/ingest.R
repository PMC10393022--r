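#' Construct a validated spectral-count matrix
#'
#' A spectral-count matrix holds non-negative integer MS/MS spectrum counts,
#' one row per protein accession and one column per sample. A zero means the
#' protein was not observed in that sample; spectral counting has no distinct
#' missing-value code.
#'
#' @param counts numeric matrix with unique rownames (protein accessions) and
#'   unique colnames (sample identifiers); all entries non-negative integers.
#' @return the validated matrix with class \code{"spectral_counts"}.
#' @export
spectral_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("spectral-count matrix needs protein rownames and sample colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stopf("duplicate protein accession(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stopf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (!is.numeric(counts))
    stopf("spectral counts must be numeric")
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("invalid count at protein '%s', sample '%s': %s",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
          format(counts[bad[1, , drop = FALSE]]))
  }
  storage.mode(counts) <- "double"
  class(counts) <- c("spectral_counts", class(matrix()))
  counts
}

#' Read a spectral-count table from delimited text
#'
#' Expects a header line; the first column holds protein accessions and every
#' remaining column the spectrum counts of one sample. The delimiter is
#' auto-detected (tab or comma) unless forced.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) auto-detects.
#' @return a \code{\link{spectral_counts}} matrix; row and column order are
#'   preserved from the file.
#' @export
read_spectral_counts <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  if (ncol(df) < 2L) stopf("expected an accession column plus sample columns: %s", path)
  acc <- df[[1L]]
  if (anyDuplicated(acc))
    stopf("duplicate protein accession(s) in %s: %s", path,
          paste(unique(acc[duplicated(acc)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(acc, colnames(df)[-1L]))
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stopf("invalid count at row '%s', column '%s': %s",
            acc[bad[1L]], colnames(m)[j], df[[j + 1L]][bad[1L]])
    m[, j] <- v
  }
  spectral_counts(m)
}

#' Write a spectral-count matrix as delimited text
#'
#' Inverse of \code{\link{read_spectral_counts}}; a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param x a \code{\link{spectral_counts}} matrix (or any numeric matrix).
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_spectral_counts <- function(x, path, sep = "\t") {
  df <- data.frame(accession = rownames(x), unclass(x), check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat(sprintf("Spectral counts: %d proteins x %d samples\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more proteins\n", nrow(x) - 6L))
  invisible(x)
}

sheet_conditions <- c("vehicle_control", "primed_control", "extract", "treated")
sheet_timepoints <- c("4h", "24h", "na")

#' Construct a validated sample sheet
#'
#' The sample sheet describes the paired experimental design: each row is one
#' sample with its condition (vehicle-control sperm, primed-control sperm,
#' oocyte extract, or cell-free-treated sperm), co-incubation timepoint,
#' biological replicate, and a pair id linking each treated sample to the
#' primed-control sample of the same replicate. Extract and vehicle-control
#' samples may carry timepoint \code{"na"}, meaning they apply to every trial.
#'
#' @param df data.frame with columns \code{sample_id}, \code{condition},
#'   \code{timepoint}, \code{replicate}, \code{pair_id}. Condition and
#'   timepoint labels are matched case-insensitively.
#' @return a \code{data.frame} of class \code{"sample_sheet"}.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "condition", "timepoint", "replicate", "pair_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id(s): %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  cond <- tolower(trimws(as.character(df$condition)))
  bad <- setdiff(unique(cond), sheet_conditions)
  if (length(bad)) stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  df$condition <- cond
  tp <- tolower(trimws(as.character(df$timepoint)))
  tp[tp %in% c("", "not_applicable", "none")] <- "na"
  bad <- setdiff(unique(tp), sheet_timepoints)
  if (length(bad)) stopf("unknown timepoint label(s): %s", paste(bad, collapse = ", "))
  df$timepoint <- tp
  df$replicate <- as.integer(df$replicate)
  df$pair_id <- as.character(df$pair_id)

  # every treated sample needs exactly one primed_control partner sharing
  # pair_id and timepoint
  tr <- df[df$condition == "treated", ]
  pc <- df[df$condition == "primed_control", ]
  for (i in seq_len(nrow(tr))) {
    hit <- pc$pair_id == tr$pair_id[i] & pc$timepoint == tr$timepoint[i]
    if (sum(hit) != 1L)
      stopf("treated sample '%s' has %d primed_control partner(s) for pair '%s'",
            tr$sample_id[i], sum(hit), tr$pair_id[i])
  }
  # replicate indices unique within condition x timepoint
  key <- paste(df$condition, df$timepoint, df$replicate)
  if (anyDuplicated(key))
    stopf("duplicate replicate index within condition x timepoint: %s",
          key[duplicated(key)][1L])
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from delimited text
#'
#' @param path file path to a delimited file with columns \code{sample_id},
#'   \code{condition}, \code{timepoint}, \code{replicate}, \code{pair_id}.
#' @param sep field separator; \code{NULL} auto-detects.
#' @return a validated \code{\link{sample_sheet}}.
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sep <- sep %||% sniff_sep(path)
  sample_sheet(utils::read.table(path, header = TRUE, sep = sep,
                                 check.names = FALSE, colClasses = "character"))
}

# samples of one condition usable at a timepoint ("na"-stamped samples are
# timepoint-agnostic)
samples_of <- function(sheet, condition, timepoint) {
  sheet$sample_id[sheet$condition == condition &
                    (sheet$timepoint == timepoint | sheet$timepoint == "na")]
}

# primed_control / treated sample pairs at a timepoint, ordered by pair_id
sample_pairs <- function(sheet, timepoint) {
  tr <- sheet[sheet$condition == "treated" & sheet$timepoint == timepoint, ]
  pc <- sheet[sheet$condition == "primed_control" & sheet$timepoint == timepoint, ]
  tr <- tr[order(tr$pair_id), ]
  data.frame(pair_id = tr$pair_id,
             control = pc$sample_id[match(tr$pair_id, pc$pair_id)],
             treated = tr$sample_id, stringsAsFactors = FALSE)
}

#' Apply the per-sample protein detection rule
#'
#' A protein counts as detected in a sample only if it was matched by at least
#' \code{min_spectra} spectra there (the identification acceptance rule of the
#' upstream database search, re-applied here as an explicit filter so that all
#' inputs pass the same gate). Sub-threshold counts are censored to zero.
#'
#' @param m a \code{\link{spectral_counts}} matrix.
#' @param min_spectra detection floor, spectra per protein per sample
#'   (default 4).
#' @return an object of class \code{"detection_matrix"}: a list with
#'   \code{detected} (logical matrix), \code{censored_counts} (numeric matrix
#'   with sub-threshold entries zeroed) and \code{min_spectra}.
#' @export
apply_detection_filter <- function(m, min_spectra = 4L) {
  if (min_spectra < 1L) stopf("min_spectra must be >= 1")
  mm <- unclass(m)
  detected <- mm >= min_spectra
  censored <- mm
  censored[!detected] <- 0
  structure(list(detected = detected, censored_counts = censored,
                 min_spectra = as.integer(min_spectra)),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("Detection matrix: %d proteins x %d samples (floor %d spectra)\n",
              nrow(x$detected), ncol(x$detected), x$min_spectra))
  cat(sprintf("  %.1f%% of cells detected\n", 100 * mean(x$detected)))
  invisible(x)
}
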