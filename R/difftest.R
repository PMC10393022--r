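#' Paired t-test on one protein's replicate values
#'
#' The study's core statistic: per-replicate differences
#' \eqn{d_i = treated_i - control_i} are tested with a one-sample t statistic
#' \eqn{t = \bar d / (s_d/\sqrt{n})} (sample standard deviation, n-1
#' denominator) against a two-sided Student t tail with n-1 degrees of
#' freedom. Direction is read from the sign of \eqn{\bar d} separately.
#'
#' Degenerate replicate sets (zero standard deviation of the differences) are
#' resolved deterministically: all differences zero gives p = 1 and direction
#' \code{"none"}; constant non-zero differences give p = 0 with the sign's
#' direction. Both carry \code{degenerate = TRUE} and an undefined t.
#'
#' @param control,treated numeric vectors of equal length >= 2, paired by
#'   index (replicate).
#' @return object of class \code{"paired_t"}: list with \code{diffs},
#'   \code{n_pairs}, \code{mean_control}, \code{mean_treated},
#'   \code{mean_diff}, \code{t_stat}, \code{df}, \code{p_value},
#'   \code{direction} (\code{"increase"}, \code{"decrease"} or \code{"none"}),
#'   \code{degenerate}.
#' @export
paired_t <- function(control, treated) {
  if (length(control) != length(treated))
    stopf("control and treated must have equal length (got %d and %d)",
          length(control), length(treated))
  n <- length(control)
  if (n < 2L) stopf("need at least 2 pairs, got %d", n)
  d <- treated - control
  m <- mean(d)
  s <- stats::sd(d)
  direction <- if (m > 0) "increase" else if (m < 0) "decrease" else "none"
  if (s == 0) {
    res <- list(t_stat = NA_real_, p_value = if (m == 0) 1 else 0,
                degenerate = TRUE)
  } else {
    t <- m / (s / sqrt(n))
    res <- list(t_stat = t, p_value = 2 * stats::pt(-abs(t), df = n - 1L),
                degenerate = FALSE)
  }
  structure(list(diffs = d, n_pairs = n,
                 mean_control = mean(control), mean_treated = mean(treated),
                 mean_diff = m, t_stat = res$t_stat, df = n - 1L,
                 p_value = res$p_value, direction = direction,
                 degenerate = res$degenerate),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t: n = %d, mean diff = %.4g, t = %s, df = %d, p = %.4g (%s%s)\n",
              x$n_pairs, x$mean_diff,
              if (is.na(x$t_stat)) "NA" else sprintf("%.4f", x$t_stat),
              x$df, x$p_value, x$direction,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Per-protein paired differential tests for one trial
#'
#' Runs \code{\link{paired_t}} on every protein present in at least one
#' primed-control or treated sample of the timepoint, pairing samples by
#' replicate (pair id). Non-detected cells enter as 0 -- required so that
#' extract-derived proteins, absent from every control, can still be tested.
#' Proteins detected in neither condition are omitted.
#'
#' @param nm normalized (or censored count) matrix whose zeros encode
#'   non-detection.
#' @param sheet a \code{\link{sample_sheet}}.
#' @param timepoint \code{"4h"} or \code{"24h"}.
#' @return data.frame with one row per tested protein: \code{protein_id},
#'   \code{timepoint}, \code{n_pairs}, \code{mean_control},
#'   \code{mean_treated}, \code{mean_diff}, \code{t_stat}, \code{df},
#'   \code{p_value}, \code{direction}, \code{degenerate}.
#' @export
run_differential <- function(nm, sheet, timepoint) {
  mm <- as_count_matrix(nm)
  pairs <- sample_pairs(sheet, timepoint)
  if (nrow(pairs) < 2L)
    stopf("need >= 2 primed_control/treated pairs at timepoint '%s'", timepoint)
  miss <- setdiff(c(pairs$control, pairs$treated), colnames(mm))
  if (length(miss)) stopf("sample(s) absent from matrix: %s", paste(miss, collapse = ", "))
  ctl <- mm[, pairs$control, drop = FALSE]
  trt <- mm[, pairs$treated, drop = FALSE]
  keep <- rowSums(ctl > 0) + rowSums(trt > 0) > 0
  ids <- rownames(mm)[keep]
  out <- lapply(ids, function(p) {
    r <- paired_t(ctl[p, ], trt[p, ])
    data.frame(protein_id = p, timepoint = timepoint, n_pairs = r$n_pairs,
               mean_control = r$mean_control, mean_treated = r$mean_treated,
               mean_diff = r$mean_diff, t_stat = r$t_stat, df = r$df,
               p_value = r$p_value, direction = r$direction,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(protein_id = character(), timepoint = character(),
                      n_pairs = integer(), mean_control = numeric(),
                      mean_treated = numeric(), mean_diff = numeric(),
                      t_stat = numeric(), df = integer(), p_value = numeric(),
                      direction = character(), degenerate = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
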