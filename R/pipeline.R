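#' Run the full screening pipeline and write all result tables
#'
#' Orchestrates both trials end to end -- ingest, detection filtering,
#' two-stage normalization, paired testing, classification, cross-timepoint
#' inventory and category summaries -- and writes every intermediate table as
#' TSV. Deterministic: identical inputs and settings give byte-identical
#' outputs.
#'
#' @param counts a \code{\link{spectral_counts}} matrix (or path) covering the
#'   samples of both trials.
#' @param sheet a \code{\link{sample_sheet}} (or path).
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param timepoints trials to run (default both).
#' @param annotation optional accession-to-category map (named vector,
#'   two-column data.frame, or path to one).
#' @param ... further arguments passed to \code{\link{cellfree_screen}}
#'   (\code{min_spectra}, \code{reference}, \code{presence_min},
#'   \code{thresholds}, \code{shared_only}).
#' @return object of class \code{"screen_report"}: per-stage protein counts,
#'   applied scale factors, threshold echo, the fitted screens, inventory and
#'   written file paths.
#' @export
run_pipeline <- function(counts, sheet, out_dir = NULL,
                         timepoints = c("4h", "24h"), annotation = NULL, ...) {
  if (is.character(counts)) counts <- read_spectral_counts(counts)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(annotation) && length(annotation) == 1L &&
      is.null(names(annotation))) {
    ann <- utils::read.table(annotation, header = TRUE, sep = sniff_sep(annotation),
                             stringsAsFactors = FALSE)
    annotation <- stats::setNames(as.character(ann[[2L]]), as.character(ann[[1L]]))
  }
  screens <- lapply(timepoints, function(tp)
    cellfree_screen(counts, sheet, tp, ...))
  names(screens) <- timepoints

  inventory <- if (all(c("4h", "24h") %in% timepoints))
    build_inventory(screens[["4h"]], screens[["24h"]], annotation)
  else NULL
  categories <- if (!is.null(inventory)) category_frequencies(inventory) else NULL

  stage_counts <- lapply(screens, function(s) {
    list(proteins_in = nrow(s$detection$detected),
         proteins_detected = sum(rowSums(s$detection$detected) > 0),
         proteins_tested = nrow(s$tests),
         classified = table(factor(s$assignments$klass,
                                   c("class1", "class2", "class3",
                                     "unclassified"))))
  })
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      path
    }
    for (tp in timepoints) {
      s <- screens[[tp]]
      nmat <- data.frame(accession = rownames(s$normalized),
                         unclass(s$normalized), check.names = FALSE)
      files <- c(files, wr(nmat, sprintf("normalized_%s.tsv", tp)))
      fac <- do.call(rbind, lapply(s$factors, function(f)
        data.frame(sample_id = names(f), stage = attr(f, "stage"),
                   factor = as.numeric(f),
                   reference_value = attr(f, "reference_value"))))
      files <- c(files, wr(fac, sprintf("scale_factors_%s.tsv", tp)))
      files <- c(files, wr(s$tests, sprintf("paired_tests_%s.tsv", tp)))
      files <- c(files, wr(s$assignments, sprintf("assignments_%s.tsv", tp)))
      # one inventory sheet per trial
      if (!is.null(inventory)) {
        e <- inventory$entries
        in_tp <- if (tp == "4h") e$in_4h else e$in_24h
        kl <- if (tp == "4h") e$class_4h else e$class_24h
        sel <- e[in_tp, c("protein_id", "category"), drop = FALSE]
        sel$class <- kl[in_tp]
        idx <- match(sel$protein_id, s$assignments$protein_id)
        sel$p_value <- s$assignments$p_value[idx]
        sel$direction <- s$assignments$direction[idx]
        files <- c(files, wr(sel[c("protein_id", "class", "p_value",
                                   "direction", "category")],
                             sprintf("inventory_%s.tsv", tp)))
      }
    }
    if (!is.null(inventory))
      files <- c(files, wr(inventory$entries, "inventory.tsv"))
    if (!is.null(categories))
      files <- c(files, wr(categories, "categories.tsv"))
  }
  structure(list(timepoints = timepoints, screens = screens,
                 inventory = inventory, categories = categories,
                 stage_counts = stage_counts,
                 thresholds = screens[[1L]]$params$thresholds,
                 params = screens[[1L]]$params, files = files),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Cell-free screening pipeline report\n")
  cat(sprintf("  thresholds: p < %g (class 2/3), p < %g (class 1)\n",
              x$thresholds$class23_alpha, x$thresholds$class1_alpha))
  for (tp in x$timepoints) {
    sc <- x$stage_counts[[tp]]
    cat(sprintf("  %s trial: %d proteins in, %d detected, %d tested; ",
                tp, sc$proteins_in, sc$proteins_detected, sc$proteins_tested))
    cat(paste(sprintf("%s=%d", names(sc$classified), sc$classified),
              collapse = " "), "\n")
  }
  if (!is.null(x$inventory)) print(x$inventory)
  if (length(x$files)) cat(sprintf("  %d tables written\n", length(x$files)))
  invisible(x)
}

#' Compare two pipeline runs
#'
#' Reconciles class memberships between two runs of the screen (e.g. a
#' recomputed normalization versus precomputed normalized values): lists
#' every accession whose class changed at either timepoint and the per-class
#' count deltas.
#'
#' @param a,b \code{"screen_report"} or \code{"mitophagy_inventory"} objects.
#' @return object of class \code{"run_diff"}: data.frame \code{changes}
#'   (accession, timepoint, class in a, class in b) and \code{count_deltas}.
#' @export
compare_runs <- function(a, b) {
  inv_a <- if (inherits(a, "screen_report")) a$inventory else a
  inv_b <- if (inherits(b, "screen_report")) b$inventory else b
  stopifnot(inherits(inv_a, "mitophagy_inventory"),
            inherits(inv_b, "mitophagy_inventory"))
  ids <- union(inv_a$entries$protein_id, inv_b$entries$protein_id)
  ea <- inv_a$entries[match(ids, inv_a$entries$protein_id), ]
  eb <- inv_b$entries[match(ids, inv_b$entries$protein_id), ]
  changes <- list()
  for (tp in c("4h", "24h")) {
    ka <- if (tp == "4h") ea$class_4h else ea$class_24h
    kb <- if (tp == "4h") eb$class_4h else eb$class_24h
    diff <- which(is.na(ka) != is.na(kb) |
                    (!is.na(ka) & !is.na(kb) & ka != kb))
    if (length(diff))
      changes[[tp]] <- data.frame(protein_id = ids[diff], timepoint = tp,
                                  class_a = ka[diff], class_b = kb[diff],
                                  stringsAsFactors = FALSE)
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(protein_id = character(), timepoint = character(),
               class_a = character(), class_b = character(),
               stringsAsFactors = FALSE)
  rownames(changes) <- NULL
  deltas <- list(
    n_4h = inv_b$totals$n_4h - inv_a$totals$n_4h,
    n_24h = inv_b$totals$n_24h - inv_a$totals$n_24h,
    n_union = inv_b$totals$n_union - inv_a$totals$n_union,
    by_class_4h = inv_b$totals$by_class_4h - inv_a$totals$by_class_4h,
    by_class_24h = inv_b$totals$by_class_24h - inv_a$totals$by_class_24h)
  structure(list(changes = changes, count_deltas = deltas), class = "run_diff")
}

#' @export
print.run_diff <- function(x, ...) {
  if (!nrow(x$changes)) {
    cat("Runs agree: no class membership differences\n")
  } else {
    cat(sprintf("%d class membership difference(s):\n", nrow(x$changes)))
    print(x$changes, row.names = FALSE)
  }
  invisible(x)
}
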