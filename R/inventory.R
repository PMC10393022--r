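#' Merge two trials' class assignments into the candidate inventory
#'
#' Each trial contributes the proteins assigned any class; the inventory
#' records both trials' classes per protein, flags overlap (present in both),
#' and tallies per-class totals plus the union/intersection arithmetic
#' (inclusion-exclusion holds as an integer identity).
#'
#' @param a4,a24 assignment tables from \code{\link{assign_classes}} (or
#'   \code{"cellfree_screen"} objects) for the 4 h and 24 h trials. Both must
#'   have been computed with identical thresholds.
#' @param annotation optional named character vector or two-column data.frame
#'   mapping accession to functional category.
#' @return object of class \code{"mitophagy_inventory"}: list with
#'   \code{entries} (data.frame: \code{protein_id}, \code{class_4h},
#'   \code{class_24h}, \code{in_4h}, \code{in_24h}, \code{overlap},
#'   \code{category}) and \code{totals} (per-timepoint, per-class, union and
#'   intersection sizes).
#' @export
build_inventory <- function(a4, a24, annotation = NULL) {
  if (inherits(a4, "cellfree_screen")) a4 <- a4$assignments
  if (inherits(a24, "cellfree_screen")) a24 <- a24$assignments
  th4 <- attr(a4, "thresholds")
  th24 <- attr(a24, "thresholds")
  if (!is.null(th4) && !is.null(th24) && !identical(unclass(th4), unclass(th24)))
    stopf("assignments were computed with different thresholds")

  hit4 <- a4[a4$klass != "unclassified", , drop = FALSE]
  hit24 <- a24[a24$klass != "unclassified", , drop = FALSE]
  ids <- union(hit4$protein_id, hit24$protein_id)
  entries <- data.frame(
    protein_id = ids,
    class_4h = hit4$klass[match(ids, hit4$protein_id)],
    class_24h = hit24$klass[match(ids, hit24$protein_id)],
    in_4h = ids %in% hit4$protein_id,
    in_24h = ids %in% hit24$protein_id,
    stringsAsFactors = FALSE)
  entries$overlap <- entries$in_4h & entries$in_24h
  entries$category <- lookup_category(ids, annotation)

  classes <- c("class1", "class2", "class3")
  totals <- list(
    n_4h = nrow(hit4), n_24h = nrow(hit24),
    n_overlap = sum(entries$overlap), n_union = nrow(entries),
    by_class_4h = vapply(classes, function(k) sum(hit4$klass == k), 0L),
    by_class_24h = vapply(classes, function(k) sum(hit24$klass == k), 0L))
  structure(list(entries = entries, totals = totals,
                 thresholds = th4 %||% th24),
            class = "mitophagy_inventory")
}

lookup_category <- function(ids, annotation) {
  if (is.null(annotation)) return(rep(NA_character_, length(ids)))
  if (is.data.frame(annotation))
    annotation <- stats::setNames(as.character(annotation[[2L]]),
                                  as.character(annotation[[1L]]))
  unname(annotation[ids])
}

#' @export
print.mitophagy_inventory <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Candidate inventory: %d proteins (4 h: %d, 24 h: %d, overlap: %d)\n",
              t$n_union, t$n_4h, t$n_24h, t$n_overlap))
  cat("  4 h  by class: ", paste(sprintf("%s=%d", names(t$by_class_4h),
                                         t$by_class_4h), collapse = "  "), "\n")
  cat("  24 h by class: ", paste(sprintf("%s=%d", names(t$by_class_24h),
                                         t$by_class_24h), collapse = "  "), "\n")
  invisible(x)
}

#' Functional-category frequencies per trial and class
#'
#' Counts and integer percentages (rounded half up, pie-chart style) of each
#' functional category within every (timepoint, class) cell of the inventory.
#' Proteins without an annotation fall into \code{"uncategorized"}.
#'
#' @param inventory a \code{"mitophagy_inventory"}.
#' @param annotation optional accession-to-category map overriding the one
#'   stored in the inventory entries.
#' @return data.frame: \code{timepoint}, \code{klass}, \code{category},
#'   \code{count}, \code{percent}.
#' @export
category_frequencies <- function(inventory, annotation = NULL) {
  e <- inventory$entries
  cat_of <- if (is.null(annotation)) e$category else
    lookup_category(e$protein_id, annotation)
  cat_of[is.na(cat_of)] <- "uncategorized"
  out <- list()
  for (tp in c("4h", "24h")) {
    in_tp <- if (tp == "4h") e$in_4h else e$in_24h
    kl <- if (tp == "4h") e$class_4h else e$class_24h
    for (k in c("class1", "class2", "class3")) {
      sel <- in_tp & !is.na(kl) & kl == k
      if (!any(sel)) next
      tab <- table(cat_of[sel])
      out[[length(out) + 1L]] <- data.frame(
        timepoint = tp, klass = k, category = names(tab),
        count = as.integer(tab),
        percent = round_half_up(100 * as.integer(tab) / sum(tab)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(timepoint = character(), klass = character(),
                      category = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot category composition of one inventory class
#'
#' Base-graphics pie chart of \code{\link{category_frequencies}} for one
#' (timepoint, class) cell, mirroring the usual candidate-screen summary
#' figures.
#'
#' @param x a \code{"mitophagy_inventory"}.
#' @param timepoint \code{"4h"} or \code{"24h"}.
#' @param klass \code{"class1"}, \code{"class2"} or \code{"class3"}.
#' @param annotation optional accession-to-category map.
#' @param ... passed to \code{\link[graphics]{pie}}.
#' @export
plot.mitophagy_inventory <- function(x, timepoint = "4h", klass = "class3",
                                     annotation = NULL, ...) {
  freq <- category_frequencies(x, annotation)
  freq <- freq[freq$timepoint == timepoint & freq$klass == klass, ]
  if (!nrow(freq)) {
    graphics::plot.new()
    graphics::title(main = sprintf("%s %s: empty", timepoint, klass))
    return(invisible(x))
  }
  graphics::pie(freq$count,
                labels = sprintf("%s (%d%%)", freq$category, freq$percent),
                main = sprintf("%s, %s (n = %d)", timepoint, klass,
                               sum(freq$count)), ...)
  invisible(x)
}
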