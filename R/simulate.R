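#' Configuration for the synthetic spectral-count generator
#'
#' Describes a simulated cell-free co-incubation experiment with planted
#' ground truth, mirroring the study design: paired primed-control/treated
#' sperm triplicates per timepoint plus vehicle-control and oocyte-extract
#' triplicates, reference (ODF-like) anchor proteins, overdispersed
#' negative-binomial replicate noise, and a detection floor applied downstream
#' at ingest.
#'
#' Count noise is negative-binomial with mean \eqn{\mu} and variance
#' \eqn{\mu + \mu^2/dispersion}. Planted effects: Class 1 proteins have hard
#' zero counts in vehicle/primed controls and baseline abundance in extract
#' and treated samples; Class 2 proteins rise by \code{effect_fold} on treated
#' sperm; Class 3 proteins fall by \code{effect_fold}. Null and Class 3
#' proteins appear in the extract with probability 0.5, exercising the "both
#' gametes or sperm only" classification branch.
#'
#' @param n_null,n_class1,n_class2,n_class3 numbers of planted proteins per
#'   truth label (defaults 200/10/20/20).
#' @param n_reference number of ODF-like anchor proteins (default 3, named
#'   after \code{\link{odf_reference}}).
#' @param n_pairs biological replicates per condition (default 3).
#' @param timepoints trials to simulate, subset of \code{c("4h", "24h")}.
#' @param baseline_mean mean spectral count of an average detected protein
#'   (default 30).
#' @param effect_fold planted fold change, > 1 (default 4).
#' @param dispersion negative-binomial size parameter, larger = less
#'   overdispersed (default 10).
#' @param sample_scale_jitter SD of the log-normal per-sample load factor
#'   (default 0.1, i.e. ~10\% sample-to-sample loading variation).
#' @param reference_fold abundance multiple of reference anchors over baseline
#'   (default 20, keeping reference normalization well-conditioned).
#' @param min_spectra detection floor the downstream ingest filter will apply
#'   (default 4); counts are left as drawn here.
#' @return list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_null = 200L, n_class1 = 10L, n_class2 = 20L,
                             n_class3 = 20L, n_reference = 3L, n_pairs = 3L,
                             timepoints = c("4h", "24h"), baseline_mean = 30,
                             effect_fold = 4, dispersion = 10,
                             sample_scale_jitter = 0.1, reference_fold = 20,
                             min_spectra = 4L) {
  if (any(c(n_null, n_class1, n_class2, n_class3) < 0L) || n_reference < 1L)
    stopf("protein counts must be non-negative (and n_reference >= 1)")
  if (n_pairs < 2L) stopf("need n_pairs >= 2")
  if (!all(timepoints %in% c("4h", "24h")) || !length(timepoints))
    stopf("timepoints must be a non-empty subset of c('4h', '24h')")
  if (effect_fold <= 1) stopf("effect_fold must be > 1")
  if (dispersion <= 0 || baseline_mean <= 0 || reference_fold <= 0)
    stopf("baseline_mean, dispersion and reference_fold must be positive")
  if (sample_scale_jitter < 0) stopf("sample_scale_jitter must be >= 0")
  structure(list(n_null = as.integer(n_null), n_class1 = as.integer(n_class1),
                 n_class2 = as.integer(n_class2), n_class3 = as.integer(n_class3),
                 n_reference = as.integer(n_reference),
                 n_pairs = as.integer(n_pairs), timepoints = timepoints,
                 baseline_mean = baseline_mean, effect_fold = effect_fold,
                 dispersion = dispersion,
                 sample_scale_jitter = sample_scale_jitter,
                 reference_fold = reference_fold,
                 min_spectra = as.integer(min_spectra)),
            class = "synthetic_config")
}

sim_protein_ids <- function(config) {
  ref <- if (config$n_reference <= 3L) odf_reference()[seq_len(config$n_reference)]
         else c(odf_reference(), sprintf("ODF%d", 4:config$n_reference))
  c(ref,
    sprintf("NULL%04d", seq_len(config$n_null)),
    sprintf("C1P%04d", seq_len(config$n_class1)),
    sprintf("C2P%04d", seq_len(config$n_class2)),
    sprintf("C3P%04d", seq_len(config$n_class3)))
}

sim_truth_labels <- function(config) {
  rep(c("reference", "null", "class1", "class2", "class3"),
      c(config$n_reference, config$n_null, config$n_class1, config$n_class2,
        config$n_class3))
}

sim_sample_sheet <- function(config) {
  rows <- list()
  for (tp in config$timepoints) {
    for (r in seq_len(config$n_pairs)) {
      tag <- sub("h$", "", tp)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf(c("VC%s_%d", "EX%s_%d", "PC%s_%d", "TR%s_%d"),
                            tag, r),
        condition = c("vehicle_control", "extract", "primed_control", "treated"),
        timepoint = tp, replicate = r,
        pair_id = c("", "", sprintf("p%s_%d", tag, r), sprintf("p%s_%d", tag, r)),
        stringsAsFactors = FALSE)
    }
  }
  sample_sheet(do.call(rbind, rows))
}

#' Simulate a complete cell-free screening experiment
#'
#' Draws a spectral-count matrix, the matching sample sheet and the planted
#' truth labels under a \code{\link{synthetic_config}}. Identical seeds give
#' bit-identical output. Planted Class 1 proteins have exactly zero counts in
#' vehicle- and primed-control samples (a hard constraint, not a draw);
#' reference anchors are absent from the extract.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer RNG seed.
#' @return object of class \code{"cellfree_sim"}: list with \code{counts}
#'   (a \code{\link{spectral_counts}} matrix), \code{sheet}
#'   (a \code{\link{sample_sheet}}), \code{truth} (named character vector of
#'   planted labels) and \code{config}.
#' @export
simulate_experiment <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  ids <- sim_protein_ids(config)
  labels <- sim_truth_labels(config)
  sheet <- sim_sample_sheet(config)
  n_prot <- length(ids)

  # per-protein extract presence, shared across timepoints
  in_extract <- stats::runif(n_prot) < 0.5
  in_extract[labels == "reference"] <- FALSE
  in_extract[labels %in% c("class1", "class2")] <- TRUE

  base <- rep(config$baseline_mean, n_prot)
  base[labels == "reference"] <- config$baseline_mean * config$reference_fold

  # condition multiplier per protein x condition
  mult <- function(cond) {
    m <- rep(1, n_prot)
    if (cond == "extract") {
      m <- as.numeric(in_extract)
      m[labels == "class1"] <- 1
    } else if (cond %in% c("vehicle_control", "primed_control")) {
      m[labels == "class1"] <- 0
    } else if (cond == "treated") {
      m[labels == "class2"] <- config$effect_fold
      m[labels == "class3"] <- 1 / config$effect_fold
    }
    m
  }
  mults <- sapply(sheet_conditions, mult)

  counts <- matrix(0, n_prot, nrow(sheet), dimnames = list(ids, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    load <- exp(stats::rnorm(1L, 0, config$sample_scale_jitter))
    mu <- base * mults[, sheet$condition[j]] * load
    draw <- numeric(n_prot)
    pos <- mu > 0
    draw[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = config$dispersion)
    counts[, j] <- draw
  }
  structure(list(counts = spectral_counts(counts), sheet = sheet,
                 truth = stats::setNames(labels, ids), config = config),
            class = "cellfree_sim")
}

#' @export
print.cellfree_sim <- function(x, ...) {
  cat(sprintf("Simulated cell-free experiment: %d proteins x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$config$timepoints, collapse = ", ")))
  print(table(x$truth))
  invisible(x)
}

#' Write a simulated experiment as a ready-to-run fixture directory
#'
#' Emits the delimited formats the ingest module reads (\code{counts.tsv},
#' \code{samples.tsv}) plus the planted-truth table (\code{truth.tsv}).
#'
#' @param sim a \code{"cellfree_sim"}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectral_counts(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(as.data.frame(unclass(sim$sheet)),
                     file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(protein_id = names(sim$truth),
                                label = unname(sim$truth)),
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Confusion matrix of assigned versus planted classes
#'
#' Cross-tabulates planted truth labels against assigned classes for one
#' trial. Planted proteins missing from the assignment table (e.g. never
#' detected) count as unclassified; assigned proteins missing from the truth
#' are an error (universe mismatch).
#'
#' @param assignments data.frame from \code{\link{assign_classes}} (or a
#'   \code{"cellfree_screen"}).
#' @param truth named character vector of planted labels.
#' @return integer matrix (rows: planted \code{null}, \code{class1},
#'   \code{class2}, \code{class3}, \code{reference}; columns: assigned
#'   \code{unclassified}, \code{class1}, \code{class2}, \code{class3}) with
#'   attributes \code{recovery} (per planted class, fraction assigned its own
#'   class) and \code{null_fpr} (fraction of planted nulls assigned class 2
#'   or 3).
#' @export
truth_confusion <- function(assignments, truth) {
  if (inherits(assignments, "cellfree_screen")) assignments <- assignments$assignments
  extra <- setdiff(assignments$protein_id, names(truth))
  if (length(extra))
    stopf("assigned protein(s) missing from truth: %s", paste(extra, collapse = ", "))
  planted <- c("null", "class1", "class2", "class3", "reference")
  assigned <- c("unclassified", "class1", "class2", "class3")
  got <- stats::setNames(rep("unclassified", length(truth)), names(truth))
  got[assignments$protein_id] <- assignments$klass
  m <- matrix(0L, length(planted), length(assigned),
              dimnames = list(planted = planted, assigned = assigned))
  tab <- table(factor(unname(truth), planted), factor(unname(got), assigned))
  m[rownames(tab), colnames(tab)] <- tab
  rec <- vapply(c("class1", "class2", "class3"), function(k) {
    n <- sum(m[k, ])
    if (n == 0) NA_real_ else m[k, k] / n
  }, 0)
  fpr <- if (sum(m["null", ]) == 0) NA_real_ else
    sum(m["null", c("class2", "class3")]) / sum(m["null", ])
  structure(m, recovery = rec, null_fpr = fpr)
}
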