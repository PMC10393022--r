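test_that("detection patterns honor presence_min and condition scope", {
  exp <- handmade_experiment()
  dm <- apply_detection_filter(exp$counts, 4)
  pat <- detection_pattern(dm, exp$sheet, "4h", presence_min = 1)
  row <- function(p) pat[pat$protein_id == p, ]

  # extract + treated only, absent from both sperm controls
  ext <- row("EXTONLY")
  expect_false(ext$in_vehicle_control || ext$in_primed_control)
  expect_true(ext$in_extract && ext$in_treated)

  # detected everywhere
  expect_true(all(unlist(row("GOUP")[paste0("in_", c("vehicle_control",
                                                     "primed_control",
                                                     "extract", "treated"))])))
  expect_false(row("GHOST")$in_treated)

  # presence_min semantics: 2/3 replicates clears 1 but not 3
  m <- unclass(exp$counts)
  m["FLAT1", "TR4_1"] <- 0
  dm2 <- apply_detection_filter(spectral_counts(m), 4)
  expect_true(detection_pattern(dm2, exp$sheet, "4h", 1)$in_treated[
    pat$protein_id == "FLAT1"])
  expect_false(detection_pattern(dm2, exp$sheet, "4h", 3)$in_treated[
    pat$protein_id == "FLAT1"])
  expect_error(detection_pattern(dm, exp$sheet, "4h", 4), "presence_min")
})

test_that("class admission follows the pattern and threshold rules", {
  pat <- function(vc, pc, ex, tr)
    data.frame(protein_id = "X", in_vehicle_control = vc,
               in_primed_control = pc, in_extract = ex, in_treated = tr)
  res <- function(p, dir)
    data.frame(protein_id = "X", timepoint = "4h", p_value = p, direction = dir)

  # extract-only protein admitted at the loosened threshold
  a <- assign_class(pat(FALSE, FALSE, TRUE, TRUE), res(0.15, "increase"))
  expect_identical(a$klass, "class1")
  expect_equal(a$admitted_alpha, 0.2)

  # increased on sperm, significant at 0.1
  a <- assign_class(pat(TRUE, TRUE, TRUE, TRUE), res(0.015, "increase"))
  expect_identical(a$klass, "class2")
  expect_equal(a$admitted_alpha, 0.1)

  # decreased from sperm, with or without extract presence
  expect_identical(assign_class(pat(TRUE, TRUE, TRUE, TRUE),
                                res(0.035, "decrease"))$klass, "class3")
  expect_identical(assign_class(pat(TRUE, TRUE, FALSE, TRUE),
                                res(0.035, "decrease"))$klass, "class3")

  # fails both alphas
  expect_identical(assign_class(pat(TRUE, TRUE, FALSE, TRUE),
                                res(0.5, "decrease"))$klass, "unclassified")

  # class 1 is impossible once the protein shows up in primed controls,
  # no matter how small p is
  expect_identical(assign_class(pat(FALSE, TRUE, TRUE, TRUE),
                                res(1e-9, "increase"))$klass, "class2")
  expect_identical(assign_class(pat(TRUE, FALSE, TRUE, TRUE),
                                res(1e-9, "increase"))$klass, "unclassified")

  expect_error(assign_class(pat(TRUE, TRUE, TRUE, TRUE),
                            data.frame(protein_id = "Y", timepoint = "4h",
                                       p_value = 0.01, direction = "increase")),
               "mismatch")
})

test_that("every tested protein gets exactly one label; alpha is monotone", {
  sim <- simulate_experiment(synthetic_config(
    n_null = 60, n_class1 = 6, n_class2 = 6, n_class3 = 6,
    timepoints = "4h"), seed = 41)
  dm <- apply_detection_filter(sim$counts, 4)
  nm <- normalize_counts(dm, sim$sheet, "4h")$normalized
  tests <- run_differential(nm, sim$sheet, "4h")
  pats <- detection_pattern(dm, sim$sheet, "4h", 1)

  a <- assign_classes(pats, tests)
  expect_identical(sort(a$protein_id), sort(tests$protein_id))
  expect_true(all(a$klass %in% c("class1", "class2", "class3", "unclassified")))

  # enlarging the class-2/3 alpha never drops an assignment
  tighter <- assign_classes(pats, tests, significance_thresholds(0.02, 0.2))
  looser <- assign_classes(pats, tests, significance_thresholds(0.2, 0.2))
  kept <- tighter$klass %in% c("class2", "class3")
  expect_identical(looser$klass[kept], tighter$klass[kept])
})

test_that("planted truth is recovered under strong effects and nulls stay calibrated", {
  # high signal-to-noise world with few effect proteins among many nulls,
  # the regime where global mean scaling is unbiased (chosen by a-priori
  # power analysis: per-pair effect size ~5-6 sd, power ~1 at df 2)
  cfg <- synthetic_config(n_null = 2000, n_class1 = 12, n_class2 = 10,
                          n_class3 = 10, baseline_mean = 200, effect_fold = 2,
                          dispersion = 400, timepoints = "4h")
  sim <- simulate_experiment(cfg, seed = 101)
  sc <- cellfree_screen(sim$counts, sim$sheet, "4h")
  conf <- truth_confusion(sc, sim$truth)

  eff <- c("class1", "class2", "class3")
  recovered <- sum(diag(conf[eff, eff])) / sum(conf[eff, ])
  expect_gte(recovered, 0.95)

  # class 1 admission only for planted extract-only proteins
  expect_equal(sum(conf[c("null", "class2", "class3", "reference"), "class1"]), 0L)

  # null misclassification rate within the binomial 99% interval of alpha
  fpr <- attr(conf, "null_fpr")
  half <- 2.576 * sqrt(0.1 * 0.9 / sum(conf["null", ]))
  expect_lte(fpr, 0.1 + half)
})

test_that("truth_confusion tabulates and guards the protein universe", {
  truth <- c(A = "class2", B = "class3", C = "null")
  perfect <- fake_assignments(c("A", "B", "C"),
                              c("class2", "class3", "unclassified"), "4h")
  conf <- truth_confusion(perfect, truth)
  expect_equal(conf["class2", "class2"], 1L)
  expect_equal(conf["class3", "class3"], 1L)
  expect_equal(conf["null", "unclassified"], 1L)
  expect_equal(sum(conf), 3L)

  none <- fake_assignments(c("A", "B", "C"), rep("unclassified", 3), "4h")
  conf0 <- truth_confusion(none, truth)
  expect_equal(sum(conf0[, "unclassified"]), 3L)
  expect_equal(sum(conf0[, c("class1", "class2", "class3")]), 0L)

  expect_error(truth_confusion(fake_assignments("Z", "class2", "4h"), truth),
               "universe|missing from truth")
})

test_that("inventories obey inclusion-exclusion and overlap accounting", {
  # sized like the study's printed inventories: 144 and 63 with 22 shared
  ids4 <- sprintf("P%03d", 1:144)
  ids24 <- sprintf("P%03d", 123:185)   # 22 overlap => union 185
  a4 <- fake_assignments(ids4, rep(c("class3", "class2", "class1"),
                                   c(108, 26, 10)), "4h")
  a24 <- fake_assignments(ids24, rep(c("class3", "class2", "class1"),
                                     c(43, 12, 8)), "24h")
  inv <- build_inventory(a4, a24)
  expect_equal(inv$totals$n_4h, 144L)
  expect_equal(inv$totals$n_24h, 63L)
  expect_equal(inv$totals$n_overlap, 22L)
  expect_equal(inv$totals$n_union, 185L)
  expect_equal(inv$totals$n_union,
               inv$totals$n_4h + inv$totals$n_24h - inv$totals$n_overlap)
  expect_equal(unname(inv$totals$by_class_4h["class3"]), 108L)
  expect_identical(inv$entries$overlap, inv$entries$in_4h & inv$entries$in_24h)

  # disjoint and identical edge cases
  disjoint <- build_inventory(fake_assignments(c("A", "B"), "class2", "4h"),
                              fake_assignments(c("C", "D", "E"), "class3", "24h"))
  expect_equal(disjoint$totals$n_union, 5L)
  expect_equal(disjoint$totals$n_overlap, 0L)
  same <- build_inventory(fake_assignments(c("A", "B"), "class2", "4h"),
                          fake_assignments(c("A", "B"), "class2", "24h"))
  expect_equal(same$totals$n_union, 2L)
  expect_equal(same$totals$n_overlap, 2L)

  # mismatched thresholds are refused
  loose <- fake_assignments(c("A", "B"), "class2", "24h",
                            thresholds = significance_thresholds(0.05, 0.2))
  expect_error(build_inventory(fake_assignments(c("A", "B"), "class2", "4h"),
                               loose), "thresholds")
})

test_that("inclusion-exclusion holds on randomly simulated inventories", {
  set.seed(51)
  for (i in 1:20) {
    pool <- sprintf("P%03d", 1:60)
    mk <- function(tp) {
      ids <- sample(pool, sample(5:40, 1))
      fake_assignments(ids, sample(c("class1", "class2", "class3",
                                     "unclassified"), length(ids), TRUE), tp)
    }
    inv <- build_inventory(mk("4h"), mk("24h"))
    expect_identical(inv$totals$n_union,
                     nrow(inv$entries))
    expect_equal(inv$totals$n_union,
                 inv$totals$n_4h + inv$totals$n_24h - inv$totals$n_overlap)
    expect_equal(sum(inv$totals$by_class_4h), inv$totals$n_4h)
    expect_equal(sum(inv$totals$by_class_24h), inv$totals$n_24h)
  }
})

test_that("category frequencies report integer percentages per class cell", {
  # 108 class-3 proteins of which 15 are tail proteins -> 14%
  ids <- sprintf("P%03d", 1:108)
  a4 <- fake_assignments(ids, "class3", "4h")
  a24 <- fake_assignments(character(0), character(0), "24h")
  annot <- setNames(rep(c("tail", "other"), c(15, 93)), ids)
  inv <- build_inventory(a4, a24, annotation = annot)
  freq <- category_frequencies(inv)
  tail_row <- freq[freq$category == "tail", ]
  expect_equal(tail_row$count, 15L)
  expect_equal(tail_row$percent, 14)
  expect_equal(sum(freq$count), 108L)

  # single category is 100%; unannotated proteins become "uncategorized"
  inv1 <- build_inventory(fake_assignments("A", "class2", "4h"),
                          a24, annotation = c(A = "chaperone"))
  f1 <- category_frequencies(inv1)
  expect_equal(f1$percent, 100)
  inv2 <- build_inventory(fake_assignments("A", "class2", "4h"), a24)
  expect_identical(category_frequencies(inv2)$category, "uncategorized")

  # an empty inventory gives an empty table, no division error
  empty <- build_inventory(a24, a24)
  expect_equal(nrow(category_frequencies(empty)), 0L)
})
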