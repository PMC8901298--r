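test_that("control-group table reproduces the published percentages", {
  tab <- confusion_table(tp = 52, fp = 7, fn = 38, tn = 8,
                         printed_marginals = list(gold_positive = 90,
                                                  gold_negative = 15,
                                                  total = 105))
  expect_length(tab$discrepancies, 0)
  st <- sen_spec_acc(tab)
  expect_equal(unname(st$percent["sensitivity"]), 57.78)
  expect_equal(unname(st$percent["specificity"]), 53.33)
  expect_equal(unname(st$percent["accuracy"]), 57.14)
})

test_that("denoised-group table exposes both sensitivity readings and the cell inconsistency", {
  tab <- confusion_table(tp = 79, fp = 3, fn = 8, tn = 13,
                         printed_marginals = list(gold_positive = 89,
                                                  total = 105))
  # cells give 79 + 8 = 87 gold positives and 103 total; the printed table
  # says 89 and 105 — both discrepancies must be surfaced, not corrected
  expect_length(tab$discrepancies, 2)
  expect_match(tab$discrepancies, "87", all = FALSE)
  st <- sen_spec_acc(tab)
  expect_equal(unname(st$percent["specificity"]), 81.25)
  expect_equal(unname(st$sensitivity_marginal), 79 / 89)
  expect_equal(unname(st$percent["sensitivity_marginal"]), 88.76)
  # cell-based reading remains available alongside
  expect_equal(unname(st$sensitivity), 79 / 87)
  expect_true(length(st$discrepancies) > 0)
})

test_that("accuracy of the denoised-group table over the printed cohort size", {
  # (79 + 13) / 105 against the printed total
  expect_equal(round(100 * (79 + 13) / 105, 2), 87.62)
})

test_that("perfect classifiers and undefined statistics behave", {
  perfect <- confusion_table(10, 0, 0, 5)
  st <- sen_spec_acc(perfect)
  expect_equal(unname(st$percent), c(100, 100, 100))
  expect_error(sen_spec_acc(confusion_table(0, 3, 0, 2)), "sensitivity")
  expect_error(sen_spec_acc(confusion_table(3, 0, 2, 0)), "specificity")
  expect_error(confusion_table(-1, 0, 0, 2), "nonnegative")
})

test_that("Cohen's kappa: perfect agreement, independence, direct-formula oracle", {
  expect_equal(cohen_kappa(confusion_table(10, 0, 0, 7))$kappa, 1)
  # factorizing margins: p_o == p_e
  indep <- confusion_table(45, 45, 5, 5)
  expect_equal(cohen_kappa(indep)$kappa, 0, tolerance = 1e-12)

  set.seed(41)
  for (rep in 1:20) {
    cells <- rmultinom(1, 200, prob = runif(4, 0.05, 1))[, 1]
    tab <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    n <- sum(cells)
    po <- (cells[1] + cells[4]) / n
    pe <- ((cells[1] + cells[2]) * (cells[1] + cells[3]) +
           (cells[3] + cells[4]) * (cells[2] + cells[4])) / n^2
    k <- cohen_kappa(tab)
    expect_equal(k$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
    expect_identical(k$kappa > 0, k$p_o > k$p_e)
  }
  expect_error(cohen_kappa(confusion_table(5, 0, 0, 0)), "degenerate")
})

test_that("kappa interpretation bands follow the conventional cutoffs", {
  expect_identical(cohen_kappa(confusion_table(10, 0, 0, 7))$band,
                   "satisfactory")
  expect_identical(cohen_kappa(confusion_table(40, 10, 10, 40))$band,
                   "relatively satisfactory")
  expect_identical(cohen_kappa(confusion_table(45, 45, 5, 5))$band,
                   "not ideal")
})

test_that("diagnostic statistics are invariant to scaling all cells", {
  tab1 <- confusion_table(52, 7, 38, 8)
  tab7 <- confusion_table(52 * 7, 7 * 7, 38 * 7, 8 * 7)
  s1 <- sen_spec_acc(tab1); s7 <- sen_spec_acc(tab7)
  expect_equal(s1$sensitivity, s7$sensitivity)
  expect_equal(s1$specificity, s7$specificity)
  expect_equal(s1$accuracy, s7$accuracy)
  expect_equal(cohen_kappa(tab1)$kappa, cohen_kappa(tab7)$kappa)
})

test_that("table_from_calls counts by definition", {
  expect_identical(table_from_calls(c(1, 1, 0, 0), c(1, 0, 0, 1))[
    c("tp", "fp", "fn", "tn")], list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  t_eq <- table_from_calls(c(1, 0, 1), c(1, 0, 1))
  expect_identical(t_eq$fp + t_eq$fn, 0L)
  expect_error(table_from_calls(c(1, 0), c(1)), "equal length")

  cohort <- simulate_cohort(500, 0.7, 0.9, 0.8, seed = 42)
  tab <- table_from_calls(cohort$truth, cohort$call)
  counts <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (i in seq_len(nrow(cohort))) {
    key <- if (cohort$truth[i] == 1 && cohort$call[i] == 1) "tp"
           else if (cohort$truth[i] == 0 && cohort$call[i] == 1) "fp"
           else if (cohort$truth[i] == 1) "fn" else "tn"
    counts[key] <- counts[key] + 1L
  }
  expect_identical(c(tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn),
                   counts)
  expect_identical(tab$total, 500L)
})

test_that("penumbra call flags band pixels around a sub-threshold core", {
  ph <- make_stroke_phantom()
  m <- adc_map(ph$stack)
  lesion <- ph$masks$core | ph$masks$penumbra
  call <- call_penumbra(m, lesion)
  expect_true(call$positive)
  expect_gt(call$n_band, 0)

  core_only <- make_stroke_phantom(penumbra_radius = 0.12 * 64,
                                   core_radius = 0.12 * 64)
  m2 <- adc_map(core_only$stack)
  call2 <- call_penumbra(m2, core_only$masks$core)
  expect_false(call2$positive)

  normal <- matrix(1.1e-3, 16, 16)
  call3 <- call_penumbra(normal, matrix(TRUE, 16, 16))
  expect_false(call3$positive)
  expect_error(call_penumbra(normal, matrix(FALSE, 16, 16)), "empty")
})
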