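#' 2 x 2 diagnostic confusion table
#'
#' Counts of a binary test against a gold standard. Optionally carries the
#' marginals as printed in a published table; when supplied they are checked
#' against the cells and any discrepancy is recorded (never silently
#' corrected) — published 2 x 2 tables are sometimes internally inconsistent,
#' and both readings should stay visible.
#'
#' @param tp,fp,fn,tn nonnegative integer cell counts.
#' @param printed_marginals optional named list with any of `gold_positive`,
#'   `gold_negative`, `test_positive`, `test_negative`, `total` as printed in
#'   the source table.
#' @return object of class `confusion_table` with fields `tp`, `fp`, `fn`,
#'   `tn`, `total`, `printed_marginals`, `discrepancies` (character vector).
#' @export
confusion_table <- function(tp, fp, fn, tn, printed_marginals = NULL) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  total <- sum(counts)
  if (total < 1) stop("table must contain at least one observation",
                      call. = FALSE)
  disc <- character(0)
  if (!is.null(printed_marginals)) {
    expected <- c(gold_positive = tp + fn, gold_negative = fp + tn,
                  test_positive = tp + fp, test_negative = fn + tn,
                  total = total)
    for (nm in names(printed_marginals)) {
      if (!nm %in% names(expected))
        stop("unknown marginal name: ", nm, call. = FALSE)
      if (printed_marginals[[nm]] != expected[[nm]])
        disc <- c(disc, sprintf(
          "%s: cells give %d but the printed table says %d",
          nm, expected[[nm]], printed_marginals[[nm]]))
    }
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, total = total,
                 printed_marginals = printed_marginals,
                 discrepancies = disc),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              gold = c("positive", "negative")))
  print(m)
  cat("total:", x$total, "\n")
  if (length(x$discrepancies)) {
    cat("printed-marginal discrepancies:\n")
    for (d in x$discrepancies) cat("  -", d, "\n")
  }
  invisible(x)
}

#' Build a confusion table from truth/call sequences
#'
#' @param truth,calls equal-length binary (0/1 or logical) vectors.
#' @return a [confusion_table()].
#' @export
table_from_calls <- function(truth, calls) {
  if (length(truth) != length(calls))
    stop("`truth` and `calls` must have equal length", call. = FALSE)
  if (length(truth) < 1L) stop("empty sequences", call. = FALSE)
  truth <- as.integer(as.logical(truth))
  calls <- as.integer(as.logical(calls))
  confusion_table(tp = sum(truth == 1L & calls == 1L),
                  fp = sum(truth == 0L & calls == 1L),
                  fn = sum(truth == 1L & calls == 0L),
                  tn = sum(truth == 0L & calls == 0L))
}

#' Sensitivity, specificity and accuracy of a confusion table
#'
#' `Sen = TP/(TP+FN)`, `Spec = TN/(TN+FP)`, `Acc = (TP+TN)/N`. When the table
#' carries printed marginals, the alternative sensitivity/specificity using
#' the printed gold-standard marginals are reported alongside (some published
#' tables have cells inconsistent with their marginals; both readings are
#' exposed, neither preferred).
#'
#' @param t a [confusion_table()].
#' @param digits decimal places for the percentage formatting (default 2,
#'   matching common reporting style).
#' @return object of class `diag_stats`: list with raw proportions
#'   (`sensitivity`, `specificity`, `accuracy`), rounded percentages
#'   (`percent`), marginal-based readings when available
#'   (`sensitivity_marginal`, `specificity_marginal`), and `discrepancies`.
#' @export
sen_spec_acc <- function(t, digits = 2) {
  stopifnot(inherits(t, "confusion_table"))
  if (t$tp + t$fn == 0)
    stop("sensitivity undefined: no gold-positive samples", call. = FALSE)
  if (t$tn + t$fp == 0)
    stop("specificity undefined: no gold-negative samples", call. = FALSE)
  sen <- t$tp / (t$tp + t$fn)
  spe <- t$tn / (t$tn + t$fp)
  acc <- (t$tp + t$tn) / t$total
  out <- list(sensitivity = sen, specificity = spe, accuracy = acc,
              percent = round(100 * c(sensitivity = sen, specificity = spe,
                                      accuracy = acc), digits),
              discrepancies = t$discrepancies)
  pm <- t$printed_marginals
  if (!is.null(pm$gold_positive) && pm$gold_positive > 0) {
    out$sensitivity_marginal <- t$tp / pm$gold_positive
    out$percent["sensitivity_marginal"] <-
      round(100 * out$sensitivity_marginal, digits)
  }
  if (!is.null(pm$gold_negative) && pm$gold_negative > 0) {
    out$specificity_marginal <- t$tn / pm$gold_negative
    out$percent["specificity_marginal"] <-
      round(100 * out$specificity_marginal, digits)
  }
  class(out) <- "diag_stats"
  out
}

#' @export
print.diag_stats <- function(x, ...) {
  cat("diagnostic performance (%):\n")
  print(x$percent)
  if (length(x$discrepancies)) {
    cat("printed-marginal discrepancies:\n")
    for (d in x$discrepancies) cat("  -", d, "\n")
  }
  invisible(x)
}

#' Cohen's kappa for a 2 x 2 table
#'
#' Unweighted Cohen's kappa: `(p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (TP+TN)/N` and chance agreement
#' `p_e = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / N^2`. The returned object also
#' carries the conventional interpretation band: >= 0.75 satisfactory,
#' 0.4-0.75 relatively satisfactory, < 0.4 not ideal.
#'
#' @param t a [confusion_table()].
#' @return object of class `kappa_result`: list with `kappa`, `p_o`, `p_e`,
#'   `band`.
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  n <- t$total
  p_o <- (t$tp + t$tn) / n
  p_e <- ((t$tp + t$fp) * (t$tp + t$fn) +
          (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  if (1 - p_e <= 0)
    stop("kappa undefined: chance agreement equals 1 (degenerate table)",
         call. = FALSE)
  k <- (p_o - p_e) / (1 - p_e)
  band <- if (k >= 0.75) "satisfactory"
          else if (k >= 0.4) "relatively satisfactory"
          else "not ideal"
  structure(list(kappa = k, p_o = p_o, p_e = p_e, band = band),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (p_o = %.4f, p_e = %.4f): %s\n",
              x$kappa, x$p_o, x$p_e, x$band))
  invisible(x)
}

#' Rule-based ischemic-penumbra call from an ADC map
#'
#' Flags a lesion as containing penumbra when, within the lesion mask, at
#' least `min_core_pixels` pixels fall below the core ADC threshold
#' (restricted-diffusion core) and at least `min_band_pixels` pixels fall
#' inside the penumbra ADC band. The band rule reflects the observation that
#' penumbral tissue shows moderately reduced ADC between the strongly reduced
#' infarct core and normal tissue.
#'
#' @param adc an [adc_map()] or a numeric ADC matrix (mm^2/s).
#' @param lesion_mask logical matrix selecting the lesion neighbourhood.
#' @param core_threshold ADC below which a pixel counts as core (mm^2/s).
#' @param penumbra_band length-2 numeric, the (low, high) ADC band of
#'   penumbral tissue (mm^2/s); must satisfy
#'   `core_threshold < low < high`.
#' @param min_core_pixels,min_band_pixels minimum pixel counts.
#' @return list with `positive` (logical IP call), `n_core`, `n_band`.
#' @export
call_penumbra <- function(adc, lesion_mask, core_threshold = 0.45e-3,
                          penumbra_band = c(0.55e-3, 1.0e-3),
                          min_core_pixels = 1L, min_band_pixels = 5L) {
  if (inherits(adc, "adc_map")) adc <- adc$adc
  if (!any(lesion_mask)) stop("empty lesion mask: call undefined",
                              call. = FALSE)
  if (!(core_threshold < penumbra_band[1L] &&
        penumbra_band[1L] < penumbra_band[2L]))
    stop("thresholds must satisfy core_threshold < band low < band high",
         call. = FALSE)
  vals <- adc[lesion_mask]
  vals <- vals[!is.na(vals)]
  n_core <- sum(vals < core_threshold)
  n_band <- sum(vals >= penumbra_band[1L] & vals <= penumbra_band[2L])
  list(positive = n_core >= min_core_pixels && n_band >= min_band_pixels,
       n_core = n_core, n_band = n_band)
}
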