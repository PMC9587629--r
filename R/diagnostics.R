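#' Expected confusion counts for a triage test
#'
#' Expected true/false positives and negatives when a test with the given
#' sensitivity and specificity is applied to `n` patients at the given
#' disease prevalence. Unrounded expectations are always retained;
#' reported counts use nearest-integer rounding with a conserving policy:
#' the diseased total is rounded first, TP is rounded and FN taken as the
#' remainder, and likewise FP / TN among the non-diseased, so the four
#' counts always sum to `n`.
#'
#' @param n Number of patients (>= 0).
#' @param sensitivity,specificity,prevalence Probabilities in \[0, 1\].
#'   Defaults are the rule-in performance of the 0/1-h algorithm in a
#'   low-prevalence population: sensitivity 73.8%, specificity 98.7%,
#'   AMI prevalence 3.6%.
#' @return A `confusion_counts` list: `n`, `counts` (named integer TP,
#'   FP, TN, FN), `expected` (unrounded), `diseased`, `ppv`, `npv`
#'   (computed on the unrounded expectations).
#' @export
#' @examples
#' cc <- expected_confusion(1000)
#' cc$diseased          # 36
#' cc$counts[["FP"]]    # 13
expected_confusion <- function(n, sensitivity = 0.738,
                               specificity = 0.987, prevalence = 0.036) {
  if (!is.numeric(n) || n < 0) {
    stop("`n` must be non-negative", call. = FALSE)
  }
  probs <- c(sensitivity = sensitivity, specificity = specificity,
             prevalence = prevalence)
  if (any(probs < 0 | probs > 1)) {
    stop("sensitivity, specificity and prevalence must lie in [0, 1]",
         call. = FALSE)
  }
  diseased <- n * prevalence
  healthy <- n - diseased
  expected <- c(
    TP = diseased * sensitivity,
    FP = healthy * (1 - specificity),
    TN = healthy * specificity,
    FN = diseased * (1 - sensitivity)
  )
  d_r <- round(diseased)
  tp_r <- round(expected[["TP"]])
  fp_r <- round(expected[["FP"]])
  counts <- c(
    TP = tp_r,
    FP = fp_r,
    TN = (n - d_r) - fp_r,
    FN = d_r - tp_r
  )
  ppv <- if (expected[["TP"]] + expected[["FP"]] > 0) {
    expected[["TP"]] / (expected[["TP"]] + expected[["FP"]])
  } else NA_real_
  npv <- if (expected[["TN"]] + expected[["FN"]] > 0) {
    expected[["TN"]] / (expected[["TN"]] + expected[["FN"]])
  } else NA_real_
  structure(
    list(n = n, counts = counts, expected = expected,
         diseased = d_r, ppv = ppv, npv = npv,
         performance = probs),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> n = ", x$n, " (prevalence ",
      x$performance[["prevalence"]], ")\n", sep = "")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d   (diseased %d)\n",
              x$counts[["TP"]], x$counts[["FP"]], x$counts[["TN"]],
              x$counts[["FN"]], x$diseased))
  cat(sprintf("  PPV %.3f  NPV %.3f (on unrounded expectations)\n",
              x$ppv, x$npv))
  invisible(x)
}
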