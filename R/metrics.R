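# Confusion-matrix metrics and the four GA optimization criteria combining
# train/test performance with a selected-descriptor-count penalty.

#' Confusion-matrix metrics for binary predictions
#'
#' Sensitivity is the true-positive rate `TP / (TP + FN)`, specificity the
#' true-negative rate `TN / (TN + FP)`, and MCC the Matthews correlation
#' coefficient.  Any zero denominator (including MCC's) yields 0 rather than
#' `NaN`, the convention used throughout the optimization criteria.
#'
#' @param truth,pred Equal-length binary (0/1) vectors.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `specificity`, `mcc`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("`truth` and `pred` must have equal length.")
  if (!is_binary(as.numeric(truth)) || !is_binary(as.numeric(pred))) {
    abort("`truth` and `pred` must be binary 0/1 vectors.")
  }
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         sensitivity = sens, specificity = spec, mcc = mcc)
}

#' Descriptor-count penalty factor
#'
#' `f(Nsel) = 1 - a * (Nsel - 1) / Ndes`: 1 for a single selected descriptor,
#' decreasing with the number selected; with a large penalty coefficient `a`
#' the factor can go negative, heavily penalizing large subsets.
#'
#' @param nsel Number of selected descriptors (`1 <= nsel <= ndes`).
#' @param ndes Total number of descriptors.
#' @param a Penalty coefficient (e.g. 1 for small descriptor pools, 4 for
#'   large ones).
#' @return The penalty factor (may be negative).
#' @export
f_nsel <- function(nsel, ndes, a) {
  if (any(nsel < 1)) abort("`nsel` must be >= 1.")
  if (any(nsel > ndes)) abort("`nsel` must not exceed `ndes`.")
  1 - a * (nsel - 1) / ndes
}

#' GA optimization criteria
#'
#' Fitness of a chromosome from its train and internal-test metrics:
#' \describe{
#'   \item{oc1}{`(MCC_train + MCC_test) * f`}
#'   \item{oc2}{`|MCC_train * MCC_test| * (1 - |MCC_train - MCC_test|) * f`}
#'   \item{oc3}{`Min_val * f`, where `Min_val` is the minimum of the four
#'     train/test sensitivities and specificities}
#'   \item{oc4}{`OC3 * (1 - (Max_val - Min_val)) * f` — note `f` enters OC4
#'     twice (once inside OC3 and once as the trailing factor), exactly as
#'     the criterion is defined; `single_f = TRUE` drops the trailing factor
#'     for sensitivity analysis.}
#' }
#'
#' @param kind One of `"oc1"`, `"oc2"`, `"oc3"`, `"oc4"`.
#' @param train_metrics,test_metrics One-row tibbles from
#'   [confusion_metrics()] on the training and internal test predictions.
#' @param nsel,ndes,a Arguments of [f_nsel()].
#' @param single_f Drop OC4's trailing duplicate penalty factor.
#' @return The scalar fitness value.
#' @export
optimization_criterion <- function(kind = c("oc1", "oc2", "oc3", "oc4"),
                                   train_metrics, test_metrics,
                                   nsel, ndes, a = 1, single_f = FALSE) {
  kind <- match.arg(kind)
  f <- f_nsel(nsel, ndes, a)
  mtr <- train_metrics; mte <- test_metrics
  switch(kind,
    oc1 = (mtr$mcc + mte$mcc) * f,
    oc2 = abs(mtr$mcc * mte$mcc) * (1 - abs(mtr$mcc - mte$mcc)) * f,
    oc3 = min(mtr$sensitivity, mte$sensitivity,
              mtr$specificity, mte$specificity) * f,
    oc4 = {
      min_val <- min(mtr$sensitivity, mte$sensitivity,
                     mtr$specificity, mte$specificity)
      max_val <- max(mtr$sensitivity, mte$sensitivity,
                     mtr$specificity, mte$specificity)
      oc3 <- min_val * f
      oc3 * (1 - (max_val - min_val)) * (if (single_f) 1 else f)
    })
}
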