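#' Rank-based inverse-normal transformation
#'
#' Maps values to normal quantiles via Blom scores:
#' `z_i = qnorm((r_i - c) / (n - 2c + 1))` with offset `c = 3/8` by default,
#' where `r_i` is the (average, under ties) rank of the i-th value among the
#' non-missing values. Variance-components likelihoods assume normal traits;
#' this transform is applied to each trait before fitting. Rank-preserving
#' and idempotent on tie-free input.
#'
#' @param values numeric vector, at least 2 non-missing and not all equal.
#'   `NA`s are passed through in place.
#' @param offset Blom offset `c`; 3/8 default, 1/2 gives van der Waerden-like
#'   scores.
#' @return Numeric vector of normal scores in input order.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 non-missing values")
  if (max(x) == min(x)) stop("degenerate input: all values identical")
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

# OR over flags/threshold exceedances with missing propagation:
# TRUE if any condition is TRUE; NA if none TRUE and any input missing;
# error only when every input is missing for every row is left to callers.
or_na <- function(...) Reduce(`|`, list(...))

#' Encode hypertension status
#'
#' Present iff a history of hypertension, systolic blood pressure over
#' 140 mmHg, diastolic over 90 mmHg, or current antihypertensive use.
#' Thresholds are strict ("over"): 140/90 exactly is negative. Vectorized;
#' missing inputs propagate (a row with all inputs missing is `NA`, a known
#' positive condition dominates missing ones).
#'
#' @param history logical, history of hypertension.
#' @param systolic,diastolic blood pressure in mmHg.
#' @param on_meds logical, current use of antihypertensives.
#' @return Logical vector.
#' @export
encode_hypertension <- function(history, systolic, diastolic, on_meds) {
  check_positive(systolic, "systolic")
  check_positive(diastolic, "diastolic")
  or_na(history, systolic > 140, diastolic > 90, on_meds)
}

#' Encode diabetes status
#'
#' Present iff a history of diabetes, current anti-diabetic use, or fasting
#' glucose above 126 mg/dl (strict).
#'
#' @param history logical, history of diabetes.
#' @param on_antidiabetics logical.
#' @param fasting_glucose mg/dl.
#' @return Logical vector.
#' @export
encode_diabetes <- function(history, on_antidiabetics, fasting_glucose) {
  check_positive(fasting_glucose, "fasting_glucose")
  or_na(history, on_antidiabetics, fasting_glucose > 126)
}

#' Encode hypercholesterolemia status
#'
#' Present iff a history of hypercholesterolemia, current lipid-lowering
#' treatment, total cholesterol higher than 200 mg/dl, or LDL cholesterol
#' higher than 130 mg/dl (both strict).
#'
#' @param history logical.
#' @param treated logical, treated at examination.
#' @param total_chol,ldl mg/dl.
#' @return Logical vector.
#' @export
encode_hypercholesterolemia <- function(history, treated, total_chol, ldl) {
  check_positive(total_chol, "total_chol")
  check_positive(ldl, "ldl")
  or_na(history, treated, total_chol > 200, ldl > 130)
}

check_positive <- function(x, what) {
  if (any(!is.na(x) & x <= 0))
    stop(what, " must be positive where present")
  invisible(x)
}

#' Convert mg/dl to mmol/l
#'
#' Unit helper for glucose (molar mass 180.16 g/mol) and cholesterol
#' (387/10 conversion factor convention: 1 mmol/l = 38.67 mg/dl).
#'
#' @param x value in mg/dl.
#' @param analyte `"glucose"` or `"cholesterol"`.
#' @return Value in mmol/l.
#' @export
mgdl_to_mmol <- function(x, analyte = c("glucose", "cholesterol")) {
  analyte <- match.arg(analyte)
  x / switch(analyte, glucose = 18.016, cholesterol = 38.67)
}
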