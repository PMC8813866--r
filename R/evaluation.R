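# Base-pair-level prediction accuracy: sensitivity X = TP/(TP+FN),
# specificity Y = TP/(TP+FP), the full Matthews correlation coefficient,
# and its common simplification sqrt(X*Y).  TP is exact (i, j) identity;
# no slipped-pair credit is given.

#' Confusion counts between predicted and reference structures
#'
#' `tn` needs a pair universe; the default is the set of admissible
#' pairs `{(i, j): j - i >= min_span, can_pair}` when a sequence is
#' supplied, else all `C(n, 2)` position pairs (`universe = "all"`).
#'
#' @param pred,ref [secondary_structure()] objects of equal length.
#' @param seq Optional [rna_sequence()]; enables the admissible-pair
#'   universe.
#' @param cfg A [fold_config()].
#' @param universe `"admissible"` (requires `seq`) or `"all"`.
#' @return List of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, ref, seq = NULL, cfg = fold_config(),
                      universe = if (!is.null(seq)) "admissible" else "all") {
  stopifnot(inherits(pred, "secondary_structure"),
            inherits(ref, "secondary_structure"))
  dp_assert(pred$n == ref$n, "dpfold_domain",
            "predicted and reference structures have different lengths")
  universe <- match.arg(universe, c("admissible", "all"))
  key <- function(s) if (n_pairs(s) == 0) character(0) else
    paste(s$pairs[, 1], s$pairs[, 2])
  kp <- key(pred); kr <- key(ref)
  tp <- length(intersect(kp, kr))
  fp <- length(setdiff(kp, kr))
  fn <- length(setdiff(kr, kp))
  U <- if (universe == "admissible") {
    dp_assert(!is.null(seq), "dpfold_domain",
              "admissible universe requires a sequence")
    sum(pairing_matrix(seq, cfg))
  } else {
    pred$n * (pred$n - 1) / 2
  }
  tn <- U - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity X = TP / (TP + FN)
#'
#' Fraction of reference pairs recovered.  Returns `NA` (never `NaN`)
#' when the reference is empty.
#'
#' @param c A [confusion()] result.
#' @return Numeric in `[0, 1]` or `NA`.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) return(NA_real_)
  c$tp / (c$tp + c$fn)
}

#' Specificity Y = TP / (TP + FP)
#'
#' Fraction of predicted pairs that are correct.  `NA` when nothing was
#' predicted.
#'
#' @inheritParams sensitivity
#' @return Numeric in `[0, 1]` or `NA`.
#' @export
specificity <- function(c) {
  if (c$tp + c$fp == 0) return(NA_real_)
  c$tp / (c$tp + c$fp)
}

#' Full Matthews correlation coefficient
#'
#' Standard form `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' ranging from -1 (TP = TN = 0) to 1 (FP = FN = 0).  `printed_variant`
#' swaps in the denominator `(TP+FP)(TP+FN)(FN+FP)(TN+FN)` occasionally
#' seen in print (almost certainly a typesetting slip of the standard
#' formula); it is provided for comparison only.
#'
#' @inheritParams sensitivity
#' @param printed_variant Use the non-standard denominator.
#' @return Numeric in `[-1, 1]`, or `NA` when a marginal is zero.
#' @export
mcc_full <- function(c, printed_variant = FALSE) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn; tn <- c$tn
  den <- if (printed_variant) {
    (tp + fp) * (tp + fn) * (fn + fp) * (tn + fn)
  } else {
    (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  }
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Simplified MCC = sqrt(X * Y)
#'
#' The common simplification of the Matthews coefficient used when only
#' sensitivity and specificity are reported; always in `[0, 1]`, equal
#' to 1 iff `x = y = 1`.
#'
#' @param x Sensitivity in `[0, 1]`.
#' @param y Specificity in `[0, 1]`.
#' @return `sqrt(x * y)`.
#' @examples
#' mcc_simple(0.61, 0.63)  # ~0.62
#' @export
mcc_simple <- function(x, y) {
  stopifnot(is.na(x) || (x >= 0 && x <= 1), is.na(y) || (y >= 0 && y <= 1))
  sqrt(x * y)
}

#' Compare a prediction against a reference structure
#'
#' @inheritParams confusion
#' @param name Label for the report row.
#' @return List of class `evaluation_report`: `name`, `n`, confusion
#'   counts and `x`, `y`, `mcc_full`, `mcc_simple` (`NA` where
#'   undefined).
#' @export
evaluate_structures <- function(pred, ref, seq = NULL, cfg = fold_config(),
                                name = if (!is.null(seq)) seq$id else "structure",
                                universe = if (!is.null(seq)) "admissible" else "all") {
  cc <- confusion(pred, ref, seq, cfg, universe)
  x <- sensitivity(cc); y <- specificity(cc)
  structure(list(name = name, n = pred$n, counts = cc, x = x, y = y,
                 mcc_full = mcc_full(cc),
                 mcc_simple = if (is.na(x) || is.na(y)) NA_real_ else mcc_simple(x, y)),
            class = "evaluation_report")
}

fmt_metric <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' @export
print.evaluation_report <- function(x, ...) {
  cat(paste(report_header(), collapse = "\t"), "\n")
  cat(paste(report_row(x), collapse = "\t"), "\n")
  invisible(x)
}

report_header <- function() c("name", "n", "X", "Y", "MCC_full", "MCC_simple")

report_row <- function(r) {
  c(r$name, as.character(r$n), fmt_metric(r$x), fmt_metric(r$y),
    fmt_metric(r$mcc_full), fmt_metric(r$mcc_simple))
}
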