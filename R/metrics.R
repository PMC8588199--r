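# Segmentation evaluation metrics from pixel confusion counts:
# conformity, Jaccard, Dice, sensitivity, sensibility, and the pixel-count
# error measures.

#' Pixel confusion counts between a segmentation and a gold standard
#'
#' @param pred,gold binary masks of identical dimensions.
#' @return object of class \code{ttc_confusion}: \code{tp}, \code{fp},
#'   \code{fn} pixel counts plus \code{ns} (predicted pixels) and \code{ng}
#'   (gold pixels).
#' @export
confusion_counts <- function(pred, gold) {
  if (!all(dim(pred) == dim(gold))) stop("mask dimensions differ")
  pred <- pred > 0; gold <- gold > 0
  tp <- sum(pred & gold)
  fp <- sum(pred & !gold)
  fn <- sum(!pred & gold)
  structure(list(tp = tp, fp = fp, fn = fn, ns = tp + fp, ng = tp + fn),
            class = "ttc_confusion")
}

#' Counts constructor from explicit values
#' @param tp,fp,fn nonnegative pixel counts.
#' @return a \code{ttc_confusion} object.
#' @export
confusion <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, ns = tp + fp, ng = tp + fn),
            class = "ttc_confusion")
}

#' Similarity metrics (percentages)
#'
#' Computes the conformity kappa_c = (1 - (FP+FN)/TP) x 100, Jaccard
#' kappa_J, Dice kappa_D, sensitivity eta_st = TP/(TP+FN) x 100 and
#' sensibility eta_sb = (1 - FP/(TP+FN)) x 100. The sensibility denominator
#' is the gold pixel count (TP+FN) rather than the usual true-negative
#' form; it measures over-segmentation relative to the object size and can
#' be negative for gross over-segmentation, as can the conformity.
#' Conformity is undefined (NA) when TP = 0.
#'
#' @param c a \code{ttc_confusion}.
#' @return named numeric vector \code{kappa_c}, \code{kappa_j},
#'   \code{kappa_d}, \code{eta_st}, \code{eta_sb}; undefined values are NA.
#' @export
similarity_metrics <- function(c) {
  stopifnot(inherits(c, "ttc_confusion"))
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  kc <- if (tp > 0) (1 - (fp + fn) / tp) * 100 else NA_real_
  kj <- if (tp + fn + fp > 0) tp / (tp + fn + fp) * 100 else NA_real_
  kd <- if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) * 100 else NA_real_
  st <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  sb <- if (tp + fn > 0) (1 - fp / (tp + fn)) * 100 else NA_real_
  c(kappa_c = kc, kappa_j = kj, kappa_d = kd, eta_st = st, eta_sb = sb)
}

#' Pixel-count error metrics
#'
#' \code{delta_n = |Ns - Ng|} (pixel number difference), \code{delta_f =
#' FP + FN} (wrong pixels), \code{epsilon_f = delta_f / Ng x 100}
#' (percentage error relative to the gold standard; NA when Ng = 0).
#'
#' @param c a \code{ttc_confusion}.
#' @return named numeric vector \code{delta_n}, \code{delta_f},
#'   \code{epsilon_f}.
#' @export
error_metrics <- function(c) {
  stopifnot(inherits(c, "ttc_confusion"))
  dn <- abs(c$ns - c$ng)
  df <- c$fp + c$fn
  ef <- if (c$ng > 0) df / c$ng * 100 else NA_real_
  c(delta_n = dn, delta_f = df, epsilon_f = ef)
}

#' Full metrics report for a mask pair
#'
#' @param pred,gold binary masks.
#' @return object of class \code{ttc_metrics_report}: all eight metrics
#'   plus the underlying counts.
#' @export
#' @examples
#' a <- matrix(FALSE, 8, 8); b <- a
#' a[2:6, 2:6] <- TRUE; b[3:7, 2:6] <- TRUE
#' segmentation_report(a, b)
segmentation_report <- function(pred, gold) {
  cc <- confusion_counts(pred, gold)
  structure(c(as.list(similarity_metrics(cc)), as.list(error_metrics(cc)),
              list(counts = cc)),
            class = "ttc_metrics_report")
}

#' @export
print.ttc_metrics_report <- function(x, digits = 4, ...) {
  cat("Segmentation evaluation report\n")
  cat(sprintf("  conformity  kappa_c : %s\n", .fmt_pct(x$kappa_c, digits)))
  cat(sprintf("  Jaccard     kappa_J : %s\n", .fmt_pct(x$kappa_j, digits)))
  cat(sprintf("  Dice        kappa_D : %s\n", .fmt_pct(x$kappa_d, digits)))
  cat(sprintf("  sensitivity eta_st  : %s\n", .fmt_pct(x$eta_st, digits)))
  cat(sprintf("  sensibility eta_sb  : %s\n", .fmt_pct(x$eta_sb, digits)))
  cat(sprintf("  pixel diff  delta_N : %d\n", as.integer(x$delta_n)))
  cat(sprintf("  wrong px    delta_F : %d\n", as.integer(x$delta_f)))
  cat(sprintf("  error ratio eps_F   : %s\n", .fmt_pct(x$epsilon_f, digits)))
  invisible(x)
}

.fmt_pct <- function(v, digits) {
  if (is.na(v)) "undefined" else paste0(formatC(v, format = "f", digits = digits), "%")
}

#' Metrics for a stack of mask pairs
#'
#' Aggregates a list of predicted/gold mask pairs either volumetrically
#' (confusion counts summed over the stack before computing metrics) or as
#' the per-slice average of individual metrics. The two modes differ on
#' unbalanced stacks; volumetric aggregation weights every pixel equally.
#'
#' @param preds,golds lists of binary masks.
#' @param mode "volumetric" or "per_slice".
#' @return named numeric vector of the eight metrics.
#' @export
stack_metrics <- function(preds, golds, mode = c("volumetric", "per_slice")) {
  mode <- match.arg(mode)
  stopifnot(length(preds) == length(golds), length(preds) >= 1)
  if (mode == "volumetric") {
    tot <- list(tp = 0, fp = 0, fn = 0)
    for (i in seq_along(preds)) {
      cc <- confusion_counts(preds[[i]], golds[[i]])
      tot$tp <- tot$tp + cc$tp; tot$fp <- tot$fp + cc$fp; tot$fn <- tot$fn + cc$fn
    }
    cc <- confusion(tot$tp, tot$fp, tot$fn)
    c(similarity_metrics(cc), error_metrics(cc))
  } else {
    per <- vapply(seq_along(preds), function(i) {
      cc <- confusion_counts(preds[[i]], golds[[i]])
      c(similarity_metrics(cc), error_metrics(cc))
    }, numeric(8))
    rowMeans(per)
  }
}
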