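# Multi-label evaluation metrics.
#
# Overall metrics treat each record's observed and predicted labels as sets.
# Empty-set conventions: a ratio whose denominator set is empty contributes
# 1 when both sets are empty (identical sets) and 0 when only the
# denominator set is empty; absolute_true uses the set-identity indicator
# directly, so two empty sets count as a correct prediction. These
# conventions are certified against the published worked evaluation of the
# 20 test sites on histone H2B type 1-K (Q16778); see table6_fixture().

as_label_logical <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != 4L) stop("label matrices must have 4 columns")
  if (is.logical(x)) return(x)
  if (!all(x %in% c(-1, 1))) stop("labels must be coded +1/-1 (or logical)")
  x == 1
}

#' Overall multi-label metrics
#'
#' Computes aiming (precision-like), coverage (recall-like), accuracy
#' (Jaccard), absolute true (exact-match rate) and absolute false
#' (normalized symmetric-difference rate) over per-record observed and
#' predicted label sets, averaged over records.
#'
#' @param observed,predicted `n x 4` matrices of `+1`/`-1` (or logical)
#'   labels, columns in [PTM_TYPES] order.
#' @param m Number of labels (denominator of absolute false); default 4.
#' @return Object of class `lys_metrics`: a list with `aiming`, `coverage`,
#'   `accuracy`, `absolute_true`, `absolute_false`, `n`, `m`.
#' @examples
#' t6 <- table6_fixture()
#' overall_metrics(t6$observed, t6$predicted)
#' @export
overall_metrics <- function(observed, predicted, m = 4L) {
  obs <- as_label_logical(observed)
  pred <- as_label_logical(predicted)
  if (nrow(obs) != nrow(pred)) stop("observed/predicted row counts differ")
  n <- nrow(obs)
  if (n == 0L) stop("no label-set pairs supplied")
  inter <- rowSums(obs & pred)
  uni <- rowSums(obs | pred)
  n_obs <- rowSums(obs)
  n_pred <- rowSums(pred)
  ratio0 <- function(num, den) ifelse(den > 0, num / den,
                                      as.numeric(n_obs + n_pred == 0))
  structure(list(
    aiming = mean(ratio0(inter, n_pred)),
    coverage = mean(ratio0(inter, n_obs)),
    accuracy = mean(ifelse(uni > 0, inter / uni, 1)),
    absolute_true = mean(rowSums(obs == pred) == 4L),
    absolute_false = mean((uni - inter) / m),
    n = n, m = as.integer(m)), class = "lys_metrics")
}

#' @export
print.lys_metrics <- function(x, ...) {
  cat(sprintf(paste0("multi-label metrics (n = %d, m = %d):\n",
                     "  aiming         %.4f\n  coverage       %.4f\n",
                     "  accuracy       %.4f\n  absolute true  %.4f\n",
                     "  absolute false %.4f\n"),
              x$n, x$m, x$aiming, x$coverage, x$accuracy,
              x$absolute_true, x$absolute_false))
  invisible(x)
}

#' @export
as.data.frame.lys_metrics <- function(x, ...) {
  data.frame(aiming = x$aiming, coverage = x$coverage, accuracy = x$accuracy,
             absolute_true = x$absolute_true,
             absolute_false = x$absolute_false, n = x$n, m = x$m)
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' @param truth Logical or `+1`/`-1` vector of positives.
#' @param score Numeric scores, larger = more positive; ties handled by
#'   midranks.
#' @return AUROC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auroc <- function(truth, score) {
  pos <- if (is.logical(truth)) truth else truth == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration of precision over recall at every distinct score
#' threshold (descending); tied scores enter as one block.
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`, or `NA` when there are no positives.
#' @export
aupr <- function(truth, score) {
  pos <- if (is.logical(truth)) truth else truth == 1
  n1 <- sum(pos)
  if (n1 == 0L) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  pos <- pos[o]; score <- score[o]
  grp <- cumsum(!duplicated(score))      # block id per distinct threshold
  tp_g <- tapply(as.integer(pos), grp, sum)
  n_g <- tabulate(grp)
  tp <- cumsum(tp_g)
  fp <- cumsum(n_g) - tp
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Per-label confusion metrics and curve areas
#'
#' For each of the four labels, counts TP/TN/FP/FN (a record is positive for
#' a label when its observed entry is `+1`) and derives sensitivity,
#' specificity, accuracy, precision and F1, plus AUROC and AUPR from the
#' continuous label scores. Precision and F1 are 0 when their denominators
#' are 0.
#'
#' @param truth,predictions `n x 4` matrices of `+1`/`-1`.
#' @param scores `n x 4` numeric matrix of label scores (column `v` is the
#'   continuous score for label `v`); optional -- without it AUROC/AUPR are
#'   `NA`.
#' @return Data frame with one row per label.
#' @export
per_label_metrics <- function(truth, predictions, scores = NULL) {
  tr <- as_label_logical(truth)
  pr <- as_label_logical(predictions)
  if (!all(dim(tr) == dim(pr))) stop("truth/prediction shapes differ")
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (!all(dim(scores) == dim(tr))) stop("score matrix shape differs")
  }
  out <- lapply(1:4, function(v) {
    t <- tr[, v]; p <- pr[, v]
    TP <- sum(t & p); TN <- sum(!t & !p)
    FP <- sum(!t & p); FN <- sum(t & !p)
    sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    prec <- if (TP + FP > 0) TP / (TP + FP) else 0
    f1 <- if (!is.na(sn) && prec + sn > 0) 2 * prec * sn / (prec + sn) else 0
    data.frame(type = PTM_TYPES[v], TP = TP, TN = TN, FP = FP, FN = FN,
               SN = sn, SP = sp, ACC = (TP + TN) / length(t),
               precision = prec, F1 = f1,
               AUROC = if (is.null(scores)) NA_real_
                       else auroc(t, scores[, v]),
               AUPR = if (is.null(scores)) NA_real_
                      else aupr(t, scores[, v]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' ROC and PR curve points for one label
#'
#' Exports the curve coordinates (for external plotting) at every distinct
#' score threshold, descending.
#'
#' @inheritParams auroc
#' @return Data frame with columns `threshold`, `FPR`, `TPR` (ROC) and
#'   `recall`, `precision` (PR).
#' @export
curve_points <- function(truth, score) {
  pos <- if (is.logical(truth)) truth else truth == 1
  o <- order(score, decreasing = TRUE)
  pos <- pos[o]; score <- score[o]
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(tapply(as.integer(pos), grp, sum))
  nn <- cumsum(tabulate(grp))
  fp <- nn - tp
  n1 <- sum(pos); n0 <- length(pos) - n1
  data.frame(threshold = score[!duplicated(score)],
             FPR = if (n0 > 0) fp / n0 else NA_real_,
             TPR = if (n1 > 0) tp / n1 else NA_real_,
             recall = if (n1 > 0) tp / n1 else NA_real_,
             precision = tp / nn)
}
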