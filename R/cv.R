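# Cross-validation with per-fold feature refitting.
#
# The distribution features depend on the training set, so each fold's
# count table and model are fitted on the training folds only and the
# held-out fold is encoded with that table -- the held-out records
# contribute nothing to their own representation. Overall metrics are
# averaged over folds; per-label metrics and curves are computed on the
# pooled held-out predictions.

# Split n items into `folds` groups as equal as possible, remainder spread
# over the first folds; `ord` is a permutation of seq_len(n).
fold_assignment <- function(ord, folds) {
  n <- length(ord)
  sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds),
                                       rep(0L, folds - n %% folds))
  assign <- integer(n)
  assign[ord] <- rep(seq_len(folds), sizes)
  assign
}

#' Cross-validate the kernel regression model
#'
#' Runs K-fold cross-validation with the feature encoder refitted inside
#' every fold. In `"general"` mode records are partitioned uniformly at
#' random; in `"strict"` mode whole proteins are partitioned (balancing
#' protein counts), so no protein contributes segments to both the training
#' and the test side of any fold.
#'
#' @param data A [lys_dataset()].
#' @param folds Number of folds (default 5).
#' @param mode `"general"` (record-randomized) or `"strict"`
#'   (protein-grouped).
#' @param seed Integer seed controlling the fold split.
#' @param exclude_unlabeled Drop records with no PTM label before splitting.
#' @param theta,engine Passed to [fit_model()].
#' @return List of class `lys_cv` with `overall` (fold-averaged
#'   [overall_metrics()]), `per_fold` (data frame of per-fold overall
#'   metrics), `per_label` (pooled [per_label_metrics()]), `predictions`
#'   (data frame of pooled held-out scores and labels) and the
#'   configuration.
#' @export
run_cv <- function(data, folds = 5L, mode = c("general", "strict"),
                   seed = 1L, exclude_unlabeled = FALSE, theta = 1 / 6,
                   engine = c("gkpr", "gkr")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  if (exclude_unlabeled)
    data <- subset_dataset(data, rowSums(data$labels == 1L) > 0L)
  n <- n_records(data)
  set.seed(as.integer(seed))
  if (mode == "general") {
    if (folds > n) stop("more folds than records")
    assign <- fold_assignment(sample.int(n), folds)
  } else {
    prot <- unique(data$protein_id)
    if (folds > length(prot)) stop("more folds than proteins")
    passign <- fold_assignment(sample.int(length(prot)), folds)
    assign <- passign[match(data$protein_id, prot)]
  }
  scores <- matrix(NA_real_, n, 4L, dimnames = list(NULL, PTM_TYPES))
  per_fold <- vector("list", folds)
  for (k in seq_len(folds)) {
    test <- assign == k
    model <- fit_model(subset_dataset(data, !test), theta = theta,
                       engine = engine)
    pred <- predict(model, subset_dataset(data, test))
    scores[test, ] <- pred$scores
    mk <- overall_metrics(data$labels[test, , drop = FALSE], pred$labels)
    per_fold[[k]] <- cbind(fold = k, as.data.frame(mk))
  }
  labels_hat <- predict_labels(scores)
  per_fold <- do.call(rbind, per_fold)
  overall <- structure(as.list(colMeans(per_fold[
    , c("aiming", "coverage", "accuracy", "absolute_true",
        "absolute_false")])), class = "lys_metrics")
  overall$n <- n
  overall$m <- 4L
  structure(list(
    overall = overall,
    per_fold = per_fold,
    per_label = per_label_metrics(data$labels, labels_hat, scores),
    predictions = data.frame(protein_id = data$protein_id,
                             position = data$position,
                             fold = assign,
                             stats::setNames(as.data.frame(scores),
                                             paste0("score_", PTM_TYPES)),
                             stats::setNames(as.data.frame(labels_hat),
                                             paste0("pred_", PTM_TYPES)),
                             stats::setNames(as.data.frame(data$labels),
                                             paste0("obs_", PTM_TYPES))),
    folds = folds, mode = mode, seed = as.integer(seed),
    exclude_unlabeled = exclude_unlabeled, theta = theta, engine = engine),
    class = "lys_cv")
}

#' @export
print.lys_cv <- function(x, ...) {
  cat(sprintf("%d-fold %s cross-validation (%s, theta = %s, seed = %d)\n",
              x$folds, x$mode, x$engine, format(x$theta), x$seed))
  print(x$overall)
  invisible(x)
}

#' Grid evaluation over kernel widths and window sizes
#'
#' Runs [run_cv()] for every combination of `thetas` and `Ls` and returns a
#' tidy table of overall metrics. Changing `L` re-extracts segments: either
#' from `sequences` (a FASTA path or named character vector of proteins, via
#' [extract_peptide_segment()]) or, when no sequences are given, by trimming
#' the dataset's own segments to the smaller window.
#'
#' @param data A [lys_dataset()].
#' @param thetas Numeric vector of kernel widths.
#' @param Ls Integer vector of half widths.
#' @param sequences Optional FASTA path or named character vector of full
#'   protein sequences for re-extraction at larger `L`.
#' @param ... Passed to [run_cv()] (`folds`, `mode`, `seed`, ...).
#' @return Data frame with one row per (theta, L) combination.
#' @export
sweep_grid <- function(data, thetas = 1 / 6, Ls = data$half_width,
                       sequences = NULL, ...) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  rows <- list()
  for (L in as.integer(Ls)) {
    dL <- reframe_dataset(data, L, sequences)
    for (theta in thetas) {
      cv <- run_cv(dL, theta = theta, ...)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(theta = theta, L = L),
              as.data.frame(cv$overall))
    }
  }
  do.call(rbind, rows)
}

# Rebuild a dataset at half width L: re-extract from sequences when given,
# otherwise trim the stored segments (only possible for L <= current L).
reframe_dataset <- function(data, L, sequences = NULL) {
  L <- as.integer(L)
  if (L == data$half_width) return(data)
  if (!is.null(sequences)) {
    segs <- vapply(seq_len(n_records(data)), function(i) {
      extract_peptide_segment(sequences[[data$protein_id[i]]],
                              data$position[i], L)
    }, character(1L))
  } else if (L < data$half_width) {
    off <- data$half_width - L
    segs <- substr(data$segment, off + 1L, off + 2L * L + 1L)
  } else {
    stop("cannot widen segments to L = ", L,
         " without the source sequences")
  }
  lys_dataset(data$protein_id, data$position, segs, data$labels, L)
}
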