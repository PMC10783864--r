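# Multi-label Gaussian kernel regression engines.
#
# Each label v in 1..4 gets a score S_v = sum_i l_i^v w_i / sum_i w_i with
# w_i = exp(-d_i / (2 theta^2)). The "gkpr" engine takes d_i as the squared
# difference restricted to label v's feature slots (columns 4j+v over the
# 2(L-1) blocks); the "gkr" baseline uses the full squared Euclidean
# distance for every label. Exponents are shifted by the per-query minimal
# distance before exponentiation: the ratio is unchanged exactly, and the
# nearest training record then always has weight 1, so the denominator is
# >= 1 and no epsilon guard is needed.

#' Masked squared distance between two feature vectors
#'
#' Sums the squared differences over the feature slots belonging to label
#' `v` only: columns `4j + v` for block `j = 0, ..., 2L-3`, i.e. `2(L-1)`
#' of the `8(L-1)` coordinates. Summing over `v = 1..4` recovers the full
#' squared Euclidean distance.
#'
#' @param x,y Numeric feature vectors of equal length `8(L-1)`.
#' @param v Label index in 1..4 ([PTM_TYPES] order).
#' @return Nonnegative scalar.
#' @export
masked_sq_distance <- function(x, y, v) {
  if (length(x) != length(y))
    stop("feature vectors have different lengths: ", length(x), " vs ",
         length(y))
  if (length(v) != 1L || !v %in% 1:4) stop("v must be a single index in 1..4")
  idx <- seq.int(v, length(x), by = 4L)
  sum((x[idx] - y[idx])^2)
}

#' Fit a multi-label kernel regression model
#'
#' Fits the di-residue count table on `training`, encodes the training
#' segments with it, and stores the encoded matrix together with the +1/-1
#' label matrix and the kernel parameters. Fitting is deterministic.
#'
#' @param training A nonempty [lys_dataset()].
#' @param theta Kernel width; the supported grid is
#'   `1/2, 1/4, 1/6, 1/8, 1/16, 1/32`, with `1/6` the default.
#' @param engine `"gkpr"` (per-label masked distances, the default) or
#'   `"gkr"` (full-distance baseline).
#' @return An object of class `lys_model`.
#' @export
fit_model <- function(training, theta = 1 / 6, engine = c("gkpr", "gkr")) {
  engine <- match.arg(engine)
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  if (n_records(training) == 0L) stop("training dataset is empty")
  table <- fit_count_table(training)
  feats <- encode_dataset(table, training)
  structure(list(theta = theta, engine = engine,
                 half_width = training$half_width,
                 table = table,
                 train_features = feats,
                 train_labels = training$labels),
            class = "lys_model")
}

#' @export
print.lys_model <- function(x, ...) {
  cat("lys_model:", x$engine, "engine, theta =", format(x$theta),
      ", L =", x$half_width, ",", nrow(x$train_features),
      "training segments\n")
  invisible(x)
}

#' Score the four labels for one or more query feature vectors
#'
#' Computes `S_v`, the kernel-weighted mean of the +1/-1 training labels for
#' each label `v`, using masked distances (`gkpr`) or the full distance
#' (`gkr`). Each score lies in `[-1, 1]`.
#'
#' @param model A fitted `lys_model`.
#' @param features A feature vector of length `8(L-1)` or an `n x 8(L-1)`
#'   matrix of queries.
#' @return Numeric `n x 4` matrix of scores (a single query yields a 1-row
#'   matrix), columns in [PTM_TYPES] order.
#' @export
score_labels <- function(model, features) {
  stopifnot(inherits(model, "lys_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  d <- ncol(model$train_features)
  if (ncol(features) != d)
    stop("query has ", ncol(features), " features; model expects ", d)
  n <- nrow(features)
  scores <- matrix(NA_real_, n, 4L, dimnames = list(NULL, PTM_TYPES))
  inv2t2 <- 1 / (2 * model$theta^2)
  full_D <- if (model$engine == "gkr")
    sq_dist_matrix(features, model$train_features) else NULL
  for (v in 1:4) {
    D <- if (model$engine == "gkr") full_D else {
      idx <- seq.int(v, d, by = 4L)
      sq_dist_matrix(features[, idx, drop = FALSE],
                     model$train_features[, idx, drop = FALSE])
    }
    shift <- apply(D, 1L, min)       # exact stabilization: ratio unchanged
    W <- exp(-(D - shift) * inv2t2)
    lv <- model$train_labels[, v]
    scores[, v] <- as.vector(W %*% lv) / rowSums(W)
  }
  # convex combination of +/-1 labels: clamp summation round-off at the ends
  scores[scores > 1] <- 1
  scores[scores < -1] <- -1
  scores
}

# Pairwise squared Euclidean distances between row sets, clamped at 0
# against cancellation noise.
sq_dist_matrix <- function(A, B) {
  D <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Threshold label scores into +1/-1 predictions
#'
#' A label is called present (`+1`) when its score is `>= 0`; a score of
#' exactly zero therefore predicts the label.
#'
#' @param scores Numeric vector of 4 scores or an `n x 4` score matrix.
#' @return Integer matrix of `+1`/`-1` with the same rows.
#' @export
predict_labels <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  out <- ifelse(scores >= 0, 1L, -1L)
  storage.mode(out) <- "integer"
  colnames(out) <- PTM_TYPES
  out
}

#' Predict PTM labels for new data
#'
#' Encodes `newdata` with the model's own count table and returns per-label
#' scores and thresholded +1/-1 labels.
#'
#' @param object A fitted `lys_model`.
#' @param newdata A `lys_dataset`, a character vector of segments, or an
#'   already-encoded feature matrix.
#' @param ... Unused.
#' @return List with elements `scores` (`n x 4` numeric) and `labels`
#'   (`n x 4` integer `+1`/`-1`).
#' @export
predict.lys_model <- function(object, newdata, ...) {
  features <- if (is.numeric(newdata)) {
    if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else newdata
  } else encode_dataset(object$table, newdata)
  scores <- score_labels(object, features)
  list(scores = scores, labels = predict_labels(scores))
}

#' Serialize a fitted model to a single JSON document
#' @param model A fitted `lys_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(format = "lysPTM_model", version = 1L,
              theta = model$theta, engine = model$engine,
              half_width = model$half_width,
              table = count_table_to_list(model$table),
              train_features = unname(model$train_features),
              train_labels = unname(model$train_labels))
  # digits = I(17): exact decimal round trip for doubles
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a fitted model from JSON
#' @param path Path written by [write_model()].
#' @return A `lys_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "lysPTM_model")) stop("not a lysPTM model document")
  table <- count_table_from_list(x$table)
  feats <- matrix(as.numeric(x$train_features),
                  nrow = nrow(x$train_features))
  labels <- matrix(as.integer(x$train_labels), ncol = 4L,
                   dimnames = list(NULL, PTM_TYPES))
  colnames(feats) <- colnames(encode_matrix(table, character(0)))
  structure(list(theta = as.numeric(x$theta), engine = x$engine,
                 half_width = as.integer(x$half_width),
                 table = table, train_features = feats,
                 train_labels = labels),
            class = "lys_model")
}
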