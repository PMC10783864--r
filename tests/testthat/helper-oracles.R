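# Naive, independent reference implementations used to cross-check the
# vectorized package code. Everything here is deliberately written as plain
# double loops over definitions.

# All (position, pair) keys of one segment, excluding center pairs.
oracle_keys <- function(segment) {
  L <- (nchar(segment) - 1L) %/% 2L
  out <- list()
  for (i in seq_len(2L * L)) {            # 1-based start of each pair
    start_pos <- i - L - 1L               # signed position of first residue
    if (start_pos %in% c(-1L, 0L)) next   # pair touches the center lysine
    out[[length(out) + 1L]] <- list(
      position = start_pos,
      pair = substr(segment, i, i + 1L))
  }
  out
}

# Count table as a named list key -> c(total, 4 per-type counts).
oracle_count_table <- function(data) {
  counts <- list()
  for (k in seq_along(data$segment)) {
    for (key in oracle_keys(data$segment[k])) {
      id <- paste0(key$position, ":", key$pair)
      if (is.null(counts[[id]])) counts[[id]] <- rep(0L, 5L)
      counts[[id]][1] <- counts[[id]][1] + 1L
      for (v in 1:4) {
        if (data$labels[k, v] == 1L)
          counts[[id]][v + 1L] <- counts[[id]][v + 1L] + 1L
      }
    }
  }
  counts
}

oracle_encode_segment <- function(counts, segment) {
  feats <- numeric(0)
  for (key in oracle_keys(segment)) {
    id <- paste0(key$position, ":", key$pair)
    block <- if (is.null(counts[[id]])) rep(0, 4L)
             else counts[[id]][2:5] / counts[[id]][1]
    feats <- c(feats, block)
  }
  feats
}

# Per-label scores by direct evaluation of the kernel ratio, without the
# stabilizing shift used in the package.
oracle_scores <- function(train_features, train_labels, query, theta,
                          engine = "gkpr") {
  a <- nrow(train_features)
  d <- ncol(train_features)
  s <- numeric(4L)
  for (v in 1:4) {
    num <- 0
    den <- 0
    for (i in seq_len(a)) {
      if (engine == "gkpr") {
        dist <- 0
        for (j in seq.int(0L, d / 4L - 1L)) {
          col <- 4L * j + v
          dist <- dist + (query[col] - train_features[i, col])^2
        }
      } else {
        dist <- sum((query - train_features[i, ])^2)
      }
      w <- exp(-dist / (2 * theta^2))
      num <- num + train_labels[i, v] * w
      den <- den + w
    }
    s[v] <- num / den
  }
  s
}

# Overall multi-label metrics straight from the set definitions.
oracle_overall <- function(observed, predicted, m = 4) {
  n <- nrow(observed)
  aim <- cov <- acc <- atrue <- afalse <- 0
  for (i in seq_len(n)) {
    O <- which(observed[i, ] == 1)
    P <- which(predicted[i, ] == 1)
    I <- length(intersect(O, P))
    U <- length(union(O, P))
    aim <- aim + (if (length(P) > 0) I / length(P)
                  else as.numeric(length(O) == 0))
    cov <- cov + (if (length(O) > 0) I / length(O)
                  else as.numeric(length(P) == 0))
    acc <- acc + (if (U > 0) I / U else 1)
    atrue <- atrue + as.numeric(setequal(O, P))
    afalse <- afalse + (U - I) / m
  }
  c(aiming = aim / n, coverage = cov / n, accuracy = acc / n,
    absolute_true = atrue / n, absolute_false = afalse / n)
}

# Random valid segments and a small labeled dataset for property tests.
random_segments <- function(n, L, alphabet = c("A", "L", "E", "G", "S",
                                               "V", "K", "T", "R", "D")) {
  vapply(seq_len(n), function(i) {
    res <- sample(alphabet, 2L * L + 1L, replace = TRUE)
    res[L + 1L] <- "K"
    paste(res, collapse = "")
  }, character(1L))
}

random_dataset <- function(n, L, p = c(0.4, 0.15, 0.15, 0.3)) {
  labels <- matrix(ifelse(matrix(runif(n * 4L), n, 4L) <
                            matrix(p, n, 4L, byrow = TRUE), 1L, -1L), n, 4L)
  lys_dataset(protein_id = sprintf("P%03d", ceiling(seq_len(n) / 4)),
              position = 100L + seq_len(n),
              segment = random_segments(n, L),
              labels = labels, half_width = L)
}

# Random label-set pairs as +/-1 matrices (empty sets common).
random_pairs <- function(n) {
  obs <- matrix(ifelse(matrix(runif(n * 4L), n, 4L) < 0.3, 1L, -1L), n, 4L)
  pred <- matrix(ifelse(matrix(runif(n * 4L), n, 4L) < 0.3, 1L, -1L), n, 4L)
  list(observed = obs, predicted = pred)
}
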