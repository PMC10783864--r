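# Location-fixed di-residue count tables and distribution (rho) features.
#
# For every key (signed start position i, residue pair ab) a fitted table
# holds N(ab(i,i+1)) = number of training segments carrying that pair there,
# plus the four per-type restrictions of that count. A segment is encoded by
# concatenating, over its 2(L-1) keys in ascending position order, the
# four proportions N_type/N -- so the feature vector has 8(L-1) entries,
# with slot v of block j at column 4j+v (blocks 0-based, slots 1-based).

key_string <- function(start_position, pair) {
  paste0(start_position, ":", pair)
}

#' Fit the di-residue count table on a training set
#'
#' Counts, for every (window position, adjacent residue pair) key, the number
#' of training segments containing that pair at exactly that location
#' (`total`), and the same count restricted to segments carrying each PTM
#' type (`per_type`). Multi-label segments contribute to every type they
#' carry; unlabeled ("other") segments contribute to `total` only. Keys never
#' observed are absent and count as zero.
#'
#' @param training A nonempty [lys_dataset()].
#' @return An object of class `lys_count_table` with elements `half_width`,
#'   `n_train`, `keys` (character), `total` (integer vector) and `per_type`
#'   (integer matrix, one column per type), all aligned on `keys`.
#' @export
fit_count_table <- function(training) {
  n <- n_records(training)
  if (n == 0L) stop("training dataset is empty")
  L <- training$half_width
  pos <- diresidue_positions(L)
  keys_by_block <- segment_keys(training$segment, L)  # n x 2(L-1)
  all_keys <- as.vector(keys_by_block)
  uk <- sort(unique(all_keys))
  total <- integer(length(uk))
  per_type <- matrix(0L, length(uk), 4L, dimnames = list(NULL, PTM_TYPES))
  tt <- table(factor(all_keys, levels = uk))
  total <- as.integer(tt)
  for (v in 1:4) {
    in_type <- training$labels[, v] == 1L
    if (any(in_type)) {
      kt <- as.vector(keys_by_block[in_type, , drop = FALSE])
      per_type[, v] <- as.integer(table(factor(kt, levels = uk)))
    }
  }
  structure(list(half_width = L, n_train = n, keys = uk,
                 total = total, per_type = per_type),
            class = "lys_count_table")
}

# n x 2(L-1) matrix of key strings for a vector of segments.
segment_keys <- function(segments, L) {
  pos <- diresidue_positions(L)
  idx <- pos + L + 1L
  n <- length(segments)
  out <- matrix(NA_character_, n, length(pos))
  for (j in seq_along(pos)) {
    out[, j] <- key_string(pos[j],
                           paste0(substring(segments, idx[j], idx[j]),
                                  substring(segments, idx[j] + 1L,
                                            idx[j] + 1L)))
  }
  out
}

#' @export
print.lys_count_table <- function(x, ...) {
  cat("lys_count_table: L =", x$half_width, ",", length(x$keys),
      "observed keys from", x$n_train, "training segments\n")
  invisible(x)
}

#' Encode one di-residue key as its four-type proportion vector
#'
#' Returns `rho_t = N_t(key) / N(key)` for the four PTM types. A key never
#' observed in training (`N = 0`) encodes as `(0, 0, 0, 0)`: absence of
#' evidence is treated as zero support for every type.
#'
#' @param table A fitted `lys_count_table`.
#' @param start_position Signed window position of the pair's first residue.
#' @param pair Two-letter residue pair.
#' @return Named numeric vector of length 4 in `[0, 1]`.
#' @export
encode_diresidue <- function(table, start_position, pair) {
  stopifnot(inherits(table, "lys_count_table"))
  k <- key_string(start_position, normalize_residues(pair))
  i <- match(k, table$keys)
  if (is.na(i)) return(stats::setNames(rep(0, 4L), PTM_TYPES))
  stats::setNames(table$per_type[i, ] / table$total[i], PTM_TYPES)
}

#' Encode a peptide segment into its distribution feature vector
#'
#' Concatenates [encode_diresidue()] over the segment's `2(L-1)` keys in
#' ascending start-position order, giving `8(L-1)` features in `[0, 1]`.
#'
#' @param table A fitted `lys_count_table`.
#' @param segment Peptide segment string with the table's half width.
#' @return Numeric vector of length `8 * (half_width - 1)`.
#' @export
encode_segment <- function(table, segment) {
  stopifnot(inherits(table, "lys_count_table"))
  segment <- normalize_residues(segment)
  L <- (nchar(segment) - 1L) %/% 2L
  if (L != table$half_width)
    stop("segment half width ", L, " does not match table half width ",
         table$half_width)
  as.vector(t(encode_matrix(table, segment)))
}

#' Encode a whole dataset into a feature matrix
#'
#' @param table A fitted `lys_count_table`.
#' @param data A `lys_dataset` (or character vector of segments) sharing the
#'   table's half width.
#' @return Numeric `n x 8(L-1)` matrix; row order equals record order.
#' @export
encode_dataset <- function(table, data) {
  segments <- if (inherits(data, "lys_dataset")) {
    if (data$half_width != table$half_width)
      stop("dataset half width ", data$half_width,
           " does not match table half width ", table$half_width)
    data$segment
  } else normalize_residues(data)
  encode_matrix(table, segments)
}

# Core vectorized encoder: rows = segments, columns = 8(L-1) features laid
# out block-major (ascending start position), type-minor (PTM_TYPES order).
encode_matrix <- function(table, segments) {
  L <- table$half_width
  pos <- diresidue_positions(L)
  n <- length(segments)
  keys <- segment_keys(segments, L)
  out <- matrix(0, n, 8L * (L - 1L))
  rho <- table$per_type / table$total  # aligned on table$keys
  for (j in seq_along(pos)) {
    i <- match(keys[, j], table$keys)
    seen <- !is.na(i)
    block <- matrix(0, n, 4L)
    if (any(seen)) block[seen, ] <- rho[i[seen], , drop = FALSE]
    out[, 4L * (j - 1L) + 1:4] <- block
  }
  colnames(out) <- as.vector(vapply(pos, function(p)
    paste0("p", p, ".", PTM_TYPES), character(4L)))
  out
}

#' Serialize a count table to JSON
#' @param table A fitted `lys_count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  jsonlite::write_json(count_table_to_list(table), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read a count table from JSON
#' @param path Path written by [write_count_table()].
#' @return A `lys_count_table`.
#' @export
read_count_table <- function(path) {
  count_table_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

count_table_to_list <- function(table) {
  list(format = "lysPTM_count_table", version = 1L,
       half_width = table$half_width, n_train = table$n_train,
       keys = table$keys, total = table$total,
       per_type = unname(table$per_type))
}

count_table_from_list <- function(x) {
  if (!identical(x$format, "lysPTM_count_table"))
    stop("not a lysPTM count table document")
  per_type <- matrix(as.integer(x$per_type), ncol = 4L,
                     dimnames = list(NULL, PTM_TYPES))
  structure(list(half_width = as.integer(x$half_width),
                 n_train = as.integer(x$n_train),
                 keys = as.character(x$keys),
                 total = as.integer(x$total),
                 per_type = per_type),
            class = "lys_count_table")
}
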