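# Peptide segments, site tables and the canonical segments_tsv dialect.

# 20 standard residues; everything else collapses onto the unknown symbol.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
UNKNOWN_AA <- "X"

#' Normalize an amino-acid string to the package alphabet
#'
#' Uppercases and maps every letter outside the 20 standard residues
#' (B, Z, U, O, J, X, ...) to the single unknown symbol `"X"`, which then
#' participates in di-residue counting like any other letter.
#'
#' @param x Character vector of residue strings.
#' @return Character vector of the same length over the 21-letter alphabet.
#' @export
normalize_residues <- function(x) {
  x <- toupper(x)
  bad <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
  gsub(bad, UNKNOWN_AA, x)
}

#' Extract a lysine-centered peptide segment
#'
#' Returns the window of `2 * half_width + 1` residues centered on
#' `position`. When the window runs past either end of the sequence, the
#' missing slots are filled by repeating the terminal residue on that side
#' (the first residue upstream, the last residue downstream).
#'
#' @param sequence Amino-acid string.
#' @param position 1-based position of the center lysine; must index a `'K'`.
#' @param half_width Window half width `L >= 1`.
#' @return Character string of length `2 * half_width + 1`.
#' @examples
#' extract_peptide_segment("AKV", 2, 2)  # "AAKVV"
#' @export
extract_peptide_segment <- function(sequence, position, half_width) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            length(position) == 1L, length(half_width) == 1L,
            half_width >= 1)
  n <- nchar(sequence)
  if (position < 1 || position > n)
    stop("position ", position, " is outside the sequence (length ", n, ")")
  if (substr(sequence, position, position) != "K")
    stop("residue at position ", position, " is '",
         substr(sequence, position, position), "', not the center lysine 'K'")
  lo <- position - half_width
  hi <- position + half_width
  pad_lo <- max(0L, 1L - lo)
  pad_hi <- max(0L, hi - n)
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep(substr(sequence, 1L, 1L), pad_lo),
         core,
         strrep(substr(sequence, n, n), pad_hi))
}

#' Enumerate the di-residue keys of a segment
#'
#' Lists the adjacent residue pairs of a `2L+1` segment at their signed window
#' positions, excluding the two pairs that contain the center lysine. Keys are
#' returned in ascending start-position order: positions
#' `-L, ..., -2, 1, ..., L-1`, giving `2 * (L - 1)` keys.
#'
#' @param segment Peptide segment string of odd length `2L+1`, or an integer
#'   half width `L` (in which case only positions are returned and `pair` is
#'   `NA`).
#' @return Data frame with columns `start_position` (integer) and `pair`
#'   (two-letter string).
#' @export
enumerate_diresidues <- function(segment) {
  if (is.numeric(segment)) {
    L <- as.integer(segment)
    stopifnot(L >= 1)
    pos <- diresidue_positions(L)
    return(data.frame(start_position = pos, pair = NA_character_,
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.character(segment), length(segment) == 1L)
  w <- nchar(segment)
  if (w %% 2L != 1L || w < 3L)
    stop("segment length must be odd and >= 3, got ", w)
  L <- (w - 1L) %/% 2L
  if (substr(segment, L + 1L, L + 1L) != "K")
    stop("segment center is not 'K': ", segment)
  pos <- diresidue_positions(L)
  idx <- pos + L + 1L  # 1-based index of the first residue of each pair
  data.frame(start_position = pos,
             pair = paste0(substring(segment, idx, idx),
                           substring(segment, idx + 1L, idx + 1L)),
             stringsAsFactors = FALSE)
}

# Signed start positions of the counted pairs: (-1,0) and (0,1) are excluded
# because they contain the fixed center lysine.
diresidue_positions <- function(L) {
  L <- as.integer(L)
  if (L == 1L) return(integer(0))
  c(seq.int(-L, -2L), seq.int(1L, L - 1L))
}

#' Construct a lysine-site dataset
#'
#' Bundles peptide segments, their provenance and their multi-label PTM
#' annotations into the container the rest of the package operates on.
#'
#' @param protein_id Character vector of accessions.
#' @param position Integer vector of 1-based lysine positions.
#' @param segment Character vector of `2L+1`-length windows with `'K'` at the
#'   center.
#' @param labels Either an `n x 4` matrix of `+1`/`-1` (columns in
#'   [PTM_TYPES] order) or a character vector of comma-separated type names
#'   (`""` meaning no label).
#' @param half_width Window half width `L` shared by all segments.
#' @return An object of class `lys_dataset`.
#' @export
lys_dataset <- function(protein_id, position, segment, labels, half_width) {
  half_width <- as.integer(half_width)
  segment <- normalize_residues(segment)
  n <- length(segment)
  stopifnot(length(protein_id) == n, length(position) == n)
  if (is.character(labels)) labels <- labels_to_matrix(labels)
  labels <- as.matrix(labels)
  if (n == 0L) labels <- matrix(integer(0), 0L, 4L)
  stopifnot(nrow(labels) == n, ncol(labels) == 4L)
  storage.mode(labels) <- "integer"
  if (n > 0L && !all(labels %in% c(-1L, 1L)))
    stop("labels must be coded +1/-1")
  colnames(labels) <- PTM_TYPES
  if (any(nchar(segment) != 2L * half_width + 1L))
    stop("all segments must have length 2*half_width + 1 = ",
         2L * half_width + 1L)
  centers <- substr(segment, half_width + 1L, half_width + 1L)
  if (any(centers != "K"))
    stop("segment(s) without 'K' at the center: record(s) ",
         paste(which(centers != "K"), collapse = ", "))
  dup <- duplicated(paste(protein_id, position, sep = "\r"))
  if (any(dup))
    stop("duplicate (protein_id, position) rows: ",
         paste(which(dup), collapse = ", "))
  structure(list(protein_id = as.character(protein_id),
                 position = as.integer(position),
                 segment = segment,
                 labels = labels,
                 half_width = half_width),
            class = "lys_dataset")
}

#' @export
print.lys_dataset <- function(x, ...) {
  cat("lys_dataset:", n_records(x), "lysine sites,",
      length(unique(x$protein_id)), "proteins, half_width L =",
      x$half_width, "\n")
  pos <- colSums(x$labels == 1L)
  cat("  +1 per type:", paste(sprintf("%s=%d", PTM_TYPES, pos),
                              collapse = ", "), "\n")
  cat("  unlabeled ('other'):", sum(rowSums(x$labels == 1L) == 0L), "\n")
  invisible(x)
}

#' Number of records in a dataset
#' @param data A `lys_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(data) length(data$segment)

#' Subset a dataset by record index
#' @param data A `lys_dataset`.
#' @param idx Integer or logical index vector.
#' @return A `lys_dataset` with the selected records, order preserved.
#' @export
subset_dataset <- function(data, idx) {
  lys_dataset(data$protein_id[idx], data$position[idx], data$segment[idx],
              data$labels[idx, , drop = FALSE], data$half_width)
}

#' Parse comma-separated label strings into a +1/-1 matrix
#'
#' @param labels Character vector; each element a comma-separated subset of
#'   [PTM_TYPES] (`""` = none).
#' @return Integer matrix with one `+1`/`-1` column per type.
#' @export
labels_to_matrix <- function(labels) {
  out <- matrix(-1L, length(labels), 4L, dimnames = list(NULL, PTM_TYPES))
  toks <- strsplit(trimws(labels), ",", fixed = TRUE)
  for (i in seq_along(toks)) {
    tk <- trimws(toks[[i]])
    tk <- tk[nzchar(tk)]
    if (length(tk) == 0L) next
    m <- match(tk, PTM_TYPES)
    if (anyNA(m))
      stop("unknown label token(s) in row ", i, ": ",
           paste(tk[is.na(m)], collapse = ", "))
    out[i, m] <- 1L
  }
  out
}

#' Collapse a +1/-1 label matrix into comma-separated strings
#' @param m Integer matrix of `+1`/`-1`, columns in [PTM_TYPES] order.
#' @return Character vector of comma-separated type names.
#' @export
matrix_to_labels <- function(m) {
  apply(m == 1L, 1L, function(r) paste(PTM_TYPES[r], collapse = ","))
}

#' Read a dataset from disk
#'
#' Two dialects are supported. `segments_tsv` is the canonical form: a
#' tab-separated table with header columns `protein_id`, `position`,
#' `segment` and `labels` (comma-separated type names, empty = unlabeled).
#' `fasta_plus_sites` reads protein sequences from a FASTA file plus a
#' tab-separated site table (`protein_id`, `position`, `labels`) and extracts
#' the segments itself via [extract_peptide_segment()].
#'
#' @param path Path to the segments TSV (or the site table for
#'   `fasta_plus_sites`).
#' @param format One of `"segments_tsv"` or `"fasta_plus_sites"`.
#' @param half_width Window half width `L`.
#' @param fasta Path to the FASTA file (required for `fasta_plus_sites`).
#' @return A [lys_dataset()], records in file order.
#' @export
load_dataset <- function(path, format = c("segments_tsv", "fasta_plus_sites"),
                         half_width = 13L, fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (format == "segments_tsv") {
    need <- c("protein_id", "position", "segment", "labels")
    if (!all(need %in% names(tab)))
      stop("segments_tsv requires columns: ", paste(need, collapse = ", "))
    return(lys_dataset(tab$protein_id, as.integer(tab$position),
                       tab$segment, tab$labels, half_width))
  }
  need <- c("protein_id", "position", "labels")
  if (!all(need %in% names(tab)))
    stop("site table requires columns: ", paste(need, collapse = ", "))
  if (is.null(fasta)) stop("fasta_plus_sites requires a `fasta` path")
  seqs <- read_fasta(fasta)
  miss <- setdiff(unique(tab$protein_id), names(seqs))
  if (length(miss) > 0L)
    stop("protein(s) in site table but not in FASTA: ",
         paste(miss, collapse = ", "))
  segs <- vapply(seq_len(nrow(tab)), function(i) {
    extract_peptide_segment(seqs[[tab$protein_id[i]]],
                            as.integer(tab$position[i]), half_width)
  }, character(1L))
  lys_dataset(tab$protein_id, as.integer(tab$position), segs, tab$labels,
              half_width)
}

#' Write a dataset in the canonical segments_tsv dialect
#' @param data A `lys_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  df <- data.frame(protein_id = data$protein_id,
                   position = data$position,
                   segment = data$segment,
                   labels = matrix_to_labels(data$labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# FASTA reading goes through Biostrings; sequences come back as plain,
# alphabet-normalized strings keyed by the first word of the header.
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  out <- normalize_residues(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1L), 1L)
  out
}

#' Load the 6394-segment benchmark training table
#'
#' Convenience loader for the published lysine PTM benchmark (6394 segments
#' from 1763 human proteins, window half width 13) after conversion to the
#' canonical segments_tsv dialect. The file itself is not distributed with
#' the package; this loader validates that a user-supplied conversion has the
#' expected shape and refuses anything that does not contain exactly 6394
#' records.
#'
#' @param path Path to the converted segments_tsv file.
#' @return A [lys_dataset()] with 6394 records at `half_width = 13`.
#' @export
load_qiu_dataset <- function(path) {
  data <- load_dataset(path, "segments_tsv", half_width = 13L)
  if (n_records(data) != 6394L)
    stop("expected the 6394-record benchmark table, got ",
         n_records(data), " records")
  data
}
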