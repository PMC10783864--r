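# Synthetic multi-label peptide datasets.
#
# Labels are drawn first (exchangeable Gaussian copula over the four types,
# so marginal prevalences are exact and `multilabel_rate` is the latent
# correlation controlling co-annotation); residues are then drawn from a
# background frequency table, and for every active label the designated
# (position, pair) motifs are placed with probability given by the
# background pair odds times the enrichment multiplier. This mirrors the
# feature model's assumption -- a location-fixed association between
# residue pairs and PTM types -- so parameter-recovery tests are
# meaningful.

# Swiss-Prot average residue frequencies (percent / 100).
SWISSPROT_FREQS <- c(A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545,
                     C = 0.0138, Q = 0.0393, E = 0.0675, G = 0.0707,
                     H = 0.0227, I = 0.0596, L = 0.0966, K = 0.0584,
                     M = 0.0242, F = 0.0386, P = 0.0470, S = 0.0656,
                     T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687)

#' Default synthetic background residue frequencies
#'
#' An eight-letter reduced background (the common residues A, L, E, G, S, V,
#' K, T at their Swiss-Prot proportions, renormalized). The reduced pair
#' diversity (~60 effective pairs per position) keeps the
#' carriers-per-di-residue-key ratio of a 1000-record synthetic dataset in
#' the same many-carrier regime as the 6394-record benchmark, so count-based
#' proportion estimates behave comparably.
#'
#' @return Named numeric vector of residue frequencies summing to 1.
#' @export
synth_background <- function() {
  f <- SWISSPROT_FREQS[c("A", "L", "E", "G", "S", "V", "K", "T")]
  f / sum(f)
}

#' Position-specific enrichment presets
#'
#' `"strong"` places, for each PTM type, up to four motif pairs at distinct
#' window positions with an odds multiplier of 1000 (placement probability
#' ~0.95 against the default background): a near-deterministic,
#' location-fixed motif per type. At `half_width >= 9` each type gets four
#' motif positions; narrower windows get as many as fit distinctly.
#' `"none"` returns an empty table (pure background, no signal).
#'
#' @param kind `"strong"` or `"none"`.
#' @param half_width Window half width `L >= 3` (positions are spread over
#'   the counted range `-L..-2, 1..L-1`).
#' @param multiplier Odds multiplier for `"strong"`.
#' @return Data frame with columns `type`, `position`, `pair`, `multiplier`.
#' @export
enrichment_preset <- function(kind = c("strong", "none"), half_width = 13L,
                              multiplier = 1000) {
  kind <- match.arg(kind)
  empty <- data.frame(type = character(0), position = integer(0),
                      pair = character(0), multiplier = numeric(0),
                      stringsAsFactors = FALSE)
  if (kind == "none") return(empty)
  L <- as.integer(half_width)
  allowed <- diresidue_positions(L)
  k <- min(4L, length(allowed) %/% 4L)   # motifs per type
  if (k < 1L) stop("the strong preset needs half_width >= 3")
  m <- 4L * k
  sel <- allowed[unique(round(seq(1L, length(allowed), length.out = m)))]
  if (length(sel) < m) sel <- allowed[seq_len(m)]
  pairs <- list(acetylation = c("LA", "AL", "LE", "EL"),
                crotonylation = c("LS", "SL", "LG", "GL"),
                methylation = c("AE", "EA", "AG", "GA"),
                succinylation = c("AS", "SA", "LL", "AA"))
  do.call(rbind, lapply(1:4, function(v) {
    data.frame(type = PTM_TYPES[v], position = sel[seq(v, m, by = 4L)],
               pair = pairs[[v]][seq_len(k)], multiplier = multiplier,
               stringsAsFactors = FALSE)
  }))
}

#' Specification of a synthetic multi-label peptide dataset
#'
#' Defaults emulate the class structure of the published lysine PTM
#' benchmark at about 1000 sites: acetylation the most prevalent type,
#' succinylation second, crotonylation and methylation rare, roughly a third
#' of sites unlabeled ("other"), with occasional co-annotation and a strong
#' location-fixed motif per type.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param sites_per_protein Integer range `c(lo, hi)`; per-protein site
#'   counts are drawn uniformly from it.
#' @param half_width Window half width `L`.
#' @param label_prevalences Marginal probability of each type, in
#'   [PTM_TYPES] order.
#' @param multilabel_rate Latent (copula) correlation between the four
#'   per-type indicators; 0 = independent, larger = more co-annotation.
#' @param enrichment Data frame as returned by [enrichment_preset()].
#' @param background Named residue frequency vector.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return List of class `lys_synth_spec`.
#' @export
synth_spec <- function(n_proteins = 100L, sites_per_protein = c(6L, 14L),
                       half_width = 13L,
                       label_prevalences = c(acetylation = 0.45,
                                             crotonylation = 0.10,
                                             methylation = 0.08,
                                             succinylation = 0.30),
                       multilabel_rate = 0.15,
                       enrichment = enrichment_preset("strong", half_width),
                       background = synth_background(),
                       seed = 1L) {
  stopifnot(n_proteins >= 1L, length(sites_per_protein) == 2L,
            sites_per_protein[1] >= 1L,
            sites_per_protein[2] >= sites_per_protein[1],
            half_width >= 2L,
            length(label_prevalences) == 4L,
            all(label_prevalences > 0), all(label_prevalences < 1),
            multilabel_rate >= 0, multilabel_rate < 1,
            abs(sum(background) - 1) < 1e-8)
  allowed <- diresidue_positions(as.integer(half_width))
  if (nrow(enrichment) > 0L) {
    bad <- !enrichment$position %in% allowed
    if (any(bad))
      stop("enrichment at excluded position(s): ",
           paste(unique(enrichment$position[bad]), collapse = ", "))
    if (any(nchar(enrichment$pair) != 2L))
      stop("enrichment pairs must be two-letter strings")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 sites_per_protein = as.integer(sites_per_protein),
                 half_width = as.integer(half_width),
                 label_prevalences = stats::setNames(label_prevalences,
                                                     PTM_TYPES),
                 multilabel_rate = multilabel_rate,
                 enrichment = enrichment,
                 background = background,
                 seed = as.integer(seed)),
            class = "lys_synth_spec")
}

#' Generate a synthetic dataset from a specification
#'
#' @param spec A [synth_spec()].
#' @return A [lys_dataset()]; record `k` of protein `p` sits at position
#'   `(k-1)*(2L+1) + L + 1` of the synthetic protein built by
#'   [synth_sequences()], so FASTA round trips reproduce the segments
#'   exactly.
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "lys_synth_spec"))
  set.seed(spec$seed)
  L <- spec$half_width
  width <- 2L * L + 1L
  site_range <- seq.int(spec$sites_per_protein[1], spec$sites_per_protein[2])
  sites <- site_range[sample.int(length(site_range), spec$n_proteins,
                                 replace = TRUE)]
  n <- sum(sites)
  protein_id <- rep(sprintf("SYNP%04d", seq_len(spec$n_proteins)), sites)
  site_idx <- unlist(lapply(sites, seq_len))
  position <- (site_idx - 1L) * width + L + 1L

  # labels: exchangeable Gaussian copula with exact marginals
  r <- spec$multilabel_rate
  z0 <- stats::rnorm(n)
  z <- sqrt(r) * z0 + sqrt(1 - r) * matrix(stats::rnorm(n * 4L), n, 4L)
  labels <- ifelse(z < matrix(stats::qnorm(spec$label_prevalences), n, 4L,
                              byrow = TRUE), 1L, -1L)
  storage.mode(labels) <- "integer"
  colnames(labels) <- PTM_TYPES

  # residues: background draw, center fixed at K, then motif placement
  aa <- names(spec$background)
  res <- matrix(sample(aa, n * width, replace = TRUE,
                       prob = spec$background), n, width)
  res[, L + 1L] <- "K"
  enr <- spec$enrichment
  if (nrow(enr) > 0L) {
    for (e in seq_len(nrow(enr))) {
      v <- match(enr$type[e], PTM_TYPES)
      a <- substr(enr$pair[e], 1L, 1L)
      b <- substr(enr$pair[e], 2L, 2L)
      q <- f_or_zero(spec$background, a) * f_or_zero(spec$background, b)
      q2 <- enr$multiplier[e] * q / (1 - q + enr$multiplier[e] * q)
      active <- which(labels[, v] == 1L)
      place <- active[stats::runif(length(active)) < q2]
      col <- enr$position[e] + L + 1L
      res[place, col] <- a
      res[place, col + 1L] <- b
    }
  }
  segments <- apply(res, 1L, paste, collapse = "")
  lys_dataset(protein_id, position, segments, labels, L)
}

f_or_zero <- function(freqs, letter) {
  if (letter %in% names(freqs)) unname(freqs[letter]) else 0
}

#' Assemble synthetic protein sequences from a generated dataset
#'
#' Concatenates each protein's segments in site order; extraction at the
#' recorded positions then returns exactly the generated segments.
#'
#' @param data A [lys_dataset()] from [generate_synthetic_dataset()].
#' @return Named character vector of protein sequences.
#' @export
synth_sequences <- function(data) {
  vapply(split(data$segment, data$protein_id)[unique(data$protein_id)],
         paste, character(1L), collapse = "")
}

#' Published evaluation pairs for the 20 test sites of protein Q16778
#'
#' The experimental and predicted label sets for the 20 lysine sites of
#' histone H2B type 1-K (UniProt Q16778) used as an independent test of the
#' model, transcribed from the published comparison table. Sites 6-86 were
#' predicted exactly; the remaining four sites carry partial or wrong
#' predictions.
#'
#' @return List with `site` (integer vector of the 20 lysine positions),
#'   `observed` and `predicted` (20 x 4 integer matrices of `+1`/`-1` in
#'   [PTM_TYPES] order).
#' @export
table6_fixture <- function() {
  site <- c(6L, 12L, 13L, 16L, 17L, 21L, 24L, 25L, 28L, 29L, 31L, 35L,
            44L, 47L, 58L, 86L, 109L, 117L, 121L, 126L)
  ac <- "acetylation,crotonylation"
  observed <- c(ac, ac, ac, ac, ac, ac, ac, "", "", "", "",
                "crotonylation", "", "methylation", "methylation",
                "acetylation,methylation", "methylation", "",
                ac, "")
  predicted <- c(ac, ac, ac, ac, ac, ac, ac, "", "", "", "",
                 "crotonylation", "", "methylation", "methylation",
                 "acetylation,methylation", "", "acetylation",
                 "acetylation,succinylation", "succinylation")
  list(site = site,
       observed = labels_to_matrix(observed),
       predicted = labels_to_matrix(predicted))
}
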