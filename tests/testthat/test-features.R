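test_that("count table counts segments per key, overall and per type", {
  d <- lys_dataset(c("p1", "p2"), c(10L, 20L), c("AGKCD", "AGKCE"),
                   c("acetylation", ""), 2L)
  tab <- fit_count_table(d)
  i <- match("-2:AG", tab$keys)
  expect_identical(tab$total[i], 2L)
  expect_identical(unname(tab$per_type[i, ]), c(1L, 0L, 0L, 0L))
  expect_identical(tab$total[match("1:CD", tab$keys)], 1L)
  expect_identical(tab$n_train, 2L)
  # conservation: per-type counts never exceed totals
  expect_true(all(tab$per_type <= tab$total))
  expect_true(all(tab$total <= tab$n_train))
  expect_error(fit_count_table(subset_dataset(d, integer(0))), "empty")
})

test_that("an all-identical unlabeled training set counts only totals", {
  d <- lys_dataset(sprintf("p%d", 1:6), 1:6 * 10L, rep("AGKCD", 6),
                   rep("", 6), 2L)
  tab <- fit_count_table(d)
  expect_true(all(tab$total == 6L))
  expect_true(all(tab$per_type == 0L))
})

test_that("di-residue encoding reproduces the worked proportion example", {
  # 500 training segments all carrying KA at (-2,-1); type counts 50/10/400
  n <- 500
  labels <- c(rep("acetylation", 50), rep("crotonylation", 10),
              rep("methylation", 400), rep("", 40))
  set.seed(11)
  tails <- replicate(n, paste(sample(c("A", "L", "G", "S"), 2,
                                     replace = TRUE), collapse = ""))
  d <- lys_dataset(sprintf("p%03d", 1:n), seq_len(n) + 5L,
                   paste0("KAK", tails), labels, 2L)
  tab <- fit_count_table(d)
  expect_equal(unname(encode_diresidue(tab, -2L, "KA")),
               c(0.1, 0.02, 0.8, 0))
})

test_that("unseen keys encode as the zero vector", {
  d <- lys_dataset("p1", 3L, "AGKCD", "acetylation", 2L)
  tab <- fit_count_table(d)
  expect_identical(unname(encode_diresidue(tab, -2L, "WW")), rep(0, 4))
  expect_identical(unname(encode_diresidue(tab, 1L, "AG")), rep(0, 4))
})

test_that("a key seen only in one type's segments encodes as a unit slot", {
  d <- lys_dataset(sprintf("p%d", 1:7), 1:7 * 3L, rep("LWKAA", 7),
                   rep("methylation", 7), 2L)
  tab <- fit_count_table(d)
  expect_identical(unname(encode_diresidue(tab, -2L, "LW")), c(0, 0, 1, 0))
})

test_that("segment encoding has the documented dimensionality and layout", {
  set.seed(5)
  d13 <- random_dataset(10, 13)
  tab13 <- fit_count_table(d13)
  expect_length(encode_segment(tab13, d13$segment[1]), 96L)

  d24 <- random_dataset(10, 24)
  tab24 <- fit_count_table(d24)
  expect_length(encode_segment(tab24, d24$segment[1]), 184L)

  expect_error(encode_segment(tab13, d24$segment[1]), "half width")

  # toy set sharing exactly one key with a test segment: only that block
  # is nonzero and equals the key's encoding
  tr <- lys_dataset(c("a", "b"), c(3L, 4L), c("AGKCD", "AGKCC"),
                    c("acetylation", "succinylation"), 2L)
  tab <- fit_count_table(tr)
  q <- "AGKWW"                            # shares only AG at (-2,-1)
  f <- encode_segment(tab, q)
  expect_equal(f[1:4], unname(encode_diresidue(tab, -2L, "AG")))
  expect_equal(f[5:8], rep(0, 4))
})

test_that("dataset encoding preserves record order and row identity", {
  set.seed(8)
  d <- random_dataset(15, 4)
  tab <- fit_count_table(d)
  M <- encode_dataset(tab, d)
  expect_identical(dim(M), c(15L, 8L * 3L))
  expect_equal(M[3, ], encode_segment(tab, d$segment[3]),
               ignore_attr = TRUE)
  perm <- sample(15)
  expect_equal(encode_dataset(tab, subset_dataset(d, perm)), M[perm, ],
               ignore_attr = TRUE)
})

test_that("fitted counts and encodings agree with the naive oracle", {
  set.seed(21)
  for (L in c(3L, 6L)) {
    d <- random_dataset(50, L)
    tab <- fit_count_table(d)
    counts <- oracle_count_table(d)
    expect_setequal(tab$keys, names(counts))
    for (id in names(counts)) {
      i <- match(id, tab$keys)
      expect_identical(tab$total[i], counts[[id]][1])
      expect_identical(unname(tab$per_type[i, ]), counts[[id]][2:5])
    }
    # encoding the training set itself: numerators count each record too
    M <- encode_dataset(tab, d)
    for (k in c(1L, 25L, 50L)) {
      expect_equal(unname(M[k, ]), oracle_encode_segment(counts,
                                                         d$segment[k]),
                   tolerance = 1e-12)
    }
  }
})

test_that("all emitted features lie in [0, 1]", {
  set.seed(31)
  d <- random_dataset(40, 5)
  tab <- fit_count_table(d)
  M <- encode_dataset(tab, random_dataset(40, 5))
  expect_true(all(M >= 0 & M <= 1))
})

test_that("relabeling a segment to a type only moves that type's rho upward", {
  set.seed(41)
  d <- random_dataset(30, 4)
  k <- which(rowSums(d$labels == 1L) == 0L)[1]   # an unlabeled record
  d2 <- d
  d2$labels[k, 1] <- 1L                          # now acetylation
  probe <- random_segments(20, 4)
  M1 <- encode_dataset(fit_count_table(d), probe)
  M2 <- encode_dataset(fit_count_table(d2), probe)
  acet_cols <- seq(1, ncol(M1), by = 4)
  expect_true(all(M2[, acet_cols] >= M1[, acet_cols]))
  expect_equal(M2[, -acet_cols], M1[, -acet_cols], ignore_attr = TRUE)
})

test_that("held-out records are invisible to a table fitted without them", {
  set.seed(51)
  d <- random_dataset(20, 4)
  tab_without <- fit_count_table(subset_dataset(d, 1:19))
  tab_with <- fit_count_table(d)
  expect_false(identical(tab_without$total, tab_with$total) &&
                 identical(tab_without$keys, tab_with$keys))
  expect_identical(sum(tab_with$total) - sum(tab_without$total),
                   2L * (d$half_width - 1L))
})

test_that("count tables survive a JSON round trip", {
  set.seed(61)
  d <- random_dataset(25, 5)
  tab <- fit_count_table(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_count_table(tab, path)
  tab2 <- read_count_table(path)
  expect_identical(tab2, tab)
})
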