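test_that("masked squared distance isolates one label's feature slots", {
  # two blocks (L = 2): slot 1 of block 0 differs by 1, everything else 0
  x <- c(1, 0, 0, 0, 0, 0, 0, 0)
  y <- rep(0, 8)
  expect_identical(masked_sq_distance(x, y, 1), 1)
  expect_identical(masked_sq_distance(x, y, 2), 0)
  expect_identical(masked_sq_distance(x, x, 3), 0)
  expect_error(masked_sq_distance(x, y[1:4], 1), "different lengths")
  expect_error(masked_sq_distance(x, y, 5), "1..4")
})

test_that("masked distances over the four labels partition the full distance", {
  set.seed(71)
  for (rep in 1:100) {
    d <- 8 * (sample(2:13, 1) - 1)
    x <- runif(d)
    y <- runif(d)
    total <- sum(vapply(1:4, function(v) masked_sq_distance(x, y, v),
                        numeric(1)))
    expect_equal(total, sum((x - y)^2), tolerance = 1e-12)
  }
})

test_that("a single-record model reproduces its own labels exactly", {
  d <- lys_dataset("p1", 6L, "AGKCD", "acetylation", 2L)
  model <- fit_model(d, theta = 1 / 6)
  pred <- predict(model, d)
  expect_identical(unname(pred$scores[1, ]), c(1, -1, -1, -1))
  expect_identical(unname(pred$labels[1, ]), c(1L, -1L, -1L, -1L))
})

test_that("scores follow the kernel ratio on hand-computable configurations", {
  # two training records equidistant from the query, labels +1 and -1
  feats <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0),
                 c(0, 0, 0, 0, 1, 0, 0, 0))
  labels <- rbind(c(1L, 1L, -1L, -1L), c(-1L, 1L, -1L, -1L))
  model <- structure(list(theta = 1 / 6, engine = "gkpr", half_width = 2L,
                          table = NULL, train_features = feats,
                          train_labels = labels),
                     class = "lys_model")
  s <- score_labels(model, rep(0, 8))
  expect_equal(unname(s[1, 1]), 0)               # symmetry cancels label 1
  expect_equal(unname(s[1, 2]), 1)               # unanimous label 2

  # masked distances 0 and 1, labels +1/-1, theta = 1/6
  feats2 <- rbind(rep(0, 8), c(1, 0, 0, 0, 0, 0, 0, 0))
  labels2 <- rbind(c(1L, -1L, -1L, -1L), c(-1L, -1L, -1L, -1L))
  model2 <- structure(list(theta = 1 / 6, engine = "gkpr", half_width = 2L,
                           table = NULL, train_features = feats2,
                           train_labels = labels2),
                      class = "lys_model")
  s2 <- score_labels(model2, rep(0, 8))
  expect_equal(unname(s2[1, 1]), (1 - exp(-18)) / (1 + exp(-18)),
               tolerance = 1e-15)
})

test_that("score thresholding keeps ties on the positive side", {
  expect_identical(unname(predict_labels(c(0.2, -0.3, 0.0, -1.0))[1, ]),
                   c(1L, -1L, 1L, -1L))
  expect_identical(unname(predict_labels(c(1, 1, 1, 1))[1, ]),
                   rep(1L, 4))
})

test_that("both engines match the naive double-loop oracle", {
  set.seed(81)
  for (engine in c("gkpr", "gkr")) {
    for (theta in c(1 / 2, 1 / 6)) {
      train <- random_dataset(50, 3)
      model <- fit_model(train, theta = theta, engine = engine)
      queries <- encode_dataset(model$table, random_segments(20, 3))
      s <- score_labels(model, queries)
      for (k in seq_len(20)) {
        expect_equal(unname(s[k, ]),
                     oracle_scores(model$train_features,
                                   model$train_labels, queries[k, ],
                                   theta, engine),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("scores stay inside [-1, 1] even for distant queries", {
  set.seed(91)
  train <- random_dataset(40, 13)
  model <- fit_model(train, theta = 1 / 6)
  # far query: all-ones features (underflow territory without stabilization)
  s <- score_labels(model, rep(1, 96))
  expect_true(all(is.finite(s)) && all(abs(s) <= 1))
  s2 <- score_labels(model, encode_dataset(model$table,
                                           random_segments(10, 13)))
  expect_true(all(is.finite(s2)) && all(abs(s2) <= 1))
})

test_that("gkpr and gkr coincide when off-slot blocks agree", {
  # training and query differ only in slot-1 coordinates: full distance
  # equals the slot-1 masked distance, so scores for label 1 coincide
  feats <- matrix(0.5, 6, 8)
  set.seed(101)
  feats[, c(1, 5)] <- runif(12)
  labels <- matrix(sample(c(-1L, 1L), 24, replace = TRUE), 6, 4)
  q <- rep(0.5, 8)
  q[c(1, 5)] <- runif(2)
  base <- list(theta = 1 / 4, half_width = 2L, table = NULL,
               train_features = feats, train_labels = labels)
  m_gkpr <- structure(c(base, engine = "gkpr"), class = "lys_model")
  m_gkr <- structure(c(base, engine = "gkr"), class = "lys_model")
  expect_equal(score_labels(m_gkpr, q)[1, 1],
               score_labels(m_gkr, q)[1, 1], tolerance = 1e-12)
})

test_that("duplicating a positive training record never lowers its label score", {
  set.seed(111)
  train <- random_dataset(30, 4)
  v <- 2L
  pos_idx <- which(train$labels[, v] == 1L)[1]
  m1 <- fit_model(train, theta = 1 / 4)
  queries <- encode_dataset(m1$table, random_segments(15, 4))
  s1 <- score_labels(m1, queries)[, v]
  # same encoder, heavier positive record
  m2 <- m1
  m2$train_features <- rbind(m1$train_features,
                             m1$train_features[pos_idx, ])
  m2$train_labels <- rbind(m1$train_labels, m1$train_labels[pos_idx, ])
  s2 <- score_labels(m2, queries)[, v]
  expect_true(all(s2 >= s1 - 1e-12))
})

test_that("models survive a JSON round trip with identical predictions", {
  set.seed(121)
  train <- random_dataset(25, 4)
  model <- fit_model(train, theta = 1 / 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  model2 <- read_model(path)
  queries <- random_segments(10, 4)
  expect_identical(predict(model2, queries), predict(model, queries))
})

test_that("model fitting is deterministic and validates inputs", {
  set.seed(131)
  train <- random_dataset(20, 3)
  m1 <- fit_model(train)
  m2 <- fit_model(train)
  expect_identical(m1, m2)
  expect_error(fit_model(subset_dataset(train, integer(0))), "empty")
  expect_error(fit_model(train, theta = -1))
})
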