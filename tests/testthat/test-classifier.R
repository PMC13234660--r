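test_that("cosine similarity matches closed forms and the scalar-loop oracle", {
  x <- runif(10, 1, 5)
  expect_equal(cosine_similarity(x, x), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))  # cos 45 deg

  set.seed(71)
  for (i in 1:30) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(length(a))
    s <- cosine_similarity(a, b)
    expect_equal(s, oracle_cosine(a, b), tolerance = 1e-12)
    expect_gte(s, -1 - 1e-12)
    expect_lte(s, 1 + 1e-12)
    # symmetry and positive-scale invariance
    expect_equal(s, cosine_similarity(b, a))
    expect_equal(s, cosine_similarity(3.7 * a, b), tolerance = 1e-12)
  }
})

test_that("degenerate cosine inputs are rejected", {
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "nonzero")
  expect_error(cosine_similarity(c(1, 1), c(0, 0)), "nonzero")
  expect_error(cosine_similarity(1:3, 1:4), "length mismatch")
})

test_that("centroids are element-wise means of each label's vectors", {
  # n = 1: centroid equals the vector
  tr1 <- feature_table(list(c(1, 2, 3)), "A-17")
  m1 <- fit_centroids(tr1)
  expect_equal(unname(m1$centroids["A-17", ]), c(1, 2, 3))

  # two-point mean
  tr2 <- feature_table(list(c(0, 0, 0), c(2, 4, 6)), c("B-20", "B-20"))
  expect_equal(unname(fit_centroids(tr2)$centroids["B-20", ]), c(1, 2, 3))

  # 5 random vectors per label vs the column-loop oracle
  set.seed(81)
  labels <- c("C-17", "A-24", "BC-27")
  vecs <- list(); labs <- character(0)
  for (lab in labels) {
    for (i in 1:5) {
      vecs <- c(vecs, list(runif(12, 0, 255)))
      labs <- c(labs, lab)
    }
  }
  model <- fit_centroids(feature_table(vecs, labs))
  for (lab in labels) {
    expect_equal(unname(model$centroids[lab, ]),
                 oracle_centroid(vecs[labs == lab]), tolerance = 1e-12)
  }
  # canonical row order
  expect_equal(rownames(model$centroids), c("C-17", "A-24", "BC-27"))

  expect_error(fit_centroids(feature_table(list(), character(0))), "empty")
  expect_error(fit_centroids(feature_table(list(1:3, 1:4), c("A-17", "A-20"))),
               "inconsistent feature lengths")
})

test_that("classification is argmax over centroid similarities with first-label ties", {
  set.seed(91)
  labels <- enumerate_categories()
  vecs <- lapply(seq_along(labels), function(i) runif(30, 0, 255))
  model <- fit_centroids(feature_table(vecs, labels))

  # a test vector equal to a centroid recovers its category
  res <- classify(model$centroids["A-27", ], model)
  expect_equal(res$label, "A-27")
  expect_equal(unname(res$similarity[["A-27"]]), 1.0, tolerance = 1e-12)

  # centroid + tiny perturbation still recovers it (exhaustive-argmax oracle)
  for (k in sample(seq_along(labels), 5)) {
    lab <- labels[[k]]
    v <- model$centroids[lab, ] + rnorm(30, sd = 1e-4)
    sims <- vapply(labels, function(l) oracle_cosine(v, model$centroids[l, ]), 0)
    expect_equal(classify(v, model)$label, labels[[which.max(sims)]])
    expect_equal(classify(v, model)$label, lab)
  }

  # single-category model classifies anything into that category
  m1 <- fit_centroids(feature_table(list(c(5, 5, 5)), "He-17"))
  expect_equal(classify(c(200, 1, 30), m1)$label, "He-17")

  # exact tie breaks to the first label in canonical order
  tied <- fit_centroids(feature_table(list(c(1, 0), c(0, 1)), c("C-17", "B-17")))
  expect_equal(classify(c(1, 1), tied)$label, "C-17")  # C before B? no: column order
  # canonical analyte order is C, B, ... so C-17 is first
  expect_equal(rownames(tied$centroids), c("C-17", "B-17"))
})

test_that("classification is invariant under a fixed permutation of all vectors", {
  set.seed(101)
  labels <- enumerate_categories()[1:8]
  vecs <- lapply(seq_along(labels), function(i) runif(24, 0, 255))
  tests <- lapply(vecs, function(v) pmin(pmax(v + rnorm(24, sd = 2), 0), 255))
  perm <- sample(24)

  model <- fit_centroids(feature_table(vecs, labels))
  model_p <- fit_centroids(feature_table(lapply(vecs, `[`, perm), labels))
  for (i in seq_along(tests)) {
    expect_equal(classify(tests[[i]], model)$label,
                 classify(tests[[i]][perm], model_p)$label)
  }
})

test_that("display normalization maps the run minimum to 0 and fixes 1", {
  S <- matrix(c(0.99, 0.95), nrow = 1)
  expect_equal(as.vector(normalize_similarities(S)), c(0.8, 0.0))

  S2 <- matrix(c(1.0, 0.95, 0.97, 0.96), nrow = 2)
  N <- normalize_similarities(S2)
  expect_equal(N[which(S2 == min(S2))], 0)
  expect_equal(N[which(S2 == 1)], 1)          # 1 is a fixed point
  expect_true(all(N >= 0 & N <= 1))
  # affine and order-preserving: ranks unchanged
  expect_equal(order(as.vector(S2)), order(as.vector(N)))

  expect_error(normalize_similarities(matrix(1, 2, 2)), "degenerate")
})

test_that("evaluate reports accuracy, misclassifications, and matrices", {
  set.seed(111)
  labels <- enumerate_categories()
  vecs <- lapply(seq_along(labels), function(i) runif(60, 0, 255))
  model <- fit_centroids(feature_table(vecs, labels))

  # self-classification of the centroids is perfect
  self <- feature_table(vecs, labels, ids = paste0(labels, "_t"))
  ev <- evaluate(self, model)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$accuracy_pct, 100)
  expect_equal(nrow(ev$misclassified), 0L)
  expect_equal(dim(ev$similarity), c(24L, 24L))
  expect_equal(rownames(ev$similarity), self$source_id)

  # 23 of 24 correct reports as 95.8% (one-decimal rounding)
  corrupted <- self
  corrupted$feature[[1]] <- vecs[[2]]  # forces one misclassification
  ev2 <- evaluate(corrupted, model)
  expect_equal(sum(ev2$predictions$correct), 23L)
  expect_equal(ev2$accuracy_pct, 95.8)
  expect_equal(ev2$misclassified$label, corrupted$label[[1]])

  # glance/tidy surface the same numbers
  g <- glance(ev2)
  expect_equal(g$n_correct, 23L)
  expect_equal(g$accuracy, 23 / 24)
  expect_equal(nrow(tidy(ev2)), 24L)
})

test_that("test labels absent from the model are classified and flagged", {
  model <- fit_centroids(feature_table(list(c(1, 2, 3), c(3, 2, 1)),
                                       c("C-17", "B-17")))
  unseen <- feature_table(list(c(1, 2, 3.1)), "A-24")
  ev <- evaluate(unseen, model)
  expect_false(ev$predictions$label_in_model[[1]])
  expect_true(ev$predictions$predicted[[1]] %in% c("C-17", "B-17"))
  expect_equal(ev$accuracy, 0)
})

test_that("per-category similarity statistics match hand-computed cases", {
  # all images identical to their centroid: mean = max = 1, diff = 0
  v <- c(10, 20, 30)
  model <- fit_centroids(feature_table(list(v, v), c("A-17", "A-17")))
  st <- category_similarity_stats(feature_table(list(v, v), c("A-17", "A-17")), model)
  expect_equal(st$mean, 1)
  expect_equal(st$max, 1)
  expect_equal(st$diff, 0)

  # two images with similarities 0.90 and 1.00 to their centroid
  cent <- c(1, 0)
  m2 <- structure(list(centroids = matrix(cent, 1, dimnames = list("B-20", NULL)),
                       counts = c("B-20" = 2L), grid = NA, region = NA),
                  class = "voc_model")
  ang <- acos(0.90)
  imgs <- feature_table(list(c(cos(ang), sin(ang)), c(1, 0)), c("B-20", "B-20"))
  st2 <- category_similarity_stats(imgs, m2)
  expect_equal(st2$mean, 0.95, tolerance = 1e-12)
  expect_equal(st2$max, 1.00, tolerance = 1e-12)
  expect_equal(st2$diff, 0.05, tolerance = 1e-12)

  expect_error(category_similarity_stats(feature_table(list(v), "C-24"), model),
               "absent from model")
})

test_that("duplicating a vector's features preserves its classification", {
  set.seed(121)
  labels <- enumerate_categories()[1:6]
  vecs <- lapply(seq_along(labels), function(i) runif(18, 0, 255))
  model <- fit_centroids(feature_table(vecs, labels))
  model_dup <- fit_centroids(feature_table(lapply(vecs, rep, times = 2), labels))
  for (i in 1:10) {
    v <- runif(18, 0, 255)
    expect_equal(classify(c(v, v), model_dup)$label, classify(v, model)$label)
  }
})

test_that("models round-trip through JSON", {
  set.seed(131)
  labels <- c("C-17", "B-24", "He-27")
  model <- fit_centroids(feature_table(lapply(1:3, function(i) runif(6, 0, 255)),
                                       labels))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$centroids, model$centroids, tolerance = 1e-12)
  expect_equal(rownames(back$centroids), rownames(model$centroids))
  expect_equal(unname(back$counts), unname(model$counts))
})
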