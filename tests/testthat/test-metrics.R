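test_that("FOSCTTM: identical embeddings, worst case, brute-force oracle", {
  Z <- runif_sphere(20, 5, seed = 1)
  expect_equal(foscttm(Z, Z), 0)

  # two points whose true matches are swapped: every non-self cell is closer
  A <- rbind(c(0, 0), c(1, 0))
  B <- rbind(c(1, 0), c(0, 0))
  expect_equal(foscttm(A, B), 1)

  A4 <- runif_sphere(4, 2, seed = 2); B4 <- runif_sphere(4, 2, seed = 3)
  expect_equal(foscttm(A4, B4), oracle_foscttm(A4, B4), tolerance = 1e-12)
  A30 <- runif_sphere(30, 6, seed = 4); B30 <- runif_sphere(30, 6, seed = 5)
  expect_equal(foscttm(A30, B30), oracle_foscttm(A30, B30), tolerance = 1e-12)
  expect_error(foscttm(A4, B30), class = "spherepair_shape_error")
})

test_that("FOSCTTM is invariant under a common rotation", {
  A <- runif_sphere(25, 5, seed = 6); B <- runif_sphere(25, 5, seed = 7)
  base <- foscttm(A, B)
  set.seed(8)
  for (r in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
    expect_equal(foscttm(A %*% R, B %*% R), base, tolerance = 1e-12)
  }
})

test_that("graph iLISI: single label, perfect mixing, scalar oracle, bounds", {
  Z <- runif_sphere(10, 4, seed = 9)
  expect_warning(v <- graph_ilisi(Z, rep("x", 10)), "single label")
  expect_equal(v, 1)

  # all cells at the same point with alternating labels: near-perfect mixing
  Zsame <- matrix(1, 12, 3) / sqrt(3)
  lab <- rep(c("a", "b"), 6)
  expect_gt(graph_ilisi(Zsame, lab, k = 11), 1.9)

  # 12-cell toy against a by-hand Simpson computation
  Z12 <- runif_sphere(12, 3, seed = 10)
  lab12 <- rep(c("a", "b", "c"), 4)
  k <- 5
  D <- as.matrix(dist(Z12))
  diag(D) <- Inf
  manual <- mean(vapply(1:12, function(i) {
    nn <- order(D[i, ])[1:k]
    oracle_simpson_inv(lab12[nn])
  }, numeric(1)))
  expect_equal(graph_ilisi(Z12, lab12, k = k), manual, tolerance = 1e-12)

  set.seed(11)
  for (r in 1:20) {
    n <- sample(10:40, 1); L <- sample(2:4, 1)
    v <- graph_ilisi(runif_sphere(n, 3), sample(letters[1:L], n, replace = TRUE),
                     k = sample(2:(n - 1), 1))
    expect_gte(v, 1); expect_lte(v, L + 1e-12)
  }
})

test_that("kNN accuracy: default grid, self-exclusion, oracle, relabeling invariance", {
  expect_equal(eval(formals(knn_accuracy)$k_list), c(5, 17, 29, 41, 53, 65))

  Z <- runif_sphere(20, 4, seed = 12)
  lab <- sample(c("a", "b"), 20, replace = TRUE)
  acc <- knn_accuracy(Z, lab, Z, lab, k_list = 1, exclude_self = TRUE)
  # distinct points: the nearest non-self neighbor decides; sanity range only
  expect_true(acc >= 0 && acc <= 1)
  acc_self <- knn_accuracy(Z, lab, Z, lab, k_list = 1, exclude_self = FALSE)
  expect_equal(unname(acc_self), 1) # each point is its own nearest neighbor

  set.seed(13)
  Ztr <- runif_sphere(30, 5); ltr <- sample(c("u", "v", "w"), 30, replace = TRUE)
  Zte <- runif_sphere(12, 5); lte <- sample(c("u", "v", "w"), 12, replace = TRUE)
  for (k in c(1, 3, 7)) {
    expect_equal(unname(knn_accuracy(Ztr, ltr, Zte, lte, k_list = k)),
                 oracle_knn(Ztr, ltr, Zte, lte, k), tolerance = 1e-12)
  }
  # renaming classes consistently leaves accuracy unchanged
  map <- c(u = "z3", v = "z1", w = "z2")
  expect_equal(unname(knn_accuracy(Ztr, map[ltr], Zte, map[lte], k_list = 5)),
               unname(knn_accuracy(Ztr, ltr, Zte, lte, k_list = 5)))
  expect_error(knn_accuracy(Ztr, ltr, Zte[0, , drop = FALSE], character(0), 3),
               class = "spherepair_value_error")
  expect_error(knn_accuracy(Ztr, ltr, Zte, lte, k_list = 31),
               class = "spherepair_value_error")
})

test_that("cross-batch and cross-validation drivers produce sane tables", {
  set.seed(14)
  Z <- runif_sphere(60, 5)
  lab <- sample(c("a", "b"), 60, replace = TRUE)
  batch <- rep(c("s1", "s2", "s3"), each = 20)
  cb <- knn_cross_batch(Z, lab, batch, k_list = c(3, 5))
  expect_equal(nrow(cb), 6)
  expect_true(all(cb$accuracy >= 0 & cb$accuracy <= 1))
  cv <- knn_cv(Z, lab, k_list = 3, folds = 5, seed = 1)
  expect_equal(nrow(cv), 5)
  expect_identical(cv, knn_cv(Z, lab, k_list = 3, folds = 5, seed = 1))
})

test_that("Tri-SIM: identical, orthogonal, scalar oracle", {
  v <- runif_sphere(1, 5, seed = 15)[1, ]
  expect_equal(trisim(v, v, v), 3)
  expect_equal(trisim(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 0)
  z1 <- runif_sphere(1, 4, seed = 16)[1, ]; z2 <- runif_sphere(1, 4, seed = 17)[1, ]
  z3 <- runif_sphere(1, 4, seed = 18)[1, ]
  expect_equal(trisim(z1, z2, z3), sum(z1 * z2) + sum(z1 * z3) + sum(z2 * z3),
               tolerance = 1e-12)
  # matrix form is row-wise
  M1 <- runif_sphere(5, 4, seed = 19); M2 <- runif_sphere(5, 4, seed = 20)
  M3 <- runif_sphere(5, 4, seed = 21)
  expect_equal(trisim(M1, M2, M3)[2], trisim(M1[2, ], M2[2, ], M3[2, ]), tolerance = 1e-12)
})

test_that("Tri-SIM percentile: separated identity, unique maximum, subsample equivalence", {
  Z <- diag(6)
  expect_equal(trisim_percentile(Z, Z, Z), rep(100, 6))
  # full-coverage subsample equals the exhaustive answer
  ex <- trisim_percentile(Z, Z, Z)
  sub <- trisim_percentile(Z, Z, Z, subsample = 100, seed = 1, exhaustive_limit = 0)
  expect_equal(ex, sub)
  # when the true triple uniquely maximizes Tri-SIM the percentile is 100
  set.seed(22)
  base <- runif_sphere(8, 5)
  Z1 <- base; Z2 <- base; Z3 <- base
  expect_equal(trisim_percentile(Z1, Z2, Z3), rep(100, 8))
  # shuffled third modality on random data: percentile ~ 50 on average
  set.seed(23)
  A <- runif_sphere(40, 6); B <- runif_sphere(40, 6); C <- runif_sphere(40, 6)
  p <- trisim_percentile(A, B, C)
  expect_gt(mean(p), 35); expect_lt(mean(p), 65)
})

test_that("pairing consistency: identity, permutation null, empty, missing labels", {
  ids <- sprintf("c%02d", 1:20)
  lab <- setNames(rep(c("t1", "t2"), 10), ids)
  pairs <- data.frame(source_id = ids, target_id = ids, similarity = 1)
  res <- pairing_consistency(pairs, lab, lab)
  expect_equal(res$proportion, 1)
  expect_equal(sum(res$per_label$n_consistent), 20)

  # label-permutation null approaches the label collision rate
  set.seed(24)
  nperm <- 300
  props <- vapply(seq_len(nperm), function(i) {
    labp <- setNames(sample(lab), ids)
    pairing_consistency(pairs, lab, labp)$proportion
  }, numeric(1))
  expect_equal(mean(props), sum((table(lab) / 20)^2), tolerance = 0.03)

  empty <- data.frame(source_id = character(0), target_id = character(0),
                      similarity = numeric(0))
  expect_equal(pairing_consistency(empty, lab, lab)$proportion, 0)
  expect_error(pairing_consistency(pairs, lab[-1], lab), class = "spherepair_value_error")
  # explicit reference count divides as given
  expect_equal(pairing_consistency(pairs[1:10, ], lab, lab, reference_count = 20)$proportion, 0.5)
})

test_that("cluster similarity: identities, constant labeling, contingency oracle", {
  a <- rep(c("x", "y", "z"), times = c(3, 4, 3))
  res <- cluster_similarity(a, a)
  expect_equal(res$ari, 1); expect_equal(res$nmi, 1)

  res0 <- cluster_similarity(a, rep("k", 10))
  expect_equal(res0$ari, 0); expect_equal(res0$nmi, 0)

  set.seed(25)
  b <- sample(c("p", "q"), 10, replace = TRUE)
  o <- oracle_ari_nmi(a, b)
  res2 <- cluster_similarity(a, b)
  expect_equal(res2$ari, o$ari, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res2$nmi, o$nmi, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(cluster_similarity(a, b[1:5]), class = "spherepair_shape_error")
})

test_that("metric report round-trips through TSV and JSON", {
  rows <- data.frame(metric = c("foscttm", "knn_accuracy"), split = c("holdout", "holdout"),
                     k = c(NA, 5), value = c(0.01, 0.95))
  path <- file.path(tempdir(), "report.tsv")
  write_metrics_report(rows, path)
  back <- read.delim(path)
  expect_equal(back$value, rows$value)
  js <- jsonlite::read_json(file.path(tempdir(), "report.json"))
  expect_equal(js$foscttm, 0.01)
})
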