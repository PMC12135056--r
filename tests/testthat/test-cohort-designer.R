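make_blob_features <- function(centers, n_per = 40, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(centers)), function(b) {
      matrix(rnorm(n_per * ncol(centers), mean = rep(centers[b, ], each = n_per),
                   sd = sd), nrow = n_per)
    }))
    out <- data.frame(id = seq_len(nrow(rows)), age = rows[, 1],
                      lbm = rows[, 2])
    out$cp10 <- rows[, 3]; out$cp40 <- rows[, 4]
    out
  })
}

test_that("cluster features are assembled exactly from profiles", {
  cohort <- tiny_cohort(n = 5)
  feats <- build_cluster_features(cohort$pop, cohort$profiles)
  expect_named(feats, c("id", "age", "lbm", "cp10", "cp40"))
  expect_equal(feats$age, cohort$pop$age)
  expect_equal(feats$cp10, vapply(cohort$profiles, function(p) p$cp[p$times == 10],
                                  numeric(1), USE.NAMES = FALSE))
  expect_false(anyNA(feats))
  # empty cohort gives an empty table; missing anchor time signals
  expect_equal(nrow(build_cluster_features(cohort$pop[0, ], list())), 0)
  short <- simulate_cohort(cohort$pop, cohort$regimen, c(5, 10))
  expect_error(build_cluster_features(cohort$pop, short), "t = 40")
})

test_that("post-infusion decay makes cp10 exceed cp40 for every subject", {
  cohort <- tiny_cohort(n = 100, seed = 13)
  feats <- build_cluster_features(cohort$pop, cohort$profiles)
  expect_true(all(feats$cp10 > feats$cp40))
})

test_that("well-separated blobs are recovered and k is validated", {
  centers <- rbind(c(0, 0, 0, 0), c(20, 20, 20, 20))
  feats <- make_blob_features(centers)
  a <- cluster_population(feats, k = 2)
  truth <- rep(1:2, each = 40)
  expect_true(all(table(a$labels, truth) %in% c(0, 40)))
  one <- cluster_population(feats, k = 1)
  expect_equal(unname(one$labels), rep(1L, 80))
  expect_error(cluster_population(feats, k = 100), "between 1")
  # distance matrix structure
  expect_equal(a$dist, t(a$dist))
  expect_equal(diag(a$dist), c("1" = 0, "2" = 0))
})

test_that("far and near clusters follow the centroid distances", {
  # three tight blobs: blob2 at distance ~56.52 and blob3 at ~20.05 from blob1
  centers <- rbind(c(0, 0, 0, 0),
                   c(56.52, 0, 0, 0) / 2, # overwritten below; keep rows distinct
                   c(0, 20.05, 0, 0))
  centers[2, ] <- c(56.52, 0, 0, 0)
  feats <- make_blob_features(centers, sd = 0.2)
  a <- cluster_population(feats, k = 3)
  lab1 <- a$labels[[1]]; lab2 <- a$labels[[41]]; lab3 <- a$labels[[81]]
  split <- select_splits(a, test_label = lab1, test_size = 10,
                         sizes = c(20, 5), seed = 1)
  expect_equal(split$far_label, lab2)
  expect_equal(split$near_label, lab3)
  expect_equal(split$far_distance, 56.52, tolerance = 0.01)
  expect_equal(split$near_distance, 20.05, tolerance = 0.01)
})

test_that("with two clusters near and far coincide", {
  feats <- make_blob_features(rbind(c(0, 0, 0, 0), c(20, 20, 20, 20)))
  a <- cluster_population(feats, k = 2)
  split <- select_splits(a, test_label = 1, test_size = 5, sizes = c(5), seed = 1)
  expect_equal(split$near_label, split$far_label)
})

test_that("splits are deterministic, disjoint and nested", {
  cohort <- tiny_cohort(n = 400, seed = 5)
  feats <- build_cluster_features(cohort$pop, cohort$profiles)
  a <- cluster_population(feats, k = 4)
  s1 <- select_splits(a, test_size = 20, sizes = c(60, 30, 10), seed = 9)
  s2 <- select_splits(a, test_size = 20, sizes = c(60, 30, 10), seed = 9)
  expect_identical(s1, s2)
  for (cl in c("near", "far")) {
    subsets <- s1$train[[cl]]
    expect_true(all(!subsets[["60"]] %in% s1$test_ids))
    expect_true(all(subsets[["10"]] %in% subsets[["30"]]))
    expect_true(all(subsets[["30"]] %in% subsets[["60"]]))
  }
  expect_error(select_splits(a, test_size = 1e5, seed = 1), "test cluster")
})

test_that("near/far ordering is invariant to feature permutation", {
  cohort <- tiny_cohort(n = 300, seed = 23)
  feats <- build_cluster_features(cohort$pop, cohort$profiles)
  perm <- feats[, c("id", "cp40", "lbm", "cp10", "age")]
  a <- cluster_population(feats, k = 5)
  b <- cluster_population(perm, k = 5)
  sa <- select_splits(a, test_label = 2, test_size = 10, sizes = 10, seed = 4)
  sb <- select_splits(b, test_label = 2, test_size = 10, sizes = 10, seed = 4)
  expect_equal(unname(a$labels), unname(b$labels))
  expect_equal(sa$near_label, sb$near_label)
  expect_equal(sa$far_label, sb$far_label)
})

test_that("test subjects are closer to near than far training subjects", {
  cohort <- tiny_cohort(n = 500, seed = 31)
  feats <- build_cluster_features(cohort$pop, cohort$profiles)
  a <- cluster_population(feats, k = 5)
  s <- select_splits(a, test_size = 30, sizes = c(30), seed = 2)
  x <- as.matrix(feats[, -1])
  rownames(x) <- feats$id
  mean_dist <- function(ids_a, ids_b) {
    xa <- x[ids_a, , drop = FALSE]; xb <- x[ids_b, , drop = FALSE]
    mean(vapply(seq_len(nrow(xa)), function(i) {
      mean(sqrt(colSums((t(xb) - xa[i, ])^2)))
    }, numeric(1)))
  }
  expect_lt(mean_dist(s$test_ids, s$train$near[["30"]]),
            mean_dist(s$test_ids, s$train$far[["30"]]))
})

test_that("oversized subset requests are capped at the cluster size", {
  feats <- make_blob_features(rbind(c(0, 0, 0, 0), c(30, 30, 30, 30)),
                              n_per = 25)
  a <- cluster_population(feats, k = 2)
  s <- select_splits(a, test_label = 1, test_size = 5, sizes = c(100, 10),
                     seed = 1)
  expect_lte(length(s$train$near[["100"]]), 25)
  expect_length(s$train$near[["10"]], 10)
})

test_that("split specs round-trip through JSON", {
  cohort <- tiny_cohort(n = 200, seed = 3)
  feats <- build_cluster_features(cohort$pop, cohort$profiles)
  a <- cluster_population(feats, k = 3)
  s <- select_splits(a, test_size = 10, sizes = c(20, 5), seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_split_spec(s, f)
  back <- read_split_spec(f)
  expect_equal(back$test_label, s$test_label)
  expect_equal(back$test_ids, s$test_ids)
  expect_equal(back$train$near[["5"]], s$train$near[["5"]])
})
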