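test_that("standardize produces exact z-scores and is idempotent", {
  expect_equal(standardize(tibble::tibble(x = c(1, 2, 3)))$x, c(-1, 0, 1))
  withr::with_seed(30, {
    df <- tibble::tibble(a = rnorm(20, 5, 3), b = runif(20))
  })
  z <- standardize(df)
  expect_lt(max(abs(colMeans(as.matrix(z)))), 1e-12)
  expect_lt(max(abs(vapply(z, sd, numeric(1)) - 1)), 1e-12)
  z2 <- standardize(z)
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-12)
  expect_error(standardize(tibble::tibble(ok = 1:3, flat = rep(2, 3))),
               class = "spidertune_argument_error", regexp = "flat")
})

test_that("centroid linkage reproduces hand-computed centroid geometry", {
  # two points merge at their Euclidean distance
  t2 <- centroid_linkage(matrix(c(0, 3), ncol = 1))
  expect_equal(t2$height, 3)
  # collinear 0, 1, 10: merge {0,1} first, then distance from centroid 0.5
  t3 <- centroid_linkage(matrix(c(0, 1, 10), ncol = 1))
  expect_equal(t3$height, c(1, 9.5))
  lab <- cut_tree(t3, 2)
  expect_equal(lab[1], lab[2])
  expect_false(lab[1] == lab[3])
})

test_that("merge sequence matches the naive O(n^3) agglomeration oracle", {
  withr::with_seed(31, {
    X <- matrix(rnorm(50 * 2), ncol = 2)
  })
  tree <- centroid_linkage(X)
  oracle <- centroid_linkage_oracle(X)
  expect_equal(tree$height, oracle$heights, tolerance = 1e-8)
  for (step in seq_len(nrow(X) - 1)) {
    expect_equal(rand_index(cut_tree(tree, nrow(X) - step),
                            oracle$partitions[[step]]), 1)
  }
})

test_that("tree cuts cover the degenerate extremes", {
  withr::with_seed(32, X <- matrix(rnorm(12), ncol = 2))
  tree <- centroid_linkage(X)
  expect_equal(length(unique(cut_tree(tree, 6))), 6)
  expect_equal(length(unique(cut_tree(tree, 1))), 1)
  expect_error(cut_tree(tree, 0), class = "spidertune_argument_error")
})

test_that("partition BIC matches the direct density-sum oracle", {
  withr::with_seed(33, {
    z <- matrix(rnorm(100), ncol = 1)
  })
  lab1 <- rep(1L, 100)
  got <- bic_for_partition(z, lab1)
  ll <- gaussian_partition_loglik_oracle(z, lab1)
  expect_equal(as.numeric(got), -2 * ll + 2 * log(100), tolerance = 1e-8)
  expect_equal(attr(got, "logLik"), ll, tolerance = 1e-8)

  # multivariate, several clusters; m = k*2d + (k - 1) free proportions
  withr::with_seed(34, z3 <- matrix(rnorm(90), ncol = 3))
  lab3 <- rep(1:3, each = 10)
  got3 <- bic_for_partition(z3, lab3)
  ll3 <- gaussian_partition_loglik_oracle(z3, lab3)
  expect_equal(attr(got3, "logLik"), ll3, tolerance = 1e-8)
  expect_equal(as.numeric(got3), -2 * ll3 + (3 * 2 * 3 + 2) * log(30),
               tolerance = 1e-8)

  # duplicating rows doubles the log-likelihood term (parameters refit equal)
  zd <- rbind(z3, z3)
  labd <- c(lab3, lab3)
  expect_equal(attr(bic_for_partition(zd, labd), "logLik"), 2 * ll3,
               tolerance = 1e-8)

  # singleton clusters hit the variance floor but stay finite
  labs <- c(1L, rep(2L, 99))
  expect_warning(bs <- bic_for_partition(z, labs), regexp = "floor")
  expect_true(is.finite(bs))
  expect_error(bic_for_partition(z, rep(1L, 10)),
               class = "spidertune_argument_error")
})

test_that("BIC model selection finds planted blob structure", {
  two_ok <- 0
  three_ok <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    withr::with_seed(4000 + i, {
      z2 <- matrix(c(rnorm(20, -3, 0.5), rnorm(20, 3, 0.5)), ncol = 1)
      z3 <- matrix(c(rnorm(15, -6, 0.5), rnorm(15, 0, 0.5),
                     rnorm(15, 6, 0.5)), ncol = 1)
    })
    if (suppress_floor(select_clusters(as.data.frame(z2)))$selected_k == 2) {
      two_ok <- two_ok + 1
    }
    if (suppress_floor(select_clusters(as.data.frame(z3)))$selected_k == 3) {
      three_ok <- three_ok + 1
    }
  }
  expect_gte(two_ok / reps, 0.95)
  expect_gte(three_ok / reps, 0.90)
})

test_that("selection invariants: BIC argmin, label count, permutation symmetry", {
  withr::with_seed(36, {
    df <- tibble::tibble(
      participant_id = sprintf("P%02d", 1:24),
      v = c(rnorm(12, -2, 0.4), rnorm(12, 2, 0.4))
    )
  })
  res <- suppress_floor(select_clusters(df))
  expect_true(res$selected_k %in% 2:4)
  expect_equal(min(res$bic$bic), res$bic$bic[res$bic$k == res$selected_k])
  expect_equal(length(unique(res$labels)), res$selected_k)
  perm <- sample(nrow(df))
  res_p <- suppress_floor(select_clusters(df[perm, ]))
  expect_equal(rand_index(res$labels[perm], res_p$labels), 1)
  expect_equal(glance(res)$selected_k, res$selected_k)
  expect_equal(nrow(tidy(res)), 24)
  expect_s3_class(autoplot(res), "ggplot")
  expect_error(select_clusters(df[1:5, ]),
               class = "spidertune_argument_error")
})

test_that("polarized synthetic subgroups are recovered from the cohort", {
  ok <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    cfg <- generator_config(
      cluster_spec = list(
        list(weight = 0.5, offsets = c(hairiness_dangerous = -0.25)),
        list(weight = 0.5, offsets = c(hairiness_dangerous = 0.25))
      ),
      seed = 5000 + i
    )
    coh <- generate_cohort(cfg)
    pm <- preference_matrix(coh)
    res <- suppress_floor(
      select_clusters(pm[c("participant_id", "hairiness_dangerous")],
                      candidate_k = 2))
    ri <- rand_index(res$labels, coh$participants$cluster_true)
    if (ri >= 0.9) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.9)
})

test_that("criterion presets select the documented variable sets", {
  expect_equal(criterion_variables("single:hairiness:dangerous"),
               "hairiness_dangerous")
  expect_length(criterion_variables("all_features"), 6)
  expect_true(all(endsWith(criterion_variables("harmless"), "harmless")))
  expect_equal(criterion_variables("all_plus_spq")[1], "spq")
  expect_error(criterion_variables("single:velcro:dangerous"),
               class = "spidertune_argument_error")
})
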