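test_that("mmpd follows the modal-part rule on hand-worked cases", {
  expect_equal(mmpd(c(0.2, 0.3, 0.9)), 0.25)
  expect_equal(mmpd(c(0.6, 0.7, 0.5, 0.1)), 0.6)
  expect_equal(mmpd(c(0.5, 0.5, 0.5)), 0.5)
  # tie between the two sides averages everything (and is signalled)
  expect_equal(mmpd(c(0.2, 0.8)), 0.5)
  cond <- NULL
  withCallingHandlers(
    mmpd(c(0.1, 0.9)),
    spidertune_mmpd_tie = function(c) cond <<- c
  )
  expect_s3_class(cond, "spidertune_mmpd_tie")
  expect_error(mmpd(numeric(0)), class = "spidertune_argument_error")
  expect_error(mmpd(c(0.2, 1.2)), class = "spidertune_range_error")
})

test_that("mmpd agrees with the recount-and-average oracle on random grids", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      v <- sample(0:9, 12, replace = TRUE) / 9
      expect_equal(mmpd(v), mmpd_oracle(v), tolerance = 1e-12)
    }
  })
})

test_that("mmpd is permutation-invariant, bounded, and reduces to the mean one-sided", {
  withr::with_seed(7, {
    for (i in 1:50) {
      v <- sample(0:9, 12, replace = TRUE) / 9
      expect_equal(mmpd(sample(v)), mmpd(v))
      expect_gte(mmpd(v), min(v))
      expect_lte(mmpd(v), max(v))
      one_side <- v[v < 0.5]
      if (length(one_side) > 0) expect_equal(mmpd(one_side), mean(one_side))
    }
  })
})

test_that("incoherency matches its closed form and identities", {
  expect_equal(incoherency(0.2, 0.8), 0)
  expect_equal(incoherency(0.9, 0.9), 0.8)
  expect_equal(incoherency(0.5, 0.5), 0)
  expect_error(incoherency(1.1, 0.5), class = "spidertune_range_error")
  withr::with_seed(3, {
    p <- runif(100)
    q <- runif(100)
    expect_equal(incoherency(p, 1 - p), rep(0, 100))
    expect_equal(incoherency(p, q), incoherency(q, p))
    expect_true(all(incoherency(p, q) >= 0 & incoherency(p, q) <= 1))
  })
  # the maximum is attained only at the two shared extremes
  grid <- expand.grid(p = 0:10 / 10, q = 0:10 / 10)
  at_max <- grid[incoherency(grid$p, grid$q) == 1, ]
  expect_equal(nrow(at_max), 2)
  expect_setequal(at_max$p + at_max$q, c(0, 2))
})

test_that("per-participant summaries compose the statistic over pooled trials", {
  coh <- generate_cohort(reference_config(seed = 6))
  s <- summarize_preferences(coh, "all")
  expect_true(all(s$n_trials == 12))
  expect_true(all(s$value >= 0 & s$value <= 1))

  one <- coh$trials[coh$trials$participant_id == "P007" &
                      coh$trials$instruction == "dangerous", ]
  pick <- function(stat) {
    s$value[s$participant_id == "P007" & s$feature == "hairiness" &
              s$instruction == "dangerous" & s$statistic == stat]
  }
  expect_equal(pick("mean"), mean(one$hairiness))
  expect_equal(pick("median"), median(one$hairiness))
  expect_equal(pick("mmpd"), mmpd(one$hairiness))
})

test_that("zero-noise cohorts summarize to the snapped latent mean under all statistics", {
  cfg <- generator_config(base_sd = 0, sd_spq_slope = 0,
                          orientation_effect = 0, seed = 2)
  s <- summarize_preferences(generate_cohort(cfg), "all")
  target <- snap_to_grid(0.75) # harmless hairiness latent mean
  hh <- s$value[s$feature == "hairiness" & s$instruction == "harmless"]
  expect_true(all(hh == target))
})

test_that("missing instruction cells are omitted with a warning", {
  coh <- make_minimal_cohort()
  half <- cohort(coh$participants,
                 coh$trials[coh$trials$instruction == "dangerous", ])
  expect_warning(s <- summarize_preferences(half, "mean"),
                 regexp = "omitted")
  expect_true(all(s$instruction == "dangerous"))
  expect_warning(incoherency_table(s), regexp = "dropped")
})

test_that("the grand-average table has the expected layout and degenerate limits", {
  coh <- make_minimal_cohort(level = 4L) # p = 4/9 everywhere
  # clone to 3 identical participants so SDs are defined
  p3 <- dplyr::bind_rows(lapply(1:3, function(i) {
    dplyr::mutate(coh$participants, participant_id = sprintf("P%03d", i))
  }))
  t3 <- dplyr::bind_rows(lapply(1:3, function(i) {
    dplyr::mutate(coh$trials, participant_id = sprintf("P%03d", i))
  }))
  c3 <- cohort(p3, t3)
  s <- summarize_preferences(c3, "all")
  g <- grand_average_table(s, incoherency_table(s))
  expect_equal(nrow(g), 3 * 6 + 3) # 3 statistic rows x 6 cells + 3 incoherency
  pref <- g[g$statistic != "incoherency", ]
  expect_true(all(pref$grand_mean == 4 / 9))
  expect_true(all(pref$grand_sd == 0))
  inc <- g[g$statistic == "incoherency", ]
  expect_equal(inc$grand_mean, rep(abs(4 / 9 + 4 / 9 - 1), 3))
  expect_error(grand_average_table(s[s$statistic == "mean", ],
                                   incoherency_table(s)),
               class = "spidertune_argument_error")
})

test_that("mirror symmetry: relabeling an axis mirrors mean summaries and fixes incoherency", {
  coh <- generate_cohort(reference_config(seed = 8))
  flipped <- coh
  flipped$trials$hairiness <- 1 - flipped$trials$hairiness
  s1 <- summarize_preferences(coh, "mean")
  s2 <- summarize_preferences(flipped, "mean")
  h1 <- s1[s1$feature == "hairiness", ]
  h2 <- s2[s2$feature == "hairiness", ]
  expect_equal(h2$value, 1 - h1$value)
  i1 <- incoherency_table(s1)
  i2 <- incoherency_table(s2)
  expect_equal(i2$incoherency[i2$feature == "hairiness"],
               i1$incoherency[i1$feature == "hairiness"])
})

test_that("orientation strata use 4 trials each and expose a known orientation effect", {
  cfg0 <- generator_config(orientation_effect = 0, seed = 31)
  o0 <- orientation_summaries(generate_cohort(cfg0), "mean")
  expect_true(all(o0$n_trials_per_participant == 4))
  hd0 <- o0[o0$feature == "hairiness" & o0$instruction == "dangerous", ]
  expect_lt(diff(range(hd0$grand_mean)), 0.05) # null effect: strata agree

  cfg1 <- generator_config(orientation_effect = -0.1, seed = 31)
  o1 <- orientation_summaries(generate_cohort(cfg1), "mean")
  hd1 <- o1[o1$feature == "hairiness" & o1$instruction == "dangerous", ]
  appr <- hd1$grand_mean[hd1$orientation == "approaching"]
  expect_lt(appr, hd1$grand_mean[hd1$orientation == "lateral"])
  expect_lt(appr, hd1$grand_mean[hd1$orientation == "withdrawing"])
})
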