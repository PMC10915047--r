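test_that("generated cohorts honour the experimental design exactly", {
  coh <- generate_cohort(reference_config(seed = 1))
  expect_equal(nrow(coh$trials), 45 * 24)
  rep <- validate_design(coh)
  expect_true(all(rep$complete))
  # 4 trials per instruction-by-orientation cell for every participant
  cell <- dplyr::count(coh$trials, participant_id, instruction, orientation)
  expect_true(all(cell$n == 4))
  for (f in c("hairiness", "bodyleg", "locomotion")) {
    expect_true(all(coh$trials[[f]] >= 0 & coh$trials[[f]] <= 1))
    expect_identical(coh$trials[[f]] * 9, round(coh$trials[[f]] * 9))
  }
  expect_true(all(coh$participants$spq >= 0 & coh$participants$spq <= 26))
})

test_that("the generator is reproducible and seed-sensitive", {
  a <- generate_cohort(reference_config(seed = 11))
  b <- generate_cohort(reference_config(seed = 11))
  c <- generate_cohort(reference_config(seed = 12))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(a$trials$hairiness, c$trials$hairiness))
})

test_that("zero noise degenerates to latent means snapped to the grid", {
  cfg <- generator_config(base_sd = 0, sd_spq_slope = 0,
                          orientation_effect = 0, seed = 5)
  coh <- generate_cohort(cfg)
  cm <- default_condition_means()
  for (i in seq_len(nrow(cm))) {
    vals <- coh$trials[[cm$feature[i]]][coh$trials$instruction ==
                                          cm$instruction[i]]
    expect_true(all(vals == snap_to_grid(cm$mean[i])))
  }
})

test_that("reference_config carries the documented study conditions", {
  cfg <- reference_config()
  expect_equal(cfg$n_participants, 45L)
  cm <- cfg$condition_means
  get <- function(f, ins) cm$mean[cm$feature == f & cm$instruction == ins]
  expect_equal(get("locomotion", "dangerous"), 0.77)
  expect_equal(get("hairiness", "harmless"), 0.75)
  expect_equal(get("hairiness", "dangerous"), 0.33)
  expect_equal(get("bodyleg", "dangerous"), 0.34)
  expect_equal(get("bodyleg", "harmless"), 0.71)
  expect_equal(get("locomotion", "harmless"), 0.40)
  expect_equal(cfg$spq_range, c(0L, 26L))
})

test_that("grand mean of dangerous-locomotion trials is near its target", {
  coh <- generate_cohort(reference_config(seed = 1))
  v <- coh$trials$locomotion[coh$trials$instruction == "dangerous"]
  expect_lt(abs(mean(v) - 0.77), 0.05)
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(generator_config(n_participants = 0),
               class = "spidertune_config_error", regexp = "n_participants")
  expect_error(generator_config(spq_range = c(5, 2)),
               class = "spidertune_config_error", regexp = "spq_range")
  cm <- default_condition_means()
  cm$mean[1] <- 1.2
  expect_error(generator_config(condition_means = cm),
               class = "spidertune_config_error", regexp = "condition_means")
  expect_error(
    generator_config(cluster_spec = list(
      list(weight = 0.6, offsets = c(hairiness_dangerous = 0.1)),
      list(weight = 0.6, offsets = c(hairiness_dangerous = -0.1))
    )),
    class = "spidertune_config_error", regexp = "weights"
  )
  expect_error(
    generator_config(cluster_spec = list(
      list(weight = 1, offsets = c(nonsense_cell = 0.1))
    )),
    class = "spidertune_config_error", regexp = "nonsense_cell"
  )
})

test_that("trial-level dispersion grows with SPQ when the slope is positive", {
  ok <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    coh <- generate_cohort(reference_config(seed = 1000 + i))
    tr <- coh$trials %>%
      tidyr::pivot_longer(c(hairiness, bodyleg, locomotion),
                          names_to = "feature") %>%
      dplyr::left_join(coh$participants[c("participant_id", "spq")],
                       by = "participant_id") %>%
      dplyr::group_by(participant_id, feature, instruction) %>%
      dplyr::mutate(r = value - mean(value)) %>%
      dplyr::ungroup()
    q <- quantile(coh$participants$spq, c(1 / 3, 2 / 3))
    if (var(tr$r[tr$spq >= q[2]]) > var(tr$r[tr$spq <= q[1]])) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95)
})

test_that("a positive incoherency slope yields SPQ-correlated hairiness incoherency", {
  ok <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    cfg <- generator_config(hairiness_incoherency_slope = 0.03,
                            seed = 2000 + i)
    coh <- generate_cohort(cfg)
    inc <- incoherency_table(summarize_preferences(coh, "mmpd"))
    h <- dplyr::left_join(inc[inc$feature == "hairiness", ],
                          coh$participants[c("participant_id", "spq")],
                          by = "participant_id")
    rho <- suppressWarnings(cor(h$incoherency, h$spq, method = "spearman"))
    if (rho > 0) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95)
})

test_that("cluster_spec produces the configured subgroup structure", {
  cfg <- generator_config(
    cluster_spec = list(
      list(weight = 0.5, offsets = c(hairiness_dangerous = -0.25)),
      list(weight = 0.5, offsets = c(hairiness_dangerous = 0.25))
    ),
    seed = 9
  )
  coh <- generate_cohort(cfg)
  pm <- preference_matrix(coh, "mean")
  truth <- coh$participants$cluster_true
  m1 <- mean(pm$hairiness_dangerous[truth == 1])
  m2 <- mean(pm$hairiness_dangerous[truth == 2])
  expect_lt(m1, m2)
  expect_gt(m2 - m1, 0.3)
})

test_that("generator configs round-trip through YAML and JSON files", {
  td <- withr::local_tempdir()
  yml <- file.path(td, "cfg.yaml")
  writeLines(c(
    "n_participants: 10",
    "base_sd: 0.05",
    "seed: 42",
    "condition_means:",
    "  hairiness:",
    "    dangerous: 0.2",
    "cluster_spec:",
    "  - weight: 0.5",
    "    offsets:",
    "      bodyleg_harmless: 0.1",
    "  - weight: 0.5",
    "    offsets:",
    "      bodyleg_harmless: -0.1"
  ), yml)
  cfg <- read_generator_config(yml)
  expect_equal(cfg$n_participants, 10L)
  expect_equal(cfg$base_sd, 0.05)
  cm <- cfg$condition_means
  expect_equal(cm$mean[cm$feature == "hairiness" &
                         cm$instruction == "dangerous"], 0.2)
  expect_equal(cm$mean[cm$feature == "locomotion" &
                         cm$instruction == "dangerous"], 0.77)
  expect_length(cfg$cluster_spec, 2)

  jsn <- file.path(td, "cfg.json")
  jsonlite::write_json(list(n_participants = 7, seed = 3), jsn,
                       auto_unbox = TRUE)
  cfg2 <- read_generator_config(jsn)
  expect_equal(cfg2$n_participants, 7L)
  expect_identical(generate_cohort(cfg2),
                   generate_cohort(generator_config(n_participants = 7,
                                                    seed = 3)))
})
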