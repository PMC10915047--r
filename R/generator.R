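#' Default condition means for the synthetic generator
#'
#' Grand-average preference targets per (feature, instruction): dangerous
#' spiders hairy, thick and spider-like; harmless spiders hairless, slim and
#' butterfly-like.
#'
#' @return A tibble with columns `feature`, `instruction`, `mean`.
#' @export
default_condition_means <- function() {
  tibble(
    feature     = rep(feature_names, each = 2),
    instruction = rep(instruction_levels, times = 3),
    mean        = c(0.33, 0.75, 0.34, 0.71, 0.77, 0.40)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study design being emulated (45 participants, 24 trials each:
#' 12 per instruction, 8 per orientation, hence 4 per cell) and the
#' statistical structure layered on top of it. See the methods vignette for
#' the rationale behind each default.
#'
#' @param n_participants Number of participants (default 45).
#' @param spq_range Integer range for the uniform SPQ draw, default `c(0, 26)`
#'   so scores are continuously spread from 0 to 26 of 30.
#' @param condition_means Tibble with columns `feature`, `instruction`,
#'   `mean`: the latent preference mean for each of the six cells, in
#'   \eqn{[0,1]}. Default [default_condition_means()].
#' @param base_sd Trial-level noise SD, in preference units, at SPQ = 0
#'   (default 0.08, about 0.7 grid steps).
#' @param sd_spq_slope Per-SPQ-point slope on the log trial-level SD, so the
#'   SD at score `s` is `base_sd * exp(sd_spq_slope * s)` (default 0.03:
#'   more fearful participants answer more variably).
#' @param hairiness_incoherency_slope Per-SPQ-point fraction by which a
#'   participant's harmless-hairiness latent mean is pulled toward their
#'   dangerous-hairiness mean (generalization of fear to harmless variants).
#'   The pull fraction `min(1, slope * spq)` interpolates between the two
#'   cell means. Default 0; see the vignette for why it is off by default.
#' @param cluster_spec Optional list of subgroups, each a
#'   `list(weight =, offsets =)` where `offsets` is a numeric vector named
#'   `"<feature>_<instruction>"` added to the affected latent means. Weights
#'   must sum to 1. Default `NULL` (no subgroup structure).
#' @param orientation_effect Additive shift of the dangerous-hairiness latent
#'   mean on approaching trials (default -0.05: approaching spiders are made
#'   slightly hairier).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A `spider_generator_config` list.
#' @export
generator_config <- function(n_participants = 45L,
                             spq_range = c(0L, 26L),
                             condition_means = default_condition_means(),
                             base_sd = 0.08,
                             sd_spq_slope = 0.03,
                             hairiness_incoherency_slope = 0,
                             cluster_spec = NULL,
                             orientation_effect = -0.05,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    spq_range = as.integer(spq_range),
    condition_means = as_tibble(condition_means),
    base_sd = base_sd,
    sd_spq_slope = sd_spq_slope,
    hairiness_incoherency_slope = hairiness_incoherency_slope,
    cluster_spec = cluster_spec,
    orientation_effect = orientation_effect,
    seed = as.integer(seed)
  )
  class(cfg) <- "spider_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.finite(cfg$n_participants) || cfg$n_participants < 1) {
    abort("invalid generator config: n_participants must be >= 1",
          class = "spidertune_config_error")
  }
  if (length(cfg$spq_range) != 2 || cfg$spq_range[1] > cfg$spq_range[2] ||
        cfg$spq_range[1] < 0 || cfg$spq_range[2] > 30) {
    abort("invalid generator config: spq_range must be an ordered pair within 0..30",
          class = "spidertune_config_error")
  }
  cm <- cfg$condition_means
  if (!all(c("feature", "instruction", "mean") %in% names(cm)) ||
        nrow(cm) != 6 ||
        !setequal(paste(cm$feature, cm$instruction),
                  paste(rep(feature_names, each = 2),
                        rep(instruction_levels, 3)))) {
    abort("invalid generator config: condition_means must cover all six (feature, instruction) cells",
          class = "spidertune_config_error")
  }
  if (any(cm$mean < 0 | cm$mean > 1)) {
    abort("invalid generator config: condition_means must lie in [0, 1]",
          class = "spidertune_config_error")
  }
  if (!is.finite(cfg$base_sd) || cfg$base_sd < 0) {
    abort("invalid generator config: base_sd must be >= 0",
          class = "spidertune_config_error")
  }
  if (!is.null(cfg$cluster_spec)) {
    w <- vapply(cfg$cluster_spec, function(cl) cl$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
      abort("invalid generator config: cluster_spec weights must be non-negative and sum to 1",
            class = "spidertune_config_error")
    }
    valid <- paste(rep(feature_names, each = 2),
                   rep(instruction_levels, 3), sep = "_")
    for (cl in cfg$cluster_spec) {
      bad <- setdiff(names(cl$offsets), valid)
      if (length(bad)) {
        abort(paste0("invalid generator config: unknown cluster_spec offset name(s): ",
                     paste(bad, collapse = ", ")),
              class = "spidertune_config_error")
      }
    }
  }
  invisible(cfg)
}

#' Reference generator configuration
#'
#' The package's documented default cohort: 45 participants, SPQ uniform on
#' 0--26, condition means at the MMPD grand averages of the study being
#' emulated, SPQ-dependent trial noise, and a small orientation effect on
#' dangerous hairiness.
#'
#' @param seed Integer seed (default 1).
#' @return A [generator_config()] object.
#' @export
reference_config <- function(seed = 1L) {
  generator_config(seed = seed)
}

#' Read a generator configuration from YAML or JSON
#'
#' Scalars override [generator_config()] defaults; `condition_means` may be
#' given as a nested map `feature -> instruction -> mean`, and
#' `cluster_spec` as a list of `{weight, offsets}` maps.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A [generator_config()] object.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$condition_means) && !is.data.frame(raw$condition_means)) {
    cm <- default_condition_means()
    for (i in seq_len(nrow(cm))) {
      v <- raw$condition_means[[cm$feature[i]]][[cm$instruction[i]]]
      if (!is.null(v)) cm$mean[i] <- v
    }
    raw$condition_means <- cm
  }
  if (!is.null(raw$cluster_spec)) {
    raw$cluster_spec <- lapply(raw$cluster_spec, function(cl) {
      list(weight = cl$weight, offsets = unlist(cl$offsets))
    })
  }
  do.call(generator_config, raw)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the configured design: each participant gets an SPQ
#' score, an optional subgroup assignment, and latent preference means per
#' (feature, instruction); each of the 24 trials then adds normal noise with
#' SD `base_sd * exp(sd_spq_slope * spq)`, is clamped to \eqn{[0,1]} and
#' snapped to the nearest grid point `k/9`. The orientation effect is applied
#' to dangerous-hairiness means on approaching trials; trial order is
#' pseudo-randomized per participant. Deterministic given the configuration.
#'
#' @param config A [generator_config()] object.
#' @return A validated [cohort()] object.
#' @export
#' @examples
#' coh <- generate_cohort(reference_config(seed = 7))
#' coh
generate_cohort <- function(config = reference_config()) {
  validate_generator_config(config)
  withr::with_seed(
    config$seed,
    generate_cohort_impl(config),
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  spq <- sample(seq(config$spq_range[1], config$spq_range[2]), n,
                replace = TRUE)

  ## latent means: participants x 6 cells
  cells <- paste(rep(feature_names, each = 2), rep(instruction_levels, 3),
                 sep = "_")
  cm <- config$condition_means
  base <- setNames(cm$mean, paste(cm$feature, cm$instruction, sep = "_"))
  latent <- matrix(rep(base[cells], each = n), nrow = n,
                   dimnames = list(ids, cells))

  cluster <- rep(1L, n)
  if (!is.null(config$cluster_spec)) {
    w <- vapply(config$cluster_spec, function(cl) cl$weight, numeric(1))
    cluster <- sample(seq_along(w), n, replace = TRUE, prob = w)
    for (j in seq_along(config$cluster_spec)) {
      off <- config$cluster_spec[[j]]$offsets
      for (nm in names(off)) {
        latent[cluster == j, nm] <- latent[cluster == j, nm] + off[[nm]]
      }
    }
  }

  ## generalization of fear: pull the harmless-hairiness mean toward the
  ## participant's dangerous-hairiness mean, proportionally to SPQ
  if (config$hairiness_incoherency_slope != 0) {
    f <- pmin(1, pmax(0, config$hairiness_incoherency_slope * spq))
    latent[, "hairiness_harmless"] <-
      latent[, "hairiness_harmless"] +
      f * (latent[, "hairiness_dangerous"] - latent[, "hairiness_harmless"])
  }
  latent[] <- pmin(pmax(latent, 0), 1)

  ## full-factorial design, shuffled per participant
  design <- tidyr::expand_grid(
    instruction = instruction_levels,
    orientation = orientation_levels,
    rep = 1:4
  )
  trials <- purrr::map_dfr(seq_len(n), function(i) {
    d <- design[sample.int(nrow(design)), c("instruction", "orientation")]
    d$participant_id <- ids[i]
    d$trial_index <- seq_len(nrow(d))
    d
  })

  sd_i <- config$base_sd * exp(config$sd_spq_slope * spq)
  trials$.sd <- sd_i[match(trials$participant_id, ids)]
  row_of <- match(trials$participant_id, ids)
  for (f in feature_names) {
    mu <- latent[cbind(row_of, match(paste(f, trials$instruction, sep = "_"),
                                     cells))]
    if (f == "hairiness") {
      mu <- mu + config$orientation_effect *
        (trials$instruction == "dangerous" &
           trials$orientation == "approaching")
    }
    trials[[f]] <- snap_to_grid(rnorm(nrow(trials), mu, trials$.sd))
  }
  trials$.sd <- NULL

  participants <- tibble(
    participant_id = ids,
    spq = as.integer(spq),
    included = TRUE,
    age = NA_real_,
    sex = NA_character_,
    cluster_true = as.integer(cluster)
  )
  cohort(
    participants,
    trials %>% select(participant_id, trial_index, instruction, orientation,
                      hairiness, bodyleg, locomotion)
  )
}
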