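#' Feature axes of the virtual-spider customization task
#'
#' The three perceptual features participants could tune, each on a 10-level
#' grid mapped to \eqn{[0, 1]}. The pole labels fix the orientation of every
#' axis throughout the package: low hairiness values mean *hairy* spiders,
#' low body/leg values mean *thick* ones, and low locomotion values mean a
#' *butterfly-like* movement pattern.
#'
#' @return A tibble with columns `feature`, `pole_zero`, `pole_one`.
#' @export
#' @examples
#' feature_axes()
feature_axes <- function() {
  tibble(
    feature   = c("hairiness", "bodyleg", "locomotion"),
    pole_zero = c("hairy", "thick", "butterfly-like"),
    pole_one  = c("hairless", "slim", "spider-like")
  )
}

instruction_levels <- c("dangerous", "harmless")
orientation_levels <- c("approaching", "withdrawing", "lateral")
feature_names <- c("hairiness", "bodyleg", "locomotion")

#' Snap values to the 10-level feature grid
#'
#' Feature settings are recorded on a 10-degree grid; analysis values are the
#' grid levels mapped to `k/9`, `k = 0, ..., 9`.
#'
#' @param x Numeric vector in \eqn{[0, 1]}.
#' @return `x` rounded to the nearest grid point `k/9`.
#' @export
snap_to_grid <- function(x) {
  round(pmin(pmax(x, 0), 1) * 9) / 9
}

is_on_grid <- function(x, tol = 1e-9) {
  abs(x * 9 - round(x * 9)) < tol & x >= -tol & x <= 1 + tol
}

#' Assemble a cohort from participant and trial tables
#'
#' Bundles a participant table and a trial table into a validated cohort
#' object, the input to every analysis stage.
#'
#' @param participants A data frame with columns `participant_id`, `spq`
#'   (integer 0--30), `included` (logical), and optionally `age`, `sex`.
#' @param trials A data frame with columns `participant_id`, `trial_index`,
#'   `instruction` (`"dangerous"`/`"harmless"`), `orientation`
#'   (`"approaching"`/`"withdrawing"`/`"lateral"`), and unit-interval feature
#'   columns `hairiness`, `bodyleg`, `locomotion` on the grid `k/9`.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `spider_cohort`: a list with tibbles
#'   `participants` and `trials`.
#' @export
cohort <- function(participants, trials, validate = TRUE) {
  participants <- as_tibble(participants)
  trials <- as_tibble(trials)
  if (!"included" %in% names(participants)) participants$included <- TRUE
  if (!"age" %in% names(participants)) participants$age <- NA_real_
  if (!"sex" %in% names(participants)) participants$sex <- NA_character_
  out <- structure(
    list(participants = participants, trials = trials),
    class = "spider_cohort"
  )
  if (validate) validate_cohort(out)
  out
}

validate_cohort <- function(x) {
  p <- x$participants
  t <- x$trials
  need_p <- c("participant_id", "spq")
  need_t <- c("participant_id", "trial_index", "instruction", "orientation",
              feature_names)
  miss <- setdiff(need_p, names(p))
  if (length(miss)) {
    abort(paste0("participants table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "spidertune_schema_error")
  }
  miss <- setdiff(need_t, names(t))
  if (length(miss)) {
    abort(paste0("trials table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "spidertune_schema_error")
  }
  if (anyDuplicated(p$participant_id)) {
    abort("participant_id must be unique within a cohort",
          class = "spidertune_integrity_error")
  }
  bad <- which(!is.finite(p$spq) | p$spq < 0 | p$spq > 30 |
                 p$spq != round(p$spq))
  if (length(bad)) {
    abort(paste0("spq must be an integer in 0..30; offending participant row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "spidertune_range_error")
  }
  bad <- which(!t$instruction %in% instruction_levels)
  if (length(bad)) {
    abort(paste0("instruction must be one of {",
                 paste(instruction_levels, collapse = ", "),
                 "}; offending trial row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "spidertune_range_error")
  }
  bad <- which(!t$orientation %in% orientation_levels)
  if (length(bad)) {
    abort(paste0("orientation must be one of {",
                 paste(orientation_levels, collapse = ", "),
                 "}; offending trial row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "spidertune_range_error")
  }
  for (f in feature_names) {
    bad <- which(!is_on_grid(t[[f]]))
    if (length(bad)) {
      abort(paste0(f, " values must lie on the grid k/9, k = 0..9; ",
                   "offending trial row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "spidertune_range_error")
    }
  }
  orphan <- setdiff(t$participant_id, p$participant_id)
  if (length(orphan)) {
    abort(paste0("trials reference unknown participant_id(s): ",
                 paste(head(orphan, 5), collapse = ", ")),
          class = "spidertune_integrity_error")
  }
  invisible(x)
}

#' @export
print.spider_cohort <- function(x, ...) {
  cat("<spider_cohort> ", nrow(x$participants), " participants, ",
      nrow(x$trials), " trials\n", sep = "")
  cat("SPQ range: ", paste(range(x$participants$spq), collapse = "-"), "\n",
      sep = "")
  invisible(x)
}

#' Read a cohort from the canonical CSV pair
#'
#' The canonical interchange format stores feature settings as integer grid
#' levels 0--9 (`hairiness_level`, `bodyleg_level`, `locomotion_level`);
#' loading maps level `k` to the analysis value `k/9` exactly.
#'
#' @param trials_path Path to the trials CSV with columns
#'   `participant_id,trial_index,instruction,orientation,hairiness_level,bodyleg_level,locomotion_level`.
#' @param participants_path Path to the participants CSV with columns
#'   `participant_id,spq,included,age,sex`.
#' @return A validated [cohort()] object.
#' @export
load_cohort <- function(trials_path, participants_path) {
  tspec <- readr::cols(
    participant_id = readr::col_character(),
    trial_index = readr::col_integer(),
    instruction = readr::col_character(),
    orientation = readr::col_character(),
    hairiness_level = readr::col_integer(),
    bodyleg_level = readr::col_integer(),
    locomotion_level = readr::col_integer()
  )
  pspec <- readr::cols(
    participant_id = readr::col_character(),
    spq = readr::col_integer(),
    included = readr::col_logical(),
    age = readr::col_double(),
    sex = readr::col_character()
  )
  trials_raw <- readr::read_csv(trials_path, col_types = tspec)
  parts <- readr::read_csv(participants_path, col_types = pspec)
  miss <- setdiff(names(tspec$cols), names(trials_raw))
  if (length(miss)) {
    abort(paste0("trials file ", trials_path, " is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "spidertune_schema_error")
  }
  miss <- setdiff(names(pspec$cols), names(parts))
  if (length(miss)) {
    abort(paste0("participants file ", participants_path,
                 " is missing column(s): ", paste(miss, collapse = ", ")),
          class = "spidertune_schema_error")
  }
  for (col in c("hairiness_level", "bodyleg_level", "locomotion_level")) {
    lv <- trials_raw[[col]]
    bad <- which(is.na(lv) | lv < 0L | lv > 9L)
    if (length(bad)) {
      abort(paste0(col, " outside 0..9 in ", trials_path, ", data row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "spidertune_range_error")
    }
  }
  trials <- trials_raw %>%
    mutate(
      hairiness = hairiness_level / 9,
      bodyleg = bodyleg_level / 9,
      locomotion = locomotion_level / 9
    ) %>%
    select(participant_id, trial_index, instruction, orientation,
           hairiness, bodyleg, locomotion)
  cohort(parts, trials)
}

#' Write a cohort to the canonical CSV pair
#'
#' Feature values are written back as integer grid levels (`value * 9`
#' rounded to the nearest integer), so a save/load round trip is exact.
#'
#' @param x A [cohort()] object.
#' @inheritParams load_cohort
#' @return Invisibly, `x`.
#' @export
save_cohort <- function(x, trials_path, participants_path) {
  validate_cohort(x)
  out <- x$trials %>%
    mutate(
      hairiness_level = as.integer(round(hairiness * 9)),
      bodyleg_level = as.integer(round(bodyleg * 9)),
      locomotion_level = as.integer(round(locomotion * 9))
    ) %>%
    select(participant_id, trial_index, instruction, orientation,
           hairiness_level, bodyleg_level, locomotion_level)
  readr::write_csv(out, trials_path)
  readr::write_csv(
    x$participants %>% select(participant_id, spq, included, age, sex),
    participants_path
  )
  invisible(x)
}

#' Check a cohort against the experimental design
#'
#' A complete participant has 24 trials: 12 per instruction and 8 per
#' orientation (hence 4 per instruction-by-orientation cell). The report
#' flags any deviation; it never errors, so partially recorded cohorts can
#' still be inspected and analysed.
#'
#' @param x A [cohort()] object.
#' @return A tibble with one row per participant: `n_trials`, per-instruction
#'   and per-orientation counts, `n_off_grid`, and a logical `complete` flag
#'   plus a semicolon-separated `flags` string describing deviations.
#' @export
validate_design <- function(x) {
  t <- x$trials
  per <- t %>%
    group_by(participant_id) %>%
    summarise(
      n_trials = dplyr::n(),
      n_dangerous = sum(instruction == "dangerous"),
      n_harmless = sum(instruction == "harmless"),
      n_approaching = sum(orientation == "approaching"),
      n_withdrawing = sum(orientation == "withdrawing"),
      n_lateral = sum(orientation == "lateral"),
      n_off_grid = sum(!is_on_grid(hairiness) | !is_on_grid(bodyleg) |
                         !is_on_grid(locomotion)),
      .groups = "drop"
    )
  per <- x$participants %>%
    select(participant_id) %>%
    left_join(per, by = "participant_id") %>%
    mutate(across(-participant_id, ~ tidyr::replace_na(.x, 0L)))
  flags <- purrr::pmap_chr(per, function(participant_id, n_trials,
                                         n_dangerous, n_harmless,
                                         n_approaching, n_withdrawing,
                                         n_lateral, n_off_grid) {
    f <- character()
    if (n_trials != 24) {
      f <- c(f, sprintf("trials: expected 24, observed %d", n_trials))
    }
    if (n_dangerous != 12 || n_harmless != 12) {
      f <- c(f, sprintf("instruction imbalance: %d dangerous / %d harmless (expected 12/12)",
                        n_dangerous, n_harmless))
    }
    if (n_approaching != 8 || n_withdrawing != 8 || n_lateral != 8) {
      f <- c(f, sprintf("orientation imbalance: %d/%d/%d approaching/withdrawing/lateral (expected 8/8/8)",
                        n_approaching, n_withdrawing, n_lateral))
    }
    if (n_off_grid > 0) {
      f <- c(f, sprintf("%d off-grid feature value(s)", n_off_grid))
    }
    paste(f, collapse = "; ")
  })
  per %>% mutate(complete = flags == "", flags = flags)
}
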