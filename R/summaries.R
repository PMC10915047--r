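#' Mean of the modal part of the distribution (MMPD)
#'
#' A robust per-participant preference summary. The trial values (in
#' \eqn{[0,1]}) are first classified as strictly above or strictly below 0.5
#' (exact 0.5 values are ignored in this count); only the values on the more
#' frequent side are then averaged, with the exact 0.5 values included in
#' that average. Compared with the mean it discounts stray trials on the
#' minority side (lapses, boredom); compared with the median it retains the
#' metric information of the majority side.
#'
#' When the two sides are equally frequent the function averages *all*
#' values (equivalent to the mean); the tie is reported via a
#' `spidertune_mmpd_tie` condition so callers can log it.
#'
#' @param values Numeric vector of trial values in \eqn{[0,1]}; must be
#'   non-empty.
#' @return A scalar in `[min(values), max(values)]`.
#' @export
#' @examples
#' mmpd(c(0.2, 0.3, 0.9)) # below side wins 2-1 -> mean(0.2, 0.3)
#' mmpd(c(0.6, 0.7, 0.5, 0.1)) # above side wins 2-1 -> mean(0.6, 0.7, 0.5)
mmpd <- function(values) {
  if (length(values) == 0) {
    abort("mmpd() needs at least one value", class = "spidertune_argument_error")
  }
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    abort("mmpd() values must lie in [0, 1]", class = "spidertune_range_error")
  }
  above <- sum(values > 0.5)
  below <- sum(values < 0.5)
  if (above > below) {
    mean(values[values >= 0.5])
  } else if (below > above) {
    mean(values[values <= 0.5])
  } else {
    signal("equal counts above and below 0.5; averaging all values",
           class = "spidertune_mmpd_tie")
    mean(values)
  }
}

#' Incoherency index between dangerous and harmless preferences
#'
#' \eqn{x = |p^D + p^H - 1|}: 0 when the harmless setting is exactly
#' specular to the dangerous one (\eqn{p^H = 1 - p^D}), 1 when both
#' preferences sit on the same extreme.
#'
#' @param p_dangerous,p_harmless Preference summaries in \eqn{[0,1]}
#'   (vectorized).
#' @return `abs(p_dangerous + p_harmless - 1)`, in \eqn{[0,1]}.
#' @export
#' @examples
#' incoherency(0.2, 0.8) # perfectly specular -> 0
#' incoherency(0.9, 0.9) # same extreme for both instructions -> 0.8
incoherency <- function(p_dangerous, p_harmless) {
  if (any(!is.finite(p_dangerous)) || any(p_dangerous < 0 | p_dangerous > 1) ||
        any(!is.finite(p_harmless)) || any(p_harmless < 0 | p_harmless > 1)) {
    abort("incoherency() inputs must lie in [0, 1]",
          class = "spidertune_range_error")
  }
  abs(p_dangerous + p_harmless - 1)
}

apply_statistic <- function(values, statistic) {
  switch(statistic,
    mean = mean(values),
    median = median(values),
    mmpd = mmpd(values),
    abort(paste0("unknown statistic: ", statistic),
          class = "spidertune_argument_error")
  )
}

#' Per-participant preference summaries
#'
#' Summarizes each participant's trial values per (feature, instruction),
#' pooling across orientations, under one or more summary statistics.
#'
#' @param x A [cohort()] object.
#' @param statistic One of `"mean"`, `"median"`, `"mmpd"`, or `"all"` for all
#'   three.
#' @return A tibble with columns `participant_id`, `feature`, `instruction`,
#'   `statistic`, `value`, `n_trials`.
#' @export
summarize_preferences <- function(x, statistic = c("mmpd", "mean", "median", "all")) {
  statistic <- match.arg(statistic)
  stats <- if (statistic == "all") c("mean", "median", "mmpd") else statistic
  long <- x$trials %>%
    tidyr::pivot_longer(dplyr::all_of(feature_names),
                        names_to = "feature", values_to = "value")
  expected <- tidyr::expand_grid(
    participant_id = x$participants$participant_id,
    instruction = instruction_levels
  )
  have <- long %>% distinct(participant_id, instruction)
  missing <- dplyr::anti_join(expected, have,
                              by = c("participant_id", "instruction"))
  if (nrow(missing) > 0) {
    warn(paste0("no trials for ", nrow(missing),
                " (participant, instruction) cell(s); summaries omitted"))
  }
  out <- purrr::map_dfr(stats, function(s) {
    long %>%
      group_by(participant_id, feature, instruction) %>%
      summarise(value = apply_statistic(value, s),
                n_trials = dplyr::n(), .groups = "drop") %>%
      mutate(statistic = s)
  })
  out %>%
    select(participant_id, feature, instruction, statistic, value, n_trials) %>%
    arrange(statistic, participant_id, feature, instruction)
}

#' Per-participant incoherency table
#'
#' Pairs each participant's dangerous and harmless summaries per feature and
#' computes the incoherency index \eqn{|p^D + p^H - 1|}.
#'
#' @param summaries Output of [summarize_preferences()] (any subset of
#'   statistics).
#' @return A tibble with columns `participant_id`, `feature`, `statistic`,
#'   `p_dangerous`, `p_harmless`, `incoherency`.
#' @export
incoherency_table <- function(summaries) {
  wide <- summaries %>%
    select(participant_id, feature, statistic, instruction, value) %>%
    tidyr::pivot_wider(names_from = instruction, values_from = value,
                       names_prefix = "p_")
  for (col in c("p_dangerous", "p_harmless")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  incomplete <- !stats::complete.cases(wide[c("p_dangerous", "p_harmless")])
  if (any(incomplete)) {
    warn(paste0(sum(incomplete),
                " participant-feature pair(s) lack one instruction; dropped"))
    wide <- wide[!incomplete, ]
  }
  wide %>%
    mutate(incoherency = incoherency(p_dangerous, p_harmless)) %>%
    arrange(statistic, participant_id, feature)
}

#' Grand-average table of preferences and incoherency
#'
#' Cross-participant grand means and SDs laid out as in the study's summary
#' table: one row per summary statistic over the six (feature, instruction)
#' cells, plus one incoherency row per feature (instruction `NA`).
#'
#' @param summaries Output of `summarize_preferences(x, "all")`; all three
#'   statistics must be present.
#' @param incoherencies Output of [incoherency_table()]; rows for
#'   `incoherency_statistic` are used for the incoherency row.
#' @param incoherency_statistic Which summary statistic feeds the
#'   incoherency row (default `"mmpd"`, the featured statistic).
#' @return A tibble with columns `statistic`, `feature`, `instruction`,
#'   `grand_mean`, `grand_sd`, `n`.
#' @export
grand_average_table <- function(summaries, incoherencies,
                                incoherency_statistic = "mmpd") {
  if (!all(c("mean", "median", "mmpd") %in% summaries$statistic)) {
    abort("grand_average_table() needs summaries for all three statistics",
          class = "spidertune_argument_error")
  }
  pref <- summaries %>%
    group_by(statistic, feature, instruction) %>%
    summarise(grand_mean = mean(value), grand_sd = sd(value),
              n = dplyr::n(), .groups = "drop")
  inc <- incoherencies %>%
    filter(statistic == incoherency_statistic) %>%
    group_by(feature) %>%
    summarise(grand_mean = mean(incoherency), grand_sd = sd(incoherency),
              n = dplyr::n(), .groups = "drop") %>%
    mutate(statistic = "incoherency", instruction = NA_character_)
  bind_rows(pref, inc) %>%
    mutate(
      statistic = factor(statistic,
                         levels = c("mean", "median", "mmpd", "incoherency")),
      feature = factor(feature, levels = feature_names)
    ) %>%
    arrange(statistic, feature, instruction) %>%
    mutate(statistic = as.character(statistic),
           feature = as.character(feature))
}

#' Orientation-stratified grand means
#'
#' The same per-participant summarization as [summarize_preferences()], but
#' restricted to each orientation stratum (4 trials per participant per
#' instruction per orientation under the complete design), then averaged
#' across participants.
#'
#' @param x A [cohort()] object.
#' @param statistic `"mean"`, `"median"` or `"mmpd"`.
#' @return A tibble with columns `feature`, `instruction`, `orientation`,
#'   `grand_mean`, `grand_sd`, `n`, `n_trials_per_participant`.
#' @export
orientation_summaries <- function(x, statistic = "mmpd") {
  statistic <- match.arg(statistic, c("mean", "median", "mmpd"))
  x$trials %>%
    tidyr::pivot_longer(dplyr::all_of(feature_names),
                        names_to = "feature", values_to = "value") %>%
    group_by(participant_id, feature, instruction, orientation) %>%
    summarise(value = apply_statistic(value, statistic),
              n_trials = dplyr::n(), .groups = "drop") %>%
    group_by(feature, instruction, orientation) %>%
    summarise(grand_mean = mean(value), grand_sd = sd(value),
              n = dplyr::n(),
              n_trials_per_participant = mean(n_trials), .groups = "drop")
}

#' Participant-by-variable preference matrix
#'
#' The wide table feeding the correlation and clustering stages: one row per
#' participant, columns `spq` plus the six summarized preferences named
#' `<feature>_<instruction>`.
#'
#' @param x A [cohort()] object.
#' @param statistic `"mean"`, `"median"` or `"mmpd"` (default).
#' @return A tibble with columns `participant_id`, `spq`,
#'   `hairiness_dangerous`, `hairiness_harmless`, `bodyleg_dangerous`,
#'   `bodyleg_harmless`, `locomotion_dangerous`, `locomotion_harmless`.
#' @export
preference_matrix <- function(x, statistic = "mmpd") {
  statistic <- match.arg(statistic, c("mean", "median", "mmpd"))
  wide <- summarize_preferences(x, statistic) %>%
    mutate(variable = paste(feature, instruction, sep = "_")) %>%
    select(participant_id, variable, value) %>%
    tidyr::pivot_wider(names_from = variable, values_from = value)
  x$participants %>%
    select(participant_id, spq) %>%
    left_join(wide, by = "participant_id") %>%
    select(participant_id, spq,
           hairiness_dangerous, hairiness_harmless,
           bodyleg_dangerous, bodyleg_harmless,
           locomotion_dangerous, locomotion_harmless)
}
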