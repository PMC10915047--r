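#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Exactly one data source must
#' be supplied: either a [generator_config()] (synthetic cohort) or the two
#' canonical CSV paths.
#'
#' @param generator A [generator_config()], or `NULL` when loading files.
#' @param trials_path,participants_path Canonical CSV paths, or `NULL` when
#'   generating.
#' @param statistic Summary statistic feeding the correlation, spline and
#'   clustering stages (default `"mmpd"`).
#' @param incoherency_statistic Statistic feeding the incoherency row of the
#'   grand-average table (default same as `statistic`).
#' @param clustering_criteria Character vector of [criterion_variables()]
#'   presets; default the six single (feature, instruction) criteria.
#' @param fit_incoherency Also fit the spline model to the per-feature
#'   incoherency indices (default `TRUE`).
#' @param grid_points Number of SPQ grid points for the band tables.
#' @param out_dir Output directory for the report files, or `NULL` to skip
#'   writing.
#' @param seed Master seed; stage-level seeds are derived from it by stage
#'   name, so adding a stage never perturbs earlier stages' draws. When a
#'   generator is supplied, its own seed is replaced by the derived
#'   simulate-stage seed.
#' @return A `spider_pipeline_config` list.
#' @export
pipeline_config <- function(generator = NULL,
                            trials_path = NULL, participants_path = NULL,
                            statistic = "mmpd",
                            incoherency_statistic = statistic,
                            clustering_criteria =
                              paste("single", rep(feature_names, each = 2),
                                    rep(instruction_levels, 3), sep = ":"),
                            fit_incoherency = TRUE,
                            grid_points = 101L,
                            out_dir = NULL,
                            seed = 1L) {
  from_files <- !is.null(trials_path) || !is.null(participants_path)
  if (is.null(generator) == !from_files) {
    abort("supply exactly one of `generator` or the CSV path pair",
          class = "spidertune_config_error")
  }
  if (from_files && (is.null(trials_path) || is.null(participants_path))) {
    abort("both trials_path and participants_path are required",
          class = "spidertune_config_error")
  }
  structure(
    list(generator = generator, trials_path = trials_path,
         participants_path = participants_path,
         statistic = match.arg(statistic, c("mean", "median", "mmpd")),
         incoherency_statistic = match.arg(incoherency_statistic,
                                           c("mean", "median", "mmpd")),
         clustering_criteria = clustering_criteria,
         fit_incoherency = isTRUE(fit_incoherency),
         grid_points = as.integer(grid_points),
         out_dir = out_dir, seed = as.integer(seed)),
    class = "spider_pipeline_config"
  )
}

## deterministic stage-keyed substream of the master seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", stage, "` failed: ", conditionMessage(e)),
          class = "spidertune_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (generate or load), design
#' validation, preference summarization (all three statistics) and
#' incoherency, the grand-average and orientation tables, the Spearman
#' correlation matrix, the six heteroskedastic spline fits (plus the three
#' incoherency fits when requested) with their band tables, and the
#' clustering criteria. Fully reproducible given the configuration: the
#' provenance block records the config hash, seed and package version, and
#' rerunning the same config yields an identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return A `spider_report` list: `provenance`, `cohort`, `validation`,
#'   `notes` (e.g. variance-floor events during clustering),
#'   `summaries`, `incoherency`, `grand_averages`, `orientation`,
#'   `correlation`, `spline_fits` (named list of `hetero_spline`), `bands`,
#'   `clusterings` (named list), `cluster_bic`, `cluster_labels`. When
#'   `config$out_dir` is set the tabular artifacts are also written there as
#'   CSV/JSON.
#' @export
#' @examples
#' cfg <- pipeline_config(generator = reference_config(), seed = 1)
#' rb <- run_pipeline(cfg)
#' rb$grand_averages
run_pipeline <- function(config) {
  if (!inherits(config, "spider_pipeline_config")) {
    abort("config must be a pipeline_config()",
          class = "spidertune_config_error")
  }
  coh <- with_stage("data_model", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- stage_seed(config$seed, "simulate")
      generate_cohort(gen)
    } else {
      load_cohort(config$trials_path, config$participants_path)
    }
  })
  validation <- with_stage("validate", validate_design(coh))
  summaries <- with_stage("summarize", summarize_preferences(coh, "all"))
  inc <- with_stage("summarize", incoherency_table(summaries))
  grand <- with_stage("summarize",
                      grand_average_table(summaries, inc,
                                          config$incoherency_statistic))
  orient <- with_stage("summarize",
                       orientation_summaries(coh, config$statistic))
  pm <- with_stage("correlate", preference_matrix(coh, config$statistic))
  corr <- with_stage("correlate", spearman_matrix(pm))

  responses <- paste(rep(feature_names, each = 2),
                     rep(instruction_levels, 3), sep = "_")
  fits <- with_stage("splinefit", {
    out <- lapply(responses, function(v) fit_hetero_spline(pm, v))
    names(out) <- responses
    if (config$fit_incoherency) {
      inc_wide <- inc %>%
        filter(statistic == config$statistic) %>%
        select(participant_id, feature, incoherency) %>%
        tidyr::pivot_wider(names_from = feature, values_from = incoherency,
                           names_prefix = "incoherency_") %>%
        left_join(coh$participants %>% select(participant_id, spq),
                  by = "participant_id")
      for (f in feature_names) {
        v <- paste0("incoherency_", f)
        out[[v]] <- fit_hetero_spline(inc_wide, v)
      }
    }
    out
  })
  bands <- with_stage("splinefit", {
    purrr::imap_dfr(fits, function(fit, nm) {
      grid <- seq(fit$boundary_knots[1], fit$boundary_knots[2],
                  length.out = config$grid_points)
      predict_bands(fit, grid) %>% mutate(response = nm, .before = 1)
    })
  })
  clusterings <- with_stage("cluster", {
    # floor warnings are routine for tight single-variable clusters; record
    # them in the validation notes instead of raising one per criterion
    floor_notes <- character(0)
    out <- lapply(config$clustering_criteria, function(cr) {
      vars <- criterion_variables(cr)
      withCallingHandlers(
        select_clusters(pm[c("participant_id", vars)]),
        warning = function(w) {
          if (grepl("variance floor", conditionMessage(w))) {
            floor_notes <<- c(floor_notes,
                              paste0(cr, ": ", conditionMessage(w)))
            invokeRestart("muffleWarning")
          }
        }
      )
    })
    names(out) <- config$clustering_criteria
    attr(out, "floor_notes") <- floor_notes
    out
  })
  floor_notes <- attr(clusterings, "floor_notes")
  attr(clusterings, "floor_notes") <- NULL
  cluster_bic <- purrr::imap_dfr(clusterings, function(cl, nm) {
    cl$bic %>% mutate(criterion = nm, .before = 1)
  })
  cluster_labels <- purrr::imap_dfr(clusterings, function(cl, nm) {
    tidy(cl) %>% mutate(criterion = nm, selected_k = cl$selected_k,
                        .before = 1)
  })

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  bundle <- structure(
    list(
      provenance = list(
        config_hash = rlang::hash(cfg_for_hash),
        seed = config$seed,
        statistic = config$statistic,
        package_version = as.character(packageVersion("spidertune"))
      ),
      config = config,
      cohort = coh,
      validation = validation,
      notes = list(variance_floor = floor_notes),
      summaries = summaries,
      incoherency = inc,
      grand_averages = grand,
      orientation = orient,
      correlation = corr,
      spline_fits = fits,
      bands = bands,
      clusterings = clusterings,
      cluster_bic = cluster_bic,
      cluster_labels = cluster_labels
    ),
    class = "spider_report"
  )
  if (!is.null(config$out_dir)) {
    with_stage("report", write_report(bundle, config$out_dir))
  }
  bundle
}

#' @export
print.spider_report <- function(x, ...) {
  cat("<spider_report> seed", x$provenance$seed,
      "| config", substr(x$provenance$config_hash, 1, 8),
      "| spidertune", x$provenance$package_version, "\n")
  cat(nrow(x$cohort$participants), "participants,",
      length(x$spline_fits), "spline fits,",
      length(x$clusterings), "clusterings\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes the tabular artifacts of a `spider_report` as CSV (summaries,
#' incoherency, grand averages, orientation table, long-format correlation
#' matrix, bands, cluster BIC and labels, canonical cohort CSVs) and JSON
#' (validation report, spline fits, provenance). Files are written to a
#' temporary name and renamed into place; on failure all files written so
#' far are removed.
#'
#' @param bundle A `spider_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(fname, writer) {
    final <- file.path(out_dir, fname)
    tmp <- paste0(final, ".tmp")
    writer(tmp)
    file.rename(tmp, final)
    written <<- c(written, final)
  }
  json_opts <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  tryCatch({
    tp <- file.path(out_dir, "trials.csv")
    pp <- file.path(out_dir, "participants.csv")
    save_cohort(bundle$cohort, paste0(tp, ".tmp"), paste0(pp, ".tmp"))
    file.rename(paste0(tp, ".tmp"), tp)
    file.rename(paste0(pp, ".tmp"), pp)
    written <- c(written, tp, pp)
    put("validation.json", function(p) {
      json_opts(list(design = bundle$validation, notes = bundle$notes), p)
    })
    put("preference_summaries.csv", function(p) {
      readr::write_csv(bundle$summaries, p)
    })
    put("incoherency.csv", function(p) readr::write_csv(bundle$incoherency, p))
    put("grand_averages.csv", function(p) {
      readr::write_csv(bundle$grand_averages, p)
    })
    put("orientation_summaries.csv", function(p) {
      readr::write_csv(bundle$orientation, p)
    })
    put("correlation_matrix.csv", function(p) {
      readr::write_csv(tidy(bundle$correlation), p)
    })
    put("spline_fits.json", function(p) {
      json_opts(lapply(bundle$spline_fits, function(f) {
        list(response = f$response, beta = as.list(f$beta),
             gamma = as.list(f$gamma),
             internal_knots = f$internal_knots,
             boundary_knots = f$boundary_knots,
             loglik = f$loglik, converged = f$converged, n = f$n)
      }), p)
    })
    put("bands.csv", function(p) readr::write_csv(bundle$bands, p))
    put("cluster_bic.csv", function(p) readr::write_csv(bundle$cluster_bic, p))
    put("clusters.csv", function(p) readr::write_csv(bundle$cluster_labels, p))
    put("provenance.json", function(p) json_opts(bundle$provenance, p))
  }, error = function(e) {
    unlink(written)
    unlink(file.path(out_dir, paste0(basename(written), ".tmp")))
    abort(paste0("failed writing report: ", conditionMessage(e)),
          parent = e)
  })
  invisible(written)
}
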