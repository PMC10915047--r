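#' Spearman correlation matrix of SPQ and preference summaries
#'
#' Pairwise Spearman rank correlations (average ranks for ties) over the
#' participant-by-variable table, with two-sided p-values from the
#' t-approximation on n - 2 degrees of freedom. Rows with any missing value
#' are dropped listwise. P-values are reported raw (no multiple-testing
#' correction), matching the descriptive use of the matrix.
#'
#' @param data A data frame of participants by numeric variables, e.g.
#'   [preference_matrix()] output; a `participant_id` column is ignored.
#' @param exact Use the exact null distribution for the p-values via
#'   [stats::cor.test()] (valid only for small samples without ties;
#'   default `FALSE`).
#' @return A `spider_corr` object: list with `variables`, matrices `rho` and
#'   `p` (diagonal p is `NA`), and `n`, the number of complete rows.
#' @export
spearman_matrix <- function(data, exact = FALSE) {
  data <- as_tibble(data)
  data <- data[setdiff(names(data), "participant_id")]
  if (!all(vapply(data, is.numeric, logical(1)))) {
    abort("spearman_matrix() needs numeric columns only (besides participant_id)",
          class = "spidertune_argument_error")
  }
  data <- data[stats::complete.cases(data), ]
  n <- nrow(data)
  if (n < 4) {
    abort("spearman_matrix() needs at least 4 complete rows",
          class = "spidertune_argument_error")
  }
  vars <- names(data)
  constant <- vapply(data, function(col) var(col) == 0, logical(1))
  if (any(constant)) {
    warn(paste0("constant column(s), correlations undefined: ",
                paste(vars[constant], collapse = ", ")))
  }
  m <- as.matrix(data)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  p <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(vars, vars))
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (i >= j) next
      r <- rho[i, j]
      if (is.na(r)) next
      if (exact) {
        p[i, j] <- suppressWarnings(
          cor.test(m[, i], m[, j], method = "spearman",
                   exact = TRUE)$p.value)
      } else if (abs(r) >= 1) {
        p[i, j] <- .Machine$double.xmin
      } else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p[i, j] <- 2 * pt(-abs(tstat), df = n - 2)
      }
      p[j, i] <- p[i, j]
    }
  }
  structure(list(variables = vars, rho = rho, p = p, n = n),
            class = "spider_corr")
}

#' @export
print.spider_corr <- function(x, ...) {
  cat("<spider_corr> Spearman correlations over", x$n, "complete rows\n")
  print(round(x$rho, 2))
  invisible(x)
}

#' @rdname spearman_matrix
#' @param x A `spider_corr` object.
#' @param ... Unused.
#' @return `tidy()`: a long tibble `var1, var2, rho, p_value, n` with one row
#'   per unordered variable pair.
#' @export
tidy.spider_corr <- function(x, ...) {
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(
    var1 = x$variables[pairs[, 1]],
    var2 = x$variables[pairs[, 2]],
    rho = x$rho[pairs],
    p_value = x$p[pairs],
    n = x$n
  )
}

#' @rdname spearman_matrix
#' @param object A `spider_corr` object.
#' @return `autoplot()`: a ggplot correlation-matrix panel (circle area and
#'   colour encode the correlation; lower triangle prints the p-values).
#' @export
autoplot.spider_corr <- function(object, ...) {
  td <- tidy(object)
  lv <- object$variables
  up <- td %>% mutate(row = match(var1, lv), col = match(var2, lv))
  lo <- td %>% mutate(row = match(var2, lv), col = match(var1, lv))
  diag_df <- tibble(row = seq_along(lv), col = seq_along(lv), rho = 1)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = bind_rows(up %>% select(row, col, rho), diag_df),
      ggplot2::aes(x = .data$col, y = .data$row, size = abs(.data$rho),
                   colour = .data$rho)
    ) +
    ggplot2::geom_text(
      data = lo,
      ggplot2::aes(x = .data$col, y = .data$row,
                   label = sprintf("%.3f", .data$p_value)),
      size = 2.7
    ) +
    ggplot2::scale_colour_gradient2(low = "#b2182b", mid = "white",
                                    high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::scale_size_area(max_size = 10, limits = c(0, 1), guide = "none") +
    ggplot2::scale_x_continuous(breaks = seq_along(lv), labels = lv,
                                position = "top") +
    ggplot2::scale_y_reverse(breaks = seq_along(lv), labels = lv) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 0))
}

#' Power of the test of zero correlation
#'
#' Monte-Carlo power of the two-sided test of \eqn{H_0: \rho = 0} at level
#' `alpha` when samples of size `n` are drawn from a bivariate normal with
#' true correlation `rho_true`, together with the closed-form Fisher-z
#' approximation
#' \eqn{\Phi(\sqrt{n-3}\,\mathrm{atanh}(\rho) - z_{1-\alpha/2})} as an
#' analytic cross-check. The simulated test is the conventional Pearson
#' t-test; set `method = "spearman"` to study the rank-based variant.
#'
#' @param rho_true True correlation in (-1, 1).
#' @param n Sample size per replicate (>= 4).
#' @param alpha Significance level (default 0.05).
#' @param reps Number of Monte-Carlo replicates (default 20000).
#' @param seed Integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `power` (rejection fraction), `se`
#'   (binomial Monte-Carlo standard error), `power_fisher_z`, plus the
#'   arguments.
#' @export
#' @examples
#' correlation_power(0.4, n = 56, reps = 2000, seed = 1)
correlation_power <- function(rho_true, n, alpha = 0.05, reps = 20000L,
                              seed = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (n < 4) abort("n must be >= 4", class = "spidertune_argument_error")
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)", class = "spidertune_argument_error")
  }
  if (abs(rho_true) >= 1) {
    abort("rho_true must lie in (-1, 1)", class = "spidertune_argument_error")
  }
  crit <- qt(1 - alpha / 2, df = n - 2)
  rej <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      z1 <- rnorm(n)
      z2 <- rnorm(n)
      x <- z1
      y <- rho_true * z1 + sqrt(1 - rho_true^2) * z2
      r <- if (method == "spearman") {
        cor(rank(x), rank(y))
      } else {
        cor(x, y)
      }
      abs(r * sqrt((n - 2) / (1 - r^2))) > crit
    }, logical(1))
  },
  .rng_kind = "Mersenne-Twister",
  .rng_normal_kind = "Inversion",
  .rng_sample_kind = "Rejection")
  power <- mean(rej)
  fisher <- pnorm(sqrt(n - 3) * atanh(abs(rho_true)) - qnorm(1 - alpha / 2)) +
    pnorm(-sqrt(n - 3) * atanh(abs(rho_true)) - qnorm(1 - alpha / 2))
  tibble(
    power = power,
    se = sqrt(power * (1 - power) / reps),
    power_fisher_z = fisher,
    rho_true = rho_true, n = n, alpha = alpha, reps = reps, method = method
  )
}

#' Recruitment accounting
#'
#' Arithmetic of the analyzed sample: recruited minus screening exclusions
#' minus drop-outs, and the share of women among those analyzed.
#'
#' @param recruited Participants recruited.
#' @param excluded_screen Participants excluded by the psychopathology
#'   screen.
#' @param dropouts Participants who abandoned the session.
#' @param n_women Women among the analyzed sample (optional).
#' @return A one-row tibble: `n_analyzed` and, when `n_women` is given,
#'   `pct_women` (percentage of the analyzed sample).
#' @export
#' @examples
#' sample_flow(recruited = 56, excluded_screen = 10, dropouts = 1, n_women = 33)
sample_flow <- function(recruited, excluded_screen = 0, dropouts = 0,
                        n_women = NULL) {
  n_analyzed <- recruited - excluded_screen - dropouts
  if (n_analyzed < 0) {
    abort("exclusions exceed the recruited count",
          class = "spidertune_argument_error")
  }
  out <- tibble(recruited = recruited, excluded_screen = excluded_screen,
                dropouts = dropouts, n_analyzed = n_analyzed)
  if (!is.null(n_women)) {
    out$n_women <- n_women
    out$pct_women <- 100 * n_women / n_analyzed
  }
  out
}
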