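#' Natural cubic spline basis with intercept
#'
#' The regression basis used for both the conditional mean and the
#' log-variance: an intercept column plus the natural cubic spline basis of
#' the SPQ score. With one internal knot (the default model: the empirical
#' median of SPQ) the basis has 3 columns in total. Natural boundary
#' conditions make every fitted curve linear at and beyond the boundary
#' knots, so prediction outside the observed SPQ range extrapolates
#' linearly.
#'
#' @param x Numeric vector of SPQ scores at which to evaluate the basis.
#' @param internal_knots Knot location(s), strictly inside the boundary
#'   range.
#' @param boundary_knots Length-2 range; defaults to `range(x)`.
#' @return A numeric matrix with `length(x)` rows; first column is the
#'   intercept.
#' @export
ncs_basis <- function(x, internal_knots, boundary_knots = range(x)) {
  if (any(internal_knots <= boundary_knots[1]) ||
        any(internal_knots >= boundary_knots[2])) {
    abort("internal knots must lie strictly inside the boundary knots",
          class = "spidertune_argument_error")
  }
  ns <- splines::ns(x, knots = internal_knots,
                    Boundary.knots = boundary_knots)
  cbind(`(Intercept)` = 1, unclass(ns)[, , drop = FALSE])
}

neg_loglik_hetero <- function(theta, Bm, Bv, y) {
  pm <- ncol(Bm)
  beta <- theta[seq_len(pm)]
  gamma <- theta[-seq_len(pm)]
  mu <- drop(Bm %*% beta)
  lv <- drop(Bv %*% gamma)
  r <- y - mu
  0.5 * sum(log(2 * pi) + lv + r^2 * exp(-lv))
}

neg_loglik_hetero_grad <- function(theta, Bm, Bv, y) {
  pm <- ncol(Bm)
  beta <- theta[seq_len(pm)]
  gamma <- theta[-seq_len(pm)]
  mu <- drop(Bm %*% beta)
  lv <- drop(Bv %*% gamma)
  r <- y - mu
  w <- exp(-lv)
  gbeta <- -drop(crossprod(Bm, r * w))
  ggamma <- -0.5 * drop(crossprod(Bv, r^2 * w - 1))
  c(gbeta, ggamma)
}

#' Heteroskedastic normal spline regression on SPQ
#'
#' Fits the location-scale model
#' \deqn{y_i \sim N(\mu(s_i), \sigma^2(s_i)), \quad
#'   \mu(s) = B(s)\beta, \quad \log \sigma^2(s) = B(s)\gamma,}
#' where \eqn{B(s)} is the natural cubic spline basis of the SPQ score with
#' one internal knot at the empirical median of SPQ (by default) and
#' boundary knots at the observed SPQ range. Both coefficient vectors are
#' estimated jointly by maximum likelihood (BFGS on the analytic gradient),
#' initialized deterministically from the ordinary least-squares fit
#' (\eqn{\beta} = OLS coefficients; \eqn{\gamma} = log OLS residual variance
#' in the intercept, 0 elsewhere), so the fit is reproducible with no
#' randomness.
#'
#' Responses are preference summaries in \eqn{[0,1]} but the likelihood is
#' an unbounded normal; no truncation correction is applied (see the
#' methods vignette for this caveat).
#'
#' @param data A data frame with the score and response columns, e.g. a
#'   [preference_matrix()].
#' @param response Response column, as a bare name or string.
#' @param score Score column (default `spq`), as a bare name or string.
#' @param internal_knots Internal knot location(s); default the empirical
#'   median of the score.
#' @param heteroskedastic If `FALSE`, the log-variance is restricted to a
#'   constant (intercept-only \eqn{\gamma}), i.e. homoskedastic spline
#'   regression.
#' @param max_iter,reltol Optimizer budget and relative log-likelihood
#'   convergence tolerance.
#' @return A `hetero_spline` object with elements `beta`, `gamma`,
#'   `internal_knots`, `boundary_knots`, `loglik`, `loglik_init`,
#'   `converged`, `n`, `heteroskedastic`, and the fitting data. Use
#'   [predict_bands()], [tidy()], [glance()] and [autoplot()] on it.
#' @export
#' @examples
#' pm <- preference_matrix(generate_cohort(reference_config(seed = 2)))
#' fit <- fit_hetero_spline(pm, hairiness_dangerous)
#' glance(fit)
fit_hetero_spline <- function(data, response, score = spq,
                              internal_knots = NULL,
                              heteroskedastic = TRUE,
                              max_iter = 500L, reltol = 1e-12) {
  response <- tidyselect_column(data, enquo(response), "response")
  score <- tidyselect_column(data, enquo(score), "score")
  y <- data[[response]]
  s <- data[[score]]
  keep <- is.finite(y) & is.finite(s)
  y <- y[keep]
  s <- s[keep]
  n <- length(y)
  if (n < 10) {
    abort("fit_hetero_spline() needs at least 10 observations",
          class = "spidertune_argument_error")
  }
  if (length(unique(s)) < 3) {
    abort("fit_hetero_spline() needs at least 3 distinct score values",
          class = "spidertune_fit_error")
  }
  boundary_knots <- range(s)
  if (is.null(internal_knots)) internal_knots <- median(s)
  Bm <- ncs_basis(s, internal_knots, boundary_knots)
  if (qr(Bm)$rank < ncol(Bm)) {
    abort("rank-deficient spline basis at the observed scores",
          class = "spidertune_fit_error")
  }
  Bv <- if (heteroskedastic) Bm else Bm[, 1, drop = FALSE]

  ## deterministic initialization from OLS
  beta0 <- drop(qr.coef(qr(Bm), y))
  resid0 <- y - drop(Bm %*% beta0)
  gamma0 <- c(log(max(mean(resid0^2), 1e-12)), rep(0, ncol(Bv) - 1))
  theta0 <- c(beta0, gamma0)
  ll_init <- -neg_loglik_hetero(theta0, Bm, Bv, y)

  opt <- optim(theta0, neg_loglik_hetero, gr = neg_loglik_hetero_grad,
               Bm = Bm, Bv = Bv, y = y, method = "BFGS",
               control = list(maxit = max_iter, reltol = reltol))
  ## Newton polish: BFGS stops on relative objective change; a few damped
  ## Newton steps push the gradient max-norm to the stated tolerance
  par <- opt$par
  val <- opt$value
  grad <- neg_loglik_hetero_grad(par, Bm, Bv, y)
  gtol <- 1e-6
  for (it in seq_len(50)) {
    if (max(abs(grad)) < gtol) break
    H <- stats::optimHess(par, neg_loglik_hetero, neg_loglik_hetero_grad,
                          Bm = Bm, Bv = Bv, y = y)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    improved <- FALSE
    for (damp in 2^-(0:10)) {
      cand <- par - damp * step
      cval <- neg_loglik_hetero(cand, Bm, Bv, y)
      cgrad <- neg_loglik_hetero_grad(cand, Bm, Bv, y)
      if (is.finite(cval) &&
            (cval < val || max(abs(cgrad)) < max(abs(grad)))) {
        par <- cand
        val <- cval
        grad <- cgrad
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  opt$par <- par
  opt$value <- val
  converged <- opt$convergence == 0 && max(abs(grad)) < gtol
  ll <- -opt$value
  if (ll < ll_init - 1e-8) {
    # BFGS never accepts an uphill step in the objective; guard anyway
    opt$par <- theta0
    ll <- ll_init
    converged <- FALSE
  }
  pm <- ncol(Bm)
  structure(
    list(
      beta = setNames(opt$par[seq_len(pm)], colnames(Bm)),
      gamma = setNames(opt$par[-seq_len(pm)], colnames(Bv)),
      internal_knots = internal_knots,
      boundary_knots = boundary_knots,
      loglik = ll,
      loglik_init = ll_init,
      converged = converged,
      n = n,
      heteroskedastic = heteroskedastic,
      response = response,
      score = score,
      data = tibble(score = s, y = y)
    ),
    class = "hetero_spline"
  )
}

tidyselect_column <- function(data, quo, what) {
  expr <- quo_get_expr(quo)
  nm <- if (is.symbol(expr) && as_string(expr) %in% names(data)) {
    as_string(expr)
  } else if (is.character(expr)) {
    expr
  } else {
    val <- tryCatch(eval_tidy(quo), error = function(e) NULL)
    if (is.character(val) && length(val) == 1) val else as_name(quo)
  }
  if (!nm %in% names(data)) {
    abort(paste0(what, " column `", nm, "` not found in data"),
          class = "spidertune_argument_error")
  }
  nm
}

spline_eval <- function(fit, s, which = c("mean", "logvar")) {
  which <- match.arg(which)
  B <- ncs_basis(s, fit$internal_knots, fit$boundary_knots)
  if (which == "mean") {
    drop(B %*% fit$beta)
  } else {
    Bv <- if (fit$heteroskedastic) B else B[, 1, drop = FALSE]
    drop(Bv %*% fit$gamma)
  }
}

#' Fitted mean and SD curves of a heteroskedastic spline fit
#'
#' @param object A `hetero_spline` fit.
#' @param newdata Optional data frame with the score column; default the
#'   fitting data.
#' @param ... Unused.
#' @return `augment()`: the data with `.mu` and `.sigma` columns appended.
#' @export
augment.hetero_spline <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$score else newdata[[object$score]]
  out <- if (is.null(newdata)) object$data else as_tibble(newdata)
  out$.mu <- spline_eval(object, s, "mean")
  out$.sigma <- sqrt(exp(spline_eval(object, s, "logvar")))
  out
}

#' @rdname fit_hetero_spline
#' @param x,object A `hetero_spline` fit.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient (`part` is `"mean"` or
#'   `"logvar"`); `glance()`: a one-row model summary.
#' @export
tidy.hetero_spline <- function(x, ...) {
  bind_rows(
    tibble(part = "mean", term = names(x$beta), estimate = unname(x$beta)),
    tibble(part = "logvar", term = names(x$gamma), estimate = unname(x$gamma))
  )
}

#' @rdname fit_hetero_spline
#' @export
glance.hetero_spline <- function(x, ...) {
  k <- length(x$beta) + length(x$gamma)
  tibble(
    n = x$n,
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * k,
    BIC = -2 * x$loglik + k * log(x$n),
    n_par = k,
    converged = x$converged,
    heteroskedastic = x$heteroskedastic,
    response = x$response
  )
}

#' @export
print.hetero_spline <- function(x, ...) {
  cat("<hetero_spline> response:", x$response, "| n =", x$n,
      "| logLik =", format(x$loglik, digits = 6),
      "| converged:", x$converged, "\n")
  cat("internal knot(s):", paste(x$internal_knots, collapse = ", "),
      "| boundary:", paste(x$boundary_knots, collapse = "-"), "\n")
  invisible(x)
}

#' Normal-quantile bands of a heteroskedastic spline fit
#'
#' Evaluates the fitted mean together with the quartile band
#' (\eqn{\mu \mp 0.6745\,\sigma}) and the decile band
#' (\eqn{\mu \mp 1.2816\,\sigma}) of the fitted normal distribution on a
#' score grid. Grid points outside the boundary knots are computed by the
#' natural spline's linear extrapolation and flagged.
#'
#' @param fit A converged `hetero_spline` fit.
#' @param grid Numeric vector of score values; default 101 equally spaced
#'   points over the boundary range.
#' @return A tibble `score, mean, q1, q3, d1, d9, extrapolated`.
#' @export
predict_bands <- function(fit, grid = NULL) {
  if (!fit$converged) {
    warn("predict_bands() called on a fit flagged as not converged")
  }
  if (is.null(grid)) {
    grid <- seq(fit$boundary_knots[1], fit$boundary_knots[2], length.out = 101)
  }
  mu <- spline_eval(fit, grid, "mean")
  sigma <- sqrt(exp(spline_eval(fit, grid, "logvar")))
  zq <- qnorm(0.75)
  zd <- qnorm(0.9)
  tibble(
    score = grid,
    mean = mu,
    q1 = mu - zq * sigma,
    q3 = mu + zq * sigma,
    d1 = mu - zd * sigma,
    d9 = mu + zd * sigma,
    extrapolated = grid < fit$boundary_knots[1] | grid > fit$boundary_knots[2]
  )
}

#' @rdname predict_bands
#' @param object A `hetero_spline` fit.
#' @param labels Optional per-point cluster labels (e.g. from
#'   [select_clusters()]) used to colour the observations.
#' @param ... Unused.
#' @return `autoplot()`: a ggplot of the observations, fitted mean, and the
#'   quartile/decile bands.
#' @export
autoplot.hetero_spline <- function(object, labels = NULL, ...) {
  bands <- predict_bands(object)
  pts <- object$data
  pts$label <- if (is.null(labels)) "all" else as.factor(labels)
  p <- ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = bands,
                         ggplot2::aes(x = .data$score, ymin = .data$d1,
                                      ymax = .data$d9),
                         fill = "grey85") +
    ggplot2::geom_ribbon(data = bands,
                         ggplot2::aes(x = .data$score, ymin = .data$q1,
                                      ymax = .data$q3),
                         fill = "grey65") +
    ggplot2::geom_line(data = bands,
                       ggplot2::aes(x = .data$score, y = .data$mean),
                       linewidth = 0.8) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$score, y = .data$y,
                                     colour = .data$label)) +
    ggplot2::labs(x = "SPQ score", y = object$response) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::guides(colour = "none") else p
}
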