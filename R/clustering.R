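#' Column-wise standardization
#'
#' Centers and scales every numeric column to mean 0 and SD 1 (n - 1
#' denominator). A `participant_id` column, if present, is carried through
#' untouched.
#'
#' @param data A data frame of numeric columns (plus optional
#'   `participant_id`).
#' @return A tibble of the same shape with standardized numeric columns.
#' @export
standardize <- function(data) {
  data <- as_tibble(data)
  num <- setdiff(names(data), "participant_id")
  for (nm in num) {
    v <- data[[nm]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      abort(paste0("standardize(): column `", nm, "` has zero variance"),
            class = "spidertune_argument_error")
    }
    data[[nm]] <- (v - mean(v)) / s
  }
  data
}

#' Centroid-linkage agglomerative clustering
#'
#' Hierarchical agglomeration in which the distance between two clusters is
#' the Euclidean distance between their centroids. Implemented via
#' [stats::hclust()] with `method = "centroid"` on squared Euclidean
#' distances; merge heights are reported back on the Euclidean scale.
#' Centroid linkage can produce height inversions (a merge lower than an
#' earlier one); these are permitted and flagged.
#'
#' @param z A numeric matrix or data frame of points (rows) to cluster,
#'   typically [standardize()]d; a `participant_id` column is dropped.
#' @return A `centroid_tree` object: list with the underlying `hclust`
#'   object, `height` (Euclidean centroid merge distances, in merge order),
#'   `merge`, `n`, and `inversions` (logical).
#' @export
centroid_linkage <- function(z) {
  if (is.data.frame(z)) {
    z <- as.matrix(as_tibble(z)[setdiff(names(z), "participant_id")])
  }
  if (nrow(z) < 2) {
    abort("centroid_linkage() needs at least 2 rows",
          class = "spidertune_argument_error")
  }
  h <- hclust(dist(z)^2, method = "centroid")
  height <- sqrt(pmax(h$height, 0))
  structure(
    list(hclust = h, merge = h$merge, height = height, n = nrow(z),
         inversions = any(diff(height) < 0)),
    class = "centroid_tree"
  )
}

#' @export
print.centroid_tree <- function(x, ...) {
  cat("<centroid_tree> ", x$n, " points, ", length(x$height), " merges",
      if (x$inversions) " (height inversions present)", "\n", sep = "")
  invisible(x)
}

#' Cut a linkage tree into k clusters
#'
#' Labels are obtained by undoing the last `k - 1` merges; with height
#' inversions the cut is by merge order, not by height.
#'
#' @param tree A [centroid_linkage()] result.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return An integer vector of cluster labels in `1..k`.
#' @export
cut_tree <- function(tree, k) {
  if (k < 1 || k > tree$n) {
    abort("k must lie in 1..n", class = "spidertune_argument_error")
  }
  unname(cutree(tree$hclust, k = k))
}

#' Gaussian BIC of a hard partition
#'
#' Scores a partition under the classification likelihood of a Gaussian
#' model: each point contributes its cluster's log mixing proportion plus
#' the log-density of a multivariate normal with cluster-specific mean and
#' diagonal (or spherical) maximum-likelihood covariance (n-denominator
#' variances),
#' \deqn{\log L = \sum_i \big[\log \pi_{c(i)} +
#'   \log \phi(x_i;\, \mu_{c(i)}, \Sigma_{c(i)})\big],}
#' with \eqn{\pi_k = n_k / n}. The mixing proportions are essential: without
#' them, splitting any cluster in two always raises the density term faster
#' than the `m log(n)` penalty grows, so BIC would degenerate to the largest
#' candidate k.
#'
#' Per-dimension variances are floored at `1e-3` times the marginal ML
#' variance of that dimension (absolute floor `1e-6` for constant columns).
#' A floor on the *data scale* is what keeps singleton or near-duplicate
#' clusters from acting as infinitely sharp density spikes — the classic
#' Gaussian-likelihood degeneracy — while leaving any genuinely compact
#' cluster untouched.
#'
#' The parameter count is `m = k * 2d + (k - 1)` for diagonal and
#' `m = k * (d + 1) + (k - 1)` for spherical covariance (means, variances,
#' and free mixing proportions), and `BIC = -2 logL + m log(n)`; smaller is
#' better.
#'
#' @param z Numeric matrix or data frame of points (a `participant_id`
#'   column is dropped).
#' @param labels Cluster assignment per row; every cluster must be
#'   non-empty.
#' @param covariance `"diagonal"` (default) or `"spherical"`.
#' @return A scalar BIC value, with attributes `logLik` and `n_par`.
#' @export
bic_for_partition <- function(z, labels, covariance = c("diagonal", "spherical")) {
  covariance <- match.arg(covariance)
  if (is.data.frame(z)) {
    z <- as.matrix(as_tibble(z)[setdiff(names(z), "participant_id")])
  }
  if (length(labels) != nrow(z)) {
    abort("labels must have one entry per row of z",
          class = "spidertune_argument_error")
  }
  groups <- split(seq_len(nrow(z)), labels)
  if (any(lengths(groups) == 0)) {
    abort("every cluster must be non-empty",
          class = "spidertune_argument_error")
  }
  d <- ncol(z)
  n <- nrow(z)
  marg_var <- colMeans(sweep(z, 2, colMeans(z))^2) # per-dimension ML variance
  floor_var <- pmax(1e-3 * marg_var, 1e-6)
  if (covariance == "spherical") floor_var <- rep(mean(floor_var), d)
  ll <- 0
  floored <- FALSE
  for (idx in groups) {
    xk <- z[idx, , drop = FALSE]
    mk <- colMeans(xk)
    ctr <- sweep(xk, 2, mk)
    vk <- colMeans(ctr^2) # ML variance, n denominator
    if (covariance == "spherical") vk <- rep(mean(vk), d)
    if (any(vk < floor_var)) {
      floored <- TRUE
      vk <- pmax(vk, floor_var)
    }
    pi_k <- length(idx) / n
    ll <- ll + length(idx) * log(pi_k) +
      sum(vapply(seq_len(d), function(j) {
        sum(stats::dnorm(xk[, j], mk[j], sqrt(vk[j]), log = TRUE))
      }, numeric(1)))
  }
  if (floored) {
    warn("variance floor hit for at least one cluster dimension")
  }
  k <- length(groups)
  m <- (if (covariance == "diagonal") k * 2 * d else k * (d + 1)) + (k - 1)
  structure(-2 * ll + m * log(n), logLik = ll, n_par = m)
}

#' Cluster participants with BIC-selected centroid linkage
#'
#' The full clustering stage: standardize the chosen variables, build the
#' centroid-linkage tree, cut it at each candidate number of clusters, score
#' each partition with the Gaussian [bic_for_partition()], and keep the
#' partition minimizing BIC. BIC ties are broken toward fewer clusters.
#'
#' @param data Participants-by-variables data frame (numeric columns;
#'   optional `participant_id` carried into the labels).
#' @param candidate_k Candidate cluster counts (default `2:4`).
#' @param covariance Covariance structure for the BIC, see
#'   [bic_for_partition()].
#' @return A `spider_clustering` object: list with `variables`, `tree`,
#'   `bic` (tibble `k`, `bic`), `selected_k`, `labels`, and
#'   `participant_id`. [tidy()] gives per-participant labels, [glance()] a
#'   one-row summary.
#' @export
#' @examples
#' pm <- preference_matrix(generate_cohort(reference_config(seed = 3)))
#' cl <- select_clusters(pm[c("participant_id", "hairiness_dangerous")])
#' glance(cl)
select_clusters <- function(data, candidate_k = 2:4,
                            covariance = c("diagonal", "spherical")) {
  covariance <- match.arg(covariance)
  data <- as_tibble(data)
  ids <- if ("participant_id" %in% names(data)) {
    data$participant_id
  } else {
    as.character(seq_len(nrow(data)))
  }
  vars <- setdiff(names(data), "participant_id")
  if (nrow(data) < 8) {
    abort("select_clusters() needs at least 8 participants",
          class = "spidertune_argument_error")
  }
  z <- standardize(data[vars])
  tree <- centroid_linkage(z)
  cuts <- lapply(candidate_k, function(k) cut_tree(tree, k))
  floored_k <- integer(0)
  bics <- vapply(seq_along(cuts), function(i) {
    withCallingHandlers(
      as.numeric(bic_for_partition(z, cuts[[i]], covariance)),
      warning = function(w) {
        if (grepl("variance floor", conditionMessage(w))) {
          floored_k <<- c(floored_k, candidate_k[i])
          invokeRestart("muffleWarning")
        }
      }
    )
  }, numeric(1))
  if (length(floored_k) > 0) {
    warn(paste0("variance floor hit for candidate k = ",
                paste(floored_k, collapse = ", ")))
  }
  best <- which.min(bics) # first minimum: ties go to the smaller k
  structure(
    list(
      variables = vars,
      tree = tree,
      bic = tibble(k = as.integer(candidate_k), bic = bics),
      selected_k = as.integer(candidate_k[best]),
      labels = cuts[[best]],
      participant_id = ids,
      covariance = covariance
    ),
    class = "spider_clustering"
  )
}

#' @export
print.spider_clustering <- function(x, ...) {
  cat("<spider_clustering> variables:", paste(x$variables, collapse = ", "),
      "\nselected k =", x$selected_k, "| BIC:",
      paste(sprintf("k=%d: %.1f", x$bic$k, x$bic$bic), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname select_clusters
#' @param x,object A `spider_clustering` object.
#' @param ... Unused.
#' @export
tidy.spider_clustering <- function(x, ...) {
  tibble(participant_id = x$participant_id, label = as.integer(x$labels))
}

#' @rdname select_clusters
#' @export
glance.spider_clustering <- function(x, ...) {
  tibble(
    n = length(x$labels),
    n_variables = length(x$variables),
    selected_k = x$selected_k,
    min_bic = min(x$bic$bic),
    inversions = x$tree$inversions,
    covariance = x$covariance
  )
}

#' @rdname select_clusters
#' @return `autoplot()`: a ggplot of BIC against the candidate number of
#'   clusters.
#' @export
autoplot.spider_clustering <- function(object, ...) {
  ggplot2::ggplot(object$bic, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(
      data = object$bic[object$bic$k == object$selected_k, ],
      colour = "red", size = 3
    ) +
    ggplot2::scale_x_continuous(breaks = object$bic$k) +
    ggplot2::labs(x = "number of clusters", y = "Gaussian BIC") +
    ggplot2::theme_minimal()
}

#' Variable subsets for the standard clustering criteria
#'
#' Presets mirroring the analyses run per figure panel: each single
#' (feature, instruction) pair, all six features, the dangerous or harmless
#' triplet, and all features plus SPQ.
#'
#' @param criterion One of `"single:<feature>:<instruction>"` (e.g.
#'   `"single:hairiness:dangerous"`), `"all_features"`, `"dangerous"`,
#'   `"harmless"`, `"all_plus_spq"`.
#' @return A character vector of [preference_matrix()] column names.
#' @export
criterion_variables <- function(criterion) {
  six <- paste(rep(feature_names, each = 2), rep(instruction_levels, 3),
               sep = "_")
  if (grepl("^single:", criterion)) {
    parts <- strsplit(criterion, ":", fixed = TRUE)[[1]]
    v <- paste(parts[2], parts[3], sep = "_")
    if (length(parts) != 3 || !v %in% six) {
      abort(paste0("unknown clustering criterion: ", criterion),
            class = "spidertune_argument_error")
    }
    return(v)
  }
  switch(criterion,
    all_features = six,
    dangerous = six[endsWith(six, "dangerous")],
    harmless = six[endsWith(six, "harmless")],
    all_plus_spq = c("spq", six),
    abort(paste0("unknown clustering criterion: ", criterion),
          class = "spidertune_argument_error")
  )
}
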