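# Independent oracles, deliberately written with different logic than the
# package implementations they check.

# recount-and-average oracle for the modal-part mean: explicit partition of
# the values into the three bins, then average of the winning bin plus ties
mmpd_oracle <- function(v) {
  bins <- cut(v, breaks = c(-Inf, 0.5 - 1e-12, 0.5 + 1e-12, Inf),
              labels = c("lo", "mid", "hi"))
  n_lo <- sum(bins == "lo")
  n_hi <- sum(bins == "hi")
  if (n_lo == n_hi) return(sum(v) / length(v))
  keep <- if (n_hi > n_lo) bins != "lo" else bins != "hi"
  sum(v[keep]) / sum(keep)
}

# average ranks computed from scratch, then the Pearson product-moment
# formula applied to them
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    })
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# textbook truncated-power construction of the natural cubic spline basis
# with knots (a, m, b): {1, x, d_a(x) - d_m(x)},
# d_k(x) = [(x - k)^3_+ - (x - b)^3_+] / (b - k)
ncs_truncated_power_oracle <- function(x, a, m, b) {
  pp <- function(u) pmax(u, 0)^3
  d <- function(k) (pp(x - k) - pp(x - b)) / (b - k)
  cbind(1, x, d(a) - d(m))
}

# O(n^3) naive centroid-linkage agglomeration: keeps explicit member sets,
# recomputes all centroid distances each step, merges the closest pair
centroid_linkage_oracle <- function(X) {
  members <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  partitions <- list()
  labels_from <- function(members) {
    lab <- integer(nrow(X))
    for (j in seq_along(members)) lab[members[[j]]] <- j
    lab
  }
  while (length(members) > 1) {
    cents <- t(vapply(members, function(ix) {
      colMeans(X[ix, , drop = FALSE])
    }, numeric(ncol(X))))
    nd <- as.matrix(dist(cents))
    diag(nd) <- Inf
    ij <- which(nd == min(nd), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    heights <- c(heights, nd[i, j])
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
    partitions[[length(partitions) + 1]] <- labels_from(members)
  }
  list(heights = heights, partitions = partitions)
}

# Rand index between two hard partitions
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- same_a == same_b
  (sum(agree[upper.tri(agree)])) / choose(n, 2)
}

# direct density-sum oracle for the Gaussian partition log-likelihood
# muffle the expected variance-floor warnings from degenerate candidate cuts
suppress_floor <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("variance floor", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# classification log-likelihood: mixing proportion plus per-cluster
# diagonal-Gaussian density, variances floored at 1e-3 of the marginal
# ML variance (1e-6 absolute for constant columns)
gaussian_partition_loglik_oracle <- function(z, labels) {
  z <- as.matrix(z)
  n <- nrow(z)
  ll <- 0
  for (g in unique(labels)) {
    xk <- z[labels == g, , drop = FALSE]
    ll <- ll + nrow(xk) * log(nrow(xk) / n)
    for (j in seq_len(ncol(z))) {
      m <- mean(xk[, j])
      fl <- max(1e-3 * mean((z[, j] - mean(z[, j]))^2), 1e-6)
      v <- max(mean((xk[, j] - m)^2), fl)
      ll <- ll + sum(-0.5 * log(2 * pi * v) - (xk[, j] - m)^2 / (2 * v))
    }
  }
  ll
}

# tiny complete cohort: one participant, full 24-trial design
make_minimal_cohort <- function(spq = 0, level = 3L) {
  trials <- tidyr::expand_grid(
    instruction = c("dangerous", "harmless"),
    orientation = c("approaching", "withdrawing", "lateral"),
    rep = 1:4
  )
  trials$participant_id <- "P001"
  trials$trial_index <- seq_len(nrow(trials))
  trials$hairiness <- level / 9
  trials$bodyleg <- level / 9
  trials$locomotion <- level / 9
  cohort(
    tibble::tibble(participant_id = "P001", spq = spq, included = TRUE),
    trials[c("participant_id", "trial_index", "instruction", "orientation",
             "hairiness", "bodyleg", "locomotion")]
  )
}
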