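#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between the rows of a
#' sample-by-category count matrix, optionally after an elementwise
#' square-root transform (which damps the influence of very abundant
#' categories). Entries lie in \[0, 1]; a pair of all-zero rows is
#' defined as distance 0 with a warning.
#'
#' @param x Numeric matrix or data frame, samples in rows.
#' @param transform `"none"` or `"sqrt"`.
#' @return A `dist` object (method `"bray"`).
#' @export
#' @examples
#' m <- rbind(a = c(4, 0), b = c(1, 1))
#' bray_curtis(m, transform = "sqrt")  # 0.5
bray_curtis <- function(x, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  m <- as.matrix(x)
  if (any(m < 0)) abort("counts must be nonnegative")
  if (transform == "sqrt") m <- sqrt(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      denom <- sum(m[i, ] + m[j, ])
      if (denom == 0) {
        if (!warned) {
          warn("pair of all-zero samples; distance defined as 0")
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
      }
    }
  }
  stats::as.dist(d)
}

permanova_f <- function(d2, groups) {
  n <- attr(d2, "Size") %||% nrow(as.matrix(d2))
  m <- as.matrix(d2)
  ss_total <- sum(m[upper.tri(m)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- m[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  a <- length(unique(groups))
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  if (!is.finite(f)) f <- 0  # zero-variance case (all samples identical)
  c(f = f, ss_between = ss_between, ss_within = ss_within,
    df_between = a - 1, df_within = n - a)
}

all_permutations <- function(n) {
  # all n! orderings of 1..n (n <= 8 intended)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutational multivariate analysis of variance
#'
#' Anderson's distance-based one-way PERMANOVA. With squared
#' dissimilarities `d2`, `SS_total = sum_{i<j} d2_ij / N` and
#' `SS_within = sum_g sum_{i<j in g} d2_ij / n_g`; the pseudo-F is
#' `(SS_between/(a-1)) / (SS_within/(N-a))`. The p-value permutes the
#' group labels: with sampled permutations it is
#' `(count of permuted F >= observed + 1) / (n_permutations + 1)` (the
#' identity is counted, so p can never be 0); with
#' `exhaustive = TRUE` every labelling is enumerated and the p-value
#' is the exact proportion of labellings (observed included) with
#' `F >= observed`.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param groups Group labels, one per sample; every group needs at
#'   least two samples.
#' @param n_permutations Number of sampled label permutations.
#' @param seed Integer seed for the permutation stream (`NULL` leaves
#'   the RNG state alone).
#' @param exhaustive Enumerate all label orderings instead of sampling
#'   (only sensible for very small N).
#' @return A list of class `"herpeco_permanova"` with elements
#'   `statistic, p.value, df_between, df_within, ss_between,
#'   ss_within, n_permutations, seed`; see [tidy()] and [glance()].
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  n <- nrow(m)
  if (length(groups) != n) abort("one group label per sample required")
  if (length(unique(groups)) < 2) abort("at least two groups required")
  if (any(table(groups) < 2)) {
    abort("every group needs at least two samples")
  }
  d2 <- stats::as.dist(m^2)
  obs <- permanova_f(d2, groups)

  if (exhaustive) {
    perms <- all_permutations(n)
    fs <- apply(perms, 1, function(p) permanova_f(d2, groups[p])["f"])
    p_value <- mean(fs >= obs["f"] - 1e-12)
    n_eff <- nrow(perms)
  } else {
    fs <- with_seed_or_not(seed, {
      vapply(seq_len(n_permutations), function(i) {
        permanova_f(d2, sample(groups))["f"]
      }, 1)
    })
    p_value <- (sum(fs >= obs["f"] - 1e-12) + 1) / (n_permutations + 1)
    n_eff <- n_permutations
  }
  structure(
    list(statistic = unname(obs["f"]), p.value = p_value,
         df_between = unname(obs["df_between"]),
         df_within = unname(obs["df_within"]),
         ss_between = unname(obs["ss_between"]),
         ss_within = unname(obs["ss_within"]),
         n_permutations = n_eff, seed = seed,
         exhaustive = exhaustive),
    class = "herpeco_permanova"
  )
}

#' @export
print.herpeco_permanova <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", signif(x$statistic, 4),
      "df = (", x$df_between, ",", x$df_within, ")",
      "p =", signif(x$p.value, 3),
      "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' @export
tidy.herpeco_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sum_of_squares = c(x$ss_between, x$ss_within),
    statistic = c(x$statistic, NA),
    p.value = c(x$p.value, NA)
  )
}

#' @export
glance.herpeco_permanova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 df_between = x$df_between, df_within = x$df_within,
                 n_permutations = x$n_permutations)
}

pcoa_embed <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  g <- -0.5 * m^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))  # sequential sweeps = full double-centering
  e <- eigen(g, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-10
  list(vectors = e$vectors[, keep, drop = FALSE] %*%
         diag(sqrt(abs(e$values[keep])), sum(keep)),
       positive = e$values[keep] > 0)
}

#' Homogeneity of multivariate dispersions
#'
#' Tests whether groups differ in their spread around their own
#' centroids in the dissimilarity space (the multivariate analogue of
#' Levene's test, and the assumption check for [permanova()]). The
#' dissimilarity matrix is embedded by principal-coordinates analysis
#' keeping the imaginary axes from negative eigenvalues; each sample's
#' distance to its group centroid is
#' `sqrt(max(0, d_real^2 - d_imag^2))`. A one-way ANOVA F on those
#' distances is assessed by permuting the distances across groups.
#'
#' @inheritParams permanova
#' @return A list of class `"herpeco_dispersion"` with `statistic`
#'   (the ANOVA F on centroid distances), `p.value`, `distances`
#'   (per-sample), `group_means` and `n_permutations`.
#' @export
dispersion_homogeneity <- function(d, groups, n_permutations = 999,
                                   seed = NULL) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  n <- nrow(m)
  if (length(groups) != n) abort("one group label per sample required")
  emb <- pcoa_embed(d)
  v <- emb$vectors
  pos <- emb$positive
  dist_to_centroid <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(v[idx, , drop = FALSE])
    dev <- sweep(v[idx, , drop = FALSE], 2, cen)
    d_real2 <- rowSums(dev[, pos, drop = FALSE]^2)
    d_imag2 <- rowSums(dev[, !pos, drop = FALSE]^2)
    dist_to_centroid[idx] <- sqrt(pmax(0, d_real2 - d_imag2))
  }
  anova_f <- function(y, grp) {
    gm <- tapply(y, grp, mean)
    ng <- tapply(y, grp, length)
    ss_b <- sum(ng * (gm - mean(y))^2)
    ss_w <- sum((y - gm[grp])^2)
    a <- length(gm)
    (ss_b / (a - 1)) / (ss_w / (length(y) - a))
  }
  f_obs <- anova_f(dist_to_centroid, groups)
  fs <- with_seed_or_not(seed, {
    vapply(seq_len(n_permutations), function(i) {
      anova_f(dist_to_centroid, sample(groups))
    }, 1)
  })
  p <- (sum(fs >= f_obs - 1e-12) + 1) / (n_permutations + 1)
  structure(
    list(statistic = f_obs, p.value = p,
         distances = tibble::tibble(sample = rownames(m) %||%
                                      as.character(seq_len(n)),
                                    group = groups,
                                    distance = dist_to_centroid),
         group_means = tapply(dist_to_centroid, groups, mean),
         n_permutations = n_permutations, seed = seed),
    class = "herpeco_dispersion"
  )
}

#' @export
print.herpeco_dispersion <- function(x, ...) {
  cat("Multivariate dispersion: F =", signif(x$statistic, 4),
      "p =", signif(x$p.value, 3), "\n")
  invisible(x)
}

#' @export
glance.herpeco_dispersion <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n_permutations = x$n_permutations)
}

kruskal_stress <- function(dhat, disp) {
  sqrt(sum((dhat - disp)^2) / sum(dhat^2))
}

nmds_run <- function(m, x0, k, max_iter, tol) {
  n <- nrow(m)
  lower <- which(lower.tri(m))
  dvec <- m[lower]
  ord <- order(dvec)
  x <- x0
  config_dist <- function(x) as.matrix(dist(x))[lower]
  dhat <- config_dist(x)
  # isotonic disparities on the rank order of the input dissimilarities
  fit_disp <- function(dhat) {
    disp <- numeric(length(dhat))
    disp[ord] <- isoreg(dhat[ord])$yf
    disp
  }
  disp <- fit_disp(dhat)
  stress <- kruskal_stress(dhat, disp)
  trace <- stress
  for (it in seq_len(max_iter)) {
    # Guttman transform with current disparities
    full_disp <- matrix(0, n, n)
    full_disp[lower] <- disp
    full_disp <- full_disp + t(full_disp)
    dm <- as.matrix(dist(x))
    ratio <- ifelse(dm > 0, full_disp / dm, 0)
    b <- -ratio
    diag(b) <- -rowSums(b)
    x_new <- b %*% x / n
    dhat_new <- config_dist(x_new)
    disp_new <- fit_disp(dhat_new)
    stress_new <- kruskal_stress(dhat_new, disp_new)
    if (stress_new > stress + 1e-12) break  # keep the trace monotone
    x <- x_new
    improved <- stress - stress_new
    stress <- stress_new
    disp <- disp_new
    dhat <- dhat_new
    trace <- c(trace, stress)
    if (improved < tol) break
  }
  list(points = x, stress = stress, trace = trace)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal's stress-1 NMDS: a k-dimensional configuration whose
#' interpoint distances preserve the rank order of the input
#' dissimilarities. Disparities are fitted by isotonic regression
#' (pool-adjacent-violators, ties averaged) on the dissimilarity rank
#' order, and the configuration is updated by the Guttman transform;
#' iterations that would increase stress are rejected, so the stress
#' sequence within a run is non-increasing. The first start is the
#' classical (metric) scaling of the dissimilarities; the remaining
#' `n_restarts - 1` starts are random. The best configuration over
#' starts is returned, centred, with stress in \[0, 1].
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param k Target dimension (default 2); must be below the number of
#'   samples.
#' @param n_restarts Total number of starts (first is classical
#'   scaling).
#' @param max_iter,tol Iteration cap and stress-improvement tolerance
#'   per run.
#' @param seed Integer seed for the random restarts.
#' @return A list of class `"herpeco_nmds"`: `points` (tibble with
#'   `sample` and `axis1..axisk`), `stress`, `trace` (stress sequence
#'   of the best run), `k`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 4, max_iter = 200,
                 tol = 1e-6, seed = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (k >= n) abort("k must be smaller than the number of samples")
  best <- NULL
  starts <- with_seed_or_not(seed, {
    first <- suppressWarnings(cmdscale(stats::as.dist(m), k = k))
    if (ncol(first) < k) {
      first <- cbind(first,
                     matrix(rnorm(n * (k - ncol(first)), sd = 1e-4),
                            n, k - ncol(first)))
    }
    c(list(first),
      lapply(seq_len(max(0, n_restarts - 1)), function(i) {
        matrix(rnorm(n * k), n, k)
      }))
  })
  for (x0 in starts) {
    run <- nmds_run(m, x0, k, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  pts <- sweep(best$points, 2, colMeans(best$points))
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(
    list(points = dplyr::bind_cols(
           tibble::tibble(sample = rownames(m) %||%
                            as.character(seq_len(n))),
           tibble::as_tibble(pts)),
         stress = best$stress, trace = best$trace, k = k, seed = seed),
    class = "herpeco_nmds"
  )
}

#' @export
print.herpeco_nmds <- function(x, ...) {
  cat("NMDS (k =", x$k, "): stress =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' @export
glance.herpeco_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k,
                 n_samples = nrow(x$points))
}
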