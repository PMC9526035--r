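#' Estimate microhabitat availability from quadrat surveys
#'
#' Crown-diameter availability estimation. Each patch is treated as an
#' ellipse with the two recorded perpendicular diameters as axes, so its
#' area is `pi * d1 * d2 / 4`. Per quadrat, the proportion covered by a
#' category is the summed patch area divided by the quadrat area;
#' uncovered land is the residual `1 - sum(covered)` (floored at zero
#' with a warning when the recorded patches overshoot the quadrat).
#' Availability is the unweighted mean of the per-quadrat proportions.
#'
#' @param quadrats Tibble as returned by [read_quadrats()] (columns
#'   `site, quadrat_id, category, diameter1_m, diameter2_m`). Rows with
#'   `NA` category declare patch-free quadrats.
#' @param quadrat_area Quadrat area in square metres; taken from the
#'   `quadrat_area` attribute of `quadrats` if present, else 400.
#' @param categories Category universe; defaults to the categories in
#'   the data plus `uncovered_land`.
#' @param pool If `TRUE`, all quadrats are treated as one population;
#'   otherwise availability is computed per site.
#'
#' @return A tibble `site, category, availability, n_quadrats` whose
#'   availabilities sum to 1 within each site. The per-quadrat
#'   proportion matrix is attached as attribute `"replicates"` (a named
#'   list of site -> quadrat x category matrix), used by the
#'   sampled-availability variance of [selection_ratios()].
#' @export
#' @examples
#' q <- tibble::tibble(site = "S1", quadrat_id = "Q1",
#'                     category = "polylepis_tree",
#'                     diameter1_m = 2, diameter2_m = 2)
#' estimate_availability(q)  # ellipse area pi m^2 out of 400
estimate_availability <- function(quadrats,
                                  quadrat_area = NULL,
                                  categories = NULL,
                                  pool = FALSE) {
  quadrat_area <- quadrat_area %||% attr(quadrats, "quadrat_area") %||% 400
  x <- tibble::as_tibble(quadrats)
  if (pool) x$site <- "pooled"
  covered_cats <- sort(unique(x$category[!is.na(x$category)]))
  categories <- categories %||% union(covered_cats, "uncovered_land")
  if (!"uncovered_land" %in% categories) {
    categories <- c(categories, "uncovered_land")
  }

  site_mats <- lapply(split(x, x$site), function(sx) {
    quads <- split(sx, sx$quadrat_id)
    template <- setNames(numeric(length(categories)),
                         c(setdiff(categories, "uncovered_land"),
                           "uncovered_land"))
    res <- vapply(quads, function(qx) {
      patches <- qx[!is.na(qx$category), , drop = FALSE]
      areas <- pi * patches$diameter1_m * patches$diameter2_m / 4
      prop <- vapply(
        setdiff(categories, "uncovered_land"),
        function(cc) sum(areas[patches$category == cc]) / quadrat_area,
        1
      )
      covered <- sum(prop)
      if (covered > 1) {
        warn(paste0("quadrat ", qx$quadrat_id[1], " covered area ",
                    "exceeds quadrat area; uncovered floored at 0"))
        covered <- min(covered, 1)
      }
      c(prop, uncovered_land = 1 - min(sum(prop), 1))
    }, template)
    if (is.matrix(res)) t(res) else
      matrix(res, ncol = 1,
             dimnames = list(names(quads), names(template)))
  })

  out <- purrr::imap_dfr(site_mats, function(mat, site) {
    tibble::tibble(
      site = site,
      category = colnames(mat),
      availability = unname(colMeans(mat)),
      n_quadrats = nrow(mat)
    )
  })
  attr(out, "replicates") <- site_mats
  out
}

#' Tabulate microhabitat use from encounter records
#'
#' Counts encounters per category. When `drop_unused = TRUE` (the usual
#' Type I workflow), categories with zero use across the pooled records
#' are removed from both the use table and, if supplied, the
#' availability profile, which is then renormalized over the retained
#' categories; the number of retained categories `I` drives the
#' Bonferroni adjustment downstream.
#'
#' @param encounters Tibble with a `microhabitat` column (e.g. from
#'   [read_encounters()]), or a named integer vector of counts.
#' @param availability Optional named availability vector or the output
#'   of [estimate_availability()] filtered to one site; its category
#'   set defines which zero-use categories exist.
#' @param drop_unused Drop categories never used, renormalizing
#'   availability over the rest.
#'
#' @return A tibble `category, count, proportion` with attributes
#'   `n_used` (total encounters), `n_retained` (`I`) and, when
#'   `availability` was given, `availability` (the aligned, possibly
#'   renormalized named vector) and `dropped` (categories removed).
#' @export
tabulate_use <- function(encounters, availability = NULL,
                         drop_unused = TRUE) {
  if (is.data.frame(encounters)) {
    counts <- table(encounters$microhabitat)
    counts <- setNames(as.integer(counts), names(counts))
  } else {
    counts <- encounters
  }
  if (length(counts) == 0 || sum(counts) == 0) abort("no uses")

  avail <- normalize_availability(availability)
  if (!is.null(avail)) {
    # the availability profile defines the category universe
    counts <- setNames(
      as.integer(counts[names(avail)]),
      names(avail)
    )
    counts[is.na(counts)] <- 0L
  }

  dropped <- character(0)
  if (drop_unused) {
    dropped <- names(counts)[counts == 0]
    counts <- counts[counts > 0]
    if (!is.null(avail)) {
      avail <- avail[names(counts)]
      avail <- avail / sum(avail)
    }
  }

  out <- tibble::tibble(
    category = names(counts),
    count = as.integer(counts),
    proportion = as.numeric(counts) / sum(counts)
  )
  attr(out, "n_used") <- sum(counts)
  attr(out, "n_retained") <- length(counts)
  attr(out, "availability") <- avail
  attr(out, "dropped") <- dropped
  out
}

normalize_availability <- function(availability) {
  if (is.null(availability)) return(NULL)
  if (is.data.frame(availability)) {
    if (length(unique(availability$site %||% "x")) > 1) {
      abort("availability spans several sites; filter to one site or pool")
    }
    availability <- setNames(availability$availability,
                             availability$category)
  }
  if (is.null(names(availability))) {
    abort("availability must be named by category")
  }
  if (any(availability < 0)) abort("availability must be nonnegative")
  availability
}

#' Type I selection ratios and their standard errors
#'
#' The selection ratio for resource `i` is `wi = (u_i/u_+) / a_i`, the
#' proportional use over proportional availability; 1 means use in
#' proportion to availability. Under `known_availability` the standard
#' error is `sqrt(p_i (1 - p_i) / (u_+ a_i^2))` with `p_i = u_i/u_+`.
#' Under `sampled_availability` a delta-method term for the estimated
#' availability is added: `var(wi) = var(p_i)/a_i^2 +
#' p_i^2 var(a_i)/a_i^4`, with `var(a_i)` the squared standard error of
#' the mean over the per-quadrat availability replicates.
#'
#' @param used Named integer vector of use counts, or proportions if
#'   `n_used` is given.
#' @param available Named availability proportions aligned (or
#'   alignable by name) with `used`; all retained categories must have
#'   `a_i > 0`.
#' @param n_used Total number of uses `u_+`; required when `used` holds
#'   proportions.
#' @param variance_mode `"known_availability"` or
#'   `"sampled_availability"`.
#' @param availability_replicates Quadrat x category matrix of
#'   per-quadrat availability proportions (see
#'   [estimate_availability()]); required for
#'   `"sampled_availability"`.
#'
#' @return A tibble `category, used, available, wi, se`.
#' @export
#' @examples
#' selection_ratios(c(a = 50, b = 50), c(a = 0.25, b = 0.75))
selection_ratios <- function(used, available, n_used = NULL,
                             variance_mode = c("known_availability",
                                               "sampled_availability"),
                             availability_replicates = NULL) {
  variance_mode <- match.arg(variance_mode)
  if (!is.null(names(used)) && !is.null(names(available))) {
    if (!setequal(names(used), names(available))) {
      abort("category sets of use and availability differ")
    }
    available <- available[names(used)]
  } else if (length(used) != length(available)) {
    abort("use and availability lengths differ")
  }

  if (is.null(n_used)) {
    if (any(used != round(used))) {
      abort("`used` looks like proportions; supply `n_used`")
    }
    n_used <- sum(used)
    p <- used / n_used
  } else {
    p <- if (sum(used) > 1 + 1e-8) used / sum(used) else used
  }
  if (any(available <= 0 & p > 0)) {
    abort("used but unavailable category (a_i = 0 with u_i > 0)")
  }

  wi <- p / available
  var_p <- p * (1 - p) / n_used
  se2 <- var_p / available^2
  if (variance_mode == "sampled_availability") {
    if (is.null(availability_replicates)) {
      abort("sampled_availability needs `availability_replicates`")
    }
    reps <- availability_replicates[, names(wi) %||% seq_along(wi),
                                    drop = FALSE]
    var_a <- apply(reps, 2, stats::var) / nrow(reps)
    se2 <- se2 + p^2 * var_a / available^4
  }
  tibble::tibble(
    category = names(wi) %||% as.character(seq_along(wi)),
    used = as.numeric(p),
    available = as.numeric(available),
    wi = as.numeric(wi),
    se = sqrt(as.numeric(se2))
  )
}

#' Bonferroni simultaneous confidence intervals for selection ratios
#'
#' Family-wise intervals `wi +/- z * se`, with the lower bound truncated
#' at zero (ratios are nonnegative). Under the `"textbook"` convention
#' the multiplier is the standard-normal quantile at `1 - alpha/(2I)`
#' (two-sided error split over `I` resources, e.g. z = 2.687 for
#' alpha = 0.05, I = 7). Under `"paper_compat"` it is the quantile at
#' `1 - alpha/I` (z = 2.450 for I = 7), the convention that reproduces
#' some published field-study tables; see the methods vignette.
#'
#' @param wi,se Numeric vectors of ratios and standard errors.
#' @param alpha Family-wise error level.
#' @param n_resources Number of simultaneous comparisons `I`.
#' @param convention `"textbook"` or `"paper_compat"`.
#' @return A tibble `ci_lo, ci_hi`.
#' @export
#' @examples
#' bonferroni_ci(0.424, 0.125, n_resources = 7,
#'               convention = "paper_compat")
bonferroni_ci <- function(wi, se, alpha = 0.05, n_resources,
                          convention = c("textbook", "paper_compat")) {
  convention <- match.arg(convention)
  if (any(se < 0)) abort("standard errors must be nonnegative")
  z <- switch(convention,
              textbook = qnorm(1 - alpha / (2 * n_resources)),
              paper_compat = qnorm(1 - alpha / n_resources))
  tibble::tibble(
    ci_lo = pmax(0, wi - z * se),
    ci_hi = wi + z * se
  )
}

#' Classify selection from a simultaneous confidence interval
#'
#' A resource is selected positively when the whole interval lies above
#' 1, negatively (avoided) when it lies below 1, and use is indifferent
#' when the interval includes 1.
#'
#' @param ci_lo,ci_hi Interval bounds.
#' @return Character vector in `{"positive", "negative",
#'   "indifferent"}`.
#' @export
classify_selection <- function(ci_lo, ci_hi) {
  dplyr::case_when(
    ci_hi < 1 ~ "negative",
    ci_lo > 1 ~ "positive",
    .default = "indifferent"
  )
}

#' Per-resource z-test of wi = 1
#'
#' `z = (wi - 1)/se` with a two-sided standard-normal p-value; the
#' significance flag compares p with the Bonferroni level
#' `alpha / n_resources`.
#'
#' @inheritParams bonferroni_ci
#' @return A tibble `z, p, significant`.
#' @export
per_resource_test <- function(wi, se, alpha = 0.05, n_resources = 1) {
  z <- ifelse(se == 0, ifelse(wi == 1, 0, Inf * sign(wi - 1)),
              (wi - 1) / se)
  p <- ifelse(se == 0, ifelse(wi == 1, 1, 0), 2 * pnorm(-abs(z)))
  tibble::tibble(z = z, p = p,
                 significant = p < alpha / n_resources)
}

#' Global log-likelihood test for a selective process
#'
#' The log-likelihood chi-square statistic
#' `XL2 = 2 sum_i u_i log(u_i / (u_+ a_i))` over categories with
#' `u_i > 0`, compared with a chi-square on `I - 1` degrees of freedom,
#' tests whether use deviates from availability anywhere in the
#' resource set.
#'
#' @param used Named integer use counts.
#' @param available Availability proportions aligned with `used`.
#' @return One-row tibble `statistic, df, p.value`.
#' @export
#' @examples
#' global_loglik_test(c(a = 15, b = 5), c(a = 0.5, b = 0.5))
global_loglik_test <- function(used, available) {
  if (!is.null(names(used)) && !is.null(names(available))) {
    available <- available[names(used)]
  }
  if (length(used) != length(available)) {
    abort("use and availability lengths differ")
  }
  keep <- used > 0
  u <- used[keep]
  a <- available[keep]
  u_plus <- sum(used)
  xl2 <- 2 * sum(u * log(u / (u_plus * a)))
  df <- length(used) - 1
  tibble::tibble(
    statistic = xl2,
    df = df,
    p.value = pchisq(xl2, df, lower.tail = FALSE)
  )
}

#' Manly's standardized selection index
#'
#' `Bi = wi / sum(wj)`: the probability that resource `i` would be the
#' one used were all resources equally available. Sums to 1 over the
#' resource set.
#'
#' @param wi Numeric vector of selection ratios.
#' @return Numeric vector summing to 1.
#' @export
#' @examples
#' standardized_index(c(0.424, 0.613, 0.807, 0.147, 1.159, 1.783, 4.089))
standardized_index <- function(wi) {
  if (any(wi < 0)) abort("selection ratios must be nonnegative")
  wi / sum(wi)
}

#' Full Type I selection analysis
#'
#' One call from use and availability to the per-resource selection
#' table: selection ratios with standard errors, simultaneous Bonferroni
#' confidence intervals, per-resource z-tests, the classification
#' (positive / negative / indifferent), the standardized index `Bi`,
#' and the global log-likelihood statistic (as attributes and via
#' [glance()]).
#'
#' @param use Encounters tibble, or named use counts; see
#'   [tabulate_use()].
#' @param availability Availability profile (named vector or the output
#'   of [estimate_availability()] for one site).
#' @param alpha Family-wise error level.
#' @param ci_convention See [bonferroni_ci()].
#' @param variance_mode,availability_replicates See
#'   [selection_ratios()]. When `availability` comes from
#'   [estimate_availability()] and `variance_mode =
#'   "sampled_availability"`, replicates are pulled from its
#'   `"replicates"` attribute automatically.
#' @param drop_unused Drop zero-use categories and renormalize
#'   availability (see [tabulate_use()]).
#'
#' @return A tibble of class `"selection_table"` with columns
#'   `category, available, used_count, used, wi, se, ci_lo, ci_hi, z,
#'   p, significant, classification, bi` and attributes `xl2` (one-row
#'   tibble from [global_loglik_test()]), `alpha`, `n_resources`,
#'   `bonferroni_level`, `dropped`.
#' @export
#' @examples
#' use <- c(polylepis_tree = 25, scrubland = 16, uncovered_land = 41)
#' avail <- c(polylepis_tree = 0.5, scrubland = 0.3, uncovered_land = 0.2)
#' selection_analysis(use, avail)
selection_analysis <- function(use, availability,
                               alpha = 0.05,
                               ci_convention = c("textbook", "paper_compat"),
                               variance_mode = c("known_availability",
                                                 "sampled_availability"),
                               availability_replicates = NULL,
                               drop_unused = TRUE) {
  ci_convention <- match.arg(ci_convention)
  variance_mode <- match.arg(variance_mode)
  if (is.data.frame(availability) &&
      variance_mode == "sampled_availability" &&
      is.null(availability_replicates)) {
    reps <- attr(availability, "replicates")
    if (!is.null(reps)) {
      site <- unique(availability$site)
      availability_replicates <- reps[[site]]
    }
  }
  ut <- tabulate_use(use, availability, drop_unused = drop_unused)
  avail <- attr(ut, "availability")
  if (is.null(avail)) abort("availability is required")
  counts <- setNames(ut$count, ut$category)
  n_res <- attr(ut, "n_retained")

  sr <- selection_ratios(counts, avail,
                         variance_mode = variance_mode,
                         availability_replicates = availability_replicates)
  ci <- bonferroni_ci(sr$wi, sr$se, alpha = alpha, n_resources = n_res,
                      convention = ci_convention)
  test <- per_resource_test(sr$wi, sr$se, alpha = alpha,
                            n_resources = n_res)
  out <- tibble::tibble(
    category = sr$category,
    available = sr$available,
    used_count = ut$count,
    used = sr$used,
    wi = sr$wi,
    se = sr$se,
    ci_lo = ci$ci_lo,
    ci_hi = ci$ci_hi,
    z = test$z,
    p = test$p,
    significant = test$significant,
    classification = classify_selection(ci$ci_lo, ci$ci_hi),
    bi = standardized_index(sr$wi)
  )
  class(out) <- c("selection_table", class(out))
  attr(out, "xl2") <- global_loglik_test(counts, avail)
  attr(out, "alpha") <- alpha
  attr(out, "n_resources") <- n_res
  attr(out, "bonferroni_level") <- alpha / n_res
  attr(out, "ci_convention") <- ci_convention
  attr(out, "dropped") <- attr(ut, "dropped")
  out
}

#' @export
tidy.selection_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "selection_table")
  attr(out, "xl2") <- NULL
  out
}

#' @export
glance.selection_table <- function(x, ...) {
  g <- attr(x, "xl2")
  dplyr::mutate(g,
                n_resources = attr(x, "n_resources"),
                alpha = attr(x, "alpha"),
                bonferroni_level = attr(x, "bonferroni_level"))
}
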