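#' Ground-truth scenarios for the synthetic-data generator
#'
#' `selection_scenario()` describes a microhabitat-selection study:
#' true availability proportions, relative (scale-free) selection
#' weights, the number of encounters, and a mixture of Gaussian
#' activity components on the diel clock. Encounter categories are
#' drawn with probability `a_i w_i / sum(a_j w_j)`, so the true
#' selection ratio of category `i` is proportional to `w_i` and the
#' true standardized index is `w / sum(w)`.
#'
#' `diet_scenario()` describes a stomach-content study: category
#' probabilities for a multinomial item draw, a mean (overdispersed)
#' item count per stomach, mean per-item dry weights, and the
#' population-level weight fraction contributed by plant material.
#'
#' Defaults mirror the two-site *Polylepis*-forest study the package
#' is built around: seven used microhabitats with availabilities near
#' the field estimates, activity peaks at 9.5 h and 13.5 h inside an
#' 8-18 h survey window, ~12 items per stomach with a clumped
#' (negative-binomial) count law, and a plant weight fraction near
#' 0.5.
#'
#' @param availability Named vector of availability proportions
#'   (sums to 1).
#' @param selection_weights Nonnegative named vector aligned with
#'   `availability`.
#' @param n_encounters Number of encounter records to draw.
#' @param activity_mixture Data frame with columns `peak_h, sd_h,
#'   weight`: Gaussian components of the encounter-time mixture,
#'   truncated to `[8, 18)`.
#' @param p_active Probability that an encounter is recorded active;
#'   either a single number or a function of time (decimal hours).
#' @param seed Integer seed making the generator a pure function of
#'   its parameters.
#' @return A list of class `"selection_scenario"` /
#'   `"diet_scenario"`.
#' @name scenarios
#' @export
selection_scenario <- function(
    availability = c(polylepis_tree = 0.351, scrubland = 0.155,
                     thorny_bush = 0.096, nonthorny_bush = 0.081,
                     rock = 0.057, small_rock = 0.200,
                     uncovered_land = 0.060),
    selection_weights = c(polylepis_tree = 0.42, scrubland = 0.61,
                          thorny_bush = 0.81, nonthorny_bush = 0.15,
                          rock = 1.16, small_rock = 1.78,
                          uncovered_land = 4.09),
    n_encounters = 168,
    activity_mixture = data.frame(peak_h = c(9.5, 13.5),
                                  sd_h = c(0.7, 0.7),
                                  weight = c(0.55, 0.45)),
    p_active = 0.8,
    seed = 1L) {
  if (abs(sum(availability) - 1) > 1e-9) {
    abort("availability must sum to 1")
  }
  if (any(selection_weights < 0) || all(selection_weights == 0)) {
    abort("selection weights must be nonnegative with at least one > 0")
  }
  if (!setequal(names(availability), names(selection_weights))) {
    abort("availability and weights must share categories")
  }
  structure(
    list(availability = availability,
         selection_weights = selection_weights[names(availability)],
         n_encounters = as.integer(n_encounters),
         activity_mixture = activity_mixture,
         p_active = p_active,
         seed = as.integer(seed)),
    class = "selection_scenario"
  )
}

#' @rdname scenarios
#' @param prey_probs Named probability vector over prey categories.
#' @param mean_items_per_stomach Positive mean of the per-stomach item
#'   count.
#' @param dispersion Negative-binomial size parameter for the item
#'   count (smaller = clumpier); `Inf` gives Poisson counts.
#' @param weight_mean_g Named vector of mean per-item dry weights (g).
#' @param weight_cv Coefficient of variation of per-item weights.
#' @param plant_weight_fraction Expected share of total dry mass
#'   contributed by plant material, in \[0, 1].
#' @param n_stomachs Number of stomachs to draw.
#' @export
diet_scenario <- function(
    prey_probs = c(Lygaeidae = 0.45, Acari = 0.17, Araneae = 0.03,
                   Sphecidae = 0.05, Anthomyiidae = 0.05,
                   Coccinelidae = 0.06, Larvae_worms = 0.06,
                   Diptera_indet = 0.04, Formicidae = 0.01,
                   Cicadelidae = 0.02, Noctuiidae = 0.02,
                   Tabanidae = 0.01, Tachinidae = 0.03),
    mean_items_per_stomach = 12,
    dispersion = 2,
    weight_mean_g = NULL,
    weight_cv = 0.5,
    plant_weight_fraction = 0.5,
    n_stomachs = 33,
    seed = 1L) {
  if (abs(sum(prey_probs) - 1) > 1e-9) abort("prey_probs must sum to 1")
  if (plant_weight_fraction < 0 || plant_weight_fraction > 1) {
    abort("plant_weight_fraction must lie in [0, 1]")
  }
  if (mean_items_per_stomach <= 0) {
    abort("mean_items_per_stomach must be positive")
  }
  if (is.null(weight_mean_g)) {
    weight_mean_g <- setNames(rep(0.002, length(prey_probs)),
                              names(prey_probs))
  }
  structure(
    list(prey_probs = prey_probs,
         mean_items_per_stomach = mean_items_per_stomach,
         dispersion = dispersion,
         weight_mean_g = weight_mean_g[names(prey_probs)],
         weight_cv = weight_cv,
         plant_weight_fraction = plant_weight_fraction,
         n_stomachs = as.integer(n_stomachs),
         seed = as.integer(seed)),
    class = "diet_scenario"
  )
}

#' Simulate quadrat surveys with known availability
#'
#' Draws patch records whose expected per-category coverage equals the
#' scenario's availability. Each quadrat receives `patches_per_quadrat`
#' patches; a patch's category is drawn with probability proportional
#' to the covered availabilities, and its ellipse area is a gamma draw
#' whose mean makes the expected summed coverage per category equal
#' the target. The two diameters are recovered from the area and a
#' random axis ratio. Estimated availability
#' ([estimate_availability()]) therefore converges to the scenario's
#' availability as quadrats accumulate.
#'
#' @param scenario A [selection_scenario()]; the `uncovered_land`
#'   entry is the residual (must be positive: covered proportions sum
#'   below 1).
#' @param n_quadrats Number of quadrats (default 30, the usual
#'   per-site survey effort).
#' @param patches_per_quadrat Mean patches per quadrat.
#' @param quadrat_area Quadrat area in square metres.
#' @param site Site label written into the table.
#' @return A quadrats tibble in the [read_quadrats()] schema.
#' @export
simulate_quadrats <- function(scenario, n_quadrats = 30,
                              patches_per_quadrat = 12,
                              quadrat_area = 400, site = "S1") {
  a <- scenario$availability
  covered <- a[setdiff(names(a), "uncovered_land")]
  if (sum(covered) >= 1) {
    abort("covered proportions must sum below 1 (uncovered residual)")
  }
  if (sum(covered) == 0) {
    out <- tibble::tibble(site = site,
                          quadrat_id = sprintf("Q%03d", seq_len(n_quadrats)),
                          category = NA_character_,
                          diameter1_m = NA_real_, diameter2_m = NA_real_)
    attr(out, "quadrat_area") <- quadrat_area
    return(out)
  }
  mean_patch_area <- sum(covered) * quadrat_area / patches_per_quadrat
  shape <- 4  # moderate patch-size spread
  out <- with_seed_or_not(scenario$seed, {
    purrr::map_dfr(seq_len(n_quadrats), function(q) {
      cats <- sample(names(covered), patches_per_quadrat,
                     replace = TRUE, prob = covered / sum(covered))
      areas <- rgamma(patches_per_quadrat, shape = shape,
                      rate = shape / mean_patch_area)
      ratio <- runif(patches_per_quadrat, 0.6, 1)
      d1 <- sqrt(4 * areas / (pi * ratio))
      tibble::tibble(site = site,
                     quadrat_id = sprintf("Q%03d", q),
                     category = cats,
                     diameter1_m = d1,
                     diameter2_m = ratio * d1)
    })
  })
  attr(out, "quadrat_area") <- quadrat_area
  out
}

rtrunc_mixture <- function(n, mixture, lo = 8, hi = 18) {
  comp <- sample.int(nrow(mixture), n, replace = TRUE,
                     prob = mixture$weight)
  t <- rnorm(n, mixture$peak_h[comp], mixture$sd_h[comp])
  bad <- which(t < lo | t >= hi)
  while (length(bad) > 0) {
    comp_b <- sample.int(nrow(mixture), length(bad), replace = TRUE,
                         prob = mixture$weight)
    t[bad] <- rnorm(length(bad), mixture$peak_h[comp_b],
                    mixture$sd_h[comp_b])
    bad <- bad[t[bad] < lo | t[bad] >= hi]
  }
  t
}

#' Simulate encounter records
#'
#' Microhabitats are multinomial with probability
#' `a_i w_i / sum(a_j w_j)`; encounter times come from the scenario's
#' Gaussian activity mixture truncated to the 8-18 h survey window;
#' activity state is Bernoulli with the scenario's (possibly
#' time-dependent) active probability.
#'
#' @inheritParams simulate_quadrats
#' @return An encounters tibble in the [read_encounters()] schema
#'   (including the parsed `time_h` column).
#' @export
simulate_encounters <- function(scenario, site = "S1") {
  a <- scenario$availability
  w <- scenario$selection_weights
  prob <- a * w / sum(a * w)
  n <- scenario$n_encounters
  with_seed_or_not(scenario$seed, {
    cats <- sample(names(prob), n, replace = TRUE, prob = prob)
    t <- rtrunc_mixture(n, scenario$activity_mixture)
    p_act <- if (is.function(scenario$p_active)) {
      scenario$p_active(t)
    } else rep(scenario$p_active, n)
    act <- ifelse(runif(n) < p_act, "active", "inactive")
    hh <- floor(t)
    mm <- floor((t - hh) * 60)
    tibble::tibble(
      site = site,
      quadrat_id = sprintf("Q%03d", sample.int(30, n, replace = TRUE)),
      time_hhmm = sprintf("%02d:%02d", hh, mm),
      microhabitat = cats,
      activity = act,
      time_h = hh + mm / 60
    )
  })
}

#' Simulate stomach contents
#'
#' Per stomach, the total item count is negative-binomial with the
#' scenario mean and dispersion (Poisson when `dispersion = Inf`),
#' categories are multinomial on `prey_probs`, and each category's
#' summed dry weight is a gamma draw around `count * weight_mean_g`.
#' Plant mass per stomach is a gamma draw whose mean is chosen so that
#' the expected population-level plant weight share equals
#' `plant_weight_fraction`.
#'
#' @param scenario A [diet_scenario()].
#' @param site Site label.
#' @return A stomachs tibble in the [read_stomachs()] schema.
#' @export
simulate_stomachs <- function(scenario, site = "S1") {
  n <- scenario$n_stomachs
  if (n == 0) {
    return(tibble::tibble(site = character(0), individual_id = character(0),
                          sex = character(0), prey_category = character(0),
                          count = numeric(0), dry_weight_g = numeric(0)))
  }
  p <- scenario$prey_probs
  wm <- scenario$weight_mean_g
  cv <- scenario$weight_cv
  f <- scenario$plant_weight_fraction
  mean_animal_mass <- scenario$mean_items_per_stomach * sum(p * wm)
  plant_mean <- if (f >= 1) Inf else f / (1 - f) * mean_animal_mass
  with_seed_or_not(scenario$seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      id <- sprintf("L%03d", i)
      k <- if (is.finite(scenario$dispersion)) {
        rnbinom(1, size = scenario$dispersion,
                mu = scenario$mean_items_per_stomach)
      } else {
        stats::rpois(1, scenario$mean_items_per_stomach)
      }
      rows <- NULL
      if (k > 0) {
        cnt <- as.vector(rmultinom(1, k, p))
        names(cnt) <- names(p)
        cnt <- cnt[cnt > 0]
        shape <- 1 / cv^2
        wts <- vapply(names(cnt), function(cc) {
          rgamma(1, shape = shape,
                 rate = shape / (cnt[cc] * wm[cc]))
        }, 1)
        rows <- tibble::tibble(site = site, individual_id = id,
                               sex = sample(c("m", "f"), 1),
                               prey_category = names(cnt),
                               count = as.numeric(cnt),
                               dry_weight_g = as.numeric(wts))
      }
      if (f > 0) {
        shape_p <- 1.5  # right-skewed plant mass, many light stomachs
        pw <- rgamma(1, shape = shape_p, rate = shape_p / plant_mean)
        rows <- dplyr::bind_rows(
          rows,
          tibble::tibble(site = site, individual_id = id,
                         sex = sample(c("m", "f"), 1),
                         prey_category = "plant_material",
                         count = NA_real_, dry_weight_g = pw))
      }
      rows %||% tibble::tibble(site = site, individual_id = id,
                               sex = sample(c("m", "f"), 1),
                               prey_category = NA_character_,
                               count = NA_real_,
                               dry_weight_g = NA_real_)
    })
  })
}

#' Simulate pitfall-trap catches
#'
#' Draws `total_catch` arthropods multinomially from the community
#' relative abundances and spreads them uniformly over `n_lines` trap
#' lines, so relative abundances converge to `community_probs` as the
#' catch grows.
#'
#' @param community_probs Named probability vector over prey
#'   categories.
#' @param total_catch Total number of individuals caught.
#' @param n_lines Number of pitfall lines (default 6).
#' @param seed Integer seed.
#' @param site Site label.
#' @return A pitfalls tibble in the [read_pitfalls()] schema.
#' @export
simulate_pitfalls <- function(community_probs, total_catch,
                              n_lines = 6, seed = 1L, site = "S1") {
  if (abs(sum(community_probs) - 1) > 1e-9) {
    abort("community_probs must sum to 1")
  }
  with_seed_or_not(seed, {
    cnt <- as.vector(rmultinom(1, total_catch, community_probs))
    names(cnt) <- names(community_probs)
    purrr::map_dfr(names(cnt)[cnt > 0], function(cc) {
      line_cnt <- as.vector(rmultinom(1, cnt[cc],
                                      rep(1 / n_lines, n_lines)))
      tibble::tibble(site = site,
                     line_id = sprintf("P%d", seq_len(n_lines)),
                     prey_category = cc,
                     count = as.numeric(line_cnt))
    }) |>
      dplyr::filter(.data$count > 0)
  })
}

#' Simulate a full study and write its input files
#'
#' Emits the four input CSVs (quadrats, encounters, stomachs,
#' pitfalls) for one scenario pair, plus a `ground_truth.json` sidecar
#' recording the generating parameters, so downstream analyses can be
#' checked against known truth.
#'
#' @param selection A [selection_scenario()].
#' @param diet A [diet_scenario()].
#' @param pitfall_probs,pitfall_total Community composition and total
#'   catch for [simulate_pitfalls()]; defaults reuse the diet
#'   scenario's prey probabilities.
#' @param dir Output directory.
#' @param site Site label.
#' @return Invisibly, a named list of the paths written.
#' @export
simulate_study <- function(selection, diet,
                           pitfall_probs = diet$prey_probs,
                           pitfall_total = 1000,
                           dir, site = "S1") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  quadrats <- simulate_quadrats(selection, site = site)
  encounters <- simulate_encounters(selection, site = site)
  stomachs <- simulate_stomachs(diet, site = site)
  pitfalls <- simulate_pitfalls(pitfall_probs, pitfall_total,
                                seed = diet$seed, site = site)
  paths <- list(
    quadrats = file.path(dir, "quadrats.csv"),
    encounters = file.path(dir, "encounters.csv"),
    stomachs = file.path(dir, "stomachs.csv"),
    pitfalls = file.path(dir, "pitfalls.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(quadrats, paths$quadrats)
  readr::write_csv(dplyr::select(encounters, -"time_h"),
                   paths$encounters)
  readr::write_csv(stomachs, paths$stomachs)
  readr::write_csv(pitfalls, paths$pitfalls)
  jsonlite::write_json(
    list(availability = as.list(selection$availability),
         selection_weights = as.list(selection$selection_weights),
         n_encounters = selection$n_encounters,
         activity_mixture = selection$activity_mixture,
         prey_probs = as.list(diet$prey_probs),
         plant_weight_fraction = diet$plant_weight_fraction,
         pitfall_probs = as.list(pitfall_probs),
         seeds = list(selection = selection$seed, diet = diet$seed)),
    paths$ground_truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
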