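test_that("availability follows the ellipse-area and residual rules", {
  # one circular 2 m patch in a 400 m^2 quadrat -> pi/400
  q <- tibble::tibble(site = "S1", quadrat_id = "Q1",
                      category = "polylepis_tree",
                      diameter1_m = 2, diameter2_m = 2)
  a <- estimate_availability(q)
  expect_equal(a$availability[a$category == "polylepis_tree"],
               pi / 400, tolerance = 1e-12)
  expect_equal(a$availability[a$category == "uncovered_land"],
               1 - pi / 400, tolerance = 1e-12)
  expect_equal(sum(a$availability), 1, tolerance = 1e-9)

  # a patch-free quadrat is all uncovered land
  q0 <- tibble::tibble(site = "S1", quadrat_id = "Q1",
                       category = NA_character_,
                       diameter1_m = NA_real_, diameter2_m = NA_real_)
  a0 <- estimate_availability(q0)
  expect_equal(a0$availability[a0$category == "uncovered_land"], 1)

  # availability is the unweighted mean of per-quadrat proportions
  r1 <- sqrt(0.2 * 400 / pi) * 2  # diameter giving coverage 0.2
  r2 <- sqrt(0.4 * 400 / pi) * 2
  q2 <- tibble::tibble(site = "S1", quadrat_id = c("Q1", "Q2"),
                       category = "rock",
                       diameter1_m = c(r1, r2), diameter2_m = c(r1, r2))
  a2 <- estimate_availability(q2)
  expect_equal(a2$availability[a2$category == "rock"], 0.3,
               tolerance = 1e-12)

  # overshooting patches floor the residual at zero with a warning
  big <- sqrt(1.2 * 400 / pi) * 2
  qb <- tibble::tibble(site = "S1", quadrat_id = "Q1", category = "rock",
                       diameter1_m = big, diameter2_m = big)
  expect_warning(ab <- estimate_availability(qb), "exceeds")
  expect_equal(ab$availability[ab$category == "uncovered_land"], 0)
})

test_that("use tabulation drops unused categories and renormalizes availability", {
  avail9 <- c(setNames(rep(0.1, 9), paste0("m", 1:9)))
  avail9["m1"] <- 0.2
  counts <- c(m1 = 5, m2 = 3, m3 = 2, m4 = 1, m5 = 1, m6 = 1, m7 = 1,
              m8 = 0, m9 = 0)
  ut <- tabulate_use(counts, avail9, drop_unused = TRUE)
  expect_equal(attr(ut, "n_retained"), 7)
  expect_setequal(attr(ut, "dropped"), c("m8", "m9"))
  expect_equal(sum(attr(ut, "availability")), 1, tolerance = 1e-12)
  expect_error(tabulate_use(c(m1 = 0)), "no uses")

  # single category used
  ut1 <- tabulate_use(c(m1 = 12), drop_unused = TRUE)
  expect_equal(ut1$proportion, 1)
})

test_that("selection ratios and standard errors match the closed forms", {
  # u+=100, p=0.5, a=0.25 -> Wi=2, SE=0.2
  sr <- selection_ratios(c(a = 50, b = 50), c(a = 0.25, b = 0.75))
  expect_equal(sr$wi[1], 2)
  expect_equal(sr$se[1], sqrt(0.5 * 0.5 / (100 * 0.25^2)))
  expect_equal(sr$se[1], 0.2)

  # use proportional to availability -> all Wi = 1
  sr1 <- selection_ratios(c(a = 25, b = 75), c(a = 0.25, b = 0.75))
  expect_equal(sr1$wi, c(1, 1))

  # Wi is invariant to scaling all counts
  sr2 <- selection_ratios(c(a = 250, b = 750), c(a = 0.25, b = 0.75))
  expect_equal(sr2$wi, sr1$wi)

  expect_error(selection_ratios(c(a = 1, b = 1), c(a = 0, b = 1)),
               "unavailable")
})

test_that("sampled-availability variance exceeds the known-availability one", {
  reps <- cbind(a = c(0.2, 0.3, 0.25, 0.28), b = c(0.8, 0.7, 0.75, 0.72))
  known <- selection_ratios(c(a = 30, b = 70), c(a = 0.25, b = 0.75))
  sampled <- selection_ratios(c(a = 30, b = 70), c(a = 0.25, b = 0.75),
                              variance_mode = "sampled_availability",
                              availability_replicates = reps)
  expect_true(all(sampled$se > known$se))
})

test_that("known-availability SE agrees with a bootstrap SE at large samples", {
  withr::local_seed(11)
  a <- c(a = 0.3, b = 0.5, c = 0.2)
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  u_plus <- 2000
  counts <- as.vector(rmultinom(1, u_plus, p))
  names(counts) <- names(p)
  sr <- selection_ratios(counts, a)
  boot <- replicate(500, {
    res <- as.vector(rmultinom(1, u_plus, counts / u_plus))
    (res / u_plus) / a
  })
  boot_se <- apply(boot, 1, sd)
  expect_equal(sr$se, unname(boot_se), tolerance = 0.1)
})

test_that("Bonferroni intervals implement both multiplier conventions", {
  # textbook: alpha/(2I); I = 1 reduces to the plain normal interval
  ci <- bonferroni_ci(1, 0.5, alpha = 0.05, n_resources = 1)
  expect_equal(ci$ci_lo, 1 - qnorm(0.975) * 0.5, tolerance = 1e-9)
  expect_equal(round(ci$ci_lo, 3), 0.020)
  expect_equal(round(ci$ci_hi, 3), 1.980)

  # paper_compat: alpha/I
  cip <- bonferroni_ci(0.424, 0.125, n_resources = 7,
                       convention = "paper_compat")
  expect_equal(round(cip$ci_lo, 3), 0.118)
  expect_equal(round(cip$ci_hi, 3), 0.730)

  # zero SE degenerates to a point; negative lower bounds truncate to 0
  ci0 <- bonferroni_ci(2, 0, n_resources = 5)
  expect_equal(c(ci0$ci_lo, ci0$ci_hi), c(2, 2))
  cin <- bonferroni_ci(0.1, 1, n_resources = 5)
  expect_equal(cin$ci_lo, 0)
  expect_error(bonferroni_ci(1, -0.1, n_resources = 2), "nonnegative")
})

test_that("interval classification follows the position relative to 1", {
  expect_equal(classify_selection(c(0.118, 0.000, 1.2),
                                  c(0.730, 2.811, 2.0)),
               c("negative", "indifferent", "positive"))
})

test_that("per-resource z-test matches the normal tail", {
  t1 <- per_resource_test(2, 0.5)
  expect_equal(t1$z, 2)
  expect_equal(t1$p, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(round(t1$p, 4), 0.0455)
  expect_equal(per_resource_test(1, 0.4)$p, 1)
  # degenerate SE
  expect_equal(per_resource_test(2, 0)$p, 0)
  expect_equal(per_resource_test(1, 0)$p, 1)
})

test_that("global log-likelihood statistic matches direct evaluation", {
  g0 <- global_loglik_test(c(a = 10, b = 10), c(a = 0.5, b = 0.5))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p.value, 1)
  g1 <- global_loglik_test(c(a = 15, b = 5), c(a = 0.5, b = 0.5))
  expect_equal(round(g1$statistic, 3), 5.232)
  expect_equal(g1$df, 1)
})

test_that("global test holds its type-I error under neutral selection", {
  withr::local_seed(21)
  a <- c(a = 0.351, b = 0.155, c = 0.096, d = 0.081, e = 0.057,
         f = 0.200, g = 0.060)
  p_values <- replicate(1000, {
    u <- as.vector(rmultinom(1, 168, a))
    names(u) <- names(a)
    global_loglik_test(u, a)$p.value
  })
  expect_gt(mean(p_values < 0.05), 0.03)
  expect_lt(mean(p_values < 0.05), 0.07)
})

test_that("standardized index normalizes ratios and sums to one", {
  wi <- c(0.424, 0.613, 0.807, 0.147, 1.159, 1.783, 4.089)
  bi <- standardized_index(wi)
  expect_equal(sum(bi), 1, tolerance = 1e-12)
  expect_equal(round(bi[7], 3), 0.453)  # uncovered land
  expect_equal(round(bi[4], 3), 0.016)  # nonthorny bushes
  expect_equal(standardized_index(rep(2, 5)), rep(0.2, 5))
})

test_that("simultaneous interval coverage is at least nominal under neutrality", {
  withr::local_seed(31)
  a <- c(a = 0.351, b = 0.155, c = 0.096, d = 0.081, e = 0.057,
         f = 0.200, g = 0.060)
  covered <- replicate(400, {
    u <- as.vector(rmultinom(1, 500, a))
    names(u) <- names(a)
    st <- selection_analysis(u, a, drop_unused = FALSE)
    all(st$ci_lo <= 1 & st$ci_hi >= 1)
  })
  # nominal 0.95 simultaneous; allow 2 MC standard errors below
  expect_gte(mean(covered), 0.95 - 2 * sqrt(0.95 * 0.05 / 400))
})

test_that("selection_analysis assembles the full table coherently", {
  ex <- pooled_example("pooled")
  st <- selection_analysis(ex$counts, ex$available,
                           ci_convention = "paper_compat")
  expect_s3_class(st, "selection_table")
  expect_equal(sum(st$bi), 1, tolerance = 1e-12)
  expect_true(all(st$ci_lo <= st$wi & st$wi <= st$ci_hi))
  expect_equal(attr(st, "bonferroni_level"), 0.05 / 7)
  g <- glance(st)
  expect_equal(g$df, 6)
  expect_named(tidy(st),
               c("category", "available", "used_count", "used", "wi",
                 "se", "ci_lo", "ci_hi", "z", "p", "significant",
                 "classification", "bi"))
})
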