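test_that("diet table reproduces the published site columns", {
  for (site in c("el_simbral", "tuctumpaya")) {
    d <- diet_site_vectors(site)
    dt <- diet_table(d$n, d$f, d$w, d$n_stomachs)
    expect_equal(sum(dt$pct_n), 100, tolerance = 1e-9)
    expect_equal(sum(dt$pct_iri), 100, tolerance = 1e-9)
    expect_true(all(dt$f <= d$n_stomachs))
  }
  es <- diet_site_vectors("el_simbral")
  dt <- diet_table(es$n, es$f, es$w, es$n_stomachs)
  lyg <- dt[dt$prey_category == "Lygaeidae", ]
  expect_equal(round(lyg$pct_n, 1), 46.9)
  expect_equal(round(lyg$pct_f, 1), 92.9)
  expect_equal(lyg$pct_iri, 62.9, tolerance = 0.3)
  expect_equal(lyg$hierarchy, "secondary")
  expect_true(all(dt$hierarchy[dt$prey_category != "Lygaeidae"] ==
                    "accidental"))
})

test_that("the pooled frequency dialect divides by total item frequency", {
  p <- diet_site_vectors("pooled")
  dt <- diet_table(p$n, p$f, p$w, p$n_stomachs,
                   freq_denominator = "total_item_frequency")
  lyg <- dt[dt$prey_category == "Lygaeidae", ]
  expect_equal(round(lyg$pct_f, 1), 20.7)  # 30 / 145
  expect_equal(sum(dt$pct_f), 100, tolerance = 1e-9)
})

test_that("degenerate diet tables behave as specified", {
  dt <- diet_table(c(Lygaeidae = 5), c(Lygaeidae = 3),
                   c(Lygaeidae = 0.01), n_stomachs = 3)
  expect_equal(dt$pct_n, 100)
  expect_equal(dt$pct_f, 100)
  expect_equal(dt$iri, 20000)
  expect_equal(dt$pct_iri, 100)
  expect_equal(dt$hierarchy, "fundamental")

  expect_error(diet_table(c(a = 1), c(a = 1), c(a = 0), 1), "weight")
  expect_error(diet_table(c(a = 1), c(a = 5), c(a = 0.1), 3),
               "exceed")
  expect_error(diet_table(c(a = 1), c(a = 1), c(a = 0.1), 0),
               "no stomachs")
})

test_that("stomach-level tabulation excludes plant mass from count columns", {
  s <- tibble::tibble(
    site = "S1",
    individual_id = c("L1", "L1", "L2", "L2", "L3"),
    sex = "f",
    prey_category = c("Lygaeidae", "plant_material", "Lygaeidae",
                      "Acari", "plant_material"),
    count = c(4, NA, 2, 3, NA),
    dry_weight_g = c(0.004, 0.05, 0.002, 0.001, 0.03)
  )
  dt <- tabulate_diet(s)
  expect_setequal(dt$prey_category, c("Lygaeidae", "Acari"))
  expect_equal(attr(dt, "n_stomachs"), 3L)  # plant-only stomach counts
  expect_equal(dt$f[dt$prey_category == "Lygaeidae"], 2)
  expect_equal(attr(dt, "plant_pct_w"),
               100 * 0.08 / (0.08 + 0.007), tolerance = 1e-9)
  expect_equal(attr(dt, "diet_mode"), "herbivorous")
  expect_equal(glance(dt)$n_categories, 2)
})

test_that("hierarchy and diet-mode bands close on the lower band", {
  expect_equal(classify_hierarchy(c(100, 75.1, 75, 62.9, 50, 44.8,
                                    25, 3)),
               c("fundamental", "fundamental", "secondary",
                 "secondary", "accessory", "accessory", "accidental",
                 "accidental"))
  expect_equal(diet_mode(c(0, 10, 10.5, 47.924, 50, 50.1, 68.865)),
               c("insectivorous", "insectivorous", "omnivorous",
                 "omnivorous", "omnivorous", "herbivorous",
                 "herbivorous"))
})

test_that("Levins breadth spans 0 (specialist) to 1 (uniform)", {
  expect_equal(levins_breadth(rep(1 / 6, 6)), 1)
  expect_equal(levins_breadth(c(1, 0, 0)), 0)
  expect_equal(levins_breadth(c(a = 10)), 0)

  # averaged method: two one-category individuals give p = (0.5, 0.5)
  s <- tibble::tibble(individual_id = c("L1", "L2"),
                      prey_category = c("a", "b"),
                      count = c(10, 1))
  expect_equal(levins_breadth(s, method = "averaged"), 1)
  # aggregated method uses pooled counts instead
  expect_equal(levins_breadth(s, method = "aggregated"),
               levins_breadth(c(10, 1)))

  # both methods agree when individuals share identical proportions
  s2 <- tibble::tibble(individual_id = rep(c("L1", "L2"), each = 2),
                       prey_category = rep(c("a", "b"), 2),
                       count = c(2, 6, 1, 3))
  expect_equal(levins_breadth(s2, "averaged"),
               levins_breadth(s2, "aggregated"), tolerance = 1e-12)

  # a fixed category universe widens the denominator
  expect_lt(levins_breadth(c(0.5, 0.5), n_categories = 10),
            levins_breadth(c(0.5, 0.5)))
})

test_that("Pianka overlap is symmetric, scale-invariant and bounded", {
  expect_equal(pianka_overlap(c(a = 1, b = 1), c(a = 3, b = 3)), 1)
  expect_equal(pianka_overlap(c(a = 1), c(b = 1)), 0)
  expect_equal(pianka_overlap(c(0.5, 0.5), c(1, 0)), 0.7071,
               tolerance = 1e-4)
  p <- c(a = 0.2, b = 0.5, c = 0.3)
  q <- c(a = 0.6, b = 0.1, c = 0.3)
  expect_equal(pianka_overlap(p, q), pianka_overlap(q, p))
  expect_equal(pianka_overlap(p * 7, q), pianka_overlap(p, q))
})

test_that("Hill numbers reduce to species counts on even communities", {
  expect_equal(hill_effective_species(rep(5, 10), q = 1), 10)
  expect_equal(hill_effective_species(rep(5, 10), q = 2), 10)
  expect_equal(hill_effective_species(rep(5, 10), q = 0), 10)
  expect_equal(round(hill_effective_species(c(50, 25, 25), q = 1), 3),
               2.828)
  expect_equal(hill_effective_species(c(100), q = 1), 1)
  # cross-check against vegan's Shannon entropy
  skip_if_not_installed("vegan")
  cnt <- c(50, 25, 12, 8, 5)
  expect_equal(hill_effective_species(cnt, 1),
               exp(vegan::diversity(cnt, "shannon")), tolerance = 1e-12)
})

test_that("prey selection recovers enrichment against pitfall availability", {
  # use = availability -> all Wi = 1
  pit <- tibble::tibble(site = "S1", line_id = "P1",
                        prey_category = c("a", "b"), count = c(60, 40))
  dt <- tibble::tibble(prey_category = c("a", "b"), n = c(60, 40))
  st <- prey_selection(dt, pit)
  expect_equal(st$wi, c(1, 1), tolerance = 1e-9)

  # 3x enrichment of one prey in the diet at large n
  probs <- c(a = 0.2, b = 0.4, c = 0.4)
  wts <- c(a = 3, b = 1, c = 1)
  use_probs <- probs * wts / sum(probs * wts)
  withr::local_seed(61)
  diet_counts <- as.vector(rmultinom(1, 5000, use_probs))
  names(diet_counts) <- names(probs)
  pitl <- simulate_pitfalls(probs, 20000, seed = 62L)
  st2 <- prey_selection(tibble::tibble(prey_category = names(diet_counts),
                                       n = diet_counts), pitl)
  wa <- st2$wi[st2$category == "a"] / sum(st2$wi * st2$available)
  # Wi for the enriched prey about 3x the others
  expect_equal(st2$wi[st2$category == "a"] /
                 st2$wi[st2$category == "b"], 3, tolerance = 0.25)

  # diet category absent from pitfalls is flagged and unscored
  dt3 <- tibble::tibble(prey_category = c("a", "b", "zz"),
                        n = c(50, 40, 10))
  expect_warning(st3 <- prey_selection(dt3, pit), "zz")
  expect_false("zz" %in% st3$category)
  expect_equal(attr(st3, "unscored"), "zz")
})
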