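test_that("Bray-Curtis matches hand values and the vegan implementation", {
  m <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.matrix(bray_curtis(m))["a", "b"], 1)
  expect_equal(as.matrix(bray_curtis(rbind(c(2, 1), c(2, 1))))[1, 2], 0)
  # sqrt transform: (|2-1| + |0-1|) / (3 + 1)
  expect_equal(as.matrix(bray_curtis(rbind(c(4, 0), c(1, 1)),
                                     transform = "sqrt"))[1, 2], 0.5)
  expect_warning(bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")

  skip_if_not_installed("vegan")
  withr::local_seed(71)
  x <- matrix(rpois(60, 5), nrow = 6)
  expect_equal(as.vector(bray_curtis(x)),
               as.vector(vegan::vegdist(x, "bray")), tolerance = 1e-12)
  expect_equal(as.vector(bray_curtis(x, "sqrt")),
               as.vector(vegan::vegdist(sqrt(x), "bray")),
               tolerance = 1e-12)
})

test_that("PERMANOVA reduces to classical ANOVA on 1-D Euclidean data", {
  withr::local_seed(72)
  y <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  pm <- permanova(dist(y), g, n_permutations = 49, seed = 1)
  f_classical <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(pm$statistic, f_classical, tolerance = 1e-9)

  skip_if_not_installed("vegan")
  x <- matrix(rpois(18 * 5, 4), nrow = 18)
  d <- bray_curtis(x)
  pm2 <- permanova(d, g, n_permutations = 49, seed = 1)
  ad <- vegan::adonis2(d ~ g, permutations = 49)
  expect_equal(pm2$statistic, ad$F[1], tolerance = 1e-9)
})

test_that("exhaustive permutation p equals the enumeration oracle", {
  d <- dist(c(0, 1, 10, 11))
  pm <- permanova(d, c("a", "a", "b", "b"), exhaustive = TRUE)
  expect_equal(pm$p.value, 1 / 3, tolerance = 1e-12)

  # identical compositions in both groups: no separation, p = 1
  m <- rbind(c(3, 1), c(3, 1), c(3, 1), c(3, 1))
  pm0 <- suppressWarnings(
    permanova(bray_curtis(m), c("a", "a", "b", "b"),
              exhaustive = TRUE))
  expect_equal(pm0$p.value, 1)

  expect_error(permanova(d, c("a", "b", "b", "b"),
                         n_permutations = 9),
               "at least two samples")
})

test_that("PERMANOVA holds its type-I error under the null", {
  withr::local_seed(73)
  rejections <- replicate(500, {
    x <- matrix(rpois(12 * 4, 5), nrow = 12)
    g <- rep(c("a", "b"), each = 6)
    pm <- permanova(bray_curtis(x), g, n_permutations = 99)
    pm$p.value <= 0.05
  })
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("PCoA embedding reproduces Euclidean distances exactly", {
  withr::local_seed(74)
  x <- matrix(rnorm(8 * 3), nrow = 8)
  d <- dist(x)
  emb <- herpeco:::pcoa_embed(d)
  expect_true(all(emb$positive))
  expect_equal(as.vector(dist(emb$vectors)), as.vector(d),
               tolerance = 1e-8)
})

test_that("dispersion test separates unequal spreads and spares equal ones", {
  # mirror-image configurations have identical dispersion
  x <- c(rnorm(10, sd = 1))
  xy <- c(x, -x)
  g <- rep(c("a", "b"), each = 10)
  disp <- dispersion_homogeneity(dist(xy), g, n_permutations = 199,
                                 seed = 2)
  expect_gt(disp$p.value, 0.9)
  expect_equal(unname(diff(disp$group_means)), 0, tolerance = 1e-12)

  # 10x spread ratio is detected
  withr::local_seed(75)
  hits <- replicate(20, {
    a <- matrix(rnorm(20 * 2, sd = 1), ncol = 2)
    b <- matrix(rnorm(20 * 2, sd = 10), ncol = 2)
    d <- dist(rbind(a, b))
    dispersion_homogeneity(d, rep(c("a", "b"), each = 20),
                           n_permutations = 99)$p.value < 0.05
  })
  expect_gte(mean(hits), 0.95)

  skip_if_not_installed("vegan")
  # F statistic agrees with vegan::betadisper on a non-Euclidean matrix
  withr::local_seed(76)
  m <- matrix(rpois(12 * 4, 6), nrow = 12)
  d <- bray_curtis(m)
  g2 <- rep(c("a", "b"), each = 6)
  ours <- dispersion_homogeneity(d, g2, n_permutations = 19, seed = 1)
  bd <- vegan::betadisper(d, g2, type = "centroid")
  f_vegan <- stats::anova(bd)$`F value`[1]
  expect_equal(ours$statistic, f_vegan, tolerance = 1e-6)
})

test_that("NMDS embeds monotone data near-perfectly and improves on its start", {
  # collinear points: exact rank-preserving embedding in k = 1
  d <- dist(c(0, 1, 3, 7, 12))
  nm <- nmds(d, k = 1, n_restarts = 1, seed = 3)
  expect_lt(nm$stress, 0.01)

  # random dissimilarities: final stress <= classical-scaling start
  withr::local_seed(77)
  m <- matrix(runif(64), 8); diag(m) <- 0; m <- (m + t(m)) / 2
  dd <- stats::as.dist(m)
  start <- cmdscale(dd, k = 2)
  d0 <- as.matrix(dist(start))[lower.tri(m)]
  disp0 <- numeric(length(d0))
  ord <- order(dd)
  disp0[ord] <- isoreg(d0[ord])$yf
  stress_start <- sqrt(sum((d0 - disp0)^2) / sum(d0^2))
  nm2 <- nmds(dd, k = 2, n_restarts = 3, seed = 4)
  expect_lte(nm2$stress, stress_start + 1e-12)
  expect_true(all(diff(nm2$trace) <= 1e-12))

  # same seed -> identical coordinates; k >= n rejected
  nm3 <- nmds(dd, k = 2, n_restarts = 3, seed = 4)
  expect_identical(nm2$points, nm3$points)
  expect_error(nmds(dd, k = 8), "smaller")
})

test_that("NMDS stress is invariant to rotation, translation and scale", {
  withr::local_seed(78)
  x <- matrix(rnorm(7 * 2), ncol = 2)
  d <- dist(x)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  x2 <- 3 * x %*% rot + matrix(rep(c(5, -2), each = 7), ncol = 2)
  # the transformed configuration produces the same rank structure,
  # hence the same stress when used as a fixed configuration
  s1 <- herpeco:::nmds_run(as.matrix(d), x, 2, max_iter = 0, tol = 0)
  s2 <- herpeco:::nmds_run(as.matrix(d), x2, 2, max_iter = 0, tol = 0)
  expect_equal(s1$stress, s2$stress, tolerance = 1e-9)
})
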