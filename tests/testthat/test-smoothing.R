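test_that("spline fits reproduce polynomials in their span", {
  x <- seq(0, 200, length.out = 60)
  y <- 0.03 * x - 2
  for (k in c(4, 8)) {
    fit <- suppressWarnings(fit_curve(x, y, k = k))
    expect_lt(max(abs(fit$grid$fit - (0.03 * fit$grid$x - 2))), 1e-6)
  }
  cst <- suppressWarnings(fit_curve(x, rep(1.4, 60), k = 5))
  expect_lt(max(abs(cst$grid$fit - 1.4)), 1e-8)
  expect_true(all(cst$grid$lower <= 1.4 + 1e-8 & cst$grid$upper >= 1.4 - 1e-8))
})

test_that("fit recovers a smooth truth within tolerance and coverage", {
  set.seed(3)
  x <- runif(200, 0, 150)
  truth <- function(v) sin(v / 30)
  y <- truth(x) + rnorm(200, 0, 0.2)
  fit <- fit_curve(x, y, k = 10)
  g <- fit$grid
  expect_lt(sqrt(mean((g$fit - truth(g$x))^2)), 0.15)
  cover <- mean(g$lower <= truth(g$x) & g$upper >= truth(g$x))
  expect_gte(cover, 0.9)
})

test_that("basis dimension selection is adaptive and deterministic", {
  set.seed(4)
  x <- seq(0, 100, length.out = 150)
  y_lin <- 0.01 * x + rnorm(150, 0, 0.1)
  expect_equal(choose_k(x, y_lin), 4) # smallest candidate passes

  y_wig <- sin(x / 4) + rnorm(150, 0, 0.1) # needs many basis functions
  expect_gte(suppressWarnings(choose_k(x, y_wig)), 10)

  expect_identical(suppressWarnings(choose_k(x, y_wig)),
                   suppressWarnings(choose_k(x, y_wig)))
})

test_that("band is pointwise and the mask marks the null z band", {
  set.seed(5)
  x <- runif(150, 0, 100)
  y <- ifelse(x < 40, 4, 0) * exp(-x / 50) + rnorm(150, 0.0, 0.3)
  fit <- fit_curve(x, y, k = 8)
  g <- fit$grid
  expect_true(all(g$lower <= g$fit & g$fit <= g$upper))
  expect_identical(g$significant, abs(g$fit) > 1.96)
  expect_true(any(g$significant[g$x < 30]))
  expect_false(any(g$significant[g$x > 80]))
})

test_that("the smoother is affine in the response", {
  set.seed(6)
  x <- runif(100, 0, 50)
  y <- sin(x / 10) + rnorm(100, 0, 0.2)
  f1 <- fit_curve(x, y, k = 8)
  f2 <- fit_curve(x, 3 * y - 1, k = 8)
  expect_equal(f2$grid$fit, 3 * f1$grid$fit - 1, tolerance = 1e-6)
})

test_that("band width shrinks as replication grows", {
  set.seed(7)
  xb <- seq(0, 150, length.out = 15)
  mk <- function(nrep) {
    x <- rep(xb, nrep)
    y <- sin(x / 40) + rnorm(length(x), 0, 0.5)
    fit_curve(x, y, k = 6)
  }
  w10 <- mk(10)$grid
  w40 <- mk(40)$grid
  expect_lt(median(w40$upper - w40$lower), median(w10$upper - w10$lower))
})

test_that("surfaces keep phylogenetic features across annuli", {
  set.seed(8)
  ann <- seq(2, 12, length.out = 10)
  phy <- seq(0, 200, length.out = 12)
  grid <- expand.grid(a = ann, p = phy, rep = 1:6)
  # separable signal: bump at 100 Ma decaying with physical distance
  f <- function(p) 4 * exp(-(p - 100)^2 / (2 * 25^2))
  g <- function(a) exp(-a / 8)
  z <- f(grid$p) * g(grid$a) + rnorm(nrow(grid), 0, 0.4)
  sf <- fit_surface(grid$a, grid$p, z, k = c(5, 8))
  gg <- sf$grid
  for (a in unique(gg$physical)) {
    s <- gg[gg$physical == a, ]
    am <- s$phylo[which.max(s$fit)]
    expect_lt(abs(am - 100), 200 / 12 + 1e-9) # within one bin width
  }
  # mask gray where the planted effect is null (far phylo, far annuli)
  far <- gg[gg$phylo > 170 & gg$physical > 8, ]
  expect_true(mean(far$significant) < 0.2)

  # cross-sections agree with independent 1D fits on feature location
  a1 <- grid$rep == 1 | TRUE
  one <- grid$a == ann[1]
  cf <- fit_curve(grid$p[one], z[one], k = 8)
  s1 <- gg[gg$physical == ann[1], ]
  expect_lt(abs(s1$phylo[which.max(s1$fit)] - cf$grid$x[which.max(cf$grid$fit)]),
            200 / 12 + 1e-9)

  # z independent of the physical axis -> constant cross-sections
  z2 <- f(grid$p) + rnorm(nrow(grid), 0, 0.3)
  sf2 <- fit_surface(grid$a, grid$p, z2, k = c(4, 8))
  g2 <- sf2$grid
  rng <- tapply(g2$fit, g2$phylo, function(v) diff(range(v)))
  expect_lt(median(rng), 0.5)
})

test_that("extrema are located with band-based screening", {
  set.seed(9)
  x <- rep(seq(0, 200, length.out = 25), 10)
  # monotone curve: no extrema
  fitm <- fit_curve(x, -x / 50 + rnorm(length(x), 0, 0.2), k = 6)
  expect_equal(nrow(locate_extrema(fitm)), 0)

  # planted valley at 100 Ma, depth 3 z units, on a gentle background
  y <- -3 * exp(-(x - 100)^2 / (2 * 15^2)) + rnorm(length(x), 0, 0.3)
  fitv <- fit_curve(x, y, k = 10)
  ex <- locate_extrema(fitv)
  expect_gte(nrow(ex), 1)
  expect_equal(ex$type[1], "valley")
  expect_lt(abs(ex$x[1] - 100), 200 / 10) # within about one bin

  # two planted features recovered in depth order
  y2 <- -3 * exp(-(x - 60)^2 / 450) + 1.8 * exp(-(x - 160)^2 / 450) +
    rnorm(length(x), 0, 0.25)
  fit2 <- fit_curve(x, y2, k = 12)
  ex2 <- locate_extrema(fit2)
  expect_gte(nrow(ex2), 2)
  expect_equal(ex2$type[1:2], c("valley", "peak"))
  expect_gt(abs(ex2$depth[1]), abs(ex2$depth[2]))
})

test_that("result wrappers fit curves and surfaces from z points", {
  sim <- small_null_sim()
  res <- run_eaa_test(sim$plot, sim$D, tests = 1,
                      config = eaa_config(n_annuli = 5, n_phylo_bins = 4,
                                          replicates = 4, iterations = 30, seed = 3))
  cf <- fit_result_curve(res, 1, annulus = 1, k = 4)
  expect_s3_class(cf, "eaa_smooth")
  expect_equal(cf$kind, "curve")
  sf <- fit_result_surface(res, 1, k = c(4, 4))
  expect_equal(sf$kind, "surface")
  expect_equal(length(unique(sf$grid$physical)), 5)
  # plots build without error
  expect_s3_class(ggplot2::autoplot(cf), "ggplot")
  expect_s3_class(plot_surface(sf), "ggplot")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  # tidiers
  expect_s3_class(generics::tidy(res), "tbl_df")
  expect_s3_class(generics::glance(res), "tbl_df")
  expect_equal(nrow(generics::tidy(cf)), 100)
  expect_equal(generics::glance(cf)$k_used, "4")
})
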