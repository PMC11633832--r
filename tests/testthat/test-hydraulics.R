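test_that("elliptical conduit conductivity matches hand-computed values", {
  eta <- 1.002e-9
  # circular vessel d = 50 um: closed form pi d^4 / (128 eta)
  d <- 50e-6
  expect_equal(kh_theoretical(d, d, eta), pi * d^4 / (128 * eta))
  expect_equal(kh_theoretical(d, d, eta), 1.531e-10, tolerance = 1e-3)
  # elliptical vessel a = 20 um, b = 40 um: direct arithmetic oracle
  a <- 20e-6; b <- 40e-6
  expect_equal(kh_theoretical(a, b, eta),
               pi / (64 * eta) * a^3 * b^3 / (a^2 + b^2))
  expect_equal(kh_theoretical(a, b, eta), 1.254e-11, tolerance = 1e-3)
  # additive over vessels
  expect_equal(kh_theoretical(c(a, a), c(b, b), eta),
               2 * kh_theoretical(a, b, eta))
  expect_error(kh_theoretical(numeric(0), numeric(0)), "one vessel")
  expect_error(kh_theoretical(-1e-6, 2e-6), "> 0")
  expect_error(kh_theoretical(3e-6, 2e-6), "exceeds")
})

test_that("circular limit equals Hagen-Poiseuille for every diameter", {
  eta <- 1.002e-9
  for (d in c(5e-6, 2e-5, 5e-5, 1e-4, 3e-4))
    expect_equal(kh_theoretical(d, d, eta), pi * d^4 / (128 * eta),
                 tolerance = 1e-12)
})

test_that("unit conversion is the dimensional-analysis constant", {
  expect_equal(convert_kh_units(1), 847294560, tolerance = 1e-6)
  expect_equal(convert_kh_units(0), 0)
  x <- c(1e-12, 3.7e-10)
  expect_equal(convert_kh_units_inv(convert_kh_units(x)), x)
})

test_that("power-law conductivity fits recover generating parameters", {
  d <- seq(0.05, 0.5, length.out = 12)
  fit <- fit_kx_vs_diameter(d, 2 * d^3)
  expect_equal(fit$alpha, 2, tolerance = 1e-6)
  expect_equal(fit$beta, 3, tolerance = 1e-6)
  # constant data -> beta ~ 0, alpha ~ the constant
  fitc <- fit_kx_vs_diameter(d, rep(4.2, 12))
  expect_equal(fitc$beta, 0, tolerance = 1e-6)
  expect_equal(fitc$alpha, 4.2, tolerance = 1e-6)
  # noisy recovery at the field's sample size (33 cross-sections)
  set.seed(12)
  d33 <- runif(33, 0.05, 0.6)
  kh33 <- 2 * d33^3 * exp(rnorm(33, 0, 0.1))
  fitn <- fit_kx_vs_diameter(d33, kh33)
  se_beta <- sqrt(diag(stats::vcov(fitn$fitted)))[["beta"]]
  expect_lt(abs(fitn$beta - 3), 2 * se_beta)
  expect_error(fit_kx_vs_diameter(c(-0.1, 0.2, 0.3), c(1, 2, 3)),
               "positive")
  expect_error(fit_kx_vs_diameter(c(0.2, 0.2, 0.2), c(1, 2, 3)),
               "distinct")
})

test_that("trivial SUF cases: normalization and symmetry", {
  hp <- hydraulic_params()
  one <- vertical_axis_system(length_cm = 5, radius = 0.1, n = 2, age = 10)
  sol <- solve_suf_krs(one, hp)
  expect_equal(sol$suf, 1)
  # two identical segments in parallel from the collar
  st <- root_axis(rbind(c(0, 0, 1), c(0, 0, 0)), type = 0L, radius = 0.3)
  a1 <- root_axis(rbind(c(0, 0, 0), c(5, 0, -5)), type = 1L, radius = 0.2,
                  ages = c(10, 10), parent = 1L, parent_node = 2L)
  a2 <- root_axis(rbind(c(0, 0, 0), c(-5, 0, -5)), type = 1L, radius = 0.2,
                  ages = c(10, 10), parent = 1L, parent_node = 2L)
  hp1 <- hydraulic_params(kr_table = data.frame(
    type = c(0, 1), age_min = 0, age_max = Inf, kr = c(0, 1e-4)))
  sol2 <- solve_suf_krs(root_system(list(st, a1, a2), validate = FALSE), hp1)
  expect_equal(sol2$suf, c(0, 0.5, 0.5))
})

test_that("numeric Krs matches the closed-form single-root solution", {
  L <- 50; a <- 0.2; kr <- 2e-5; kx <- 0.1; n <- 2000
  rs <- vertical_axis_system(length_cm = L, radius = a, n = n + 1,
                             age = 100)  # suberized kr class
  hp <- hydraulic_params(kx_alpha = kx / (2 * a)^2.5, kx_beta = 2.5)
  sol <- solve_suf_krs(rs, hp)
  exact <- krs_single_root(L, kx, kr, a)
  expect_equal(sol$krs, exact, tolerance = 1e-6)
  # SUF independent of the imposed potentials (linearity)
  sol2 <- solve_suf_krs(rs, hp, psi_soil = -300, psi_collar = -15000)
  expect_equal(sol2$suf, sol$suf, tolerance = 1e-9)
  expect_equal(sol2$krs, sol$krs, tolerance = 1e-9)
})

test_that("SUF sums to one and is non-negative on random trees", {
  hp <- hydraulic_params()
  for (seed in c(3, 14, 15)) {
    rs <- random_root_system(seed)
    sol <- solve_suf_krs(rs, hp)
    expect_equal(sum(sol$suf), 1, tolerance = 1e-8)
    expect_true(all(sol$suf >= -1e-12))
    expect_gt(sol$krs, 0)
  }
})

test_that("Krs is monotone in kr and invariant to dead segments", {
  rs <- random_root_system(6)
  base <- hydraulic_params()
  sol0 <- solve_suf_krs(rs, base)
  up <- base
  up$kr_table$kr <- up$kr_table$kr * 2
  expect_gt(solve_suf_krs(rs, up)$krs, sol0$krs)
  # adding a zero-radial-conductance axis leaves Krs unchanged
  ktab <- base$kr_table
  ktab$kr[ktab$type == 3] <- 0
  hp0 <- hydraulic_params(kr_table = ktab)
  sol1 <- solve_suf_krs(rs, hp0)
  rs2 <- rs
  host <- which(axis_types(rs) == 2L)[1]
  nd <- rs$axes[[host]]$nodes
  stub <- root_axis(rbind(nd[2, ], nd[2, ] + c(0.5, 0, -0.5)), type = 3L,
                    radius = 0.05, ages = c(50, 50),
                    parent = host, parent_node = 2L)
  rs2$axes[[length(rs2$axes) + 1L]] <- stub
  expect_equal(solve_suf_krs(rs2, hp0)$krs, sol1$krs, tolerance = 1e-10)
})

test_that("aging roots into a lower-kr class shifts SUF away from them", {
  # two identical laterals, one old (suberized class) one young
  st <- root_axis(rbind(c(0, 0, 1), c(0, 0, 0)), type = 0L, radius = 0.3)
  mk <- function(sgn, age) {
    z <- seq(0, -20, length.out = 21)
    nd <- cbind(sgn * seq(0, 20, length.out = 21), 0, z)
    nd[1, ] <- c(0, 0, 0)
    root_axis(nd, type = 2L, radius = 0.1, ages = rep(age, 21),
              parent = 1L, parent_node = 2L)
  }
  rs <- root_system(list(st, mk(1, 100), mk(-1, 5)), validate = FALSE)
  sol <- solve_suf_krs(rs, hydraulic_params())
  old_suf <- sum(sol$suf[sol$segments$axis == 2])
  young_suf <- sum(sol$suf[sol$segments$axis == 3])
  expect_lt(old_suf, young_suf)
  # and making the old root young again restores symmetry
  rs_sym <- root_system(list(st, mk(1, 5), mk(-1, 5)), validate = FALSE)
  sol_sym <- solve_suf_krs(rs_sym, hydraulic_params())
  expect_equal(sum(sol_sym$suf[sol_sym$segments$axis == 2]),
               sum(sol_sym$suf[sol_sym$segments$axis == 3]),
               tolerance = 1e-9)
})

test_that("SUF depth profiles conserve mass and refine consistently", {
  rs <- random_root_system(9)
  sol <- solve_suf_krs(rs, hydraulic_params())
  pr1 <- suf_profile(sol, layer_thickness = 1)
  expect_equal(sum(pr1$layers$suf), 1, tolerance = 1e-9)
  expect_equal(sum(pr1$horizons$suf), 1, tolerance = 1e-9)
  # halving the layer thickness leaves horizon aggregates unchanged
  pr05 <- suf_profile(sol, layer_thickness = 0.5)
  expect_equal(pr05$horizons$suf, pr1$horizons$suf, tolerance = 1e-9)
  # all roots shallower than 30 cm -> all SUF in the first horizon
  shallow <- vertical_axis_system(length_cm = 25, radius = 0.1, n = 26,
                                  age = 10)
  ps <- suf_profile(solve_suf_krs(shallow, hydraulic_params()))
  expect_equal(ps$horizons$suf[ps$horizons$horizon == "0-30"], 1,
               tolerance = 1e-9)
})
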