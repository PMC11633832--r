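test_that("the elongation law has the right limits and values", {
  expect_equal(growth_length(0, 99.5, 0.28), 0)
  expect_equal(growth_length(1e7, 99.5, 0.28), 99.5, tolerance = 1e-6)
  # closed-form evaluation at the 6-month horizon
  expect_equal(growth_length(180, 99.5, 0.28), 39.54316, tolerance = 1e-5)
  expect_error(growth_length(-1, 10, 0.1), "negative")
  # monotone increasing, bounded
  t <- seq(0, 2000, by = 10)
  l <- growth_length(t, 47.2, 0.07)
  expect_true(all(diff(l) > 0))
  expect_true(all(l <= 47.2))
  # growth_time inverts it
  expect_equal(growth_time(growth_length(123, 47.2, 0.07), 47.2, 0.07), 123)
})

test_that("emergence schedule spaces laterals between basal and apical zones", {
  # constant interlateral distance: arithmetic case
  s <- emergence_schedule(8.4, rep(4.1, 30), 11.8, 99.5)
  expect_length(s, 20L)  # floor((87.7 - 8.4)/4.1) + 1
  expect_equal(s[1], 8.4)
  expect_equal(s[length(s)], 86.3, tolerance = 1e-9)
  expect_true(all(s <= 99.5 - 11.8))
  # basal + apical zones covering the root -> empty schedule
  expect_length(emergence_schedule(50, rep(4, 10), 60, 100), 0L)
  # activation time: the first lateral activates when the parent length
  # reaches s1 + la, by inversion of the elongation law
  t1 <- growth_time(8.4 + 11.8, 99.5, 0.28)
  expect_equal(growth_length(t1, 99.5, 0.28), 20.2, tolerance = 1e-9)
})

test_that("tropism objectives pick the intended candidate directions", {
  # N = 1: no choice, the single deflected candidate is returned
  set.seed(1)
  tp1 <- list(N = 1, sigma = 0.2, p_gravi = 1)
  h <- tropism_next_heading(c(0, 0, -1), 2L, tp1, 0.5)
  expect_equal(sqrt(sum(h^2)), 1, tolerance = 1e-12)
  # sigma = 0: candidates equal the old heading -> straight growth
  tp0 <- list(N = 5, sigma = 0, p_gravi = 1)
  expect_equal(as.numeric(tropism_next_heading(c(1, 0, 0), 2L, tp0, 0.5)),
               c(1, 0, 0))
  expect_error(tropism_next_heading(c(0, 0, 0), 2L, tp0, 0.5), "zero")
  # gravitropism turns a horizontal heading downward
  set.seed(2)
  tpg <- list(N = 4, sigma = 0.3, objective = "gravi")
  h <- c(1, 0, 0)
  for (k in 1:100) h <- tropism_next_heading(h, 2L, tpg, 0.5)
  expect_lt(h[3], -0.9)
  # plagiotropism keeps a downward heading near the horizontal plane
  set.seed(3)
  tpp <- list(N = 4, sigma = 0.3, objective = "plagio")
  h <- c(0, 0, -1)
  zs <- numeric(100)
  for (k in 1:100) { h <- tropism_next_heading(h, 2L, tpp, 0.5); zs[k] <- h[3] }
  expect_lt(mean(abs(zs[51:100])), 0.2)
  # selection property: with the gravitropic objective the chosen heading
  # is at least as downward as with no selection, on average
})

test_that("probabilistic draws follow the genotype threshold", {
  set.seed(9)
  tp <- list(N = 2, sigma = 0.2, p_gravi = 0.85)
  n <- 4000
  obj <- character(n)
  h <- c(0, 0, -1)
  for (k in seq_len(n)) {
    h2 <- tropism_next_heading(h, 2L, tp, 0.5)
    obj[k] <- attr(h2, "objective")
  }
  frac <- mean(obj == "gravi")
  expect_lt(abs(frac - 0.85), 3 * sqrt(0.85 * 0.15 / n))
})

test_that("static initialization keeps type-0/1 axes and schedules laterals", {
  tpl <- static_template(n_type1 = 7, n_type2_per = 3, seed = 2)
  gp <- genotype_params("101-14")
  st <- initialize_static(tpl, gp)
  expect_equal(sum(axis_types(st$static) == 1L), 7L)
  expect_equal(nrow(st$emergence), 21L)  # one per source type-2 axis
  # no type-2 roots in the source -> zero scheduled laterals
  tpl0 <- static_template(n_type1 = 3, n_type2_per = 0, seed = 2)
  st0 <- initialize_static(tpl0, gp)
  expect_equal(nrow(st0$emergence), 0L)
  sim0 <- simulate_growth(st0, days = 50, seed = 1)
  expect_equal(sort(unique(axis_types(sim0))), c(0L, 1L))
  # no type-1 axis -> error
  stem_only <- root_system(list(root_axis(rbind(c(0, 0, 2), c(0, 0, -10)),
                                          type = 0L)))
  expect_error(initialize_static(stem_only, gp), "type-1")
})

test_that("simulation is deterministic and respects the growth law", {
  gp <- genotype_params("101-14")
  tpl <- static_template(n_type1 = 4, n_type2_per = 3, seed = 8)
  st <- initialize_static(tpl, gp)
  sim1 <- simulate_growth(st, days = 120, seed = 77)
  sim2 <- simulate_growth(st, days = 120, seed = 77)
  expect_identical(lapply(sim1$axes, function(a) a$nodes),
                   lapply(sim2$axes, function(a) a$nodes))
  # days = 0 -> static system unchanged
  sim0 <- simulate_growth(st, days = 0, seed = 77)
  expect_equal(length(sim0$axes), length(st$static$axes))
  # static axes byte-identical before/after growth
  for (i in seq_along(st$static$axes))
    expect_identical(sim1$axes[[i]]$nodes, st$static$axes[[i]]$nodes)
  # every simulated axis matches the elongation law to 1e-6 cm and stays
  # below its lmax
  types <- axis_types(sim1)
  for (i in which(types == 2L)) {
    a <- sim1$axes[[i]]
    age <- 120  # all type-2 emerge at t = 0
    expect_equal(axis_length(a), growth_length(age, gp$type2$lmax,
                                               gp$type2$r),
                 tolerance = 1e-6)
    expect_lt(axis_length(a), gp$type2$lmax)
  }
  expect_error(simulate_growth(st, days = 10, dt = 0), "dt")
  expect_error(simulate_growth(st, days = -1), "days")
})

test_that("per-segment draw fraction approaches p_gravi in simulation", {
  gp <- genotype_params("101-14")
  tpl <- static_template(n_type1 = 8, n_type2_per = 6, seed = 3)
  sim <- simulate_growth(initialize_static(tpl, gp), days = 180, seed = 11)
  d <- attr(sim, "tropism_draws")
  n <- sum(d)
  expect_gt(n, 2000)
  expect_lt(abs(d[["gravi"]] / n - 0.85), 3 * sqrt(0.85 * 0.15 / n))
})

test_that("gravitropic populations end deeper than plagiotropic ones", {
  tip_depths <- function(p_gravi) {
    gp <- genotype_params("101-14")
    gp$type2$p_gravi <- p_gravi
    tpl <- static_template(n_type1 = 8, n_type2_per = 13, seed = 4)
    sim <- simulate_growth(initialize_static(tpl, gp), days = 180, seed = 4)
    tys <- axis_types(sim)
    vapply(sim$axes[tys == 2L], function(a) a$nodes[nrow(a$nodes), 3],
           numeric(1))
  }
  deep <- tip_depths(1)
  shallow <- tip_depths(0)
  expect_gte(length(deep), 100L)
  # two-sample comparison: strictly more negative tips under gravitropism
  expect_lt(mean(deep), mean(shallow) - 10)
  expect_lt(stats::t.test(deep, shallow)$p.value, 1e-6)
})

test_that("sigma = 0 grows straight type-2 roots regardless of N", {
  gp <- genotype_params("101-14")
  gp$type2$sigma <- 0; gp$type3$sigma <- 0
  tpl <- static_template(n_type1 = 2, n_type2_per = 2, seed = 6)
  sim <- simulate_growth(initialize_static(tpl, gp), days = 120, seed = 6)
  for (i in which(axis_types(sim) == 2L)) {
    nd <- sim$axes[[i]]$nodes
    chord <- sqrt(sum((nd[nrow(nd), ] - nd[1, ])^2))
    expect_equal(chord, axis_length(sim$axes[[i]]), tolerance = 1e-9)
  }
})
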