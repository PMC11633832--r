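test_that("cylinder formulas: single vertical axis traits", {
  rs <- vertical_axis_system(length_cm = 10, radius = 0.1, n = 11)
  tr <- compute_traits(rs)
  expect_equal(tr$total$length_cm, 10)
  expect_equal(tr$by_type$surface_cm2, 2 * pi * 0.1 * 10)
  expect_equal(tr$by_type$volume_cm3, pi * 0.01 * 10)
  expect_equal(tr$height_cm, 10)
  expect_equal(tr$width_cm, 0)
  # ten 1-cm bins of 1 cm root length each
  prof <- tr$depth_profile
  expect_equal(nrow(prof), 10L)
  expect_equal(prof$length_cm, rep(1, 10))
})

test_that("oblique segments are clipped linearly at bin boundaries", {
  # 45-degree segment crossing one boundary: each touched bin receives
  # sqrt(2) x (vertical extent within the bin)
  nd <- rbind(c(0, 0, -0.5), c(1, 0, -1.5))
  rs <- root_system(list(root_axis(nd, type = 2L, radius = 0.05)))
  prof <- depth_profile(rs, 1)
  expect_equal(prof$length_cm, c(sqrt(2) * 0.5, sqrt(2) * 0.5))
  # dense-resampling oracle on a random branched system
  rs2 <- random_root_system(21)
  prof2 <- depth_profile(rs2, 1)
  oracle <- depth_bins_oracle(rs2, 1)
  got <- prof2$length_cm[match(oracle$bin, prof2$depth_top)]
  expect_equal(got, oracle$length, tolerance = 1e-3)
})

test_that("depth profile conserves total length for any layer thickness", {
  rs <- random_root_system(8)
  total <- sum(axis_lengths(rs)[axis_types(rs) != 0L])
  for (h in c(0.3, 1, 2.7, 10))
    expect_equal(sum(depth_profile(rs, h)$length_cm), total,
                 tolerance = 1e-9)
  # boundary rule: a horizontal segment exactly on a boundary goes deep
  nd <- rbind(c(0, 0, -2), c(3, 0, -2))
  prof <- depth_profile(root_system(list(root_axis(nd, type = 2L))), 1)
  expect_equal(prof$depth_top[prof$length_cm > 0], 2)
})

test_that("hull volumes: cube and degenerate cases", {
  # root nodes at the 8 corners of a 1 m cube -> 1 m^3
  corners <- as.matrix(expand.grid(c(0, 100), c(0, 100), c(-100, 0)))
  axes <- list()
  for (i in seq_len(4)) {
    nd <- rbind(corners[2 * i - 1, ], corners[2 * i, ])
    axes[[i]] <- root_axis(nd, type = 1L, radius = 0.1)
  }
  rs <- root_system(axes, validate = FALSE)
  tr <- compute_traits(rs)
  expect_equal(tr$hull_volume_m3, 1.0, tolerance = 1e-9)
  expect_equal(tr$hull_area_xy_cm2, 1e4)
  # < 4 non-coplanar nodes -> volume 0, flagged
  flat <- convex_hull_volume(cbind(runif(10), runif(10), 0))
  expect_equal(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "degenerate")))
  # octahedron closed form 4/3, and scipy-style random check vs tetrahedra
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(convex_hull_volume(oct), 4 / 3, tolerance = 1e-12)
})

test_that("traits are invariant under horizontal rotation", {
  rs <- random_root_system(5)
  tr1 <- compute_traits(rs)
  tr2 <- compute_traits(rotate_root_system(rs, 0.83))
  expect_equal(tr2$total$length_cm, tr1$total$length_cm)
  expect_equal(tr2$height_cm, tr1$height_cm)
  expect_equal(tr2$width_cm, tr1$width_cm, tolerance = 1e-9)
  expect_equal(tr2$hull_volume_m3, tr1$hull_volume_m3, tolerance = 1e-9)
  expect_equal(tr2$depth_profile$length_cm, tr1$depth_profile$length_cm,
               tolerance = 1e-9)
})

test_that("branching parameters: hand-computed straight-axis case", {
  # straight 20-cm axis, branches at s = 8, 12, 16
  n <- 21L
  nd <- cbind(seq(0, 20, length.out = n), 0, -seq(0, 20, length.out = n))
  nd[, 1] <- nd[, 1] / sqrt(2) * sqrt(2)  # keep it simple: use arc = index
  nd <- cbind(seq(0, 20, 1), 0, 0)
  parent <- root_axis(nd, type = 2L, radius = 0.1)
  mk_lat <- function(j, dirv) {
    nd2 <- rbind(nd[j, ], nd[j, ] + dirv)
    root_axis(nd2, type = 3L, radius = 0.05, parent = 1L, parent_node = j)
  }
  rs <- root_system(list(parent, mk_lat(9L, c(0, 3, 0)),
                         mk_lat(13L, c(0, 0, -3)), mk_lat(17L, c(0, -3, 0))))
  bp <- branching_parameters(rs)
  expect_equal(unname(bp$type2$lb["mean"]), 8)
  expect_equal(unname(bp$type2$la["mean"]), 4)
  expect_equal(unname(bp$type2$ln["mean"]), 4)
  expect_equal(unname(bp$type2$ln["sd"]), 0)
  # laterals perpendicular to a straight parent -> theta = 90 degrees
  expect_equal(unname(bp$type3$theta["mean"]), 90)
  expect_equal(unname(bp$type3$a["mean"]), 0.05)
})

test_that("lmax and r estimation inverts the elongation law", {
  # lengths all equal lmax*(1 - exp(-1)) at age lmax/r -> recovers r
  lmax <- 80; r_true <- 0.4; age <- lmax / r_true
  lens <- rep(lmax * (1 - exp(-1)), 5)
  lens[1] <- lmax  # the maximum defines lmax
  est <- estimate_lmax_r(lens, age)
  expect_equal(est$lmax, lmax)
  expect_equal(growth_length(age, est$lmax, est$r), mean(lens),
               tolerance = 1e-9)
  # bisection oracle case: mean 40.7 cm, lmax 99.5 cm, age 180 d
  lens2 <- c(99.5, 11.3, 11.3)  # mean 40.7
  est2 <- estimate_lmax_r(lens2, 180)
  expect_equal(est2$r, 0.29, tolerance = 0.01)
  expect_equal(growth_length(180, 99.5, est2$r), 40.7, tolerance = 1e-8)
  # degenerate and error cases
  expect_equal(estimate_lmax_r(0, 100)$r, 0)
  expect_error(estimate_lmax_r(c(50, 50), 180), "unbounded")
  expect_error(estimate_lmax_r(50, 0), "age")
})

test_that("tropism probability is the shallow-tip share of long type-2 roots", {
  mk <- function(tip_z, L = 60) {
    nd <- rbind(c(0, 0, -10), c(L / 2, 0, (tip_z - 10) / 2), c(L, 0, tip_z))
    root_axis(nd, type = 2L, radius = 0.1)
  }
  tips <- c(rep(-20, 3), rep(-80, 17))  # 3 of 20 shallower than 50 cm
  rs <- root_system(lapply(tips, mk), validate = FALSE)
  expect_equal(estimate_tropism_probability(rs), 0.15)
  rs_deep <- root_system(lapply(rep(-90, 5), mk), validate = FALSE)
  expect_equal(estimate_tropism_probability(rs_deep), 0)
  rs_shallow <- root_system(lapply(rep(-5, 5), mk), validate = FALSE)
  expect_equal(estimate_tropism_probability(rs_shallow), 1)
  # short roots do not qualify
  short <- root_system(list(mk(-5, L = 20)), validate = FALSE)
  expect_error(estimate_tropism_probability(short), "longer than")
})
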