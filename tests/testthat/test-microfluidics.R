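test_that("hydraulic diameter 2ab/(a+b)", {
  expect_equal(hydraulic_diameter(1e-4, 1e-4), 1e-4)          # square duct
  expect_equal(hydraulic_diameter(310e-6, 163e-6) * 1e6,
               2 * 310 * 163 / 473, tolerance = 1e-12)        # 213.7 um
  expect_equal(hydraulic_diameter(2e-4, 5e-5),
               hydraulic_diameter(5e-5, 2e-4))
  expect_error(hydraulic_diameter(0, 1e-4), "positive")
})

test_that("path pressure drop is the laminar resistance sum", {
  fluid <- flow_config(sample_rate = ul_per_min(60),
                       sheath_rate = 7.2e-6 / 60)
  seg <- channel_segment(200e-6, 100e-6, 5e-3)
  Q <- 1e-8
  d <- hydraulic_diameter(200e-6, 100e-6)
  manual <- 32 * fluid$kinematic_viscosity * fluid$density * 5e-3 / d^2 *
    (Q / (200e-6 * 100e-6))
  expect_equal(path_pressure_drop(list(seg), Q, fluid), manual,
               tolerance = 1e-12)
  expect_equal(path_pressure_drop(list(seg), 0, fluid), 0)
  # linear in Q, additive over concatenation, proportional to length
  expect_equal(path_pressure_drop(list(seg), 2 * Q, fluid), 2 * manual,
               tolerance = 1e-12)
  seg2 <- channel_segment(150e-6, 120e-6, 8e-3, K_P = 1.4)
  expect_equal(path_pressure_drop(list(seg, seg2), Q, fluid),
               path_pressure_drop(list(seg), Q, fluid) +
                 path_pressure_drop(list(seg2), Q, fluid), tolerance = 1e-12)
  segL <- channel_segment(200e-6, 100e-6, 10e-3)
  expect_equal(path_pressure_drop(list(segL), Q, fluid), 2 * manual,
               tolerance = 1e-12)
  # parallel branches split the path flow
  seg4 <- channel_segment(200e-6, 100e-6, 5e-3, parallel_count = 4L)
  expect_equal(path_pressure_drop(list(seg4), Q, fluid), manual / 4,
               tolerance = 1e-12)
  # shared segments add the sample flow unless the approximation is chosen
  segS <- channel_segment(200e-6, 100e-6, 5e-3, carries_sample = TRUE)
  exact <- path_pressure_drop(list(segS), Q, fluid)
  approx_ <- path_pressure_drop(list(segS), Q, fluid, include_sample = FALSE)
  expect_equal(approx_, manual, tolerance = 1e-12)
  expect_gt(exact, approx_)
})

test_that("sheath split ratio follows the resistance-ratio formula", {
  fluid <- flow_config()
  mk <- function(lv, lh) channel_network(
    vertical_path = list(
      channel_segment(300e-6, 150e-6, lv[1], parallel_count = 4L),
      channel_segment(310e-6, 163e-6, lv[2], carries_sample = TRUE),
      channel_segment(310e-6, 163e-6, lv[3], carries_sample = TRUE)),
    horizontal_path = list(
      channel_segment(1000e-6, 150e-6, lh[1], parallel_count = 2L, K_P = 1.4),
      channel_segment(1000e-6, 150e-6, lh[2], parallel_count = 2L, K_P = 1.4)))
  net <- mk(c(20e-3, 2e-3, 3e-3), c(6e-3, 4e-3))
  # independent hand evaluation
  term <- function(a, b, l, pc) {
    l / (pc * a * b * hydraulic_diameter(a, b)^2)
  }
  rv <- term(300e-6, 150e-6, 20e-3, 4) + term(310e-6, 163e-6, 2e-3, 1) +
    term(310e-6, 163e-6, 3e-3, 1)
  rh <- 1.4 * (term(1000e-6, 150e-6, 6e-3, 2) + term(1000e-6, 150e-6, 4e-3, 2))
  expect_equal(flow_split_ratio(net, fluid), rv / rh + 0.75,
               tolerance = 1e-12)
  # vanishing vertical resistance -> ratio tends to K_Q
  tiny <- mk(c(1e-12, 1e-12, 1e-12), c(6e-3, 4e-3))
  expect_equal(flow_split_ratio(tiny, fluid), 0.75, tolerance = 1e-6)
  # halving the horizontal lengths doubles the resistance term exactly
  half <- mk(c(20e-3, 2e-3, 3e-3), c(3e-3, 2e-3))
  expect_equal(flow_split_ratio(half, fluid) - 0.75,
               2 * (flow_split_ratio(net, fluid) - 0.75), tolerance = 1e-12)
  # invariance under a common scaling of all lengths
  scaled <- mk(3 * c(20e-3, 2e-3, 3e-3), 3 * c(6e-3, 4e-3))
  expect_equal(flow_split_ratio(scaled, fluid), flow_split_ratio(net, fluid),
               tolerance = 1e-12)
  # K_Q enters as a pure shift
  fluid2 <- flow_config(K_Q = 1.05)
  expect_equal(flow_split_ratio(net, fluid2) - flow_split_ratio(net, fluid),
               0.3, tolerance = 1e-12)
  # the packaged example chip lands near the design optimum of 8
  expect_equal(flow_split_ratio(example_network(), fluid), 8,
               tolerance = 0.15)
  sp <- split_sheath_flow(example_network(), fluid)
  expect_equal(sp$Q_HS + sp$Q_VS, fluid$sheath_rate, tolerance = 1e-12)
})

test_that("duct velocity profile obeys no-slip and the classical limits", {
  a <- 310e-6; b <- 163e-6
  v0 <- duct_velocity(0, 0, a, b, n_terms = 100L)
  # walls
  expect_lt(abs(duct_velocity(a / 2, 0, a, b, n_terms = 50L)), 1e-6 * v0)
  expect_lt(abs(duct_velocity(0, b / 2, a, b, n_terms = 50L)), 1e-6 * v0)
  expect_lt(abs(duct_velocity(-a / 2, -b / 2, a, b, n_terms = 50L)),
            1e-6 * v0)
  # maximum at the centre
  set.seed(8)
  ys <- stats::runif(50, -a / 2, a / 2)
  zs <- stats::runif(50, -b / 2, b / 2)
  expect_true(all(duct_velocity(ys, zs, a, b) <= v0 + 1e-15))
  # square duct: V_MAX / V_AVR = 2.096 (classical)
  expect_equal(round(max_to_mean_ratio(1e-4, 1e-4), 3), 2.096)
  # parallel-plate limit 1.5
  expect_equal(max_to_mean_ratio(0.5, 1e-4, n_terms = 200L), 1.5,
               tolerance = 1e-3)
  expect_error(duct_velocity(a, 0, a, b), "outside")
})

test_that("profile integration recovers the flow rate (quadrature oracle)", {
  a <- 310e-6; b <- 163e-6
  Q <- ul_per_min(60) + 7.2e-6 / 60
  cv <- centerline_velocity(Q, a, b)
  expect_equal(cv$V_AVR, Q / (a * b))
  expect_equal(cv$V_MAX, cv$ratio * cv$V_AVR)
  # independent dense-quadrature oracle: scale the unit-gradient profile so
  # its centreline velocity equals V_MAX, then integrate over the section
  ny <- 201; nz <- 201
  ys <- seq(-a / 2, a / 2, length.out = ny)
  zs <- seq(-b / 2, b / 2, length.out = nz)
  grid <- expand.grid(y = ys, z = zs)
  v <- duct_velocity(grid$y, grid$z, a, b, n_terms = 60L)
  v <- v * cv$V_MAX / duct_velocity(0, 0, a, b, n_terms = 60L)
  wy <- rep(1, ny); wy[c(1, ny)] <- 0.5
  wz <- rep(1, nz); wz[c(1, nz)] <- 0.5
  w <- outer(wy, wz) * (a / (ny - 1)) * (b / (nz - 1))
  Q_num <- sum(matrix(v, ny, nz) * w)
  expect_lt(abs(Q_num / Q - 1), 1e-3)
})

test_that("max-to-mean ratio decreases monotonically with aspect ratio", {
  aspects <- c(1, 1.5, 2, 3, 5, 10, 30)
  r <- vapply(aspects, function(ar) max_to_mean_ratio(ar * 1e-4, 1e-4),
              numeric(1))
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 1.5 & r <= 2.097))
})
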