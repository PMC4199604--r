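test_that("slab solver reproduces the linear profile to solver precision", {
  res <- solve_steady_slab(n_cells = 64)
  expect_lt(max(abs(res$profile$concentration -
                      (1 - res$profile$position))), 1e-10)
  expect_lt(abs(res$profile$concentration[1] -
                  (1 - res$profile$position[1])), 1e-10)
  mid <- which.min(abs(res$profile$position - 0.5))
  expect_equal(res$profile$concentration[mid],
               1 - res$profile$position[mid], tolerance = 1e-10)
  # no secretion, no profile
  res0 <- solve_steady_slab(params = diffusion_params(J = 0))
  expect_equal(max(abs(res0$profile$concentration)), 0)
})

test_that("radial solver matches the closed form across a geometry sweep", {
  for (rs in c(0.5, 1, 2.5, 5)) {
    for (rmax in c(5, 10, 20)) {
      g <- wall_geometry(r_s = rs, r_max = rmax)
      res <- solve_steady_radial(g, radial_grid(1024, rmax))
      ana <- apposed_concentration(res$profile$position, g)
      relerr <- max(abs(res$profile$concentration - ana)) / ana[1]
      expect_lt(relerr, 0.005)
      expect_lt(res$residual, 1e-10)
    }
  }
})

test_that("radial solver center value is within 0.5% of 5.89 J/D", {
  res <- solve_steady_radial()
  expect_lt(abs(res$profile$concentration[1] - 5.89) / 5.89, 0.005)
})

test_that("full-disc source reduces to the parabolic closed form", {
  g <- wall_geometry(r_s = 10, r_max = 10)
  res <- solve_steady_radial(g, radial_grid(512, 10))
  ana <- (10^2 - res$profile$position^2) / 4
  expect_lt(max(abs(res$profile$concentration - ana)) / max(ana), 0.005)
})

test_that("radial solver converges at second order", {
  cs <- convergence_study(n_cells = c(64, 128, 256))
  expect_true(all(cs$observed_order[-1] >= 1.8))
  # halving dr cuts the error about fourfold
  expect_equal(cs$max_abs_error[1] / cs$max_abs_error[2], 4, tolerance = 0.3)
})

test_that("discrete source input balances the rim outflux", {
  g <- wall_geometry()
  res <- solve_steady_radial(g, radial_grid(256, 10))
  C <- res$profile$concentration
  dr <- res$grid$dr
  outflux <- 2 * pi * g$r_max * C[length(C)] / (dr / 2)
  expect_equal(outflux, pi * g$r_s^2, tolerance = 1e-8)
})

test_that("transient solution relaxes monotonically to the steady state", {
  tr <- solve_transient_radial(grid = radial_grid(64, 10), horizon = 200,
                               n_out = 40)
  expect_equal(tr$center[1], tr$center[1])  # finite
  expect_true(all(diff(tr$center) >= -1e-12))
  steady <- solve_steady_radial(wall_geometry(), radial_grid(64, 10))
  final <- tr$snapshots[[40]]$profile$concentration
  expect_lt(max(abs(final - steady$profile$concentration)) /
              steady$profile$concentration[1], 0.005)
  t50 <- tr$time_to_fraction(0.5)
  t90 <- tr$time_to_fraction(0.9)
  expect_true(t50 < t90)
  expect_error(tr$time_to_fraction(1.5))
})

test_that("transient starts from a zero profile", {
  tr <- solve_transient_radial(grid = radial_grid(32, 10), horizon = 0.5,
                               n_out = 2)
  expect_lt(tr$center[1], apposed_drops()$C_tot * 0.2)
})

test_that("depth-resolved solver agrees with its limiting oracles", {
  # reflecting face: depth average reproduces the 2-D radial solution
  rz <- solve_steady_rz(grid = radial_grid(128, 10), nz = 8)
  rad <- solve_steady_radial(wall_geometry(), radial_grid(128, 10))
  expect_lt(max(abs(rz$depth_mean - rad$profile$concentration)) /
              rad$profile$concentration[1], 0.005)
  # depth variation at the center stays below 20% of its mean
  depth_var <- diff(range(rz$C[1, ])) / mean(rz$C[1, ])
  expect_lt(depth_var, 0.20)
  # absorbing face, wide disc: center column approaches the 1-D slab
  g <- wall_geometry(r_s = 20, r_max = 25)
  rzA <- solve_steady_rz(g, radial_grid(100, 25), nz = 16,
                         apposed_face = "absorbing")
  expect_lt(abs(rzA$C[1, 1] - 1.0), 0.1)
  col <- rzA$C[1, ]
  lin <- 1 - rzA$z
  expect_lt(max(abs(col - lin)), 0.1)
  # no secretion, identically zero
  rz0 <- solve_steady_rz(grid = radial_grid(32, 10), nz = 4,
                         params = diffusion_params(J = 0))
  expect_equal(max(abs(rz0$C)), 0)
})

test_that("grid constructor enforces its invariants", {
  expect_error(radial_grid(4), "n_cells")
  g <- radial_grid(16, 8)
  expect_equal(g$dr, 0.5)
  expect_equal(g$centers[1], 0.25)     # r = 0 singularity stays off-grid
  expect_error(solve_steady_radial(wall_geometry(), radial_grid(64, 5)),
               "match")
})
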