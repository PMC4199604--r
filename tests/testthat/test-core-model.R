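test_that("unapposed profile is linear with C0 = J/D and a zero sink", {
  expect_equal(unapposed_concentration(0), 1.0)
  expect_equal(unapposed_concentration(1), 0.0)
  expect_equal(unapposed_concentration(0.5), 0.5)
  expect_error(unapposed_concentration(-0.1), "\\[0, 1\\]")
  expect_error(unapposed_concentration(1.1), "\\[0, 1\\]")
  expect_equal(unapposed_concentration(0.25, diffusion_params(J = 3, D = 2)),
               3 / 2 * 0.75)
})

test_that("unapposed mean is J/2D and equals the quadrature mean", {
  expect_equal(unapposed_mean_concentration(), 0.5)
  expect_equal(unapposed_mean_concentration(diffusion_params(J = 0)), 0)
  quad <- integrate(unapposed_concentration, 0, 1, rel.tol = 1e-13)$value
  expect_equal(unapposed_mean_concentration(), quad, tolerance = 1e-12)
})

test_that("apposed closed form reproduces the printed drops", {
  d <- apposed_drops()
  expect_equal(d$C_s, 2.5^2 / 4)
  expect_equal(d$C_d, (2.5^2 / 2) * log(10 / 2.5))
  expect_equal(d$C_tot, d$C_s + d$C_d)
  expect_equal(round(d$C_tot, 2), 5.89)
  expect_equal(apposed_concentration(0), d$C_tot)
  expect_equal(apposed_concentration(10), 0)
  expect_equal(apposed_concentration(2.5), (2.5^2 / 2) * log(4),
               tolerance = 1e-12)
  # annulus vanishes when r_s = r_max
  d2 <- apposed_drops(wall_geometry(r_s = 10, r_max = 10))
  expect_equal(d2$C_d, 0)
  expect_equal(d2$C_tot, d2$C_s)
})

test_that("apposed profile is continuous, differentiable at r_s, decreasing", {
  g <- wall_geometry()
  eps <- 1e-7
  expect_equal(apposed_concentration(g$r_s - eps, g),
               apposed_concentration(g$r_s + eps, g), tolerance = 1e-5)
  d_in <- (apposed_concentration(g$r_s, g) -
             apposed_concentration(g$r_s - eps, g)) / eps
  d_out <- (apposed_concentration(g$r_s + eps, g) -
              apposed_concentration(g$r_s, g)) / eps
  expect_equal(d_in, -g$r_s / 2, tolerance = 1e-5)
  expect_equal(d_out, -g$r_s / 2, tolerance = 1e-5)
  r <- seq(0.01, g$r_max, length.out = 400)
  expect_true(all(diff(apposed_concentration(r, g)) < 0))
  expect_error(apposed_concentration(-1, g), "\\[0, r_max\\]")
  expect_error(apposed_concentration(11, g), "\\[0, r_max\\]")
})

test_that("outputs in J/D units are invariant under joint (J, D) rescaling", {
  for (k in c(0.1, 3, 1e4)) {
    p1 <- diffusion_params(J = 2, D = 5)
    pk <- diffusion_params(J = 2 * k, D = 5 * k)
    expect_equal(apposed_drops(params = p1)$C_tot,
                 apposed_drops(params = pk)$C_tot, tolerance = 1e-12)
    expect_equal(unapposed_concentration(0.3, p1),
                 unapposed_concentration(0.3, pk), tolerance = 1e-12)
    expect_equal(enhancement_ratio(params = p1),
                 enhancement_ratio(params = pk), tolerance = 1e-12)
  }
})

test_that("radial flux through each circle balances the enclosed source", {
  g <- wall_geometry()
  h <- 1e-6
  for (r in c(0.5, 1.8, 2.5, 4, 7, 9.5)) {
    dCdr <- (apposed_concentration(r + h, g) -
               apposed_concentration(r - h, g)) / (2 * h)
    flux <- -dCdr * 2 * pi * r            # D = 1
    expect_equal(flux, pi * min(r, g$r_s)^2, tolerance = 1e-6)
  }
})

test_that("C_tot is monotone in geometry and has the correct annulus limit", {
  ctot <- function(rs, rmax) apposed_drops(wall_geometry(r_s = rs,
                                                         r_max = rmax))$C_tot
  expect_true(all(diff(sapply(c(10, 12, 15, 20), ctot, rs = 2.5)) > 0))
  expect_true(all(diff(sapply(c(1, 2, 3, 5), ctot, rmax = 10)) > 0))
  # r_max -> r_s+: the log drop vanishes
  expect_equal(ctot(2.5, 2.5 + 1e-9), 2.5^2 / 4, tolerance = 1e-7)
  # doubling both radii: log term unchanged, quadratic terms x4
  expect_gt(enhancement_ratio(wall_geometry(r_s = 5, r_max = 20)),
            enhancement_ratio(wall_geometry()))
})

test_that("enhancement ratio exceeds 10 at the default geometry", {
  expect_gte(enhancement_ratio(), 10)
  expect_equal(enhancement_ratio(), apposed_drops()$C_tot / 0.5)
  expect_error(enhancement_ratio(params = diffusion_params(J = 0)),
               "undefined")
})

test_that("profile_table samples both scenarios consistently", {
  pt <- profile_table(n_points = 2)
  expect_equal(pt$unapposed$concentration, c(1, 0))
  pt <- profile_table(n_points = 101)
  expect_equal(max(pt$apposed$concentration), apposed_drops()$C_tot)
  expect_equal(round(max(pt$apposed$concentration), 2), 5.89)
  expect_equal(pt$apposed$concentration,
               apposed_concentration(pt$apposed$position))
  expect_equal(pt$unapposed$concentration,
               unapposed_concentration(pt$unapposed$position))
  expect_true(all(diff(pt$apposed$position) > 0))
  expect_equal(pt$apposed$concentration[101], 0)
  expect_error(profile_table(n_points = 1), "n_points")
})

test_that("geometry and parameter validation rejects bad inputs", {
  expect_error(wall_geometry(r_s = 5, r_max = 2), "r_s <= r_max")
  expect_error(diffusion_params(D = 0))
  expect_error(diffusion_params(J = -1))
  expect_error(apposed_drops(wall_geometry(mode = "unapposed")), "apposed")
})
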