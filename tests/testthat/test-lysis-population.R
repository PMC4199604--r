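# shared fixture: ten hand-written event records
fixture_records <- function() {
  tibble::tibble(
    cell_id = 1:10,
    condition = "fixture",
    onset_min = c(20, 25, 30, 30, 40, 45, 50, 60, 70, 80),
    breach_min = c(50, 60, 70, NA, 90, 100, NA, 120, NA, NA),
    lysis_min = c(60, 70, 80, NA, 100, 110, NA, 130, NA, NA),
    max_conc = 3
  )
}

test_that("condition presets encode the assay protocols", {
  fl <- make_condition("flow")
  expect_equal(fl$contact, "two_surfaces")
  expect_equal(fl$alpha_factor, 50)
  expect_equal(fl$duration, 300)
  bn <- make_condition("flow_benomyl")
  expect_true(bn$benomyl)
  expect_equal(bn$alpha_factor, 0)
  wi <- make_condition("flow_sorbitol_washin")
  expect_equal(wi$sorbitol_windows[1, ], c(80, 300))
  wo <- make_condition("flow_sorbitol_washout")
  expect_equal(wo$sorbitol_windows[1, ], c(0, 300))
  expect_equal(wo$duration, 360)
  ca <- make_condition("conA")
  expect_equal(ca$contact, "one_surface")
  expect_equal(ca$r_max_eff, 5)
  dd <- make_condition("dose", alpha_factor = 20)
  expect_equal(dd$alpha_factor, 20)
  expect_error(make_condition("dose"), "alpha_factor")
  expect_error(make_condition("plate"), "unknown")
  expect_error(make_condition("flow", alpha_factor = 10), "dose")
})

test_that("fraction_dead matches a hand count on the fixture", {
  rec <- fixture_records()
  expect_equal(fraction_dead(rec, 0), 0)
  expect_equal(fraction_dead(rec, 60), 0.1)
  expect_equal(fraction_dead(rec, 100), 0.4)
  expect_equal(fraction_dead(rec, 130), 0.6)
  expect_equal(fraction_dead(rec, 1e6), 0.6)
  expect_equal(fraction_breached(rec), 0.6)
})

test_that("fold_change is plain arithmetic with an undefined-ratio guard", {
  rec <- fixture_records()
  # deaths in (0,80]: 60, 70, 80; in (80,140]: 100, 110, 130
  expect_equal(fold_change(rec, c(0, 80), c(80, 140)), 1.0)
  # deaths in (0,70]: 60, 70; in (70,140]: 80, 100, 110, 130
  expect_equal(fold_change(rec, c(0, 70), c(70, 140)), 2.0)
  expect_warning(fc <- fold_change(rec, c(0, 10), c(10, 140)), "undefined")
  expect_true(is.na(fc))
  expect_error(fold_change(rec, c(0, 100), c(80, 140)), "disjoint")
})

test_that("compare_conditions reproduces the hand-computed Welch t", {
  a <- c(0.10, 0.12, 0.08)
  b <- c(0.50, 0.55, 0.45)
  ht <- compare_conditions(a, b)
  # Welch formula by hand
  va <- var(a) / 3; vb <- var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  expect_equal(unname(ht$statistic), t_hand, tolerance = 1e-10)
  expect_equal(unname(ht$parameter), df_hand, tolerance = 1e-10)
  expect_equal(ht$p.value, 2 * pt(t_hand, df_hand), tolerance = 1e-10)
  expect_lt(ht$p.value, 0.01)
  # identical sets: t = 0, p = 1
  ht0 <- compare_conditions(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4))
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)
  expect_error(compare_conditions(0.1, c(0.2, 0.3)), "2 replicates")
})

test_that("simulation is deterministic given the seed", {
  cond <- make_condition("flow")
  a <- simulate_population(300, cond, seed = 5)
  b <- simulate_population(300, cond, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_population(300, cond, seed = 6)
  expect_false(identical(a, c2))
})

test_that("an infinite breach threshold protects every cell", {
  p <- modifyList(lysis_params(), list(theta_mean = Inf))
  for (preset in c("flow", "bulk")) {
    rec <- simulate_population(200, make_condition(preset), seed = 1,
                               params = p)
    expect_equal(fraction_dead(rec, 300), 0)
    expect_equal(fraction_breached(rec), 0)
  }
})

test_that("threshold between the two analytic levels separates geometries", {
  # heterogeneity off; theta strictly between the unapposed surface value
  # (1.0 J/D) and the apposed center value (5.89 J/D)
  p <- modifyList(lysis_params(),
                  list(theta_gsd = 1, sec_gsd = 1, theta_mean = 3))
  full <- simulate_population(500, make_condition("flow"), seed = 2,
                              params = p)
  none <- simulate_population(500, make_condition("bulk"), seed = 2,
                              params = p)
  expect_equal(fraction_breached(full), 1)
  expect_equal(fraction_breached(none), 0)
})

test_that("death fraction is nondecreasing in time for any population", {
  for (preset in c("flow", "conA", "flow_sorbitol_washout")) {
    cond <- make_condition(preset)
    rec <- simulate_population(400, cond, seed = 8)
    ps <- population_summary(rec, cond$duration)
    expect_true(all(diff(ps$fraction_dead) >= 0))
    expect_true(all(ps$fraction_dead >= 0 & ps$fraction_dead <= 1))
    # lysis requires breach, and never precedes it
    dead <- !is.na(rec$lysis_min)
    expect_true(all(!is.na(rec$breach_min[dead])))
    expect_true(all(rec$lysis_min[dead] >= rec$breach_min[dead]))
    expect_true(all(rec$breach_min[dead] >= rec$onset_min[dead]))
  }
})

test_that("dose response is monotone and order-independent", {
  dr <- dose_response(c(5, 20, 50), n_cells = 400, seed = 1)
  expect_true(all(diff(dr$fraction_dead) > 0))
  # dose 0: no shmooing, no deaths
  dr0 <- dose_response(0, n_cells = 200, seed = 1)
  expect_equal(dr0$fraction_dead, 0)
  # permuting the dose order permutes the outputs identically
  perm <- dose_response(c(50, 5, 20), n_cells = 400, seed = 1)
  expect_equal(perm$fraction_dead[match(dr$dose, perm$dose)],
               dr$fraction_dead)
})

test_that("genotype presets modulate the lysis rate in the right direction", {
  frac <- function(g) {
    fraction_dead(simulate_population(600, make_condition("flow"), seed = 3,
                                      genotype = genotype_preset(g)), 300)
  }
  wt <- frac("wild_type")
  for (g in c("fus1d", "fus2d", "fus1d_fus2d", "scw4d_scw11d")) {
    expect_lt(frac(g), wt)
  }
  expect_error(genotype_preset("rad52d"), "unknown")
})

test_that("parameter validation happens before simulation", {
  cond <- make_condition("flow")
  expect_error(simulate_population(100, cond, seed = 1,
                                   params = list(sec_gsd = 0.5)), ">= 1")
  expect_error(simulate_population(100, cond, seed = 1,
                                   params = list(theta_mean = -1)), "theta")
  expect_error(simulate_population(100, cond), "seed")
})
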