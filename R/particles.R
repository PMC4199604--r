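# Brownian random-walk oracle for the apposed sheet.
#
# Enzymes are point particles performing isotropic Gaussian steps
# (per-axis sd sqrt(2 dt), D = 1 in nondimensional units) in the plane of
# the wall.  They are injected uniformly over the secretion disc and
# absorbed at step end.  Checking absorption only at discrete times pushes
# the effective absorbing boundary outward by 0.5826 * sigma (the
# Broadie-Glasserman/Gobet constant, sigma the per-axis step sd), an
# O(sqrt(dt)) bias; the absorption test is therefore applied at the
# shrunken radius r_max - 0.5826 * sigma, which cancels the bias to leading
# order.  Occupancy of the stationary state estimates the concentration
# profile with no PDE discretization in common with the finite-volume
# oracle.

# continuity correction for discretely monitored absorption
BG_CONST <- 0.5825971579390107

#' Random-walk configuration
#'
#' @param n_particles Number of particles to inject (>= 1).
#' @param dt Time step in units of \code{h^2/D}.  Must satisfy
#'   \code{sqrt(4 dt) <= 0.1 (r_max - r_s)} for the geometry it is used
#'   with (checked at simulation time).
#' @param seed Integer seed; mandatory, there is no silent nondeterminism.
#' @return An object of class \code{"walk_config"}.
#' @export
walk_config <- function(n_particles, dt = 0.02, seed) {
  if (missing(seed)) stop("walk_config: an explicit seed is required")
  stopifnot(is.numeric(n_particles), n_particles >= 0,
            n_particles == round(n_particles),
            is.numeric(dt), dt > 0,
            is.numeric(seed), seed == round(seed))
  structure(list(n_particles = as.integer(n_particles), dt = dt,
                 seed = as.integer(seed)), class = "walk_config")
}

check_step_size <- function(config, geometry) {
  lim <- 0.1 * (geometry$r_max - geometry$r_s)
  if (geometry$r_max > geometry$r_s && sqrt(4 * config$dt) > lim + 1e-12) {
    stop("walk_config: rms step sqrt(4 dt) = ", signif(sqrt(4 * config$dt), 3),
         " exceeds 0.1 * (r_max - r_s) = ", signif(lim, 3))
  }
  invisible(config)
}

inject_disc <- function(n, r_s) {
  r <- r_s * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Expected enzyme residence time in the apposed patch
#'
#' Closed-form prediction for the mean time a secreted enzyme spends inside
#' the apposed patch before absorption at the rim: by Little's law the
#' stationary particle content \code{integral of C over the patch} equals the
#' injection rate \code{pi r_s^2 J} times the mean residence time.  The
#' domain integral of the analytic profile is evaluated by quadrature.
#'
#' @param geometry A [wall_geometry()] in apposed mode.
#' @return Mean residence time in units of \code{h^2/D}.
#' @export
expected_residence_time <- function(geometry = wall_geometry()) {
  assert_apposed(geometry)
  total <- stats::integrate(function(r)
    2 * pi * r * apposed_concentration(r, geometry),
    0, geometry$r_max, rel.tol = 1e-10)$value
  total / (pi * geometry$r_s^2)
}

#' First-passage residence times of secreted enzymes
#'
#' Simulates \code{n_particles} independent walkers from a uniform start in
#' the secretion disc until absorption at the rim and reports the mean
#' first-passage time with its standard error.  Walkers that exhaust the
#' step budget are counted and reported, never silently dropped.
#'
#' @param config A [walk_config()].
#' @param geometry A [wall_geometry()] in apposed mode.
#' @param max_steps Per-particle step budget.
#' @return A list: \code{mean_residence_time}, \code{se}, \code{times}
#'   (completed walkers), \code{n_censored}, \code{absorption_angles}
#'   (radians in \code{[0, 2 pi)}, one per completed walker).
#' @export
simulate_residence <- function(config, geometry = wall_geometry(),
                               max_steps = 200000L) {
  assert_apposed(geometry)
  check_step_size(config, geometry)
  set.seed(config$seed)
  n <- config$n_particles
  dt <- config$dt
  sd_step <- sqrt(2 * dt)
  r2max <- (geometry$r_max - BG_CONST * sd_step)^2
  pos <- inject_disc(n, geometry$r_s)
  alive <- rep(TRUE, n)
  times <- rep(NA_real_, n)
  angles <- rep(NA_real_, n)
  step <- 0L
  while (any(alive) && step < max_steps) {
    step <- step + 1L
    na <- sum(alive)
    pos[alive, ] <- pos[alive, , drop = FALSE] +
      matrix(stats::rnorm(2L * na, sd = sd_step), ncol = 2L)
    out <- alive & (pos[, 1]^2 + pos[, 2]^2 > r2max)
    if (any(out)) {
      times[out] <- step * dt
      angles[out] <- atan2(pos[out, 2], pos[out, 1]) %% (2 * pi)
      alive[out] <- FALSE
    }
  }
  done <- times[!is.na(times)]
  list(mean_residence_time = mean(done),
       se = stats::sd(done) / sqrt(length(done)),
       times = done,
       n_censored = sum(alive),
       absorption_angles = angles[!is.na(angles)])
}

#' Stationary occupancy profile from continuous injection
#'
#' Runs the walk with continuous injection at the physical rate
#' \code{pi r_s^2 J} (Poisson arrivals per step), discards a burn-in of five
#' expected residence times, then time-averages annular bin counts of the
#' surviving walkers.  Counts per unit area estimate the concentration in
#' \code{J/D} units directly.  Standard errors come from batch means over
#' the sampling window, which respects the autocorrelation of successive
#' frames.
#'
#' @param config A [walk_config()]; \code{n_particles} is the target number
#'   of injected particles after burn-in.
#' @param geometry A [wall_geometry()] in apposed mode.
#' @param n_bins Number of annular bins over \code{[0, r_max]} (>= 4).
#' @param n_batches Number of batches for the standard-error estimate.
#' @return An object of class \code{"occupancy_estimate"}: a list with
#'   \code{bin_edges}, \code{concentration}, \code{standard_error},
#'   \code{n_events} (absorptions during sampling),
#'   \code{mean_residence_time} and \code{se_residence} (from absorptions
#'   during the sampling window).
#' @export
occupancy_profile <- function(config, geometry = wall_geometry(),
                              n_bins = 20, n_batches = 16) {
  assert_apposed(geometry)
  check_step_size(config, geometry)
  stopifnot(n_bins >= 4)
  set.seed(config$seed)
  dt <- config$dt
  sd_step <- sqrt(2 * dt)
  r_max <- geometry$r_max
  r_support <- r_max - BG_CONST * sd_step   # walkers never live beyond this
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  # bin areas clipped to the walk support, so counts/area estimates the
  # mean density over the region the estimator can actually populate
  areas <- pi * diff(pmin(edges, r_support)^2)
  # injection rate pi r_s^2 J with J = 1; zero particles means no injection
  rate <- if (config$n_particles == 0L) 0 else pi * geometry$r_s^2
  t_burn <- 5 * expected_residence_time(geometry)
  n_burn <- ceiling(t_burn / dt)
  # sampling window: long enough to inject n_particles, with a floor of
  # 12 residence times so the population-size fluctuation (correlation
  # time about one residence time) is averaged over enough turnovers
  n_sample <- max(n_batches,
                  if (rate > 0) ceiling(config$n_particles / (rate * dt))
                  else n_batches,
                  if (rate > 0) ceiling(12 * t_burn / (5 * dt)) else 0L)
  n_sample <- n_batches * ceiling(n_sample / n_batches)
  batch_len <- n_sample %/% n_batches

  pos <- matrix(numeric(0), ncol = 2L)
  birth <- numeric(0)
  counts <- matrix(0, nrow = n_batches, ncol = n_bins)
  res_times <- numeric(0)
  n_events <- 0L
  total_steps <- n_burn + n_sample
  r2max <- (r_max - BG_CONST * sd_step)^2
  for (step in seq_len(total_steps)) {
    n_new <- stats::rpois(1L, rate * dt)
    if (n_new > 0L) {
      pos <- rbind(pos, inject_disc(n_new, geometry$r_s))
      birth <- c(birth, rep(step * dt, n_new))
    }
    np <- nrow(pos)
    if (np > 0L) {
      pos <- pos + matrix(stats::rnorm(2L * np, sd = sd_step), ncol = 2L)
      out <- pos[, 1]^2 + pos[, 2]^2 > r2max
      if (any(out)) {
        if (step > n_burn) {
          res_times <- c(res_times, step * dt - birth[out])
          n_events <- n_events + sum(out)
        }
        pos <- pos[!out, , drop = FALSE]
        birth <- birth[!out]
      }
    }
    if (step > n_burn) {
      b <- ((step - n_burn - 1L) %/% batch_len) + 1L
      if (b <= n_batches && nrow(pos) > 0L) {
        r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
        h <- tabulate(findInterval(r, edges, rightmost.closed = TRUE),
                      nbins = n_bins)
        counts[b, ] <- counts[b, ] + h
      }
    }
  }
  # per-batch mean concentration per bin
  conc_b <- sweep(counts / batch_len, 2L, areas, "/")
  conc <- colMeans(conc_b)
  se <- apply(conc_b, 2L, stats::sd) / sqrt(n_batches)
  # successive batches stay correlated when the batch length is comparable
  # to the residence time; inflate the SE by the usual AR(1) factor using
  # the lag-1 autocorrelation pooled across bins
  rho_i <- apply(conc_b, 2L, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v[-1], v[-length(v)])
  })
  rho <- min(max(mean(rho_i, na.rm = TRUE), 0), 0.95)
  if (!is.na(rho)) se <- se * sqrt((1 + rho) / (1 - rho))
  se[conc == 0] <- Inf
  structure(list(bin_edges = edges, r_support = r_support,
                 concentration = conc,
                 standard_error = se, n_events = n_events,
                 mean_residence_time = if (length(res_times)) mean(res_times)
                                       else NA_real_,
                 se_residence = if (length(res_times) > 1L)
                   stats::sd(res_times) / sqrt(length(res_times))
                   else NA_real_,
                 geometry = geometry),
            class = "occupancy_estimate")
}

#' Analytic bin-average concentrations
#'
#' Area-weighted average of the closed-form apposed profile over each
#' annular bin, the quantity the occupancy estimator converges to.
#'
#' @param bin_edges Increasing vector of bin edges in \code{[0, r_max]}.
#' @param geometry A [wall_geometry()] in apposed mode.
#' @param upper Optional clip radius: averages are taken over the part of
#'   each bin below \code{upper} (used to match an occupancy estimate whose
#'   support ends at the continuity-corrected absorption radius).
#' @return Vector of bin-average concentrations (J/D units).
#' @export
analytic_bin_means <- function(bin_edges, geometry = wall_geometry(),
                               upper = NULL) {
  assert_apposed(geometry)
  n <- length(bin_edges) - 1L
  vapply(seq_len(n), function(i) {
    lo <- bin_edges[i]; hi <- bin_edges[i + 1L]
    if (!is.null(upper)) {
      lo <- min(lo, upper); hi <- min(hi, upper)
    }
    if (hi <= lo) return(0)
    stats::integrate(function(r) 2 * pi * r *
                       apposed_concentration(r, geometry),
                     lo, hi, rel.tol = 1e-10)$value / (pi * (hi^2 - lo^2))
  }, numeric(1))
}

#' Compare an occupancy estimate to the closed form
#'
#' Per-bin z-scores \code{(estimate - analytic) / SE} against the analytic
#' bin averages, with a pass/fail summary: pass when at most 5 percent of
#' bins exceed \code{|z| = 3}.
#'
#' @param estimate An \code{occupancy_estimate}.
#' @param geometry A [wall_geometry()] matching the estimate's geometry.
#' @return A list: \code{z} (per bin), \code{analytic}, \code{frac_extreme},
#'   \code{pass}.
#' @export
compare_to_analytic <- function(estimate, geometry = wall_geometry()) {
  stopifnot(inherits(estimate, "occupancy_estimate"))
  g <- estimate$geometry
  if (abs(g$r_s - geometry$r_s) > 1e-12 ||
      abs(g$r_max - geometry$r_max) > 1e-12 || g$mode != geometry$mode) {
    stop("compare_to_analytic: estimate and geometry do not match")
  }
  ana <- analytic_bin_means(estimate$bin_edges, geometry,
                            upper = estimate$r_support)
  z <- (estimate$concentration - ana) / estimate$standard_error
  z[is.infinite(estimate$standard_error)] <- 0
  frac <- mean(abs(z) > 3)
  list(z = z, analytic = ana, frac_extreme = frac, pass = frac <= 0.05)
}
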