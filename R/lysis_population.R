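# Synthetic cohorts of pheromone-arrested cells and an osmotic-lysis rule.
#
# The diffusion model supplies, per cell, a local steady enzyme
# concentration set by its contact geometry and polarization.  Everything
# downstream of that concentration -- the breach-and-lysis rule, the
# dose-to-polarization map, the between-cell heterogeneity -- is a model
# extension, not derived content: the rule is a minimal threshold model
# whose defaults are calibrated only to reproduce the qualitative orderings
# of the emulated experiments (confinement, dose, osmolarity, deletion
# mutants), never their measured percentages.
#
# Breach: once a cell has shmooed, its wall accumulates damage at rate
# max(0, C_local - theta); the wall is breached when the accumulated excess
# exceeds the integrity capacity.  Lysis: a breached wall fails
# osmotically; at each 10-minute observation frame a breached, living cell
# lyses with probability logistic in the osmotic differential,
# 1 / (1 + exp(-k (dPi - Pi0))).  Raising medium osmolarity (1 M sorbitol)
# shrinks dPi and suppresses lysis without touching breach.

#' Default parameters of the lysis model
#'
#' All tunables of the population simulator in one list.  Concentrations in
#' J/D units, times in minutes, osmotic differentials as multiples of the
#' baseline turgor excess.
#'
#' \describe{
#'   \item{theta_mean}{Median breach threshold (J/D).  Above the unapposed
#'     surface concentration (1 J/D), so a baseline free cell does not
#'     self-lyse.}
#'   \item{theta_gsd}{Geometric SD of the per-cell threshold (wall-strength
#'     heterogeneity); 1 switches it off.}
#'   \item{sec_gsd}{Geometric SD of the per-cell secretion multiplier; 1
#'     switches it off.}
#'   \item{capacity}{Integrity capacity: accumulated concentration excess
#'     (J/D x min) a wall tolerates before breach.}
#'   \item{lysis_k, lysis_pi0}{Slope and midpoint of the logistic lysis
#'     probability per observation frame as a function of dPi.}
#'   \item{dpi_normal, dpi_sorbitol}{Osmotic differential without and with
#'     1 M sorbitol in the medium.}
#'   \item{onset_shape, onset_mean}{Gamma-distributed shmoo-onset time
#'     (minutes after pheromone exposure).}
#'   \item{benomyl_secretion}{Relative local concentration under unpolarized
#'     (benomyl) secretion: vesicle fusion spread over the whole membrane
#'     instead of a focused disc.}
#'   \item{rs_ref}{Reference secretion-disc radius (wall-thickness units) at
#'     which the areal flux equals J; total secretion is conserved, so a
#'     disc of radius r gets areal flux J (rs_ref / r)^2.}
#' }
#'
#' @return A named list of defaults; override entries via
#'   \code{modifyList()} or the \code{params} argument of the simulators.
#' @export
lysis_params <- function() {
  list(
    theta_mean = 1.7,
    theta_gsd = 1.8,
    sec_gsd = 1.3,
    capacity = 200,
    lysis_k = 10,
    lysis_pi0 = 0.6,
    dpi_normal = 1.0,
    dpi_sorbitol = 0.1,
    onset_shape = 8,
    onset_mean = 60,
    benomyl_secretion = 0.15,
    rs_ref = 2.5
  )
}

#' Genotype presets
#'
#' Multiplier sets for the emulated deletion mutants.  \code{focus} scales
#' the tightness of secretion polarization (the effective secretion-disc
#' radius is divided by it; fus1/fus2 deletions disperse the vesicle
#' cluster), \code{activity} scales the wall-degrading activity per enzyme
#' (scw4/scw11 deletions remove glucanases).  The individual values are free
#' parameters of the extension, not measured quantities.
#'
#' @param name One of \code{"wild_type"}, \code{"fus1d"}, \code{"fus2d"},
#'   \code{"fus1d_fus2d"}, \code{"scw4d"}, \code{"scw11d"},
#'   \code{"scw4d_scw11d"}.
#' @return A list with \code{focus} and \code{activity} multipliers.
#' @export
genotype_preset <- function(name = "wild_type") {
  presets <- list(
    wild_type    = list(focus = 1,    activity = 1),
    fus1d        = list(focus = 0.5,  activity = 1),
    fus2d        = list(focus = 0.6,  activity = 1),
    fus1d_fus2d  = list(focus = 0.35, activity = 1),
    scw4d        = list(focus = 1,    activity = 0.6),
    scw11d       = list(focus = 1,    activity = 0.6),
    scw4d_scw11d = list(focus = 1,    activity = 0.36)
  )
  if (!name %in% names(presets)) {
    stop("unknown genotype preset '", name, "'; known: ",
         paste(names(presets), collapse = ", "))
  }
  c(list(name = name), presets[[name]])
}

#' Experimental condition presets
#'
#' Builds a fully populated condition matching one of the emulated assay
#' protocols.  The physical environment fixes the contact geometry: bulk
#' culture gives no enforced contact (unapposed escape), a ConA-coated
#' coverslip one attached surface with half the flow-chamber contact
#' radius, and the flow chamber confinement between two surfaces with the
#' full contact radius.  Sorbitol schedules follow the assay timings: the
#' wash-in protocol adds 1 M sorbitol 80 minutes after pheromone exposure;
#' the wash-out protocol grows cells in sorbitol for 300 minutes and then
#' removes it.
#'
#' @param preset One of \code{"bulk"}, \code{"conA"}, \code{"flow"},
#'   \code{"flow_benomyl"}, \code{"flow_sorbitol_washin"},
#'   \code{"flow_sorbitol_washout"}, \code{"dose"}.
#' @param alpha_factor Pheromone dose in nM; required for \code{"dose"},
#'   fixed at 50 nM for the named assay presets.
#' @return An object of class \code{"lysis_condition"}: a list with
#'   \code{name}, \code{environment}, \code{contact} (\code{"none"},
#'   \code{"one_surface"}, \code{"two_surfaces"}), \code{r_max_eff},
#'   \code{alpha_factor}, \code{benomyl}, \code{sorbitol_windows} (matrix of
#'   \code{[start, end)} minutes during which sorbitol is present) and
#'   \code{duration} (minutes).
#' @examples
#' make_condition("flow")
#' make_condition("dose", alpha_factor = 20)
#' @export
make_condition <- function(preset, alpha_factor = NULL) {
  known <- c("bulk", "conA", "flow", "flow_benomyl",
             "flow_sorbitol_washin", "flow_sorbitol_washout", "dose")
  if (!is.character(preset) || length(preset) != 1L || !preset %in% known) {
    stop("unknown condition preset '", preset, "'; known: ",
         paste(known, collapse = ", "))
  }
  base <- list(name = preset, environment = "flow_chamber",
               contact = "two_surfaces", r_max_eff = 10,
               alpha_factor = 50, benomyl = FALSE,
               sorbitol_windows = matrix(numeric(0), ncol = 2),
               duration = 300)
  cond <- switch(preset,
    bulk = modifyList(base, list(environment = "bulk", contact = "none",
                                 r_max_eff = NA_real_)),
    conA = modifyList(base, list(environment = "conA_coverslip",
                                 contact = "one_surface", r_max_eff = 5)),
    flow = base,
    flow_benomyl = modifyList(base, list(benomyl = TRUE, alpha_factor = 0)),
    flow_sorbitol_washin = modifyList(base, list(
      sorbitol_windows = matrix(c(80, 300), ncol = 2))),
    flow_sorbitol_washout = modifyList(base, list(
      sorbitol_windows = matrix(c(0, 300), ncol = 2), duration = 360)),
    dose = {
      if (is.null(alpha_factor)) {
        stop("preset 'dose' requires alpha_factor (nM)")
      }
      modifyList(base, list(alpha_factor = alpha_factor,
                            name = paste0("dose_", alpha_factor)))
    })
  if (!is.null(alpha_factor) && preset != "dose") {
    stop("alpha_factor can only be set with preset 'dose'")
  }
  if (cond$benomyl && cond$alpha_factor > 0) {
    stop("benomyl and alpha_factor > 0 are mutually exclusive")
  }
  structure(cond, class = "lysis_condition")
}

#' @export
print.lysis_condition <- function(x, ...) {
  cat(sprintf("lysis_condition '%s': %s (%s), %g nM alpha-factor%s, %g min\n",
              x$name, x$environment, x$contact, x$alpha_factor,
              if (x$benomyl) " + benomyl" else "", x$duration))
  invisible(x)
}

# dose (nM) -> relative secretion level, 0 at dose 0, 1 at 50 nM
dose_secretion <- function(dose) {
  ifelse(dose <= 0, 0, 1.4 * dose / (dose + 20))
}

# dose (nM) -> effective secretion-disc radius: higher dose, tighter
# polarization (pointier shmoos); 2.5 wall thicknesses at 50 nM
dose_rs <- function(dose, rs_ref = 2.5) {
  rs_ref + 1.5 * (1 - pmin(dose, 50) / 50)
}

sorbitol_present <- function(time, windows) {
  if (nrow(windows) == 0L) return(rep(FALSE, length(time)))
  res <- rep(FALSE, length(time))
  for (w in seq_len(nrow(windows))) {
    res <- res | (time >= windows[w, 1] & time < windows[w, 2])
  }
  res
}

# local steady enzyme concentration (J/D units) for one set of cell-level
# multipliers under a condition's contact geometry
local_concentration <- function(cond, genotype, sec_mult, params) {
  rs_ref <- params$rs_ref
  if (cond$benomyl) {
    # unpolarized secretion: no concentrated zone, whole-membrane dilution
    return(params$benomyl_secretion * genotype$activity * sec_mult)
  }
  if (cond$alpha_factor <= 0) return(rep(0, length(sec_mult)))
  r_s_eff <- dose_rs(cond$alpha_factor, rs_ref) / genotype$focus
  # conserved total secretion: areal flux scales as (rs_ref / r_s_eff)^2
  J_eff <- genotype$activity * dose_secretion(cond$alpha_factor) *
    sec_mult * (rs_ref / r_s_eff)^2
  if (cond$contact == "none") {
    return(J_eff)       # unapposed surface concentration C0 = J/D
  }
  r_max_eff <- max(cond$r_max_eff, r_s_eff)
  geom <- wall_geometry(r_s = r_s_eff, r_max = r_max_eff, mode = "apposed")
  J_eff * apposed_drops(geom)$C_tot
}

#' Simulate a synthetic cohort of pheromone-arrested cells
#'
#' Draws per-cell secretion multipliers (lognormal), breach thresholds
#' (lognormal) and shmoo-onset times (gamma), computes each cell's local
#' steady enzyme concentration from the diffusion model given the
#' condition's contact geometry, and applies the breach-and-lysis rule on a
#' 10-minute observation grid (deaths between frames are recorded at the
#' next frame, mirroring the imaging cadence).
#'
#' @param n_cells Number of cells (>= 1).
#' @param condition A [make_condition()] object.
#' @param seed Integer seed; mandatory.
#' @param params Model parameters, see [lysis_params()].
#' @param genotype A [genotype_preset()] or equivalent list.
#' @return A tibble of per-cell event records: \code{cell_id},
#'   \code{condition}, \code{onset_min}, \code{breach_min} (NA if never
#'   breached), \code{lysis_min} (NA if alive at the end), \code{max_conc}
#'   (J/D units).
#' @examples
#' rec <- simulate_population(200, make_condition("flow"), seed = 1)
#' fraction_dead(rec, 300)
#' @export
simulate_population <- function(n_cells, condition, seed,
                                params = lysis_params(),
                                genotype = genotype_preset("wild_type")) {
  if (missing(seed)) stop("simulate_population: an explicit seed is required")
  stopifnot(inherits(condition, "lysis_condition"),
            is.numeric(n_cells), n_cells >= 1, n_cells == round(n_cells))
  p <- modifyList(lysis_params(), params)
  bad <- vapply(p[c("theta_gsd", "sec_gsd")], function(v) v < 1, logical(1))
  if (any(bad)) stop("geometric SDs must be >= 1")
  if (p$theta_mean <= 0 || p$capacity < 0) {
    stop("theta_mean must be > 0 and capacity >= 0")
  }
  set.seed(as.integer(seed))
  n <- as.integer(n_cells)

  sec_mult <- stats::rlnorm(n, 0, log(p$sec_gsd))
  theta <- p$theta_mean * stats::rlnorm(n, 0, log(p$theta_gsd))
  shmooing <- !condition$benomyl && condition$alpha_factor > 0
  onset <- if (shmooing) {
    stats::rgamma(n, shape = p$onset_shape,
                  rate = p$onset_shape / p$onset_mean)
  } else if (condition$benomyl) {
    rep(0, n)           # arrest (and unpolarized secretion) from t = 0
  } else {
    rep(NA_real_, n)    # no arrest, no shmoo, no secretion focus
  }
  conc <- local_concentration(condition, genotype, sec_mult, p)
  if (length(conc) == 1L) conc <- rep(conc, n)

  # breach: accumulated excess (conc - theta) * elapsed > capacity
  excess <- pmax(conc - theta, 0)
  active <- excess > 0 & !is.na(onset)
  breach <- rep(NA_real_, n)
  breach[active] <- onset[active] +
    ifelse(excess[active] > 0, p$capacity / excess[active], Inf)
  breach[!is.na(breach) & breach > condition$duration] <- NA_real_

  # lysis: per-frame Bernoulli for breached, living cells
  frames <- seq(10, condition$duration, by = 10)
  sorb <- sorbitol_present(frames - 5, condition$sorbitol_windows)
  dpi <- ifelse(sorb, p$dpi_sorbitol, p$dpi_normal)
  p_lyse <- stats::plogis(p$lysis_k * (dpi - p$lysis_pi0))
  lysis <- rep(NA_real_, n)
  alive_breached <- rep(FALSE, n)
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    alive_breached <- !is.na(breach) & breach <= t & is.na(lysis)
    if (any(alive_breached)) {
      u <- stats::runif(sum(alive_breached))
      died <- u < p_lyse[fi]
      lysis[which(alive_breached)[died]] <- t
    }
  }

  tibble::tibble(
    cell_id = seq_len(n),
    condition = condition$name,
    onset_min = onset,
    breach_min = breach,
    lysis_min = lysis,
    max_conc = ifelse(is.na(onset), 0, conc)
  )
}

#' Fraction of cells dead at a time point
#'
#' @param records Event records from [simulate_population()].
#' @param time Observation time in minutes.
#' @return Deaths at or before \code{time}, divided by the cohort size.
#' @export
fraction_dead <- function(records, time) {
  stopifnot(is.data.frame(records), nrow(records) >= 1, is.numeric(time))
  mean(!is.na(records$lysis_min) & records$lysis_min <= time)
}

#' Fraction of cells breached by the end of observation
#'
#' Breach (loss of wall integrity) precedes lysis and is insensitive to the
#' osmotic environment; this is the quantity the sharp separation test of
#' the model operates on.
#'
#' @param records Event records from [simulate_population()].
#' @return Fraction of cells with a recorded breach.
#' @export
fraction_breached <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  mean(!is.na(records$breach_min))
}

#' Population death-curve summary
#'
#' @param records Event records from [simulate_population()].
#' @param duration Observation window end (minutes); defaults to the last
#'   frame present in the records' condition.
#' @return A tibble \code{time}, \code{fraction_dead} on the 10-minute
#'   observation grid; the fraction is nondecreasing by construction.
#' @export
population_summary <- function(records, duration = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(duration)) {
    duration <- max(c(300, records$lysis_min), na.rm = TRUE)
  }
  times <- seq(0, duration, by = 10)
  tibble::tibble(
    time = times,
    fraction_dead = vapply(times, function(t) fraction_dead(records, t),
                           numeric(1))
  )
}

#' Fold change in deaths between two time windows
#'
#' Ratio of death counts in a later window to an earlier one, the statistic
#' used to read out the sorbitol wash-in protocol (deaths during the 80
#' minutes before versus the 60 minutes after the medium change).
#'
#' @param records Event records from [simulate_population()].
#' @param window_a,window_b Numeric \code{c(start, end]} windows in minutes;
#'   must be ordered and disjoint.
#' @return \code{deaths(window_b) / deaths(window_a)}, or \code{NA} (with a
#'   warning) when no deaths fall in \code{window_a} -- an undefined ratio,
#'   never infinity.
#' @export
fold_change <- function(records, window_a = c(0, 80), window_b = c(80, 140)) {
  stopifnot(length(window_a) == 2, length(window_b) == 2,
            window_a[1] < window_a[2], window_b[1] < window_b[2])
  if (window_a[2] > window_b[1]) {
    stop("fold_change: windows must be ordered and disjoint")
  }
  deaths_in <- function(w) {
    sum(!is.na(records$lysis_min) &
          records$lysis_min > w[1] & records$lysis_min <= w[2])
  }
  a <- deaths_in(window_a)
  b <- deaths_in(window_b)
  if (a == 0) {
    warning("fold_change undefined: no deaths in the reference window")
    return(NA_real_)
  }
  b / a
}

#' Compare replicate death fractions between two conditions
#'
#' Welch's unequal-variance two-sample t-test, two-sided, on
#' replicate-level death fractions.
#'
#' @param fractions_a,fractions_b Numeric vectors of replicate-level death
#'   fractions (>= 2 each).
#' @return The \code{htest} object from [stats::t.test()].
#' @export
compare_conditions <- function(fractions_a, fractions_b) {
  if (length(fractions_a) < 2 || length(fractions_b) < 2) {
    stop("compare_conditions requires at least 2 replicates per side")
  }
  stats::t.test(fractions_a, fractions_b)
}

#' Death fraction across pheromone doses
#'
#' Runs the flow-chamber cohort at each dose.  Higher dose means tighter
#' polarization (smaller effective secretion disc) and higher secretion,
#' hence a higher local enzyme concentration and, at shipped defaults, a
#' nondecreasing mean death fraction.  Each dose uses a seed derived
#' deterministically from the dose value, so permuting the dose order
#' permutes the outputs identically.
#'
#' @param doses Numeric vector of alpha-factor doses (nM).
#' @param n_cells Cells per dose.
#' @param seed Root integer seed.
#' @param params Model parameters, see [lysis_params()].
#' @return A tibble \code{dose}, \code{fraction_dead}.
#' @export
dose_response <- function(doses, n_cells = 1000, seed,
                          params = lysis_params()) {
  if (missing(seed)) stop("dose_response: an explicit seed is required")
  stopifnot(is.numeric(doses), all(doses >= 0))
  frac <- vapply(doses, function(d) {
    cond <- make_condition("dose", alpha_factor = d)
    dseed <- (as.integer(seed) + as.integer(round(100 * d))) %% .Machine$integer.max
    rec <- simulate_population(n_cells, cond, seed = dseed, params = params)
    fraction_dead(rec, cond$duration)
  }, numeric(1))
  tibble::tibble(dose = doses, fraction_dead = frac)
}
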