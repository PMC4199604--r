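# Closed-form steady-state solutions.
#
# Unapposed cell: enzymes secreted at the plasma membrane (x = 0) diffuse
# through the wall thickness to an infinite sink at the outer surface
# (x = 1, wall-thickness units).  Constant flux J implies a linear profile
# C(x) = (J/D) (1 - x).
#
# Apposed cell: a thin wall sheet (both faces reflecting) with a uniform
# areal source J over the disc r <= r_s and an absorbing rim at r = r_max.
# Flux balance through the circle of radius r gives
#   -D dC/dr * 2 pi r = pi min(r, r_s)^2 J,
# which integrates to a quadratic drop inside the source disc and a
# logarithmic drop across the source-free annulus:
#   C_s  = J r_s^2 / (4 D)
#   C_d  = J r_s^2 / (2 D) * log(r_max / r_s)

#' Steady-state concentration through the wall of an unapposed cell
#'
#' Linear profile \code{C(x) = (J/D)(1 - x)} for depth \code{x} in
#' wall-thickness units, with \code{x = 0} at the plasma membrane and
#' \code{x = 1} at the wall/solution interface (an infinite sink, so
#' \code{C(1) = 0}).
#'
#' @param x Depth in \code{[0, 1]} (wall-thickness units); vectorized.
#' @param params A [diffusion_params()] object.
#' @return Concentration at \code{x}, in absolute units (\code{J/D} when
#'   \code{J = D = 1}).
#' @examples
#' unapposed_concentration(c(0, 0.5, 1))
#' @export
unapposed_concentration <- function(x, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"), is.numeric(x))
  if (any(x < 0 | x > 1)) {
    stop("unapposed_concentration: depth x must lie in [0, 1]")
  }
  (params$J / params$D) * (1 - x)
}

#' Depth-averaged concentration in the wall of an unapposed cell
#'
#' The mean of the linear unapposed profile over the wall thickness,
#' \code{J/(2D)}: the average of \code{J/D} at the cell surface and 0 at the
#' wall/solution interface.  This is the reference level against which the
#' apposed-geometry enhancement is quoted.
#'
#' @inheritParams unapposed_concentration
#' @return The depth-mean concentration \code{J/(2D)}.
#' @export
unapposed_mean_concentration <- function(params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  params$J / (2 * params$D)
}

#' Steady-state radial concentration in the apposed wall sheet
#'
#' Piecewise profile of the depth-averaged apposed solution with an absorbing
#' rim, \code{C(r_max) = 0}:
#' \itemize{
#'   \item annulus \code{r_s <= r <= r_max}:
#'     \code{C(r) = (J r_s^2 / 2D) log(r_max / r)}
#'   \item source disc \code{0 <= r <= r_s}:
#'     \code{C(r) = C(r_s) + (J / 4D) (r_s^2 - r^2)}
#' }
#' The profile is continuous and differentiable at \code{r = r_s} and
#' strictly decreasing on \code{(0, r_max)}.  At the default geometry
#' (\code{r_s = 2.5}, \code{r_max = 10}) the center value is
#' 5.89 \code{J/D} to two decimals.
#'
#' @param r Radius in \code{[0, r_max]} (wall-thickness units); vectorized.
#' @param geometry A [wall_geometry()] in apposed mode.
#' @param params A [diffusion_params()] object.
#' @return Concentration at \code{r}.
#' @examples
#' apposed_concentration(0)            # about 5.89
#' apposed_concentration(c(2.5, 10))
#' @export
apposed_concentration <- function(r, geometry = wall_geometry(),
                                  params = diffusion_params()) {
  assert_apposed(geometry)
  stopifnot(inherits(params, "diffusion_params"), is.numeric(r))
  if (any(r < 0 | r > geometry$r_max)) {
    stop("apposed_concentration: radius r must lie in [0, r_max]")
  }
  JD <- params$J / params$D
  r_s <- geometry$r_s
  r_max <- geometry$r_max
  annulus <- JD * (r_s^2 / 2) * log(r_max / pmax(r, r_s))
  disc <- JD * pmax(r_s^2 - pmin(r, r_s)^2, 0) / 4
  annulus + disc
}

#' The three concentration drops of the apposed geometry
#'
#' \code{C_s}, the drop from the center to the edge of the secretion disc;
#' \code{C_d}, the drop across the source-free annulus; and their sum
#' \code{C_tot}, the total drop from the center of the apposed patch to its
#' absorbing rim (which equals the center concentration, since the rim is at
#' zero).
#'
#' @inheritParams apposed_concentration
#' @return An object of class \code{"apposed_solution"}: a list with
#'   components \code{C_s}, \code{C_d}, \code{C_tot}.
#' @examples
#' apposed_drops()          # C_tot = 5.89 J/D at the default geometry
#' @export
apposed_drops <- function(geometry = wall_geometry(),
                          params = diffusion_params()) {
  assert_apposed(geometry)
  stopifnot(inherits(params, "diffusion_params"))
  JD <- params$J / params$D
  C_s <- JD * geometry$r_s^2 / 4
  C_d <- JD * (geometry$r_s^2 / 2) * log(geometry$r_max / geometry$r_s)
  structure(list(C_s = C_s, C_d = C_d, C_tot = C_s + C_d),
            class = "apposed_solution")
}

#' @export
print.apposed_solution <- function(x, ...) {
  cat(sprintf("apposed_solution: C_s = %.4f, C_d = %.4f, C_tot = %.4f (J/D units)\n",
              x$C_s, x$C_d, x$C_tot))
  invisible(x)
}

#' Concentration enhancement of apposition
#'
#' Ratio of the concentration at the center of the apposed patch (uniform
#' across the wall depth, because both wall faces are reflecting) to the
#' depth-mean concentration in the wall of an unapposed cell, \code{J/(2D)}.
#' At the default geometry the ratio is about 11.8, i.e. apposition raises
#' the local enzyme concentration more than tenfold.
#'
#' @inheritParams apposed_concentration
#' @return A dimensionless ratio.
#' @examples
#' enhancement_ratio()      # about 11.79
#' @export
enhancement_ratio <- function(geometry = wall_geometry(),
                              params = diffusion_params()) {
  assert_apposed(geometry)
  stopifnot(inherits(params, "diffusion_params"))
  if (params$J == 0) {
    stop("enhancement_ratio is undefined for J = 0 (no secretion)")
  }
  apposed_drops(geometry, params)$C_tot / unapposed_mean_concentration(params)
}

#' Sampled concentration profiles for both scenarios
#'
#' Samples the unapposed (depth) and apposed (radius) closed-form profiles on
#' uniform grids, in the tabular schema used by all profile writers:
#' columns \code{position}, \code{concentration}, \code{method}, \code{mode},
#' \code{r_s}, \code{r_max}.
#'
#' @param geometry A [wall_geometry()]; its \code{r_s}/\code{r_max} set the
#'   apposed scenario (mode is ignored, both scenarios are returned).
#' @param params A [diffusion_params()] object.
#' @param n_points Number of grid points per profile (>= 2).
#' @return A list with tibbles \code{unapposed} and \code{apposed}.
#' @examples
#' pt <- profile_table(n_points = 5)
#' pt$apposed
#' @export
profile_table <- function(geometry = wall_geometry(),
                          params = diffusion_params(), n_points = 101) {
  stopifnot(inherits(geometry, "wall_geometry"),
            inherits(params, "diffusion_params"))
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2) {
    stop("profile_table: n_points must be an integer >= 2")
  }
  apo <- geometry
  apo$mode <- "apposed"
  x <- seq(0, 1, length.out = n_points)
  r <- seq(0, geometry$r_max, length.out = n_points)
  list(
    unapposed = tibble::tibble(
      position = x,
      concentration = unapposed_concentration(x, params),
      method = "analytic", mode = "unapposed",
      r_s = geometry$r_s, r_max = geometry$r_max),
    apposed = tibble::tibble(
      position = r,
      concentration = apposed_concentration(r, apo, params),
      method = "analytic", mode = "apposed",
      r_s = geometry$r_s, r_max = geometry$r_max)
  )
}

#' Scalar summary of the apposed solution
#'
#' Collects the apposed concentration drops, the enhancement ratio and the
#' geometry into one list, ready for JSON export.
#'
#' @inheritParams apposed_concentration
#' @return A list with elements \code{C_s}, \code{C_d}, \code{C_tot},
#'   \code{enhancement_ratio} and \code{geometry}.
#' @export
apposed_summary <- function(geometry = wall_geometry(),
                            params = diffusion_params()) {
  drops <- apposed_drops(geometry, params)
  list(C_s = drops$C_s, C_d = drops$C_d, C_tot = drops$C_tot,
       enhancement_ratio = enhancement_ratio(geometry, params),
       geometry = list(h = geometry$h, r_s = geometry$r_s,
                       r_max = geometry$r_max, mode = geometry$mode))
}
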