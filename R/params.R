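#' Diffusion parameters
#'
#' Bundles the two physical constants of the wall-diffusion model: the
#' secretion flux density \code{J} (enzymes per unit membrane area per unit
#' time) and the diffusion coefficient \code{D} of the enzyme inside the cell
#' wall.  Every concentration the package reports is a pure multiple of
#' \code{J/D}, so all outputs are invariant under the joint rescaling
#' \code{(J, D) -> (k*J, k*D)}.
#'
#' @param J Secretion rate per unit membrane area. Must be >= 0.
#' @param D Diffusion coefficient inside the wall. Must be > 0.
#' @return An object of class \code{"diffusion_params"}.
#' @examples
#' p <- diffusion_params()
#' p$J / p$D
#' @export
diffusion_params <- function(J = 1, D = 1) {
  stopifnot(is.numeric(J), length(J) == 1L, is.finite(J), J >= 0,
            is.numeric(D), length(D) == 1L, is.finite(D), D > 0)
  structure(list(J = J, D = D), class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("diffusion_params: J = %g, D = %g (concentration unit J/D = %g)\n",
              x$J, x$D, x$J / x$D))
  invisible(x)
}

#' Wall geometry
#'
#' Describes the geometry of the enzyme escape problem.  Lengths are
#' nondimensionalized by the wall thickness \code{h}: with the defaults
#' \code{h = 0.1} micrometres, a secretion-disc radius \code{r_s = 2.5} and an
#' apposed-disc radius \code{r_max = 10} correspond to physical radii of
#' 0.25 and 1 micrometre.
#'
#' Two modes are supported.  \code{"unapposed"}: the cell is free in solution
#' and enzymes escape one-dimensionally through the wall thickness.
#' \code{"apposed"}: a circular wall patch of radius \code{r_max} is pressed
#' against an impermeable surface, enzymes are secreted over the central disc
#' of radius \code{r_s} and escape only by diffusing radially, in the plane of
#' the wall, to the rim of the apposed patch.
#'
#' @param h Wall thickness in micrometres (> 0).
#' @param r_s Secretion-disc radius in wall-thickness units (> 0).
#' @param r_max Apposed-disc radius in wall-thickness units (>= \code{r_s}).
#' @param mode \code{"apposed"} or \code{"unapposed"}.
#' @return An object of class \code{"wall_geometry"}.
#' @examples
#' wall_geometry()                      # micron-scale defaults, apposed
#' wall_geometry(mode = "unapposed")
#' @export
wall_geometry <- function(h = 0.1, r_s = 2.5, r_max = 10,
                          mode = c("apposed", "unapposed")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(h), length(h) == 1L, h > 0,
            is.numeric(r_s), length(r_s) == 1L, r_s > 0,
            is.numeric(r_max), length(r_max) == 1L)
  if (r_s > r_max) {
    stop("wall_geometry: need 0 < r_s <= r_max (got r_s = ", r_s,
         ", r_max = ", r_max, ")")
  }
  structure(list(h = h, r_s = r_s, r_max = r_max, mode = mode),
            class = "wall_geometry")
}

#' @export
print.wall_geometry <- function(x, ...) {
  cat(sprintf("wall_geometry [%s]: h = %g um, r_s = %g, r_max = %g (wall-thickness units)\n",
              x$mode, x$h, x$r_s, x$r_max))
  invisible(x)
}

assert_apposed <- function(geometry) {
  stopifnot(inherits(geometry, "wall_geometry"))
  if (geometry$mode != "apposed") {
    stop("this operation requires geometry in 'apposed' mode")
  }
  invisible(geometry)
}
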