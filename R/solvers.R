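# Finite-volume oracles for the closed forms.
#
# All solvers work in nondimensional units (lengths in wall thickness,
# D = 1 internally, results scaled to J/D).  Radial discretizations are
# cell-centered: centers at (i - 1/2) dr keep the r = 0 coordinate
# singularity off the grid, and face-based fluxes make conservation exact
# at the discrete level.

#' Cell-centered radial grid
#'
#' @param n_cells Number of cells (>= 8).
#' @param r_max Outer radius (wall-thickness units).
#' @return An object of class \code{"radial_grid"} with faces, centers and
#'   spacing \code{dr = r_max / n_cells}.
#' @export
radial_grid <- function(n_cells, r_max = 10) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 8,
            n_cells == round(n_cells), r_max > 0)
  n_cells <- as.integer(n_cells)
  dr <- r_max / n_cells
  structure(list(n_cells = n_cells, r_max = r_max, dr = dr,
                 faces = seq(0, r_max, length.out = n_cells + 1L),
                 centers = (seq_len(n_cells) - 0.5) * dr),
            class = "radial_grid")
}

solver_result <- function(profile, residual, grid) {
  structure(list(profile = profile, residual = residual, grid = grid),
            class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf("solver_result: %d cells, residual %.3e, center value %.6g\n",
              x$grid$n_cells, x$residual, x$profile$concentration[1]))
  invisible(x)
}

# Thomas-style tridiagonal solve via Matrix's banded sparse LU.
solve_tridiag <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  A <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(lower, diag, upper))
  as.numeric(Matrix::solve(A, rhs))
}

#' Finite-volume solution of the unapposed slab problem
#'
#' Solves steady 1-D diffusion through the wall thickness with influx
#' \code{J} at the membrane face (\code{x = 0}) and an absorbing outer
#' surface (\code{C = 0} at \code{x = 1}).  The discrete problem is exactly
#' linear, so the solution reproduces \code{C(x) = (J/D)(1 - x)} to solver
#' precision.
#'
#' @param geometry A [wall_geometry()] in unapposed mode.
#' @param n_cells Number of cells through the thickness.
#' @param params A [diffusion_params()] object.
#' @return A \code{solver_result} whose profile holds cell-center depths and
#'   concentrations.
#' @export
solve_steady_slab <- function(geometry = wall_geometry(mode = "unapposed"),
                              n_cells = 64, params = diffusion_params()) {
  stopifnot(inherits(geometry, "wall_geometry"))
  if (geometry$mode != "unapposed") {
    stop("solve_steady_slab requires geometry in 'unapposed' mode")
  }
  n <- as.integer(n_cells)
  stopifnot(n >= 2)
  dx <- 1 / n
  JD <- params$J / params$D
  # interior faces: flux -(C[i+1]-C[i])/dx; x=0 face: influx JD;
  # x=1 face: absorbing half-cell flux 2 C[n]/dx
  dg <- rep(2 / dx, n)
  dg[1] <- 1 / dx
  dg[n] <- 3 / dx
  lo <- rep(-1 / dx, n - 1L)
  up <- rep(-1 / dx, n - 1L)
  rhs <- c(JD, rep(0, n - 1L))
  C <- solve_tridiag(lo, dg, up, rhs)
  x <- (seq_len(n) - 0.5) * dx
  resid <- {
    flux <- c(JD, -diff(C) / dx, 2 * C[n] / dx)
    max(abs(diff(flux)))
  }
  grid <- structure(list(n_cells = n, r_max = 1, dr = dx,
                         faces = seq(0, 1, length.out = n + 1L),
                         centers = x), class = "radial_grid")
  profile <- tibble::tibble(position = x, concentration = C,
                            method = "numeric", mode = "unapposed",
                            r_s = geometry$r_s, r_max = geometry$r_max)
  solver_result(profile, resid, grid)
}

radial_source <- function(grid, r_s, J) {
  # integrated source per cell divided by 2*pi: J * (min(r_s,f_i)^2 -
  # min(r_s,f_{i-1})^2)/2 -- the boundary cell automatically receives J
  # weighted by its covered area fraction
  f <- grid$faces
  J * diff(pmin(f, r_s)^2) / 2
}

#' Finite-volume solution of the apposed radial problem
#'
#' Solves the depth-averaged steady equation
#' \code{(1/r) d/dr (r D dC/dr) + S(r) = 0} on the apposed patch, with
#' uniform source \code{S = J} over \code{r <= r_s}, zero flux at
#' \code{r = 0} and an absorbing rim \code{C(r_max) = 0}.  Cell-centered
#' finite volumes with face fluxes give exact discrete conservation and
#' second-order accuracy; the cell cut by \code{r = r_s} receives the source
#' weighted by its covered area fraction.
#'
#' @param geometry A [wall_geometry()] in apposed mode.
#' @param grid A [radial_grid()]; its \code{r_max} must match the geometry.
#' @param params A [diffusion_params()] object.
#' @return A \code{solver_result}; \code{residual} is the maximum cell-wise
#'   defect of the solved linear system (flux divergence minus source).
#' @export
solve_steady_radial <- function(geometry = wall_geometry(),
                                grid = radial_grid(1024, geometry$r_max),
                                params = diffusion_params()) {
  assert_apposed(geometry)
  stopifnot(inherits(grid, "radial_grid"))
  if (abs(grid$r_max - geometry$r_max) > 1e-12) {
    stop("solve_steady_radial: grid r_max must match geometry r_max")
  }
  n <- grid$n_cells
  dr <- grid$dr
  f <- grid$faces
  JD <- params$J / params$D
  s <- radial_source(grid, geometry$r_s, JD)
  # row i: F_i - F_{i-1} = s_i with F_j = -f_j (C[j+1]-C[j])/dr,
  # rim flux F_n = f_n C[n] / (dr/2)
  fin <- f[seq_len(n)]          # inner faces f_0..f_{n-1}
  fout <- f[seq_len(n) + 1L]    # outer faces f_1..f_n
  dg <- (fin + fout) / dr
  dg[n] <- fin[n] / dr + 2 * fout[n] / dr
  lo <- -fin[-1L] / dr
  up <- -fout[-n] / dr
  C <- solve_tridiag(lo, dg, up, s)
  flux <- c(0, -f[2:n] * diff(C) / dr, 2 * f[n + 1L] * C[n] / dr)
  resid <- max(abs(diff(flux) - s))
  profile <- tibble::tibble(position = grid$centers, concentration = C,
                            method = "numeric", mode = "apposed",
                            r_s = geometry$r_s, r_max = geometry$r_max)
  solver_result(profile, resid, grid)
}

#' Mesh-convergence study for the radial solver
#'
#' Compares the finite-volume apposed solution to the closed form on a
#' sequence of grids and reports the observed order of accuracy between
#' successive refinements.
#'
#' @param geometry A [wall_geometry()] in apposed mode.
#' @param n_cells Integer vector of resolutions (each >= 8), typically a
#'   doubling sequence.
#' @param params A [diffusion_params()] object.
#' @return A tibble with columns \code{n_cells}, \code{max_abs_error},
#'   \code{observed_order} (NA in the first row).
#' @export
convergence_study <- function(geometry = wall_geometry(),
                              n_cells = c(32, 64, 128, 256),
                              params = diffusion_params()) {
  stopifnot(length(n_cells) >= 2)
  err <- vapply(n_cells, function(n) {
    res <- solve_steady_radial(geometry, radial_grid(n, geometry$r_max), params)
    max(abs(res$profile$concentration -
              apposed_concentration(res$profile$position, geometry, params)))
  }, numeric(1))
  ord <- c(NA_real_,
           log(err[-length(err)] / err[-1]) /
             log(n_cells[-1] / n_cells[-length(n_cells)]))
  tibble::tibble(n_cells = as.integer(n_cells), max_abs_error = err,
                 observed_order = ord)
}

#' Explicit transient solution of the apposed radial problem
#'
#' Time-marches the depth-averaged radial diffusion equation from a zero
#' initial condition with the constant source switched on at \code{t = 0},
#' using forward Euler with a stability-bounded step (automatic sub-stepping
#' to hit the requested output times exactly).  The profile relaxes
#' monotonically toward the steady state, which justifies the steady-state
#' treatment used everywhere else.
#'
#' @param geometry A [wall_geometry()] in apposed mode.
#' @param grid A [radial_grid()].
#' @param horizon Final time, in units of \code{h^2/D}.
#' @param n_out Number of output times (uniform over \code{(0, horizon]}).
#' @param params A [diffusion_params()] object.
#' @return A list: \code{times}, \code{center} (center concentration per
#'   output time), \code{snapshots} (list of \code{solver_result}),
#'   \code{time_to_fraction(f)} returning the first output time at which the
#'   center concentration reaches \code{f} times its steady value.
#' @export
solve_transient_radial <- function(geometry = wall_geometry(),
                                   grid = radial_grid(128, geometry$r_max),
                                   horizon = 100, n_out = 50,
                                   params = diffusion_params()) {
  assert_apposed(geometry)
  stopifnot(horizon > 0, n_out >= 1)
  n <- grid$n_cells
  dr <- grid$dr
  f <- grid$faces
  JD <- params$J / params$D
  s <- radial_source(grid, geometry$r_s, JD)
  vol <- diff(f^2) / 2                 # cell area / (2 pi)
  dt_stab <- 0.2 * dr^2                # explicit diffusion stability (D = 1)
  out_times <- seq(horizon / n_out, horizon, length.out = n_out)
  C <- rep(0, n)
  fin <- f[seq_len(n)]
  fout <- f[seq_len(n) + 1L]
  rate <- function(C) {
    Fi <- numeric(n + 1L)              # face fluxes (per radian)
    Fi[2:n] <- -f[2:n] * diff(C) / dr
    Fi[n + 1L] <- 2 * f[n + 1L] * C[n] / dr
    (s - diff(Fi)) / vol
  }
  t <- 0
  snapshots <- vector("list", n_out)
  center <- numeric(n_out)
  for (k in seq_len(n_out)) {
    while (t < out_times[k] - 1e-12) {
      dt <- min(dt_stab, out_times[k] - t)
      C <- C + dt * rate(C)
      t <- t + dt
    }
    center[k] <- C[1]
    profile <- tibble::tibble(position = grid$centers, concentration = C,
                              method = "numeric", mode = "apposed",
                              r_s = geometry$r_s, r_max = geometry$r_max)
    snapshots[[k]] <- solver_result(profile, NA_real_, grid)
  }
  steady_center <- apposed_drops(geometry, params)$C_tot
  list(times = out_times, center = center, snapshots = snapshots,
       time_to_fraction = function(fr) {
         stopifnot(fr > 0, fr < 1)
         hit <- which(center >= fr * steady_center)
         if (!length(hit)) return(NA_real_)
         out_times[hit[1]]
       })
}

#' Depth-resolved steady solution on the (r, z) wall cross-section
#'
#' Solves steady diffusion on the axisymmetric wall cross-section
#' (\code{0 <= r <= r_max}, \code{0 <= z <= 1} in wall-thickness units) with
#' secretion entering as an influx at the membrane face (\code{z = 0},
#' \code{r <= r_s}).  The outer wall face (\code{z = 1}) is either
#' \code{"reflecting"} (pressed against an impermeable surface) or
#' \code{"absorbing"} (free escape into solution); the rim \code{r = r_max}
#' is absorbing and the axis is a symmetry boundary.  With a reflecting face
#' the depth average reproduces the 2-D radial solution, since integrating
#' the equation over depth removes the axial fluxes exactly.
#'
#' @param geometry A [wall_geometry()].
#' @param grid A [radial_grid()] for the radial direction.
#' @param nz Number of cells through the depth (>= 4).
#' @param apposed_face \code{"reflecting"} or \code{"absorbing"}.
#' @param params A [diffusion_params()] object.
#' @return A list: \code{r}, \code{z} (cell centers), \code{C} (matrix
#'   \code{n_r x nz}), \code{depth_mean} (radial profile of the depth
#'   average), \code{residual}.
#' @export
solve_steady_rz <- function(geometry = wall_geometry(),
                            grid = radial_grid(128, geometry$r_max),
                            nz = 8,
                            apposed_face = c("reflecting", "absorbing"),
                            params = diffusion_params()) {
  apposed_face <- match.arg(apposed_face)
  stopifnot(inherits(geometry, "wall_geometry"), nz >= 4)
  nz <- as.integer(nz)
  nr <- grid$n_cells
  dr <- grid$dr
  dz <- 1 / nz
  f <- grid$faces
  JD <- params$J / params$D
  src_face <- radial_source(grid, geometry$r_s, JD)   # influx per cell at z=0
  idx <- function(i, k) (k - 1L) * nr + i
  N <- nr * nz
  # assemble -div(grad C) V = source as sparse triplets
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  rhs <- numeric(N)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }
  fin <- f[seq_len(nr)]
  fout <- f[seq_len(nr) + 1L]
  for (k in seq_len(nz)) {
    for (i in seq_len(nr)) {
      p <- idx(i, k)
      # radial neighbours (face area per radian: f * dz)
      if (i > 1L) {
        w <- fin[i] * dz / dr
        add(p, p, w); add(p, idx(i - 1L, k), -w)
      }
      if (i < nr) {
        w <- fout[i] * dz / dr
        add(p, p, w); add(p, idx(i + 1L, k), -w)
      } else {
        w <- 2 * fout[i] * dz / dr      # absorbing rim, half-cell
        add(p, p, w)
      }
      # axial neighbours (face area per radian: r_i dr)
      rA <- grid$centers[i] * dr
      if (k > 1L) {
        w <- rA / dz
        add(p, p, w); add(p, idx(i, k - 1L), -w)
      } else {
        rhs[p] <- rhs[p] + src_face[i]  # membrane influx
      }
      if (k < nz) {
        w <- rA / dz
        add(p, p, w); add(p, idx(i, k + 1L), -w)
      } else if (apposed_face == "absorbing") {
        add(p, p, 2 * rA / dz)          # absorbing outer face, half-cell
      }                                 # reflecting: zero flux, no term
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  C <- as.numeric(Matrix::solve(A, rhs))
  resid <- max(abs(as.numeric(A %*% C) - rhs))
  Cm <- matrix(C, nrow = nr, ncol = nz)
  list(r = grid$centers, z = (seq_len(nz) - 0.5) * dz, C = Cm,
       depth_mean = rowMeans(Cm), residual = resid)
}
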