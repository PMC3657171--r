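# Compressible viscous-fluid operator solver -----------------------------
#
# Solves   mu * lap(v) + (mu + lambda) * grad(div v) = -F   on the crop box.
#
# Discretisation: central differences on the image grid with impermeable
# free-slip boundaries (zero normal displacement; zero normal derivative of
# the tangential components).  Under these conditions the operator is
# block-diagonalised exactly by a mixed trigonometric basis: component i is
# expanded with a sine basis along its own axis and cosine bases along the
# other two, giving an independent 3x3 linear system per frequency.  The
# "fft" solver inverts those systems directly; the "sor" solver relaxes the
# identical finite-difference equations iteratively, so the two agree to
# the iterative tolerance.

# Basis matrices for one axis of length n with grid step h: sine modes
# m = 1..n-2 on the interior (zero at both faces) and cosine modes
# m = 0..n-1.  Frequencies theta_m = pi m / (n-1) per grid step.
fluid_basis <- function(n, h) {
  key <- paste("basis", n, signif(h, 12), sep = "_")
  if (!is.null(.gma_cache[[key]])) return(.gma_cache[[key]])
  m_all <- 0:(n - 1)
  theta <- pi * m_all / (n - 1)
  j <- 0:(n - 1)
  # synthesis matrices: rows = grid points, cols = modes
  Syn_s <- sin(outer(j, theta))          # n x n; cols 1 and n vanish
  Syn_c <- cos(outer(j, theta))
  # analysis: invert on the supported modes
  Ana_s <- matrix(0, n, n)
  Ana_s[2:(n - 1), 2:(n - 1)] <- solve(Syn_s[2:(n - 1), 2:(n - 1)])
  Ana_c <- solve(Syn_c)
  out <- list(Syn_s = Syn_s, Syn_c = Syn_c, Ana_s = Ana_s, Ana_c = Ana_c,
              lam = (2 - 2 * cos(theta)) / h^2, s = sin(theta) / h)
  .gma_cache[[key]] <- out
  out
}

# Multiply matrix M (n x n) along axis ax of 3D array a.
axis_mult <- function(a, ax, M) {
  d <- dim(a)
  if (ax == 1L) {
    array(M %*% matrix(a, d[1]), d)
  } else if (ax == 2L) {
    ap <- aperm(a, c(2, 1, 3))
    aperm(array(M %*% matrix(ap, d[2]), d[c(2, 1, 3)]), c(2, 1, 3))
  } else {
    array(matrix(a, d[1] * d[2]) %*% t(M), d)
  }
}

#' Fluid-equation parameters
#'
#' @param mu,lambda viscosity coefficients (mu > 0; defaults mu = 1,
#'   lambda = 0).
#' @param force_threshold exit threshold on the mean body-force norm over
#'   the mask.  The default is calibrated on phantom runs; `5e-8` is kept
#'   available as a published preset.
#' @param max_iter iteration cap for [fluid_register()].
#' @param max_step maximum displacement increment per iteration, as a
#'   fraction of the smallest voxel dimension.
#' @param regrid_threshold regrid when the minimum Jacobian determinant of
#'   the incremental field falls below this value (in (0,1)).
#' @param smooth_sigma Gaussian pre-smoothing of both images before the
#'   similarity/force computation, in voxels (0 disables).  Smoothing
#'   regularises the correlation landscape so that interpolation artefacts
#'   at tissue edges do not masquerade as signal; the recovered field is
#'   still applied to the unsmoothed images for the final rendering.
#' @param solver `"fft"` (direct spectral) or `"sor"` (successive
#'   over-relaxation of the same equations).
#' @param sor_omega,sor_max_iter,sor_tol SOR relaxation factor, iteration
#'   cap and relative-residual tolerance.
#' @return object of class `fluid_params`.
#' @export
fluid_params <- function(mu = 1, lambda = 0, force_threshold = 2e-9,
                         max_iter = 30L, max_step = 0.3,
                         regrid_threshold = 0.5, smooth_sigma = 1,
                         solver = c("fft", "sor"), sor_omega = 1.5,
                         sor_max_iter = 2000L, sor_tol = 1e-3) {
  solver <- match.arg(solver)
  if (mu <= 0) stop("mu must be positive")
  if (force_threshold <= 0) stop("force threshold must be positive")
  if (regrid_threshold <= 0 || regrid_threshold >= 1)
    stop("regrid threshold must be in (0, 1)")
  structure(list(mu = mu, lambda = lambda,
                 force_threshold = force_threshold,
                 max_iter = as.integer(max_iter), max_step = max_step,
                 regrid_threshold = regrid_threshold,
                 smooth_sigma = smooth_sigma, solver = solver,
                 sor_omega = sor_omega,
                 sor_max_iter = as.integer(sor_max_iter),
                 sor_tol = sor_tol),
            class = "fluid_params")
}

#' Solve the viscous-fluid equation for a velocity field
#'
#' @param force 4D array (`dim x 3`) of body-force components on the grid.
#' @param params a [fluid_params()].
#' @param spacing voxel spacing (mm per axis).
#' @return list: `v` (4D velocity array, same shape as `force`),
#'   `residual` (relative finite-difference residual), `solver`.
#' @export
solve_velocity <- function(force, params = fluid_params(),
                           spacing = c(1, 1, 1)) {
  d <- dim(force)
  if (length(d) != 4L || d[4] != 3L)
    stop("force must be a dim x 3 array")
  if (any(!is.finite(force))) stop("force contains NaN/Inf")
  if (all(force == 0))
    return(list(v = array(0, d), residual = 0, solver = params$solver))
  v <- if (params$solver == "fft") fluid_solve_fft(force, params, spacing)
       else fluid_solve_sor(force, params, spacing)
  res <- fluid_residual(v, force, params, spacing)
  if (params$solver == "sor" && res > params$sor_tol)
    stop("SOR failed to converge: relative residual ", signif(res, 4))
  list(v = v, residual = res, solver = params$solver)
}

fluid_solve_fft <- function(force, params, spacing) {
  d <- dim(force)[1:3]
  B <- lapply(1:3, function(ax) fluid_basis(d[ax], spacing[ax]))
  mu <- params$mu; ml <- params$mu + params$lambda
  # analysis of each component in its own mixed basis
  co <- vector("list", 3)
  for (i in 1:3) {
    a <- force[, , , i]
    for (ax in 1:3) {
      M <- if (ax == i) B[[ax]]$Ana_s else B[[ax]]$Ana_c
      a <- axis_mult(a, ax, M)
    }
    co[[i]] <- a
  }
  lam1 <- array(B[[1]]$lam, d)
  lam2 <- array(rep(rep(B[[2]]$lam, each = d[1]), d[3]), d)
  lam3 <- array(rep(B[[3]]$lam, each = d[1] * d[2]), d)
  s1 <- array(B[[1]]$s, d)
  s2 <- array(rep(rep(B[[2]]$s, each = d[1]), d[3]), d)
  s3 <- array(rep(B[[3]]$s, each = d[1] * d[2]), d)
  L <- lam1 + lam2 + lam3
  # M vhat = -Fhat with M_ii = -(mu L + ml lam_i), M_ij = -ml s_i s_j
  a11 <- mu * L + ml * lam1
  a22 <- mu * L + ml * lam2
  a33 <- mu * L + ml * lam3
  a12 <- ml * s1 * s2
  a13 <- ml * s1 * s3
  a23 <- ml * s2 * s3
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  det[det == 0] <- Inf  # the all-zero frequency carries no force
  f1 <- co[[1]]; f2 <- co[[2]]; f3 <- co[[3]]
  v1 <- ((a22 * a33 - a23^2) * f1 + (a13 * a23 - a12 * a33) * f2 +
           (a12 * a23 - a13 * a22) * f3) / det
  v2 <- ((a13 * a23 - a12 * a33) * f1 + (a11 * a33 - a13^2) * f2 +
           (a12 * a13 - a11 * a23) * f3) / det
  v3 <- ((a12 * a23 - a13 * a22) * f1 + (a12 * a13 - a11 * a23) * f2 +
           (a11 * a22 - a12^2) * f3) / det
  vh <- list(v1, v2, v3)
  v <- array(0, c(d, 3))
  for (i in 1:3) {
    a <- vh[[i]]
    for (ax in 1:3) {
      M <- if (ax == i) B[[ax]]$Syn_s else B[[ax]]$Syn_c
      a <- axis_mult(a, ax, M)
    }
    v[, , , i] <- a
  }
  v
}

# Shift with reflection ghost (Neumann): the vacated face takes the value
# two grid rows in, consistent with a zero normal derivative at the face.
shift_mirror <- function(a, ax, by) {
  out <- shift_array(a, ax, by, 0)
  d <- dim(a)
  sel <- function(i) {
    s <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])); s[[ax]] <- i; s
  }
  face <- if (by > 0) 1L else d[ax]
  inner <- if (by > 0) 2L else d[ax] - 1L
  do.call(`[<-`, c(list(out), sel(face),
                   list(do.call(`[`, c(list(a), sel(inner))))))
}

# Shift with odd-reflection ghost (Dirichlet/sine): the vacated face takes
# minus the value two grid rows in (v_{-1} = -v_{1} about the zero face).
shift_odd <- function(a, ax, by) {
  out <- shift_array(a, ax, by, 0)
  d <- dim(a)
  sel <- function(i) {
    s <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])); s[[ax]] <- i; s
  }
  face <- if (by > 0) 1L else d[ax]
  inner <- if (by > 0) 2L else d[ax] - 1L
  do.call(`[<-`, c(list(out), sel(face),
                   list(-do.call(`[`, c(list(a), sel(inner))))))
}

# Apply the discrete Navier operator (free-slip boundaries) to v.
# Component i is sine-like (odd ghost) along its own axis and cosine-like
# (mirror ghost) along the others.
fluid_apply <- function(v, params, spacing) {
  mu <- params$mu; ml <- params$mu + params$lambda
  out <- array(0, dim(v))
  comp <- list(dirichlet_faces(v[, , , 1], 1),
               dirichlet_faces(v[, , , 2], 2),
               dirichlet_faces(v[, , , 3], 3))
  d2 <- function(a, ax, own) {
    sh <- if (own) shift_odd else shift_mirror
    (sh(a, ax, 1) + sh(a, ax, -1) - 2 * a) / spacing[ax]^2
  }
  d1 <- function(a, ax, own) {
    sh <- if (own) shift_odd else shift_mirror
    (sh(a, ax, -1) - sh(a, ax, 1)) / (2 * spacing[ax])
  }
  for (i in 1:3) {
    lap <- 0
    for (ax in 1:3) lap <- lap + d2(comp[[i]], ax, own = (ax == i))
    gd <- d2(comp[[i]], i, own = TRUE)          # d_i d_i v_i
    for (j in setdiff(1:3, i))                  # d_i d_j v_j
      gd <- gd + d1(d1(comp[[j]], j, own = TRUE), i, own = FALSE)
    out[, , , i] <- dirichlet_faces(mu * lap + ml * gd, i)
  }
  out
}

dirichlet_faces <- function(a, ax) {
  d <- dim(a)
  sel <- function(i) {
    s <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])); s[[ax]] <- i; s
  }
  a <- do.call(`[<-`, c(list(a), sel(1L), list(0)))
  do.call(`[<-`, c(list(a), sel(d[ax]), list(0)))
}

fluid_residual <- function(v, force, params, spacing) {
  lhs <- fluid_apply(v, params, spacing)
  r <- lhs + force
  # compare on the equations actually solved: interior of each component's
  # own axis (faces carry the Dirichlet condition instead)
  for (i in 1:3) r[, , , i] <- dirichlet_faces(r[, , , i], i)
  f <- force
  for (i in 1:3) f[, , , i] <- dirichlet_faces(f[, , , i], i)
  sqrt(sum(r^2) / max(sum(f^2), 1e-300))
}

# Red-black successive over-relaxation of the same finite-difference
# system (mixed-derivative couplings lagged at the latest values).
fluid_solve_sor <- function(force, params, spacing) {
  d <- dim(force)[1:3]
  mu <- params$mu; ml <- params$mu + params$lambda
  diag_i <- function(i) -2 * mu * sum(1 / spacing^2) - 2 * ml / spacing[i]^2
  idx <- index_grid(d)
  red <- array((colSums(idx) %% 2) == 0, d)
  v <- array(0, dim(force))
  om <- params$sor_omega
  for (it in seq_len(params$sor_max_iter)) {
    for (colour in list(red, !red)) {
      lhs <- fluid_apply(v, params, spacing)
      for (i in 1:3) {
        upd <- -(force[, , , i] + lhs[, , , i]) / diag_i(i)
        v[, , , i] <- dirichlet_faces(v[, , , i] + om * upd * colour, i)
      }
    }
    if (it %% 10 == 0 &&
        fluid_residual(v, force, params, spacing) < params$sor_tol)
      break
  }
  v
}
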