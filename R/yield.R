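# Singlet reaction yield under equal-rate spin-selective (Haberkorn)
# recombination, orientation scans over the sphere, and the anisotropy
# statistics derived from a yield map.
#
# Initial condition everywhere: singlet-born pair with fully mixed nuclear
# spins, rho_0 = P_S / Tr(P_S).  With equal singlet and triplet rate
# constants the kinetics reduce to a uniform exponential decay, and the
# yield has the closed spectral form
#   Phi_S = (1/M) sum_{mn} |<m|P_S|n>|^2 k^2 / (k^2 + (w_m - w_n)^2),
# M = Tr(P_S), evaluated in the eigenbasis of H.

check_hermitian <- function(H, tol = 1e-10) {
  res <- max(abs(H - Conj(t(H))))
  if (res > tol * max(1, max(abs(H))))
    stop("matrix is not Hermitian (residual ", format(res), ")",
         call. = FALSE)
  (H + Conj(t(H))) / 2
}

#' Singlet yield from the spectral formula
#'
#' Exact yield for a static Hamiltonian via eigendecomposition and the
#' Lorentzian double sum over eigenstate pairs.  Degenerate pairs take
#' weight 1 with no special casing.
#'
#' @param H Hermitian matrix in rad/us with the electrons as the first two
#'   tensor factors (dimension divisible by 4).
#' @param k Recombination rate constant, s^-1 (> 0).
#' @return Singlet yield in \[0, 1\].
#' @seealso [singlet_yield_timedomain()] for the independent
#'   propagation-based route.
#' @export
singlet_yield_spectral <- function(H, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("rate constant k must be a positive scalar", call. = FALSE)
  H <- check_hermitian(H)
  d <- nrow(H)
  if (d %% 4 != 0)
    stop("Hamiltonian dimension must be a multiple of 4 (two electrons)",
         call. = FALSE)
  e <- eigen(H, symmetric = TRUE)
  Q <- singlet_basis_factor(d)
  W <- Conj(t(Q)) %*% e$vectors          # (d/4) x d
  P <- Conj(t(W)) %*% W                  # P_S in the eigenbasis
  k_us <- rate_per_us(k)
  dw <- outer(e$values, e$values, "-")
  phi <- sum(Mod(P)^2 * k_us^2 / (k_us^2 + dw^2)) / (d / 4)
  min(max(Re(phi), 0), 1)
}

#' Triplet yield
#'
#' Complement of the singlet yield under equal-rate recombination,
#' \eqn{\Phi_T = 1 - \Phi_S}, computed independently from the triplet
#' projector so that \eqn{\Phi_S + \Phi_T = 1} is a genuine numerical check.
#'
#' @inheritParams singlet_yield_spectral
#' @return Triplet yield in \[0, 1\].
#' @export
triplet_yield_spectral <- function(H, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("rate constant k must be a positive scalar", call. = FALSE)
  H <- check_hermitian(H)
  d <- nrow(H)
  e <- eigen(H, symmetric = TRUE)
  V <- e$vectors
  # both projectors in the eigenbasis; P_T built explicitly (not as 1 - P_S)
  PT <- Conj(t(V)) %*% triplet_projector(c(2L, 2L, d %/% 4L)) %*% V
  W <- Conj(t(singlet_basis_factor(d))) %*% V
  PS <- Conj(t(W)) %*% W
  k_us <- rate_per_us(k)
  dw <- outer(e$values, e$values, "-")
  # Phi_T = (1/M) sum_{mn} Re[(P_T)_{mn} (P_S)_{nm}] k^2/(k^2 + dw^2)
  phi_t <- sum(Re(PT * t(PS)) * k_us^2 / (k_us^2 + dw^2)) / (d / 4)
  min(max(phi_t, 0), 1)
}

#' Singlet yield by direct time propagation
#'
#' Independent route: propagates \eqn{\rho(t) = U \rho U^\dagger} in fixed
#' steps and integrates \eqn{\Phi_S = k \int_0^\infty e^{-kt}
#' \mathrm{Tr}[P_S \rho(t)] dt} by composite Simpson quadrature, with an
#' analytic tail beyond the horizon.  Serves as the oracle against which the
#' spectral route is validated.
#'
#' @inheritParams singlet_yield_spectral
#' @param horizon Integration horizon in multiples of 1/k (default 20).
#' @param oversample Steps per period of the fastest eigenfrequency
#'   difference (controls quadrature error; default 64).
#' @param max_steps Hard cap on step count; exceeding it is an error rather
#'   than a silent accuracy loss.
#' @return Singlet yield in \[0, 1\].
#' @export
singlet_yield_timedomain <- function(H, k, horizon = 20, oversample = 64,
                                     max_steps = 4e6) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("rate constant k must be a positive scalar", call. = FALSE)
  H <- check_hermitian(H)
  d <- nrow(H)
  e <- eigen(H, symmetric = TRUE)
  span <- max(e$values) - min(e$values)       # largest eigen-gap, rad/us
  k_us <- rate_per_us(k)
  Tmax <- horizon / k_us                       # us
  h <- if (span > 0) 2 * pi / (span * oversample) else Tmax / 64
  nstep <- ceiling(Tmax / h)
  if (nstep %% 2 == 1) nstep <- nstep + 1      # Simpson needs even count
  if (nstep > max_steps)
    stop("time-domain integration needs ", nstep, " steps (> max_steps); ",
         "increase k or reduce the coupling span", call. = FALSE)
  h <- Tmax / nstep
  U <- e$vectors %*% (exp(-1i * e$values * h) * Conj(t(e$vectors)))
  Ud <- Conj(t(U))
  PS <- singlet_projector(c(2L, 2L, d %/% 4L))
  rho <- PS / (d / 4)
  s <- numeric(nstep + 1)
  s[1] <- Re(sum(PS * t(rho)))
  for (j in seq_len(nstep)) {
    rho <- U %*% rho %*% Ud
    s[j + 1] <- Re(sum(PS * t(rho)))
  }
  t_grid <- h * (0:nstep)
  f <- k_us * exp(-k_us * t_grid) * s
  wts <- rep(c(2, 4), length.out = nstep + 1)
  wts[1] <- wts[nstep + 1] <- 1
  integral <- h / 3 * sum(wts * f)
  tail <- exp(-k_us * Tmax) * s[nstep + 1]     # survival beyond the horizon
  min(max(integral + tail, 0), 1)
}

#' Spherical orientation grid
#'
#' Regular grid in colatitude and azimuth with exact per-cell solid-angle
#' weights (integral of \eqn{\sin\theta \, d\theta \, d\phi} over each
#' cell), summing to \eqn{4\pi}.  A Gauss-Legendre-in-cos(theta) grid is
#' available for high-accuracy spherical means.
#'
#' @param theta_step,phi_step Step sizes in degrees (regular grid).
#' @param type `"regular"` (default) or `"gauss"` (Gauss-Legendre nodes in
#'   cos(theta), uniform azimuth).
#' @param n_theta,n_phi Node counts for the Gauss grid.
#' @return data.frame with columns `theta`, `phi`, `weight` (steradian).
#' @export
orientation_grid <- function(theta_step = 2, phi_step = 2,
                             type = c("regular", "gauss"),
                             n_theta = 48, n_phi = 96) {
  type <- match.arg(type)
  if (type == "gauss") {
    gl <- gauss_legendre_nodes(n_theta)
    theta <- acos(gl$x) * 180 / pi
    phi <- seq(0, 360 - 360 / n_phi, by = 360 / n_phi)
    grid <- expand.grid(theta = theta, phi = phi)
    grid$weight <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
    return(grid[order(grid$theta, grid$phi), c("theta", "phi", "weight")])
  }
  stopifnot(theta_step > 0, phi_step > 0)
  theta <- seq(0, 180, by = theta_step)
  phi <- seq(0, 360 - phi_step, by = phi_step)
  lo <- pmax(theta - theta_step / 2, 0) * pi / 180
  hi <- pmin(theta + theta_step / 2, 180) * pi / 180
  wt_theta <- cos(lo) - cos(hi)
  grid <- expand.grid(theta = theta, phi = phi)
  grid$weight <- rep(wt_theta, times = length(phi)) *
    (phi_step * pi / 180)
  rownames(grid) <- NULL
  grid[order(grid$theta, grid$phi), c("theta", "phi", "weight")]
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre_nodes <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1)] <- b
  Jm[cbind(i + 1, i)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' Scan the singlet yield over field orientations
#'
#' Evaluates \eqn{\Phi_S(\theta, \phi)} at fixed field magnitude for every
#' grid direction.  Antipodal symmetry (\eqn{\Phi_S(\hat b) =
#' \Phi_S(-\hat b)}, a time-reversal property of the real-tensor model) is
#' exploited by default: only one hemisphere is diagonalized and the rest
#' is mirrored.
#'
#' @param pair [radical_pair()].
#' @param B_uT Field magnitude (uT).
#' @param grid Orientation grid from [orientation_grid()].
#' @param use_symmetry Mirror antipodal directions instead of recomputing.
#' @param engine `"cpp"` (compiled kernel) or `"r"` (reference R loop).
#' @return A `yield_map`: the grid data.frame with a `phi_s` column and
#'   metadata attributes.
#' @export
orientation_scan <- function(pair, B_uT = 49,
                             grid = orientation_grid(theta_step = 10,
                                                     phi_step = 10),
                             use_symmetry = TRUE,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (nrow(grid) == 0) stop("empty orientation grid", call. = FALSE)
  dirs <- sph_direction(grid$theta, grid$phi)
  key_dirs <- if (use_symmetry) canonical_direction(dirs) else dirs
  key <- apply(round(key_dirs, 10), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  u_dirs <- key_dirs[uniq, , drop = FALSE]
  parts <- hamiltonian_parts(pair)
  w <- mhz_to_angular(larmor_frequency(B_uT, g = pair$radical_a$g))
  k_us <- rate_per_us(pair$k)
  Q <- singlet_basis_factor(prod(parts$dims))
  phi_u <- if (engine == "cpp") {
    cpp_yield_scan(parts$H0, parts$Z$x, parts$Z$y, parts$Z$z, Q,
                   u_dirs, w, k_us)
  } else {
    vapply(seq_len(nrow(u_dirs)), function(i) {
      b <- u_dirs[i, ]
      H <- parts$H0 + w * (b[1] * parts$Z$x + b[2] * parts$Z$y +
                             b[3] * parts$Z$z)
      singlet_yield_spectral(H, pair$k)
    }, numeric(1))
  }
  grid$phi_s <- phi_u[match(key, key[uniq])]
  structure(grid, class = c("yield_map", "data.frame"),
            B_uT = B_uT, k = pair$k, hilbert_dim = prod(parts$dims))
}

# Antipodal canonical representative: flip to the upper hemisphere
# (bz > 0; ties broken on bx then by).
canonical_direction <- function(dirs) {
  flip <- dirs[, 3] < -1e-12 |
    (abs(dirs[, 3]) <= 1e-12 & (dirs[, 1] < -1e-12 |
       (abs(dirs[, 1]) <= 1e-12 & dirs[, 2] < 0)))
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  dirs
}

#' @export
print.yield_map <- function(x, ...) {
  cat(sprintf(
    "<yield map: %d orientations, B = %g uT, Phi_S in [%.6g, %.6g]>\n",
    nrow(x), attr(x, "B_uT"), min(x$phi_s), max(x$phi_s)))
  invisible(x)
}

#' Reaction-yield anisotropy
#'
#' \eqn{\Delta\Phi_S = \max \Phi_S - \min \Phi_S} over the sampled sphere,
#' the directional "compass signal", with the extremal directions recorded.
#'
#' @param map `yield_map` from [orientation_scan()].
#' @return Object of class `anisotropy_stats`: list with `delta_phi_s`,
#'   `mean_phi_s`, `argmax`, `argmin` (each a `c(theta, phi)` pair).
#' @export
delta_phi_s <- function(map) {
  stopifnot(nrow(map) > 0)
  i_max <- which.max(map$phi_s)
  i_min <- which.min(map$phi_s)
  ap <- anisotropic_part(map)
  structure(list(
    delta_phi_s = map$phi_s[i_max] - map$phi_s[i_min],
    mean_phi_s = ap$mean_phi_s,
    argmax = c(theta = map$theta[i_max], phi = map$phi[i_max]),
    argmin = c(theta = map$theta[i_min], phi = map$phi[i_min])
  ), class = "anisotropy_stats")
}

#' @export
print.anisotropy_stats <- function(x, ...) {
  cat(sprintf(
    "<anisotropy: delta Phi_S = %.6g, <Phi_S> = %.6g,\n  max at (%g, %g) deg, min at (%g, %g) deg>\n",
    x$delta_phi_s, x$mean_phi_s, x$argmax[1], x$argmax[2],
    x$argmin[1], x$argmin[2]))
  invisible(x)
}

#' Anisotropic part of a yield map
#'
#' Splits the map into its isotropic component (the solid-angle-weighted
#' spherical mean \eqn{\langle\Phi_S\rangle}) and the residual
#' \eqn{\bar\Phi_S(\theta,\phi) = \Phi_S(\theta,\phi) -
#' \langle\Phi_S\rangle}, which integrates to zero by construction.
#'
#' @param map `yield_map` with quadrature weights.
#' @return List with `mean_phi_s` and `residual` (the map with `phi_s`
#'   replaced by the residual).
#' @export
anisotropic_part <- function(map) {
  stopifnot(nrow(map) > 0, !is.null(map$weight))
  mean_phi <- sum(map$weight * map$phi_s) / sum(map$weight)
  res <- map
  res$phi_s <- map$phi_s - mean_phi
  list(mean_phi_s = mean_phi, residual = res)
}

#' Baseline-subtracted colatitude profile
#'
#' \eqn{\Phi_S(\theta, \phi) - \Phi_S(0, \phi)} along a meridian at fixed
#' azimuth, the standard way of plotting how the yield varies as the field
#' tips away from the molecular z-axis.
#'
#' @param pair [radical_pair()].
#' @param phi_deg Fixed azimuth (degrees).
#' @param theta_deg Colatitudes to evaluate (degrees).
#' @param B_uT Field magnitude.
#' @return data.frame with columns `theta`, `phi_s_rel`.
#' @export
theta_profile <- function(pair, phi_deg = 0,
                          theta_deg = seq(0, 180, by = 2), B_uT = 49) {
  parts <- hamiltonian_parts(pair)
  w <- mhz_to_angular(larmor_frequency(B_uT, g = pair$radical_a$g))
  Q <- singlet_basis_factor(prod(parts$dims))
  dirs <- sph_direction(theta_deg, rep(phi_deg, length(theta_deg)))
  phi_s <- cpp_yield_scan(parts$H0, parts$Z$x, parts$Z$y, parts$Z$z, Q,
                          dirs, w, rate_per_us(pair$k))
  data.frame(theta = theta_deg, phi_s_rel = phi_s - phi_s[1])
}
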