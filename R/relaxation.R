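# Two-site hopping stochastic Liouville model for libration-induced spin
# relaxation: the flavin radical jumps at rate k_m between two equally
# probable orientations rotated +/- delta about a molecular axis.
#
# The reaction yield is obtained from the time-integrated coupled Liouville
# equations: with L_j[rho] = -i[H_j, rho], site populations x_j solve
#   (L_j - (k + k_m)) X_j + k_m X_other = -x_j(0),
# and Phi_S = k * sum_j Tr[P_S X_j].  Column-stacking vectorization is used:
# vec(-i[H, rho]) = -i (I (x) H - H^T (x) I) vec(rho).

#' Two-site hopping model
#'
#' @param axis Rotation axis in the molecular frame (default flavin x).
#' @param half_angle_deg Libration half-angle delta in degrees (default 5).
#' @param k_m Hop rate constant, s^-1 (>= 0).
#' @return Object of class `hopping_model`.
#' @export
hopping_model <- function(axis = c(1, 0, 0), half_angle_deg = 5, k_m = 1e6) {
  axis <- as.numeric(axis)
  if (length(axis) != 3 || abs(sqrt(sum(axis^2)) - 1) > 1e-8)
    stop("hopping axis must be a unit 3-vector", call. = FALSE)
  stopifnot(half_angle_deg >= 0, k_m >= 0)
  structure(list(axis = axis, half_angle_deg = half_angle_deg, k_m = k_m),
            class = "hopping_model")
}

#' @export
print.hopping_model <- function(x, ...) {
  cat(sprintf("<two-site hop: +/-%g deg about (%g, %g, %g), k_m = %g s^-1>\n",
              x$half_angle_deg, x$axis[1], x$axis[2], x$axis[3], x$k_m))
  invisible(x)
}

# rotate all hyperfine tensors of one radical rigidly
rotate_radical_tensors <- function(radical, axis, angle_deg) {
  radical$nuclei <- lapply(radical$nuclei, function(n) {
    nucleus(n$site, n$isotope, rotate_tensor(n$tensor, axis, angle_deg))
  })
  radical
}

#' Site Hamiltonians of the hopping model
#'
#' Returns the two total Hamiltonians with the flavin (radical A) hyperfine
#' tensors rotated by +delta and -delta about the hopping axis.  Partner
#' tensors, J, D and the field are untouched.
#'
#' @param pair [radical_pair()]; radical A is the librating flavin.
#' @param field [field_spec()].
#' @param model [hopping_model()].
#' @return List with Hermitian matrices `H_plus`, `H_minus` (rad/us).
#' @export
site_hamiltonians <- function(pair, field, model) {
  stopifnot(inherits(model, "hopping_model"))
  mk <- function(sgn) {
    p <- pair
    p$radical_a <- rotate_radical_tensors(pair$radical_a, model$axis,
                                          sgn * model$half_angle_deg)
    total_hamiltonian(p, field)
  }
  list(H_plus = mk(+1), H_minus = mk(-1))
}

# vec of -i[H, .] - (k + km) as a dense Liouville-space matrix (column
# stacking), plus the scalar decay on the diagonal
liouville_block <- function(H, decay_per_us) {
  d <- nrow(H)
  Id <- diag(d)
  -1i * (kronecker(Id, H) - kronecker(t(H), Id)) -
    decay_per_us * diag(d * d)
}

#' Singlet yield of the two-site stochastic Liouville model
#'
#' Solves the coupled time-integrated Liouville equations for the two
#' libration sites (equal populations 1/2 each, singlet-born initial
#' condition) by one direct linear solve and returns
#' \eqn{\Phi_S = k \sum_j \mathrm{Tr}[P_S \bar\rho_j]}.
#'
#' @param pair [radical_pair()].
#' @param field [field_spec()].
#' @param model [hopping_model()].
#' @param dim_limit Refuse Hilbert dimensions above this (the Liouville
#'   system has dimension \eqn{2 d^2}).
#' @return List with `phi_s` and `total_time_integral` (the k-weighted
#'   time-integrated trace over both sites; equals 1 when every pair
#'   eventually reacts).
#' @export
two_site_yield <- function(pair, field, model, dim_limit = 48) {
  d <- hilbert_dimension(pair)
  if (d > dim_limit)
    stop("Hilbert dimension ", d, " exceeds dim_limit = ", dim_limit,
         " (Liouville dimension 2 d^2 = ", 2 * d^2, ")", call. = FALSE)
  H <- site_hamiltonians(pair, field, model)
  k_us <- rate_per_us(pair$k)
  km_us <- rate_per_us(model$k_m)
  N <- d * d
  L1 <- liouville_block(H$H_plus, k_us + km_us)
  L2 <- liouville_block(H$H_minus, k_us + km_us)
  A <- rbind(cbind(L1, km_us * diag(N) + 0i),
             cbind(km_us * diag(N) + 0i, L2))
  PS <- singlet_projector(c(2L, 2L, d %/% 4L))
  rho0 <- PS / (d / 4)
  x0 <- c(as.vector(rho0) / 2, as.vector(rho0) / 2)
  X <- solve(A, -x0)
  rho1 <- matrix(X[seq_len(N)], d, d)
  rho2 <- matrix(X[N + seq_len(N)], d, d)
  phi <- k_us * Re(sum(PS * t(rho1 + rho2)))
  total <- k_us * Re(sum(diag(rho1)) + sum(diag(rho2)))
  list(phi_s = min(max(phi, 0), 1), total_time_integral = total)
}

#' Anisotropy versus hop rate
#'
#' Computes \eqn{\Delta\Phi_S} with the two-site relaxation model for each
#' hop rate in `km_values`, scanning the field direction over `grid`.
#' Antipodal symmetry is exploited as in [orientation_scan()].
#'
#' @param pair [radical_pair()].
#' @param model [hopping_model()] (its `k_m` is overridden per scan point).
#' @param km_values Hop rates, s^-1 (typically log-spaced 1e4 .. 1e8).
#' @param grid Orientation grid (coarse by default: the two-site solve is
#'   far costlier per direction than the static engine).
#' @param B_uT Field magnitude.
#' @param dim_limit Passed to [two_site_yield()].
#' @return data.frame with columns `k_m`, `delta_phi_s`, `mean_phi_s`.
#' @export
km_scan <- function(pair, model, km_values = 10^seq(4, 8, by = 0.5),
                    grid = orientation_grid(theta_step = 30, phi_step = 30),
                    B_uT = 49, dim_limit = 48) {
  stopifnot(all(km_values >= 0))
  dirs <- sph_direction(grid$theta, grid$phi)
  key_dirs <- canonical_direction(dirs)
  key <- apply(round(key_dirs, 10), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  u_dirs <- key_dirs[uniq, , drop = FALSE]
  u_theta <- acos(pmin(pmax(u_dirs[, 3], -1), 1)) * 180 / pi
  u_phi <- (atan2(u_dirs[, 2], u_dirs[, 1]) * 180 / pi) %% 360
  out <- lapply(km_values, function(km) {
    m <- hopping_model(model$axis, model$half_angle_deg, km)
    phis <- vapply(seq_len(nrow(u_dirs)), function(i) {
      f <- field_spec(B_uT, u_theta[i], u_phi[i])
      two_site_yield(pair, f, m, dim_limit = dim_limit)$phi_s
    }, numeric(1))
    full <- phis[match(key, key[uniq])]
    mean_phi <- sum(grid$weight * full) / sum(grid$weight)
    data.frame(k_m = km, delta_phi_s = max(full) - min(full),
               mean_phi_s = mean_phi)
  })
  do.call(rbind, out)
}
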