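# Assembly of the coherent spin Hamiltonian.
#
# All terms are returned in angular-frequency units of rad/us; couplings are
# entered in MHz (factor 2*pi), the field in uT (via the Larmor frequency).

#' Electron Zeeman term
#'
#' \eqn{\omega (\hat S_1 + \hat S_2) \cdot \hat b} with
#' \eqn{\omega = 2\pi \nu_L}; both electrons share the same g-value, so this
#' term alone causes no singlet-triplet mixing.
#'
#' @param field [field_spec()].
#' @param dims Subsystem dimensions (electrons first).
#' @param g Electron g-value.
#' @return Hermitian matrix, rad/us.
#' @export
zeeman_term <- function(field, dims, g = physical_constants()$g_e) {
  stopifnot(inherits(field, "field_spec"))
  w <- mhz_to_angular(larmor_frequency(field$B_uT, g = g))
  e <- electron_operators(dims)
  b <- field$b
  w * (b[1] * (e$S1$x + e$S2$x) +
       b[2] * (e$S1$y + e$S2$y) +
       b[3] * (e$S1$z + e$S2$z))
}

#' Hyperfine coupling term
#'
#' \eqn{2\pi\, \hat S_e \cdot A \cdot \hat I_n} for one electron-nucleus
#' pair, with the tensor in MHz.
#'
#' @param tensor `hf_tensor` or symmetric 3x3 matrix (MHz).
#' @param iso Isotope of the nucleus (sets its spin operators); I = 0 is
#'   rejected.
#' @param electron_position Tensor-factor index of the electron (1 or 2).
#' @param nucleus_position Tensor-factor index of the nucleus.
#' @param dims Subsystem dimensions.
#' @return Hermitian matrix, rad/us.
#' @export
hyperfine_term <- function(tensor, iso, electron_position, nucleus_position,
                           dims) {
  iso <- isotope(iso)
  if (iso$spin == 0)
    stop("isotope ", iso$symbol, " has I = 0 and cannot carry a hyperfine ",
         "term", call. = FALSE)
  A <- unclass(as_hf_tensor(tensor))
  stopifnot(electron_position %in% c(1L, 2L),
            dims[nucleus_position] == iso$multiplicity)
  se <- spin_operators(1 / 2)
  sn <- spin_operators(iso$spin)
  d <- prod(dims)
  H <- matrix(0 + 0i, d, d)
  for (p in 1:3) {
    # B_p = sum_q A[p, q] I_q acts on the nuclear factor alone
    Bp <- A[p, 1] * sn$x + A[p, 2] * sn$y + A[p, 3] * sn$z
    H <- H + embed_two(se[[p]], electron_position, Bp, nucleus_position,
                       dims)
  }
  mhz_to_angular(1) * H
}

#' Exchange interaction term
#'
#' \eqn{H_J = -2\pi J (2 \hat S_1 \cdot \hat S_2 + 1/2)}.  With this
#' convention the singlet-triplet energy gap is \eqn{2J} (in angular units
#' \eqn{2\pi \cdot 2J}); a function of \eqn{S_1 \cdot S_2} only, so it
#' commutes with the singlet projector.
#'
#' @param J Exchange coupling, MHz.
#' @param dims Subsystem dimensions.
#' @return Hermitian matrix, rad/us.
#' @export
exchange_term <- function(J, dims) {
  -mhz_to_angular(J) * (2 * electron_dot_product(dims) +
                          diag(prod(dims)) / 2)
}

#' Electron-electron dipolar term
#'
#' \eqn{H_D = 2\pi (2D/3) [3 (\hat S_1 \cdot \hat n)(\hat S_2 \cdot \hat n)
#' - \hat S_1 \cdot \hat S_2]}; traceless for any axis.
#'
#' @param D Dipolar coupling, MHz.
#' @param axis Unit inter-radical axis in the molecular frame.
#' @param dims Subsystem dimensions.
#' @return Hermitian matrix, rad/us.
#' @export
dipolar_term <- function(D, axis, dims) {
  axis <- as.numeric(axis)
  if (length(axis) != 3 || abs(sqrt(sum(axis^2)) - 1) > 1e-8)
    stop("dipolar axis must be a unit 3-vector", call. = FALSE)
  s <- spin_operators(1 / 2)
  sn <- axis[1] * s$x + axis[2] * s$y + axis[3] * s$z  # S . n on one spin
  mhz_to_angular(2 * D / 3) *
    (3 * embed_two(sn, 1L, sn, 2L, dims) - electron_dot_product(dims))
}

# Field-independent part (hyperfine + exchange + dipolar) and the three
# embedded total-electron-spin components used to add the Zeeman term for
# any field direction: H(b) = H0 + omega * (b . Z).
hamiltonian_parts <- function(pair) {
  dims <- pair_dims(pair)
  d <- prod(dims)
  H0 <- exchange_term(pair$J, dims) +
    dipolar_term(pair$D, pair$dipolar_axis, dims)
  nuc_pos <- 2L
  for (rad in list(list(r = pair$radical_a, e = 1L),
                   list(r = pair$radical_b, e = 2L))) {
    for (n in rad$r$nuclei) {
      nuc_pos <- nuc_pos + 1L
      H0 <- H0 + hyperfine_term(n$tensor, n$isotope, rad$e, nuc_pos, dims)
    }
  }
  e <- electron_operators(dims)
  list(H0 = H0,
       Z = list(x = e$S1$x + e$S2$x,
                y = e$S1$y + e$S2$y,
                z = e$S1$z + e$S2$z),
       dims = dims)
}

#' Total coherent spin Hamiltonian
#'
#' Sum of the electron Zeeman terms, all hyperfine terms, exchange and
#' dipolar couplings, symmetrized as \eqn{(H + H^\dagger)/2} to guard
#' against rounding.
#'
#' @param pair [radical_pair()].
#' @param field [field_spec()].
#' @return Hermitian complex matrix, rad/us.
#' @export
total_hamiltonian <- function(pair, field) {
  parts <- hamiltonian_parts(pair)
  w <- mhz_to_angular(larmor_frequency(field$B_uT, g = pair$radical_a$g))
  b <- field$b
  H <- parts$H0 + w * (b[1] * parts$Z$x + b[2] * parts$Z$y +
                         b[3] * parts$Z$z)
  herm <- max(abs(H - Conj(t(H))))
  if (herm > 1e-12 * max(1, max(abs(H))))
    stop("assembled Hamiltonian is not Hermitian (residual ", format(herm),
         ")", call. = FALSE)
  (H + Conj(t(H))) / 2
}
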