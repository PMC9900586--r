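# Radical, radical-pair and field specifications.

#' Nucleus entry for a radical
#'
#' Binds a site label, an isotope and a hyperfine tensor.  Spinless isotopes
#' (12C) are rejected: they carry no hyperfine interaction and are
#' represented by absence from the nucleus list.
#'
#' @param site Unique site label within the radical.
#' @param iso Isotope symbol or `isotope_spec`.
#' @param tensor `hf_tensor` or symmetric 3x3 matrix (MHz).
#' @return List of class `rp_nucleus`.
#' @export
nucleus <- function(site, iso, tensor) {
  iso <- isotope(iso)
  if (iso$spin == 0)
    stop("isotope ", iso$symbol, " has I = 0 and cannot carry a hyperfine ",
         "interaction", call. = FALSE)
  structure(list(site = site, isotope = iso,
                 tensor = as_hf_tensor(tensor, site = site)),
            class = "rp_nucleus")
}

#' Radical specification
#'
#' An electron spin with an ordered list of hyperfine-coupled nuclei.  An
#' empty nucleus list is valid and describes the hypothetical partner
#' radical Z with no hyperfine interactions.
#'
#' @param nuclei List of [nucleus()] objects (possibly empty).
#' @param g Electron g-value (defaults to the free-electron value).
#' @param name Optional radical name (e.g. `"FAD"`, `"Trp"`, `"Z"`).
#' @return Object of class `radical_spec`.
#' @export
radical_spec <- function(nuclei = list(), g = physical_constants()$g_e,
                         name = NULL) {
  if (inherits(nuclei, "rp_nucleus")) nuclei <- list(nuclei)
  stopifnot(is.list(nuclei))
  labels <- vapply(nuclei, function(n) n$site, character(1))
  if (anyDuplicated(labels))
    stop("duplicate nucleus site labels: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  structure(list(nuclei = nuclei, g = g, name = name),
            class = "radical_spec")
}

#' @export
print.radical_spec <- function(x, ...) {
  cat(sprintf("<radical%s: %d nuclei%s>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$nuclei),
              if (length(x$nuclei))
                paste0(" (", paste(site_labels(x), collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Site labels of a radical
#' @param radical `radical_spec`.
#' @return Character vector of nucleus site labels.
#' @export
site_labels <- function(radical) {
  vapply(radical$nuclei, function(n) n$site, character(1))
}

nuclear_multiplicities <- function(radical) {
  vapply(radical$nuclei, function(n) n$isotope$multiplicity, integer(1))
}

#' Radical-pair specification
#'
#' Two radicals plus the inter-electron exchange (J) and dipolar (D)
#' couplings, the dipolar axis in the molecular frame, and the
#' spin-selective recombination rate constant k (equal for singlet and
#' triplet channels).
#'
#' @param radical_a Flavin-side [radical_spec()] (first nuclear block).
#' @param radical_b Partner [radical_spec()] (second nuclear block).
#' @param J Exchange coupling, MHz.
#' @param D Dipolar coupling, MHz.
#' @param dipolar_axis Unit 3-vector, molecular frame.
#' @param k Recombination rate constant, s^-1 (> 0).
#' @return Object of class `radical_pair`.
#' @export
radical_pair <- function(radical_a, radical_b = radical_spec(name = "Z"),
                         J = -0.65, D = -11.2,
                         dipolar_axis = c(0, 0, 1), k = 1e5) {
  stopifnot(inherits(radical_a, "radical_spec"),
            inherits(radical_b, "radical_spec"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("recombination rate k must be a positive scalar", call. = FALSE)
  dipolar_axis <- as.numeric(dipolar_axis)
  if (length(dipolar_axis) != 3 ||
      abs(sqrt(sum(dipolar_axis^2)) - 1) > 1e-8)
    stop("dipolar_axis must be a unit 3-vector", call. = FALSE)
  structure(list(radical_a = radical_a, radical_b = radical_b,
                 J = J, D = D, dipolar_axis = dipolar_axis, k = k),
            class = "radical_pair")
}

#' @export
print.radical_pair <- function(x, ...) {
  cat(sprintf(
    "<radical pair: dim %d; J = %g MHz, D = %g MHz, k = %g s^-1>\n",
    hilbert_dimension(x), x$J, x$D, x$k))
  cat("  A: "); print(x$radical_a)
  cat("  B: "); print(x$radical_b)
  invisible(x)
}

#' Subsystem dimensions of a radical pair
#'
#' Electron factors first (2, 2), then the nuclear multiplicities of
#' radical A, then those of radical B.
#'
#' @param pair `radical_pair`.
#' @return Integer vector of tensor-factor dimensions.
#' @export
pair_dims <- function(pair) {
  c(2L, 2L, nuclear_multiplicities(pair$radical_a),
    nuclear_multiplicities(pair$radical_b))
}

#' Hilbert-space dimension of a radical pair
#'
#' \eqn{4 \prod_i (2 I_i + 1)} over all nuclei of both radicals; the main
#' driver of simulation cost.
#'
#' @param pair `radical_pair`.
#' @return Integer dimension.
#' @export
hilbert_dimension <- function(pair) {
  as.integer(prod(pair_dims(pair)))
}

#' Magnetic field specification
#'
#' Field magnitude and direction in spherical polar angles relative to the
#' molecular frame: \eqn{\mathbf{B} = |B| (\sin\theta\cos\phi,
#' \sin\theta\sin\phi, \cos\theta)}.
#'
#' @param B_uT Magnitude in uT (>= 0); default 49 uT, Earth-strength.
#' @param theta_deg Colatitude in degrees.
#' @param phi_deg Azimuth in degrees.
#' @return Object of class `field_spec` with the unit direction in `$b`.
#' @export
field_spec <- function(B_uT = 49, theta_deg = 0, phi_deg = 0) {
  stopifnot(is.numeric(B_uT), length(B_uT) == 1L, B_uT >= 0)
  b <- drop(sph_direction(theta_deg, phi_deg))
  structure(list(B_uT = B_uT, theta_deg = theta_deg, phi_deg = phi_deg,
                 b = b), class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field: %g uT, theta = %g deg, phi = %g deg>\n",
              x$B_uT, x$theta_deg, x$phi_deg))
  invisible(x)
}
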