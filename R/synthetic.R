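# Synthetic flavin-like inputs: physically structured stand-in hyperfine
# tensors, canned analytic reference systems, and the tensor-table file
# format.  Synthetic tensors target the qualitative structure of the real
# radical (two strongly axial nitrogens, several near-isotropic protons,
# carbons split between axial and in-plane classes), not its DFT values.

#' Axial hyperfine tensor constructor
#'
#' Tensor with principal values \eqn{(a_{iso}-T, a_{iso}-T, a_{iso}+2T)}
#' and unique principal axis `axis`:
#' \eqn{A = (a_{iso}-T) 1 + 3T \hat n \hat n^T}.
#'
#' @param a_iso Isotropic part, MHz.
#' @param T_aniso Axiality parameter T, MHz (negative gives an "in-plane"
#'   tensor with the two large components perpendicular to `axis`).
#' @param axis Unit principal axis.
#' @param site Optional site label.
#' @return `hf_tensor`.
#' @export
axial_tensor <- function(a_iso, T_aniso, axis = c(0, 0, 1), site = NULL) {
  axis <- as.numeric(axis)
  if (length(axis) != 3 || abs(sqrt(sum(axis^2)) - 1) > 1e-8)
    stop("axis must be a unit 3-vector", call. = FALSE)
  A <- (a_iso - T_aniso) * diag(3) + 3 * T_aniso * tcrossprod(axis)
  hyperfine_tensor(A, site = site)
}

# run expr with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

rand_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# small random rotation of a tensor: angle <= jitter_deg about a random axis
jitter_tensor <- function(A, jitter_deg) {
  if (jitter_deg <= 0) return(A)
  rotate_tensor(A, rand_unit_vector(), stats::runif(1, 0, jitter_deg))
}

# nitrogen-like: strongly axial along ~z; |A_zz| 3-10x the perpendicular part
synth_nitrogen_tensor <- function(site, jitter_deg = 10) {
  a <- stats::runif(1, 3, 15)
  f <- stats::runif(1, 3, 10)
  T_aniso <- a * (f - 1) / (f + 2)     # makes A_zz = f * A_perp
  jitter_tensor(axial_tensor(a, T_aniso, c(0, 0, 1), site = site),
                jitter_deg)
}

# proton-like: small and near-isotropic (anisotropy <= 20% of |a|+1)
synth_proton_tensor <- function(site) {
  a <- stats::runif(1, 0, 15) * sample(c(-1, 1), 1)
  T_aniso <- stats::runif(1, 0, 0.1 * (abs(a) + 1))
  axial_tensor(a, T_aniso, rand_unit_vector(), site = site)
}

# carbon classes: "axial" (large |A_zz|, N5-like symmetry) vs "in-plane"
# (large |A_xx + A_yy|/2, small |A_zz|)
synth_carbon_tensor <- function(site, class, jitter_deg = 10) {
  s <- sample(c(-1, 1), 1)
  A <- if (class == "axial-z-large") {
    p <- stats::runif(1, 1, 5)
    zz <- stats::runif(1, 15, 40)
    diag(c(p, p, zz)) * s
  } else {
    xx <- stats::runif(1, 10, 30)
    yy <- stats::runif(1, 10, 30)
    zz <- stats::runif(1, 0, 5)
    diag(c(xx, yy, zz)) * s
  }
  jitter_tensor(hyperfine_tensor(A, site = site), jitter_deg)
}

#' Carbon class assignment of the synthetic catalogue
#'
#' Which synthetic carbons are generated "axial" (large \eqn{|A_{zz}|})
#' versus "in-plane" (large \eqn{|A_{xx}+A_{yy}|/2}).
#'
#' @return Named character vector over [carbon_sites()].
#' @export
synthetic_carbon_classes <- function() {
  cls <- c(C2 = "in-plane-large", C4 = "in-plane-large",
           C4a = "in-plane-large", C5a = "axial-z-large",
           C6 = "axial-z-large", C7 = "in-plane-large",
           C8 = "axial-z-large", C9 = "axial-z-large",
           C9a = "axial-z-large", C10a = "in-plane-large",
           C7alpha = "in-plane-large", C8alpha = "in-plane-large")
  cls[carbon_sites()]
}

#' Synthetic flavin-like radical
#'
#' Deterministic-per-seed stand-in for the flavin radical anion: two
#' strongly axial nitrogen tensors (N5, N10; I = 1), five small near-
#' isotropic proton tensors (H6, 3 x H8alpha, H1prime; I = 1/2), plus a
#' 12-entry 13C tensor catalogue split between the axial and in-plane
#' classes.  The catalogue is attached as attribute `"carbon_table"`
#' (a tensor table data.frame) and retrievable with [carbon_catalogue()].
#'
#' @param seed Integer seed; the same seed gives bit-identical tensors.
#' @param n_protons Number of proton sites to keep (4 or 5).
#' @return `radical_spec` named `"FAD"` with the carbon catalogue attached.
#' @export
flavin_like_radical <- function(seed, n_protons = 5) {
  stopifnot(n_protons %in% c(4L, 5L))
  with_local_seed(seed, {
    nuc <- list(
      nucleus("N5", "14N", synth_nitrogen_tensor("N5")),
      nucleus("N10", "14N", synth_nitrogen_tensor("N10"))
    )
    protons <- .working_hydrogens[seq_len(n_protons)]
    for (s in protons)
      nuc <- c(nuc, list(nucleus(s, "1H", synth_proton_tensor(s))))
    cls <- synthetic_carbon_classes()
    rows <- lapply(carbon_sites(), function(s) {
      A <- unclass(synth_carbon_tensor(s, cls[[s]]))
      data.frame(radical = "FAD", site = s, isotope = "13C",
                 Axx = A[1, 1], Axy = A[1, 2], Axz = A[1, 3],
                 Ayy = A[2, 2], Ayz = A[2, 3], Azz = A[3, 3],
                 frame = "flavin", provenance = "synthetic",
                 stringsAsFactors = FALSE)
    })
    rad <- radical_spec(nuc, name = "FAD")
    attr(rad, "carbon_table") <- do.call(rbind, rows)
    rad
  })
}

#' Carbon tensor catalogue of a synthetic radical
#'
#' @param radical Radical built by [flavin_like_radical()].
#' @return Tensor-table data.frame with twelve 13C rows.
#' @export
carbon_catalogue <- function(radical) {
  tbl <- attr(radical, "carbon_table")
  if (is.null(tbl))
    stop("radical carries no carbon catalogue", call. = FALSE)
  tbl
}

#' Synthetic flavin-like radical pair
#'
#' Couples a [flavin_like_radical()] to either the hyperfine-free partner Z
#' or a tryptophan-like partner with one strongly anisotropic indole
#' nitrogen.  Couplings default to the model values J = -0.65 MHz,
#' D = -11.2 MHz, k = 1e5 s^-1.  The dipolar axis defaults to a fixed
#' oblique synthetic stand-in for the structure-derived inter-radical axis.
#'
#' @param seed Integer seed.
#' @param partner `"Z"` or `"Trp"`.
#' @param n_protons Passed to [flavin_like_radical()].
#' @param J,D,k,dipolar_axis Pair parameters; see [radical_pair()].
#' @return `radical_pair` (carbon catalogue available on `$radical_a`).
#' @export
flavin_like_pair <- function(seed, partner = c("Z", "Trp"), n_protons = 5,
                             J = -0.65, D = -11.2, k = 1e5,
                             dipolar_axis = c(1, 1, 2) / sqrt(6)) {
  partner <- match.arg(partner)
  rad_a <- flavin_like_radical(seed, n_protons = n_protons)
  rad_b <- if (partner == "Z") radical_spec(name = "Z")
  else with_local_seed(seed + 1L, radical_spec(list(
    nucleus("N1", "14N", synth_nitrogen_tensor("N1"))), name = "Trp"))
  radical_pair(rad_a, rad_b, J = J, D = D, dipolar_axis = dipolar_axis,
               k = k)
}

#' Canned analytic reference systems
#'
#' Small fully specified systems with machine-checkable expected behaviour,
#' used throughout the test suite:
#' \describe{
#'   \item{no-coupling}{bare electron pair, no field, J = D = 0: yield 1.}
#'   \item{zeeman-only}{bare pair at 49 uT: Zeeman term commutes with the
#'     singlet projector, yield 1.}
#'   \item{one-proton-isotropic}{one 1H with a = 1 MHz isotropic: isotropic
#'     map.}
#'   \item{one-nitrogen-axial}{one 14N axial along z: phi-independent map.}
#'   \item{two-site-trivial}{one proton plus a zero-angle hopping model:
#'     two-site yield equals the static yield.}
#' }
#'
#' @param name Reference system name.
#' @return List with `pair`, `field`, optional `model`, and `expect` (a
#'   descriptor of the expected property).
#' @export
reference_system <- function(name) {
  iso_h <- nucleus("H1", "1H", diag(3) * 1)
  ax_n <- nucleus("N5", "14N", axial_tensor(2, 8 / 3, c(0, 0, 1)))
  sys <- switch(
    name,
    "no-coupling" = list(
      pair = radical_pair(radical_spec(name = "FAD"), J = 0, D = 0),
      field = field_spec(0, 0, 0),
      expect = list(phi_s = 1)),
    "zeeman-only" = list(
      pair = radical_pair(radical_spec(name = "FAD"), J = 0, D = 0),
      field = field_spec(49, 37, 122),
      expect = list(phi_s = 1, delta_phi_s = 0)),
    "one-proton-isotropic" = list(
      pair = radical_pair(radical_spec(list(iso_h), name = "FAD"),
                          J = 0, D = 0),
      field = field_spec(49, 0, 0),
      expect = list(isotropic_map = TRUE)),
    "one-nitrogen-axial" = list(
      pair = radical_pair(radical_spec(list(ax_n), name = "FAD"),
                          J = 0, D = 0),
      field = field_spec(49, 45, 0),
      expect = list(phi_independent = TRUE)),
    "two-site-trivial" = list(
      pair = radical_pair(radical_spec(list(iso_h), name = "FAD"),
                          J = 0, D = 0),
      field = field_spec(49, 60, 30),
      model = hopping_model(c(1, 0, 0), half_angle_deg = 0, k_m = 1e6),
      expect = list(equals_static = TRUE)),
    stop("unknown reference system: ", name, call. = FALSE)
  )
  sys
}

# ---- tensor-table file format ----------------------------------------------

.tensor_table_columns <- c("radical", "site", "isotope",
                           "Axx", "Axy", "Axz", "Ayy", "Ayz", "Azz",
                           "frame", "provenance")

#' Read a hyperfine tensor table
#'
#' Tab-separated table with one row per nucleus: `radical`, `site`,
#' `isotope`, the six independent tensor components in MHz (`Axx` ...
#' `Azz`), a `frame` tag and a `provenance` tag (`"synthetic"`,
#' `"synthetic-placeholder"` or `"SI-transcribed"` for values transcribed
#' from quantum-chemistry supporting data).
#'
#' @param path File path.
#' @return data.frame with the canonical columns.
#' @export
read_tensor_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.tensor_table_columns, names(tbl))
  if (length(missing_cols))
    stop("tensor table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tbl[, .tensor_table_columns]
}

#' Write a hyperfine tensor table
#'
#' @param tbl data.frame with the canonical tensor-table columns.
#' @param path Destination path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_tensor_table <- function(tbl, path) {
  missing_cols <- setdiff(.tensor_table_columns, names(tbl))
  if (length(missing_cols))
    stop("tensor table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.table(tbl[, .tensor_table_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the canonical tensor-table skeleton
#'
#' Full site roster of the flavin radical (11 hydrogens, 4 nitrogens, 12
#' carbons) plus the tryptophan indole nitrogen, with zero placeholder
#' tensors flagged `"synthetic-placeholder"`, ready for transcription of
#' externally computed values.
#'
#' @param path Destination path.
#' @return The skeleton data.frame, invisibly.
#' @export
fixture_table <- function(path) {
  hydrogens <- c("H3", "H6", "H7alpha1", "H7alpha2", "H7alpha3",
                 "H8alpha1", "H8alpha2", "H8alpha3", "H9",
                 "H1prime1", "H1prime2")
  nitrogens <- c("N1", "N3", "N5", "N10")
  sites <- data.frame(
    radical = c(rep("FAD", 11 + 4 + 12), "Trp"),
    site = c(hydrogens, nitrogens, carbon_sites(), "N1"),
    isotope = c(rep("1H", 11), rep("14N", 4), rep("13C", 12), "14N"),
    stringsAsFactors = FALSE)
  sites[, c("Axx", "Axy", "Axz", "Ayy", "Ayz", "Azz")] <- 0
  sites$frame <- "flavin"
  sites$provenance <- "synthetic-placeholder"
  write_tensor_table(sites, path)
  invisible(sites)
}
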