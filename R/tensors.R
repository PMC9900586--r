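# Hyperfine tensors: construction, principal-component analysis, rotation
# and the quadratic-form surfaces used to visualize anisotropy.

#' Hyperfine coupling tensor
#'
#' A 3x3 real symmetric coupling matrix in MHz, expressed in the flavin
#' molecular frame (the frame is treated as opaque but must be shared by all
#' tensors, the dipolar axis and the field direction).
#'
#' @param A 3x3 numeric matrix, symmetric to within `tol` (relative);
#'   symmetrized exactly on construction.
#' @param site Atom site label (IUPAC-style, e.g. `"N5"`, `"H8alpha1"`).
#' @param tol Relative asymmetry tolerance.
#' @return Object of class `hf_tensor`: the symmetrized matrix with a
#'   `site` attribute.
#' @export
hyperfine_tensor <- function(A, site = NULL, tol = 1e-8) {
  A <- as.matrix(A)
  if (!is.numeric(A) || any(dim(A) != c(3, 3)))
    stop("hyperfine tensor must be a real 3x3 matrix", call. = FALSE)
  asym <- max(abs(A - t(A)))
  if (asym > tol * max(1, max(abs(A))))
    stop("hyperfine tensor is not symmetric (max asymmetry ",
         format(asym), " MHz)", call. = FALSE)
  A <- (A + t(A)) / 2
  structure(A, class = "hf_tensor", site = site)
}

as_hf_tensor <- function(A, site = NULL) {
  if (inherits(A, "hf_tensor")) A else hyperfine_tensor(A, site = site)
}

#' @export
print.hf_tensor <- function(x, ...) {
  site <- attr(x, "site")
  cat(sprintf("<hyperfine tensor%s, MHz>\n",
              if (is.null(site)) "" else paste0(" at ", site)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Principal components labelled by molecular axis
#'
#' Eigenvalues of the tensor assigned to the x/y/z labels by maximal overlap
#' of each eigenvector with the corresponding molecular axis (greedy, in
#' descending |cosine|).  For a diagonal tensor this returns the diagonal in
#' place; for a rotated tensor the labels follow the dominant axis of each
#' principal direction.
#'
#' @param A `hf_tensor` or symmetric 3x3 matrix.
#' @return Named numeric vector `c(xx=, yy=, zz=)` in MHz.
#' @export
principal_components <- function(A) {
  A <- as_hf_tensor(A)
  e <- eigen(unclass(A), symmetric = TRUE)
  ov <- abs(e$vectors)                  # |cos| overlap: rows axes, cols eigvecs
  lab <- integer(3)                     # lab[axis] <- eigen index
  taken_axis <- taken_vec <- logical(3)
  for (step in 1:3) {
    ov_masked <- ov
    ov_masked[taken_axis, ] <- -1
    ov_masked[, taken_vec] <- -1
    ij <- arrayInd(which.max(ov_masked), dim(ov))
    lab[ij[1]] <- ij[2]
    taken_axis[ij[1]] <- TRUE
    taken_vec[ij[2]] <- TRUE
  }
  stats::setNames(e$values[lab], c("xx", "yy", "zz"))
}

#' Axiality summary of a hyperfine tensor
#'
#' Returns the isotropic part and the two magnitudes that separate
#' "axial" tensors (large \eqn{|A_{zz}|}, N5/N10-like) from "in-plane"
#' tensors (large \eqn{|A_{xx}+A_{yy}|/2}, C4/C4a/C8alpha-like), the
#' classification that predicts which carbon substitutions most attenuate
#' the yield anisotropy.
#'
#' @param A `hf_tensor` or symmetric 3x3 matrix.
#' @return Named vector `c(a_iso=, abs_Azz=, abs_Axy_mean=)` in MHz.
#' @export
axiality_summary <- function(A) {
  A <- as_hf_tensor(A)
  pc <- principal_components(A)
  c(a_iso = sum(diag(unclass(A))) / 3,
    abs_Azz = abs(pc[["zz"]]),
    abs_Axy_mean = abs(pc[["xx"]] + pc[["yy"]]) / 2)
}

#' Right-handed rotation matrix
#'
#' Rodrigues rotation by `angle_deg` degrees about a unit `axis`.
#'
#' @param axis Length-3 unit vector.
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 orthogonal matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  if (length(axis) != 3 || abs(sqrt(sum(axis^2)) - 1) > 1e-8)
    stop("rotation axis must be a unit 3-vector", call. = FALSE)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotate a hyperfine tensor
#'
#' \eqn{A' = R A R^T} with R the right-handed rotation about `axis` by
#' `angle_deg`; eigenvalues are preserved.
#'
#' @param A `hf_tensor` or symmetric 3x3 matrix.
#' @inheritParams rotation_matrix
#' @return Rotated `hf_tensor` (site label preserved).
#' @export
rotate_tensor <- function(A, axis, angle_deg) {
  A <- as_hf_tensor(A)
  R <- rotation_matrix(axis, angle_deg)
  hyperfine_tensor(R %*% unclass(A) %*% t(R), site = attr(A, "site"),
                   tol = 1e-6)
}

#' Quadratic-form tensor surface
#'
#' Signed radial distance \eqn{r(\mathbf{b}) = \mathbf{b}^T A \mathbf{b}}
#' for unit directions, the quantity used to render hyperfine tensors as
#' three-dimensional surfaces around each nucleus.
#'
#' @param A `hf_tensor` or symmetric 3x3 matrix.
#' @param directions n x 3 matrix of unit vectors (rows).
#' @return data.frame with columns `r` (signed value) and `sign`.
#' @export
tensor_surface <- function(A, directions) {
  A <- unclass(as_hf_tensor(A))
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("direction vectors must have unit norm", call. = FALSE)
  r <- rowSums((directions %*% A) * directions)
  data.frame(r = r, sign = sign(r))
}

# direction unit vector from spherical angles in degrees
sph_direction <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}
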