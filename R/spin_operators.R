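# Angular-momentum operator algebra on the tensor-product Hilbert space.
#
# Subsystem ordering convention (fixed throughout the package): the two
# electrons occupy the first two tensor factors, followed by the nuclei of
# radical A (the flavin) in list order, then the nuclei of radical B.

#' Spin operator matrices
#'
#' Standard angular-momentum matrices \eqn{S_x, S_y, S_z} in the
#' \eqn{|I, m\rangle} basis (m descending), satisfying
#' \eqn{[S_x, S_y] = i S_z} and \eqn{S^2 = I(I+1) 1}.
#'
#' @param I Spin quantum number; a positive half-integer (1/2, 1, ...).
#'   I = 0 is rejected: a spinless nucleus carries no operators.
#' @return List with complex matrices `x`, `y`, `z` of dimension 2I+1.
#' @examples
#' spin_operators(1/2)$z   # diag(1/2, -1/2)
#' @export
spin_operators <- function(I) {
  if (!is.numeric(I) || length(I) != 1L || I <= 0 ||
      abs(2 * I - round(2 * I)) > 1e-12)
    stop("invalid spin quantum number: I must be a positive half-integer",
         call. = FALSE)
  n <- as.integer(round(2 * I + 1))
  m <- I - seq_len(n) + 1          # I, I-1, ..., -I
  Sz <- diag(m) + 0i
  # raising operator: <m+1|S+|m> = sqrt(I(I+1) - m(m+1))
  Sp <- matrix(0 + 0i, n, n)
  for (j in seq_len(n - 1))
    Sp[j, j + 1] <- sqrt(I * (I + 1) - m[j + 1] * (m[j + 1] + 1))
  Sm <- Conj(t(Sp))
  list(x = (Sp + Sm) / 2, y = (Sp - Sm) / (2i), z = Sz)
}

#' Embed an operator into the full tensor-product space
#'
#' Places `op` at tensor factor `position` of a space with subsystem
#' dimensions `dims`, with identities on every other factor.
#'
#' @param op Square matrix of dimension `dims[position]`.
#' @param position 1-based factor index.
#' @param dims Integer vector of subsystem dimensions.
#' @return Complex matrix of dimension `prod(dims)`.
#' @export
embed_operator <- function(op, position, dims) {
  op <- as.matrix(op)
  if (position < 1 || position > length(dims))
    stop("position out of range", call. = FALSE)
  if (nrow(op) != ncol(op) || nrow(op) != dims[position])
    stop("operator dimension ", nrow(op), " does not match subsystem ",
         "dimension ", dims[position], call. = FALSE)
  d_pre  <- prod(dims[seq_len(position - 1)])
  d_post <- prod(dims[seq_along(dims) > position])
  out <- op
  if (d_pre > 1)  out <- kronecker(diag(d_pre), out)
  if (d_post > 1) out <- kronecker(out, diag(d_post))
  out + 0i
}

# Embedded electron spin component matrices for electron 1 and 2.
electron_operators <- function(dims) {
  s <- spin_operators(1 / 2)
  list(
    S1 = lapply(s, embed_operator, position = 1L, dims = dims),
    S2 = lapply(s, embed_operator, position = 2L, dims = dims)
  )
}

# Product of two operators acting on disjoint tensor factors, built as a
# single Kronecker chain (O(d^2), avoids full-dimension matrix products).
embed_two <- function(opA, posA, opB, posB, dims) {
  stopifnot(posA != posB,
            nrow(opA) == dims[posA], nrow(opB) == dims[posB])
  facs <- lapply(seq_along(dims), function(i) {
    if (i == posA) opA else if (i == posB) opB else diag(dims[i])
  })
  Reduce(kronecker, facs) + 0i
}

# S1 . S2 on the full space
electron_dot_product <- function(dims) {
  s <- spin_operators(1 / 2)
  embed_two(s$x, 1L, s$x, 2L, dims) +
    embed_two(s$y, 1L, s$y, 2L, dims) +
    embed_two(s$z, 1L, s$z, 2L, dims)
}

#' Singlet projection operator
#'
#' \eqn{P_S = (1/4) 1 - S_1 \cdot S_2}, embedded with identities on all
#' nuclear factors.  Idempotent with trace equal to one quarter of the total
#' Hilbert-space dimension.
#'
#' @param dims Subsystem dimensions; the first two must be 2 (the electrons).
#' @return Complex projection matrix.
#' @export
singlet_projector <- function(dims) {
  stopifnot(length(dims) >= 2, dims[1] == 2, dims[2] == 2)
  diag(prod(dims)) / 4 - electron_dot_product(dims)
}

#' Triplet projection operator
#'
#' Complement of the singlet projector, \eqn{P_T = 1 - P_S}.
#'
#' @inheritParams singlet_projector
#' @return Complex projection matrix.
#' @export
triplet_projector <- function(dims) {
  diag(prod(dims)) - singlet_projector(dims)
}

# Rank factor Q of the singlet projector: P_S = Q %*% Conj(t(Q)) with Q of
# size d x (d/4).  Columns are |S> tensor nuclear basis states, where
# |S> = (|ab> - |ba>)/sqrt(2) in the kron ordering (aa, ab, ba, bb).
singlet_basis_factor <- function(d) {
  stopifnot(d %% 4 == 0)
  dn <- d %/% 4
  Q <- matrix(0 + 0i, d, dn)
  idx <- seq_len(dn)
  Q[cbind(1L * dn + idx, idx)] <-  1 / sqrt(2)   # |alpha beta>
  Q[cbind(2L * dn + idx, idx)] <- -1 / sqrt(2)   # |beta alpha>
  Q
}
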