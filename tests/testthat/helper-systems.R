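# Shared fixtures: small radical pairs built in code.

# random symmetric 3x3 tensor with entries of scale `scale` MHz
random_symmetric_tensor <- function(scale = 5) {
  A <- matrix(stats::rnorm(9, sd = scale), 3, 3)
  (A + t(A)) / 2
}

# pair with n_protons spin-1/2 nuclei (random small tensors) on radical A
random_proton_pair <- function(n_protons, seed, J = -0.65, D = -11.2,
                               k = 1e5, scale = 2) {
  set.seed(seed)
  nuc <- lapply(seq_len(n_protons), function(i)
    nucleus(paste0("H", i), "1H", random_symmetric_tensor(scale)))
  radical_pair(radical_spec(nuc, name = "FAD"), radical_spec(name = "Z"),
               J = J, D = D, dipolar_axis = rand_unit(seed + 1), k = k)
}

rand_unit <- function(seed) {
  set.seed(seed)
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# one-nitrogen-one-proton pair, dim 24
small_mixed_pair <- function(seed = 7, k = 1e5) {
  set.seed(seed)
  nuc <- list(nucleus("N5", "14N", axial_tensor(4, 3, c(0, 0, 1))),
              nucleus("H6", "1H", random_symmetric_tensor(1.5)))
  radical_pair(radical_spec(nuc, name = "FAD"), radical_spec(name = "Z"),
               J = -0.65, D = -11.2, dipolar_axis = c(1, 1, 2) / sqrt(6),
               k = k)
}

expect_hermitian <- function(H, tol = 1e-10) {
  expect_lt(max(abs(H - Conj(t(H)))), tol * max(1, max(abs(H))))
}
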