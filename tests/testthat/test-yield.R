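test_that("zero Hamiltonian and Zeeman-only systems give unit singlet yield", {
  rs <- reference_system("no-coupling")
  H <- total_hamiltonian(rs$pair, rs$field)
  expect_equal(singlet_yield_spectral(H, 1e5), 1)
  expect_equal(singlet_yield_timedomain(H, 1e5), 1, tolerance = 1e-9)

  rz <- reference_system("zeeman-only")
  Hz <- total_hamiltonian(rz$pair, rz$field)
  expect_equal(singlet_yield_spectral(Hz, 1e5), 1, tolerance = 1e-12)
})

test_that("spectral and time-domain yields agree on a seeded battery", {
  # system size paired with a recombination rate that keeps the
  # time-domain oracle resolvable
  battery <- list(list(n = 1, seed = 101, k = 1e5),
                  list(n = 2, seed = 102, k = 1e6),
                  list(n = 3, seed = 103, k = 1e7))
  for (cs in battery) {
    pair <- random_proton_pair(cs$n, cs$seed, k = cs$k)
    H <- total_hamiltonian(pair, field_spec(49, 40, 110))
    phi_sp <- singlet_yield_spectral(H, cs$k)
    phi_td <- singlet_yield_timedomain(H, cs$k)
    expect_lt(abs(phi_sp - phi_td), 1e-6)
  }
})

test_that("singlet and triplet yields sum to one", {
  for (seed in c(31, 32)) {
    pair <- random_proton_pair(2, seed)
    H <- total_hamiltonian(pair, field_spec(49, 70, 20))
    phi_s <- singlet_yield_spectral(H, pair$k)
    phi_t <- triplet_yield_spectral(H, pair$k)
    expect_lt(abs(phi_s + phi_t - 1), 1e-10)
  }
})

test_that("yield inputs are validated", {
  H <- total_hamiltonian(small_mixed_pair(), field_spec(49, 0, 0))
  expect_error(singlet_yield_spectral(H, -1), "positive")
  expect_error(singlet_yield_spectral(H, 0), "positive")
  Hbad <- H; Hbad[1, 2] <- Hbad[1, 2] + 1
  expect_error(singlet_yield_spectral(Hbad, 1e5), "not Hermitian")
})

test_that("yield increases to one as recombination outruns mixing", {
  pair <- small_mixed_pair(seed = 40)
  H <- total_hamiltonian(pair, field_spec(49, 50, 50))
  ks <- 10^seq(9, 12, by = 1)
  phis <- vapply(ks, function(k) singlet_yield_spectral(H, k), numeric(1))
  expect_true(all(diff(phis) > -1e-12))
  expect_equal(phis[length(phis)], 1, tolerance = 1e-4)
})

test_that("orientation grid weights integrate the sphere exactly", {
  for (g in list(orientation_grid(10, 10), orientation_grid(7.5, 15),
                 orientation_grid(type = "gauss", n_theta = 12,
                                  n_phi = 24))) {
    expect_equal(sum(g$weight), 4 * pi, tolerance = 1e-12)
  }
  # spherical mean of cos^2(theta) is 1/3 (quadrature sanity)
  g <- orientation_grid(type = "gauss", n_theta = 16, n_phi = 8)
  expect_equal(sum(g$weight * cos(g$theta * pi / 180)^2) / (4 * pi), 1 / 3,
               tolerance = 1e-12)
})

test_that("isotropic systems give a constant map and zero anisotropy", {
  rs <- reference_system("one-proton-isotropic")
  m <- orientation_scan(rs$pair, grid = orientation_grid(30, 45))
  expect_lt(max(m$phi_s) - min(m$phi_s), 1e-10)
  st <- delta_phi_s(m)
  expect_lt(st$delta_phi_s, 1e-10)
  expect_true(all(m$phi_s >= 0 & m$phi_s <= 1))
})

test_that("antipodal symmetry holds and the mirrored scan matches the full one", {
  pair <- small_mixed_pair(seed = 55)
  g <- orientation_grid(30, 45)
  m_sym <- orientation_scan(pair, grid = g, use_symmetry = TRUE)
  m_full <- orientation_scan(pair, grid = g, use_symmetry = FALSE)
  expect_lt(max(abs(m_sym$phi_s - m_full$phi_s)), 1e-10)
  # explicit antipodal pairs
  th <- c(35, 145); ph <- c(72, 252)
  parts <- radicalpair:::hamiltonian_parts(pair)
  w <- 2 * pi * larmor_frequency(49)
  for (i in 1:2) {
    b <- drop(radicalpair:::sph_direction(th[i], ph[i]))
    Hp <- parts$H0 + w * (b[1] * parts$Z$x + b[2] * parts$Z$y +
                            b[3] * parts$Z$z)
    Hm <- parts$H0 - w * (b[1] * parts$Z$x + b[2] * parts$Z$y +
                            b[3] * parts$Z$z)
    expect_lt(abs(singlet_yield_spectral(Hp, pair$k) -
                    singlet_yield_spectral(Hm, pair$k)), 1e-10)
  }
})

test_that("compiled scan kernel agrees with the R spectral engine", {
  pair <- small_mixed_pair(seed = 60)
  g <- orientation_grid(45, 60)
  m_cpp <- orientation_scan(pair, grid = g, engine = "cpp")
  m_r <- orientation_scan(pair, grid = g, engine = "r")
  expect_lt(max(abs(m_cpp$phi_s - m_r$phi_s)), 1e-12)
})

test_that("axially symmetric systems give phi-independent maps", {
  rs <- reference_system("one-nitrogen-axial")
  # dipolar axis along z keeps the cylindrical symmetry
  m <- orientation_scan(rs$pair, grid = orientation_grid(30, 45))
  spread_by_theta <- tapply(m$phi_s, m$theta, function(v) max(v) - min(v))
  expect_lt(max(spread_by_theta), 1e-10)
})

test_that("theta profile is baseline-subtracted and symmetric for axial systems", {
  rs <- reference_system("one-nitrogen-axial")
  prof <- theta_profile(rs$pair, phi_deg = 0,
                        theta_deg = seq(0, 180, by = 15))
  expect_equal(prof$phi_s_rel[1], 0)
  # symmetry about theta = 90 for an axial-z system
  expect_equal(prof$phi_s_rel, rev(prof$phi_s_rel), tolerance = 1e-9)
  # isotropic system: identically zero
  ri <- reference_system("one-proton-isotropic")
  prof0 <- theta_profile(ri$pair, theta_deg = seq(0, 180, by = 45))
  expect_lt(max(abs(prof0$phi_s_rel)), 1e-10)
})

test_that("anisotropy statistics decompose the map correctly", {
  pair <- small_mixed_pair(seed = 72)
  m <- orientation_scan(pair, grid = orientation_grid(30, 45))
  st <- delta_phi_s(m)
  expect_gte(st$delta_phi_s, 0)
  expect_equal(st$delta_phi_s, max(m$phi_s) - min(m$phi_s))
  ap <- anisotropic_part(m)
  # residual integrates to zero
  expect_lt(abs(sum(ap$residual$weight * ap$residual$phi_s)), 1e-12)
  # adding a constant shifts the mean, not the residual
  m2 <- m; m2$phi_s <- m$phi_s + 0.1
  ap2 <- anisotropic_part(m2)
  expect_equal(ap2$mean_phi_s, ap$mean_phi_s + 0.1, tolerance = 1e-12)
  expect_equal(ap2$residual$phi_s, ap$residual$phi_s, tolerance = 1e-12)
  # argmax/argmin directions recorded
  expect_equal(unname(st$argmax),
               c(m$theta[which.max(m$phi_s)], m$phi[which.max(m$phi_s)]))
})

test_that("anisotropy is rotationally covariant", {
  pair <- small_mixed_pair(seed = 80)
  g <- orientation_grid(30, 45)
  st1 <- delta_phi_s(orientation_scan(pair, grid = g))
  R <- rotation_matrix(rand_unit(81), 54)
  pair_r <- pair
  pair_r$radical_a$nuclei <- lapply(pair$radical_a$nuclei, function(n)
    nucleus(n$site, n$isotope, R %*% unclass(n$tensor) %*% t(R)))
  pair_r$dipolar_axis <- drop(R %*% pair$dipolar_axis)
  # co-rotate the grid directions
  dirs <- radicalpair:::sph_direction(g$theta, g$phi) %*% t(R)
  parts <- radicalpair:::hamiltonian_parts(pair_r)
  w <- 2 * pi * larmor_frequency(49)
  Q <- radicalpair:::singlet_basis_factor(prod(parts$dims))
  phis <- radicalpair:::cpp_yield_scan(parts$H0, parts$Z$x, parts$Z$y,
                                       parts$Z$z, Q, dirs, w,
                                       pair$k * 1e-6)
  st2 <- max(phis) - min(phis)
  expect_lt(abs(st1$delta_phi_s - st2), 1e-9)
})

test_that("grid refinement changes the anisotropy only slightly", {
  pair <- small_mixed_pair(seed = 90)
  st_coarse <- delta_phi_s(orientation_scan(pair,
                                            grid = orientation_grid(30, 30)))
  st_fine <- delta_phi_s(orientation_scan(pair,
                                          grid = orientation_grid(15, 15)))
  # max - min can only grow under refinement, and not by much
  expect_gte(st_fine$delta_phi_s + 1e-12, st_coarse$delta_phi_s)
  expect_lt(abs(st_fine$delta_phi_s - st_coarse$delta_phi_s),
            0.15 * max(st_fine$delta_phi_s, 1e-12))
})
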