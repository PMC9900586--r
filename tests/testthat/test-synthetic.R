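test_that("axial tensor constructor places the unique axis as requested", {
  A <- axial_tensor(2, 1, c(0, 0, 1))
  expect_equal(unclass(A), diag(c(1, 1, 4)))
  expect_equal(axial_tensor(3, 0, c(0, 1, 0)), hyperfine_tensor(3 * diag(3)))
  expect_equal(sum(diag(unclass(axial_tensor(2, 7, rand_unit(2))))), 6,
               tolerance = 1e-12)
  expect_equal(axiality_summary(axial_tensor(0, 2)),
               c(a_iso = 0, abs_Azz = 4, abs_Axy_mean = 2))
})

test_that("the synthetic radical is deterministic per seed", {
  r1 <- flavin_like_radical(17)
  r2 <- flavin_like_radical(17)
  expect_identical(r1, r2)
  expect_identical(carbon_catalogue(r1), carbon_catalogue(r2))
  r3 <- flavin_like_radical(18)
  expect_false(identical(unclass(r1$nuclei[[1]]$tensor),
                         unclass(r3$nuclei[[1]]$tensor)))
  # generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(flavin_like_radical(5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("synthetic tensors satisfy their class definitions", {
  for (seed in 1:10) {
    fad <- flavin_like_radical(seed)
    labs <- site_labels(fad)
    # nitrogens: axial, |A_zz| > |A_xx + A_yy|/2
    for (s in c("N5", "N10")) {
      ax <- axiality_summary(fad$nuclei[[match(s, labs)]]$tensor)
      expect_gt(ax[["abs_Azz"]], ax[["abs_Axy_mean"]])
    }
    # protons: small anisotropy relative to |a_iso| + 1
    for (s in grep("^H", labs, value = TRUE)) {
      A <- unclass(fad$nuclei[[match(s, labs)]]$tensor)
      pc <- principal_components(A)
      aniso <- max(pc) - min(pc)
      expect_lte(aniso, 0.2 * (abs(mean(pc)) + 1) * 1.5 + 1e-9)
    }
    # carbons: class predicate holds for every catalogue entry
    ctab <- carbon_catalogue(fad)
    cls <- synthetic_carbon_classes()
    for (i in seq_len(nrow(ctab))) {
      A <- with(ctab[i, ], matrix(c(Axx, Axy, Axz, Axy, Ayy, Ayz,
                                    Axz, Ayz, Azz), 3, 3))
      ax <- axiality_summary(A)
      if (cls[[ctab$site[i]]] == "axial-z-large") {
        expect_gt(ax[["abs_Azz"]], ax[["abs_Axy_mean"]])
      } else {
        expect_lt(ax[["abs_Azz"]], ax[["abs_Axy_mean"]])
      }
    }
  }
})

test_that("synthetic yields stay in [0, 1] across a seeded sweep", {
  # reduced systems keep the sweep cheap
  for (seed in 1:25) {
    fad <- remove_nuclei(flavin_like_radical(seed),
                         c("H8alpha1", "H8alpha2", "H8alpha3", "H1prime"))
    pair <- radical_pair(fad, dipolar_axis = c(1, 1, 2) / sqrt(6))
    set.seed(seed)
    f <- field_spec(49, runif(1, 0, 180), runif(1, 0, 360))
    phi <- singlet_yield_spectral(total_hamiltonian(pair, f), pair$k)
    expect_gte(phi, 0)
    expect_lte(phi, 1)
  }
})

test_that("anisotropy vanishes when its sources are ablated", {
  pair <- flavin_like_pair(6, n_protons = 4)
  pair$radical_a <- remove_nuclei(pair$radical_a,
                                  c("H8alpha1", "H8alpha2", "H8alpha3"))
  g <- orientation_grid(30, 45)
  st <- delta_phi_s(orientation_scan(pair, grid = g))
  expect_gt(st$delta_phi_s, 0)
  # isotropic-part replacement plus D = 0 kills every anisotropy source
  iso_pair <- pair
  iso_pair$D <- 0
  iso_pair$radical_a$nuclei <- lapply(pair$radical_a$nuclei, function(n)
    nucleus(n$site, n$isotope,
            mean(diag(unclass(n$tensor))) * diag(3)))
  st_iso <- delta_phi_s(orientation_scan(iso_pair, grid = g))
  expect_lt(st_iso$delta_phi_s, 1e-10)
})

test_that("reference systems expose their expected behaviour descriptors", {
  expect_equal(reference_system("no-coupling")$expect$phi_s, 1)
  expect_true(reference_system("one-nitrogen-axial")$expect$phi_independent)
  expect_true(!is.null(reference_system("two-site-trivial")$model))
  expect_error(reference_system("nope"), "unknown reference system")
  # every reference pair is small
  for (nm in c("no-coupling", "zeeman-only", "one-proton-isotropic",
               "one-nitrogen-axial", "two-site-trivial")) {
    expect_lte(hilbert_dimension(reference_system(nm)$pair), 24L)
  }
})

test_that("tensor tables round-trip through disk and validate their schema", {
  path <- tempfile(fileext = ".tsv")
  skel <- fixture_table(path)
  # roster: 11 H + 4 N + 12 C + Trp N
  expect_identical(nrow(skel), 28L)
  expect_identical(sum(skel$isotope == "13C"), 12L)
  expect_setequal(skel$site[skel$isotope == "13C"], carbon_sites())
  back <- read_tensor_table(path)
  expect_equal(back, skel)
  # write -> read -> write is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  write_tensor_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # schema validation
  broken <- skel[, setdiff(names(skel), "Azz")]
  path3 <- tempfile(fileext = ".tsv")
  utils::write.table(broken, path3, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_error(read_tensor_table(path3), "missing required columns: Azz")
  expect_error(write_tensor_table(broken, tempfile()), "missing required")
})

test_that("the shipped skeleton fixture matches the generator output", {
  shipped <- system.file("extdata", "tensor_table_skeleton.tsv",
                         package = "radicalpair")
  expect_true(nzchar(shipped))
  tbl <- read_tensor_table(shipped)
  expect_identical(nrow(tbl), 28L)
  expect_true(all(tbl$provenance == "synthetic-placeholder"))
})
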