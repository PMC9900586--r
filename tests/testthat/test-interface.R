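test_that("run configuration applies model defaults and rejects typos", {
  cfg <- read_run_config(list(seed = 3))
  expect_equal(cfg$B_uT, 49)
  expect_equal(cfg$J, -0.65)
  expect_equal(cfg$D, -11.2)
  expect_equal(cfg$k, 1e5)
  expect_error(read_run_config(list(seeed = 3)), "unknown config fields")
  # YAML round trip
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "preset: '-H'", "theta_step: 30",
               "phi_step: 45"), path)
  cfg2 <- read_run_config(path)
  expect_identical(cfg2$preset, "-H")
  expect_equal(cfg2$theta_step, 30)
})

test_that("yield-map runs are deterministic and serialize round-trip", {
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  cfg <- list(seed = 2, preset = "U", theta_step = 30, phi_step = 45,
              n_protons = 4, output_dir = out1)
  res1 <- run_yield_map(cfg)
  cfg$output_dir <- out2
  res2 <- run_yield_map(cfg)
  expect_gt(res1$stats$delta_phi_s, 0)
  # byte-identical outputs for identical configs
  expect_identical(readLines(file.path(out1, "yield_map.csv")),
                   readLines(file.path(out2, "yield_map.csv")))
  expect_identical(readLines(file.path(out1, "anisotropy.json")),
                   readLines(file.path(out2, "anisotropy.json")))
  # written CSV re-parses to the in-memory map
  csv <- utils::read.csv(file.path(out1, "yield_map.csv"))
  expect_equal(csv$phi_s, res1$map$phi_s)
  js <- jsonlite::read_json(file.path(out1, "anisotropy.json"))
  expect_equal(js$delta_phi_s, res1$stats$delta_phi_s)
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("preset runs shrink the Hilbert dimension as advertised", {
  cfg_u <- read_run_config(list(seed = 2, preset = "U"))
  cfg_h <- read_run_config(list(seed = 2, preset = "-H"))
  d_u <- hilbert_dimension(radicalpair:::config_pair(cfg_u))
  d_h <- hilbert_dimension(radicalpair:::config_pair(cfg_h))
  expect_identical(d_u, 4L * 9L * 32L)
  expect_identical(d_h, 4L * 9L)
})

test_that("carbon screen ranks subsets deterministically on a reduced catalogue", {
  fad <- remove_nuclei(flavin_like_radical(2),
                       c("N10", "H8alpha1", "H8alpha2", "H8alpha3",
                         "H1prime"))
  ctab <- carbon_catalogue(flavin_like_radical(2))
  pair <- radical_pair(fad, dipolar_axis = c(1, 1, 2) / sqrt(6))
  sites6 <- c("C4", "C4a", "C8alpha", "C6", "C8", "C9a")
  tab <- run_carbon_screen(pair, ctab, k_substitutions = 2,
                           grid = orientation_grid(30, 45),
                           sites = sites6)
  expect_identical(nrow(tab), as.integer(choose(6, 2)))
  expect_identical(tab$rank, seq_len(nrow(tab)))
  # rank 1 holds the minimum anisotropy
  expect_equal(tab$delta_phi_s[1], min(tab$delta_phi_s))
  expect_false(is.unsorted(tab$delta_phi_s))
  # membership columns mark the subsets
  expect_identical(sum(tab$C4), as.integer(choose(5, 1)))
  first_sites <- strsplit(tab$sites[1], "+", fixed = TRUE)[[1]]
  expect_true(all(unlist(tab[1, first_sites])))
  # deterministic rerun
  tab2 <- run_carbon_screen(pair, ctab, k_substitutions = 2,
                            grid = orientation_grid(30, 45),
                            sites = sites6)
  expect_identical(tab, tab2)
  expect_gt(attr(tab, "unsubstituted"), 0)
})

test_that("in-plane carbon pairs attenuate the anisotropy more than axial pairs", {
  # mechanism check at reduced size: the axial nitrogens dominate the
  # anisotropy; in-plane carbons offset them, axial carbons reinforce them
  ranks_by_class <- lapply(1:5, function(seed) {
    fad <- remove_nuclei(flavin_like_radical(seed),
                         c("H8alpha1", "H8alpha2", "H8alpha3", "H1prime"))
    ctab <- carbon_catalogue(flavin_like_radical(seed))
    pair <- radical_pair(fad, dipolar_axis = c(1, 1, 2) / sqrt(6))
    sites <- c("C4", "C4a", "C8alpha", "C6", "C8", "C9a")
    tab <- run_carbon_screen(pair, ctab, k_substitutions = 2,
                             grid = orientation_grid(30, 45),
                             sites = sites)
    cls <- synthetic_carbon_classes()
    subsets <- strsplit(tab$sites, "+", fixed = TRUE)
    all_inplane <- vapply(subsets, function(s)
      all(cls[s] == "in-plane-large"), logical(1))
    all_axial <- vapply(subsets, function(s)
      all(cls[s] == "axial-z-large"), logical(1))
    c(inplane = stats::median(tab$delta_phi_s[all_inplane]),
      axial = stats::median(tab$delta_phi_s[all_axial]))
  })
  m <- do.call(rbind, ranks_by_class)
  expect_lt(stats::median(m[, "inplane"]), stats::median(m[, "axial"]))
})

test_that("relaxation scan driver produces the configured k_m table", {
  # N5,N10,-H preset leaves two 15N: dim 16, Liouville dimension 512
  cfg <- list(seed = 11, preset = "N5,N10,-H", n_protons = 4,
              relaxation = list(km_values = c(1e4, 1e6, 1e8)))
  out <- run_relaxation_scan(cfg, grid = orientation_grid(60, 90),
                             dim_limit = 48)
  expect_identical(nrow(out), 3L)
  expect_identical(out$k_m, c(1e4, 1e6, 1e8))
  expect_true(all(out$delta_phi_s >= 0))
  expect_true(all(out$mean_phi_s >= 0 & out$mean_phi_s <= 1))
  # delta = 0 gives a flat curve at the static anisotropy
  cfg0 <- list(seed = 11, preset = "N5,N10,-H", n_protons = 4,
               relaxation = list(half_angle_deg = 0,
                                 km_values = c(1e4, 1e8)))
  out0 <- run_relaxation_scan(cfg0, grid = orientation_grid(60, 90),
                              dim_limit = 48)
  expect_lt(abs(out0$delta_phi_s[1] - out0$delta_phi_s[2]), 1e-9)
  p <- radicalpair:::config_pair(read_run_config(cfg0))
  st <- delta_phi_s(orientation_scan(p, grid = orientation_grid(60, 90)))
  expect_lt(abs(out0$delta_phi_s[1] - st$delta_phi_s), 1e-9)
  expect_error(run_relaxation_scan(list(seed = 1)), "no relaxation block")
})
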