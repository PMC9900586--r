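# Run configuration, results serialization, and the screening drivers that
# reproduce the isotopologue scans end to end.

#' Read and validate a run configuration
#'
#' YAML configuration with the model defaults filled in: `B_uT = 49`,
#' `J = -0.65`, `D = -11.2`, `k = 1e5`, a 2-degree orientation grid, and a
#' synthetic pair seeded by `seed`.  Unknown top-level keys are an error so
#' that typos fail loudly.
#'
#' @param path YAML file path, or a list already in config form.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    seed = 1L, partner = "Z", n_protons = 5L,
    B_uT = 49, J = -0.65, D = -11.2, k = 1e5,
    dipolar_axis = c(1, 1, 2) / sqrt(6),
    theta_step = 2, phi_step = 2,
    preset = "U",
    carbon_sites = NULL, drop_h1prime = FALSE,
    relaxation = NULL,
    output_dir = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  if (!is.null(cfg$relaxation)) {
    rdef <- list(axis = c(1, 0, 0), half_angle_deg = 5,
                 km_values = 10^seq(4, 8, by = 0.5))
    cfg$relaxation <- utils::modifyList(rdef, cfg$relaxation)
  }
  structure(cfg, class = "run_config")
}

config_pair <- function(cfg) {
  pair <- flavin_like_pair(cfg$seed, partner = cfg$partner,
                           n_protons = cfg$n_protons, J = cfg$J, D = cfg$D,
                           k = cfg$k,
                           dipolar_axis = as.numeric(cfg$dipolar_axis))
  catalogue <- carbon_catalogue(pair$radical_a)
  pair$radical_a <- apply_preset(pair$radical_a, cfg$preset)
  if (cfg$drop_h1prime &&
      "H1prime" %in% site_labels(pair$radical_a))
    pair$radical_a <- remove_nuclei(pair$radical_a, "H1prime")
  if (length(cfg$carbon_sites))
    pair$radical_a <- substitute_carbons(pair$radical_a, cfg$carbon_sites,
                                         catalogue)
  attr(pair, "carbon_table") <- catalogue
  pair
}

config_hash <- function(cfg) {
  cfg$output_dir <- NULL          # hash the science, not the destination
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(unclass(cfg),
                                              digits.d = 15)), f)
  unname(tools::md5sum(f))
}

#' Compute and serialize a yield map
#'
#' Builds the configured radical pair (synthetic tensors, preset
#' substitutions, optional carbon insertions), scans the singlet yield over
#' the configured orientation grid, and writes the map as CSV
#' (`theta, phi, weight, phi_s`) and the anisotropy statistics as JSON.
#' Outputs are deterministic functions of the configuration.
#'
#' @param cfg `run_config` (or path / list accepted by
#'   [read_run_config()]).
#' @return List with `map` (`yield_map`), `stats` (`anisotropy_stats`) and
#'   the output `paths` (NULL when no `output_dir` is configured).
#' @export
run_yield_map <- function(cfg) {
  cfg <- read_run_config(cfg)
  pair <- config_pair(cfg)
  grid <- orientation_grid(cfg$theta_step, cfg$phi_step)
  map <- orientation_scan(pair, B_uT = cfg$B_uT, grid = grid)
  stats <- delta_phi_s(map)
  paths <- NULL
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- config_hash(cfg)
    csv <- file.path(cfg$output_dir, "yield_map.csv")
    jsn <- file.path(cfg$output_dir, "anisotropy.json")
    utils::write.csv(as.data.frame(map)[, c("theta", "phi", "weight",
                                            "phi_s")],
                     csv, row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash,
           delta_phi_s = stats$delta_phi_s,
           mean_phi_s = stats$mean_phi_s,
           argmax = as.list(stats$argmax),
           argmin = as.list(stats$argmin),
           hilbert_dimension = hilbert_dimension(pair)),
      jsn, auto_unbox = TRUE, digits = NA)
    paths <- c(map = csv, stats = jsn)
  }
  list(map = map, stats = stats, paths = paths)
}

#' Combinatorial carbon-substitution screen
#'
#' Enumerates all \eqn{\binom{12}{k}} sets of 12C -> 13C substitutions,
#' computes \eqn{\Delta\Phi_S} for each isotopologue over the orientation
#' grid, and returns the table ranked ascending (rank 1 = strongest
#' attenuation of the compass signal).
#'
#' @param pair Base [radical_pair()] (without the carbons).
#' @param tensor_table 13C tensor catalogue (data.frame or named list).
#' @param k_substitutions Subset size (3 reproduces the 220-set screen).
#' @param grid Orientation grid.
#' @param B_uT Field magnitude.
#' @param sites Carbon catalogue to draw from.
#' @param progress Print one line per subset batch.
#' @return data.frame with columns `rank`, `sites` (plus-separated),
#'   `delta_phi_s`, `mean_phi_s`, and one logical membership column per
#'   catalogue site; attribute `unsubstituted` holds the base-pair
#'   `delta_phi_s`.
#' @export
run_carbon_screen <- function(pair, tensor_table, k_substitutions = 3,
                              grid = orientation_grid(theta_step = 10,
                                                      phi_step = 10),
                              B_uT = 49, sites = carbon_sites(),
                              progress = FALSE) {
  subsets <- enumerate_carbon_sets(k_substitutions, sites = sites)
  base_map <- orientation_scan(pair, B_uT = B_uT, grid = grid)
  base_stats <- delta_phi_s(base_map)
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    p <- pair
    p$radical_a <- substitute_carbons(p$radical_a, sub, tensor_table)
    map <- orientation_scan(p, B_uT = B_uT, grid = grid)
    st <- delta_phi_s(map)
    rows[[i]] <- data.frame(sites = paste(sub, collapse = "+"),
                            delta_phi_s = st$delta_phi_s,
                            mean_phi_s = st$mean_phi_s,
                            stringsAsFactors = FALSE)
    if (progress && (i %% 20 == 0 || i == length(subsets)))
      message(sprintf("screen %d/%d: %s dPhi_S = %.4g", i, length(subsets),
                      rows[[i]]$sites, st$delta_phi_s))
  }
  out <- do.call(rbind, rows)
  ord <- order(out$delta_phi_s, out$sites)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  membership <- vapply(sites, function(s)
    vapply(subsets[ord], function(x) s %in% x, logical(1)),
    logical(length(subsets)))
  out <- cbind(out[, c("rank", "sites", "delta_phi_s", "mean_phi_s")],
               membership)
  rownames(out) <- NULL
  attr(out, "unsubstituted") <- base_stats$delta_phi_s
  out
}

#' Anisotropy-versus-hop-rate scan driver
#'
#' Configured wrapper around [km_scan()]: builds the pair from the config,
#' runs the two-site stochastic Liouville scan over the configured
#' log-spaced hop rates, and optionally writes a `(k_m, delta_phi_s)` CSV.
#'
#' @param cfg `run_config` with a `relaxation` block.
#' @param grid Orientation grid for the scan (coarse by default).
#' @param dim_limit Passed to [two_site_yield()].
#' @return data.frame from [km_scan()]; written to
#'   `output_dir/relaxation_scan.csv` when an output directory is set.
#' @export
run_relaxation_scan <- function(cfg,
                                grid = orientation_grid(theta_step = 30,
                                                        phi_step = 45),
                                dim_limit = 48) {
  cfg <- read_run_config(cfg)
  if (is.null(cfg$relaxation))
    stop("config has no relaxation block", call. = FALSE)
  pair <- config_pair(cfg)
  model <- hopping_model(as.numeric(cfg$relaxation$axis),
                         cfg$relaxation$half_angle_deg, k_m = 0)
  out <- km_scan(pair, model, km_values = cfg$relaxation$km_values,
                 grid = grid, B_uT = cfg$B_uT, dim_limit = dim_limit)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$output_dir, "relaxation_scan.csv"),
                     row.names = FALSE)
  }
  out
}
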