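# Isotopically substituted radical specifications: magnetogyric-ratio
# scaling (1H/2H, 14N/15N), 13C tensor insertion, nucleus removal, and
# combinatorial enumeration of substitution sets.

#' The twelve flavin carbon sites
#'
#' The 10 isoalloxazine ring carbons plus the two methyl carbons, the
#' catalogue over which 12C -> 13C substitution sets are enumerated.
#'
#' @return Character vector of 12 site labels.
#' @export
carbon_sites <- function() {
  c("C2", "C4", "C4a", "C5a", "C6", "C7", "C8", "C9", "C9a", "C10a",
    "C7alpha", "C8alpha")
}

# five hydrogens of the standard working nucleus set
.working_hydrogens <- c("H6", "H8alpha1", "H8alpha2", "H8alpha3", "H1prime")

#' Substitute one isotope at a site
#'
#' Replaces the isotope at `site` by `new_iso` of the same element.  The
#' hyperfine tensor is rescaled component-wise by the magnetogyric ratio
#' (2H: x0.154; 15N: x(-1.402)) and the spin quantum number is updated; all
#' other nuclei are untouched.
#'
#' @param radical [radical_spec()].
#' @param site Site label present in the radical.
#' @param new_iso Target isotope symbol or `isotope_spec`.
#' @return Modified `radical_spec`.
#' @export
substitute_isotope <- function(radical, site, new_iso) {
  stopifnot(inherits(radical, "radical_spec"))
  new_iso <- isotope(new_iso)
  idx <- match(site, site_labels(radical))
  if (is.na(idx))
    stop("site not present in radical: ", site, call. = FALSE)
  old <- radical$nuclei[[idx]]
  if (old$isotope$element != new_iso$element)
    stop("invalid substitution: ", old$isotope$symbol, " -> ",
         new_iso$symbol, " crosses elements", call. = FALSE)
  if (identical(old$isotope$symbol, new_iso$symbol)) return(radical)
  scale <- gamma_ratio(new_iso, old$isotope)
  radical$nuclei[[idx]] <- nucleus(site, new_iso,
                                   scale * unclass(old$tensor))
  radical
}

#' Insert 13C nuclei
#'
#' Appends one I = 1/2 carbon nucleus per requested site, taking its
#' hyperfine tensor from a tensor table (see [read_tensor_table()]).  Each
#' insertion doubles the Hilbert-space dimension.
#'
#' @param radical [radical_spec()].
#' @param sites Character vector drawn from [carbon_sites()].
#' @param tensor_table data.frame with columns `site`, `isotope`,
#'   `Axx ... Azz` containing a 13C row per requested site, or a named list
#'   of 3x3 tensors.
#' @return Modified `radical_spec`.
#' @export
substitute_carbons <- function(radical, sites, tensor_table) {
  stopifnot(inherits(radical, "radical_spec"))
  if (length(sites) == 0) return(radical)
  bad <- setdiff(sites, carbon_sites())
  if (length(bad))
    stop("unknown carbon sites: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (s in sites) {
    A <- lookup_tensor(tensor_table, s, "13C")
    radical$nuclei <- c(radical$nuclei, list(nucleus(s, "13C", A)))
  }
  # re-validate uniqueness
  radical_spec(radical$nuclei, g = radical$g, name = radical$name)
}

lookup_tensor <- function(tensor_table, site, iso) {
  if (is.list(tensor_table) && !is.data.frame(tensor_table)) {
    A <- tensor_table[[site]]
    if (is.null(A))
      stop("no tensor entry for site ", site, call. = FALSE)
    return(A)
  }
  row <- tensor_table[tensor_table$site == site &
                        tensor_table$isotope == iso, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("tensor table has ", nrow(row), " entries for ", site, "/", iso,
         " (need exactly 1)", call. = FALSE)
  with(row, matrix(c(Axx, Axy, Axz, Axy, Ayy, Ayz, Axz, Ayz, Azz), 3, 3))
}

#' Remove nuclei from a radical
#'
#' Deletes the listed sites (used, e.g., to drop all five working hydrogens
#' for the "-H" preset).
#'
#' @param radical [radical_spec()].
#' @param sites Site labels, all of which must exist.
#' @return Modified `radical_spec`.
#' @export
remove_nuclei <- function(radical, sites) {
  stopifnot(inherits(radical, "radical_spec"))
  if (length(sites) == 0) return(radical)
  labels <- site_labels(radical)
  bad <- setdiff(sites, labels)
  if (length(bad))
    stop("cannot remove unknown sites: ", paste(bad, collapse = ", "),
         call. = FALSE)
  radical$nuclei <- radical$nuclei[!labels %in% sites]
  radical
}

#' Enumerate carbon substitution sets
#'
#' All \eqn{\binom{12}{k}} subsets of the carbon catalogue in deterministic
#' lexicographic order (220 subsets for k = 3).
#'
#' @param k Subset size, 0 <= k <= 12.
#' @param sites Site catalogue (defaults to the 12 flavin carbons).
#' @return List of character vectors.
#' @export
enumerate_carbon_sets <- function(k, sites = carbon_sites()) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > length(sites) ||
      k != round(k))
    stop("k must be an integer in [0, ", length(sites), "]", call. = FALSE)
  if (k == 0) return(list(character(0)))
  cmb <- utils::combn(sites, k, simplify = FALSE)
  cmb
}

#' Named substitution presets
#'
#' The bar-label presets of the hydrogen/nitrogen isotopologue survey:
#' `"U"` (unsubstituted), `"N5"`, `"N10"`, `"N5,N10"` (15N substitution),
#' `"D"` (all five working hydrogens deuterated), `"-H"` (all five working
#' hydrogens removed), and the combinations `"N5,N10,D"` and `"N5,N10,-H"`.
#'
#' @param name Preset name.
#' @return List of class `substitution_set` with fields `n15` (sites to
#'   turn into 15N) and `hydrogens` (`"keep"`, `"deuterate"` or `"remove"`).
#' @export
preset_substitution <- function(name) {
  presets <- list(
    "U"         = list(n15 = character(0), hydrogens = "keep"),
    "N5"        = list(n15 = "N5",         hydrogens = "keep"),
    "N10"       = list(n15 = "N10",        hydrogens = "keep"),
    "N5,N10"    = list(n15 = c("N5", "N10"), hydrogens = "keep"),
    "N5,N10,D"  = list(n15 = c("N5", "N10"), hydrogens = "deuterate"),
    "N5,N10,-H" = list(n15 = c("N5", "N10"), hydrogens = "remove"),
    "-H"        = list(n15 = character(0), hydrogens = "remove"),
    "D"         = list(n15 = character(0), hydrogens = "deuterate")
  )
  p <- presets[[name]]
  if (is.null(p))
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")", call. = FALSE)
  structure(c(p, list(name = name)), class = "substitution_set")
}

#' Apply a substitution preset to a flavin-like radical
#'
#' @param radical [radical_spec()] carrying N5/N10 and (a subset of) the
#'   five working hydrogens.
#' @param name Preset name for [preset_substitution()], or a
#'   `substitution_set`.
#' @return Modified `radical_spec`.
#' @export
apply_preset <- function(radical, name) {
  p <- if (inherits(name, "substitution_set")) name
       else preset_substitution(name)
  for (s in p$n15) radical <- substitute_isotope(radical, s, "15N")
  hyd <- intersect(.working_hydrogens, site_labels(radical))
  if (p$hydrogens == "deuterate") {
    for (s in hyd) radical <- substitute_isotope(radical, s, "2H")
  } else if (p$hydrogens == "remove") {
    radical <- remove_nuclei(radical, hyd)
  }
  radical
}
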