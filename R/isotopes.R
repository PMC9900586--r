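# Nuclear isotope data.
#
# gamma_scale is the ratio of the magnetogyric ratio to that of the reference
# isotope of the same element (1H, 13C, 14N) and is the factor by which
# hyperfine tensors are rescaled upon substitution.  The 2H/1H and 15N/14N
# ratios are the model's adopted constants (0.154 and -1.402); 12C carries no
# spin and therefore no hyperfine interaction.

.isotope_table <- data.frame(
  symbol      = c("1H", "2H", "12C", "13C", "14N", "15N"),
  element     = c("H", "H", "C", "C", "N", "N"),
  spin        = c(0.5, 1, 0, 0.5, 1, 0.5),
  gamma_scale = c(1, 0.154, 0, 1, 1, -1.402),
  stringsAsFactors = FALSE
)

#' Isotope specification
#'
#' Looks up an isotope by symbol and returns its spin quantum number and the
#' magnetogyric-ratio scale factor relative to the reference isotope of the
#' same element (1H, 13C or 14N).
#'
#' @param symbol One of `"1H"`, `"2H"`, `"12C"`, `"13C"`, `"14N"`, `"15N"`.
#' @return An object of class `isotope_spec` with fields `symbol`, `element`,
#'   `spin` (I), `multiplicity` (2I+1) and `gamma_scale`.
#' @examples
#' isotope("15N")$gamma_scale  # -1.402
#' @export
isotope <- function(symbol) {
  if (inherits(symbol, "isotope_spec")) return(symbol)
  row <- .isotope_table[.isotope_table$symbol == symbol, ]
  if (nrow(row) != 1L)
    stop("unknown isotope symbol: ", symbol, call. = FALSE)
  out <- list(symbol = row$symbol, element = row$element, spin = row$spin,
              multiplicity = as.integer(2 * row$spin + 1),
              gamma_scale = row$gamma_scale)
  class(out) <- "isotope_spec"
  out
}

#' @export
print.isotope_spec <- function(x, ...) {
  cat(sprintf("<isotope %s: I = %s, gamma scale (vs reference %s) = %g>\n",
              x$symbol, format(x$spin), reference_isotope(x$element),
              x$gamma_scale))
  invisible(x)
}

reference_isotope <- function(element) {
  switch(element, H = "1H", C = "13C", N = "14N",
         stop("unknown element: ", element, call. = FALSE))
}

#' Magnetogyric-ratio scale between two isotopes of one element
#'
#' Factor by which a hyperfine tensor is multiplied when `from` is replaced
#' by `to` (e.g. 1H -> 2H gives 0.154, 14N -> 15N gives -1.402).
#'
#' @param from,to Isotope symbols or `isotope_spec` objects of one element.
#' @return Scalar scale factor.
#' @export
gamma_ratio <- function(to, from) {
  to <- isotope(to); from <- isotope(from)
  if (to$element != from$element)
    stop("isotopes belong to different elements: ", from$symbol, " vs ",
         to$symbol, call. = FALSE)
  if (from$spin == 0)
    stop("reference isotope ", from$symbol,
         " has no spin; no coupling to rescale", call. = FALSE)
  to$gamma_scale / from$gamma_scale
}

#' Relaxation slow-down on isotope substitution
#'
#' Spin relaxation driven by stochastic modulation of a hyperfine coupling
#' scales with the square of the coupling, hence substitution multiplies the
#' relaxation rate by the squared magnetogyric ratio.  For deuteration the
#' slow-down factor is \eqn{[\gamma(^1H)/\gamma(^2H)]^2 \approx 42}.
#'
#' @param to,from Isotope symbols; defaults give the deuteration factor.
#' @return The squared inverse ratio (relaxation slow-down factor).
#' @export
relaxation_scale_factor <- function(to = "2H", from = "1H") {
  (1 / gamma_ratio(to, from))^2
}
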