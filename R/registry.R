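#' Element registry
#'
#' The set of elements monitored along a laser-ablation ICP-MS otolith
#' transect, each identified by its chemical symbol and the mass number
#' (m/z) at which counts were acquired. All concentrations handled by this
#' package are expressed as molar ratios to calcium (internal standard
#' \eqn{^{43}}Ca), so the registry carries no per-element unit beyond that
#' convention.
#'
#' @param symbols character vector of unique element symbols (e.g. "Sr").
#' @param masses positive integer mass numbers, one per symbol.
#' @return A data frame of class `element_registry` with columns `symbol`,
#'   `mass` and `unit`.
#' @examples
#' element_registry(c("Sr", "Rb"), c(88, 85))
#' @export
element_registry <- function(symbols, masses) {
  symbols <- as.character(symbols)
  masses <- as.integer(masses)
  if (length(symbols) != length(masses))
    stop("`symbols` and `masses` must have equal length", call. = FALSE)
  if (anyDuplicated(symbols))
    stop("element symbols must be unique: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(masses)) || any(masses <= 0L))
    stop("mass numbers must be positive integers", call. = FALSE)
  out <- data.frame(symbol = symbols, mass = masses,
                    unit = "molar ratio to Ca",
                    stringsAsFactors = FALSE)
  class(out) <- c("element_registry", "data.frame")
  out
}

#' Default monitored-element registry
#'
#' Nine elements routinely monitored on otolith ablation transects: Li (7),
#' B (11), Mg (25), P (31), K (39), Mn (55), Rb (85), Sr (88) and Ba (138).
#' Ba is registered at its most abundant isotope mass 138; inputs declaring
#' a different monitored mass override the default, since the registry
#' stores whatever the acquisition declared.
#'
#' @return An [element_registry()].
#' @export
default_element_registry <- function() {
  element_registry(
    symbols = c("Li", "B", "Mg", "P", "K", "Mn", "Rb", "Sr", "Ba"),
    masses  = c(7L, 11L, 25L, 31L, 39L, 55L, 85L, 88L, 138L))
}

#' @export
print.element_registry <- function(x, ...) {
  cat("Element registry (", nrow(x), " elements, molar ratio to Ca)\n",
      sep = "")
  cat(paste0(x$symbol, "(", x$mass, ")", collapse = " "), "\n")
  invisible(x)
}
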