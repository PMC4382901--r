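# Closed unit vocabularies of the BDML 0.2 schema. The spatial/feature list
# extends the SBML unit kinds with names common in quantitative imaging
# ("micrometer", "a.u." for arbitrary fluorescence units, "p.d.u." for
# procedure-defined units); the temporal list runs from nanosecond to year.

#' Allowed spatial and feature units
#'
#' Returns the closed set of unit names accepted for `xyzUnit` and
#' `featureUnit` in a BDML 0.2 document (34 names, including the
#' imaging-specific additions `"a.u."`, `"p.d.u."` and `"micrometer"`).
#'
#' @return Character vector of valid unit names.
#' @seealso [bdml_time_units()]
#' @export
#' @examples
#' "micrometer" %in% bdml_units()
bdml_units <- function() {
  c(
    "ampere", "a.u.", "becquerel", "candela", "Celsius", "dimensionless",
    "farad", "gram", "gray", "henry", "hertz", "item", "joule", "katal",
    "kelvin", "kilogram", "liter", "lumen", "lux", "meter", "micrometer",
    "mole", "newton", "ohm", "pascal", "p.d.u.", "radian", "siemens",
    "sievert", "steradian", "tesla", "volt", "watt", "weber"
  )
}

#' Allowed time units
#'
#' The closed set of unit names accepted for `tUnit` in BDML 0.2.
#'
#' @return Character vector of the nine valid time unit names.
#' @export
bdml_time_units <- function() {
  c(
    "nanosecond", "microsecond", "millisecond", "second", "minute",
    "hour", "day", "month", "year"
  )
}

# entity kinds supported by the format
BDML_ENTITY_KINDS <- c("point", "line", "circle", "sphere", "face")

# basedon enumeration
BDML_BASEDON <- c("experiment", "simulation")
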