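#' Parse a unit-suffixed quantity to SI
#'
#' Config files and the command line accept values such as `"1.33cm"`,
#' `"0.75mm"` or `"300um/s"`. All internal computation is in SI, so these
#' are converted exactly at the boundary. Every supported unit is a
#' power-of-ten multiple of its SI base, and the conversion is performed by
#' shifting the decimal exponent of the literal before numeric parsing, so
#' the result is bit-identical to parsing the equivalent SI literal.
#'
#' @param x Character scalar, a number with an optional unit suffix.
#'   Supported suffixes: lengths `m, cm, mm, um, µm`; times `s, ms`;
#'   speeds `m/s, cm/s, mm/s, um/s, µm/s`; pressures `Pa, kPa`.
#'   A bare number is taken as already in SI.
#' @return Numeric scalar in SI units (m, s, m/s or Pa).
#' @examples
#' parse_quantity("1.33cm")   # 0.0133 m
#' parse_quantity("300um/s")  # 3e-4 m/s
#' @export
parse_quantity <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort_invalid_parameter("`x` must be a single character string")
  }
  m <- regexec("^\\s*([-+]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][-+]?[0-9]+)?)\\s*([A-Za-zµ][A-Za-zµ/]*)?\\s*$",
               x)
  parts <- regmatches(x, m)[[1]]
  if (length(parts) == 0L) {
    abort_format_error(sprintf("cannot parse quantity '%s'", x))
  }
  num <- parts[2]
  unit <- parts[3]
  if (is.na(unit) || unit == "") {
    return(as.numeric(num))
  }
  k <- .unit_exponents[[unit]]
  if (is.null(k)) {
    abort_format_error(sprintf("unknown unit suffix '%s' in '%s'", unit, x))
  }
  as.numeric(shift_exponent(num, k))
}

# power-of-ten exponent taking each unit to its SI base
.unit_exponents <- list(
  "m" = 0L, "cm" = -2L, "mm" = -3L, "um" = -6L, "µm" = -6L,
  "s" = 0L, "ms" = -3L,
  "m/s" = 0L, "cm/s" = -2L, "mm/s" = -3L, "um/s" = -6L, "µm/s" = -6L,
  "Pa" = 0L, "kPa" = 3L
)

# Shift the decimal exponent of a numeric literal by k without evaluating
# it, so "1.33" with k = -2 becomes "1.33e-2" and "3e-2" with k = -2
# becomes "3e-4". Keeps decimal->binary rounding to a single step.
shift_exponent <- function(num, k) {
  if (grepl("[eE]", num)) {
    bits <- strsplit(num, "[eE]")[[1]]
    sprintf("%se%d", bits[1], as.integer(bits[2]) + k)
  } else {
    sprintf("%se%d", num, k)
  }
}

#' Format an SI value in a given unit
#'
#' Inverse of [parse_quantity()]: `parse_quantity(format_quantity(v, u))`
#' returns `v` exactly.
#'
#' @param value Numeric scalar in SI units.
#' @param unit One of the suffixes accepted by [parse_quantity()].
#' @return Character scalar such as `"1.33cm"`.
#' @export
format_quantity <- function(value, unit) {
  check_scalar(value, "value")
  k <- .unit_exponents[[unit]]
  if (is.null(k)) {
    abort_format_error(sprintf("unknown unit suffix '%s'", unit))
  }
  paste0(shift_exponent(sprintf("%.17g", value), -k), unit)
}
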