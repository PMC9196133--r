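# Unit handling for the yaml parameter dialect.
#
# Supported units form a closed set; anything else is rejected. Conversion
# to SI multiplies by a fixed factor, so to_si/from_si round-trip exactly
# up to one floating-point rounding.

unit_table <- stats::setNames(
  c(1, 1e-3, 1, 1e-3, 1, 1e-9, 1e-12, 1, 1e3, 1, 1, 1e-3, 1, 1),
  c("s", "ms", "V", "mV", "A", "nA", "pA", "Hz", "1/mm", "1/m",
    "m", "mm", "", "dimensionless")
)

#' Convert a value with unit to SI
#'
#' @param value numeric scalar, vector or (nested-list) matrix.
#' @param unit unit string from the supported set (`s`, `ms`, `V`, `mV`,
#'   `A`, `nA`, `pA`, `Hz`, `1/mm`, `1/m`, `m`, `mm`, `""`,
#'   `dimensionless`).
#' @return numeric object scaled to SI units.
#' @export
to_si <- function(value, unit = "") {
  f <- unit_factor(unit)
  value * f
}

#' Convert an SI value back to a given unit
#' @inheritParams to_si
#' @export
from_si <- function(value, unit = "") {
  value / unit_factor(unit)
}

unit_factor <- function(unit) {
  if (is.null(unit)) unit <- ""
  if (!is.character(unit) || length(unit) != 1) {
    stop("unit must be a single string")
  }
  # match() rather than name-subsetting: the empty unit "" is a valid name
  # but cannot be used as a subscript
  i <- match(unit, names(unit_table))
  if (is.na(i)) {
    stop("unknown unit '", unit, "'; supported: ",
         paste(setdiff(names(unit_table), ""), collapse = ", "))
  }
  unname(unit_table[i])
}

# Parse one yaml entry: either a bare scalar/list (unitless) or a mapping
# with keys `val` and `unit`. Nested lists become matrices/vectors.
parse_quantity <- function(x, key = "<unnamed>") {
  if (is.list(x) && !is.null(names(x)) && "val" %in% names(x)) {
    extra <- setdiff(names(x), c("val", "unit"))
    if (length(extra)) {
      stop("entry '", key, "': unexpected keys ", paste(extra, collapse = ", "))
    }
    val <- listify_to_numeric(x$val, key)
    to_si(val, if (is.null(x$unit)) "" else x$unit)
  } else {
    listify_to_numeric(x, key)
  }
}

# nested yaml lists -> numeric vector or matrix (row-major nesting)
listify_to_numeric <- function(x, key = "<unnamed>") {
  if (is.numeric(x)) return(x)
  if (is.list(x)) {
    if (length(x) == 0) stop("entry '", key, "': empty list")
    if (all(vapply(x, function(e) is.numeric(e) && length(e) == 1, logical(1)))) {
      return(unlist(x))
    }
    rows <- lapply(x, listify_to_numeric, key = key)
    len <- unique(vapply(rows, length, integer(1)))
    if (length(len) != 1) stop("entry '", key, "': ragged nested list")
    return(do.call(rbind, rows))
  }
  stop("entry '", key, "': cannot interpret as numeric quantity")
}
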