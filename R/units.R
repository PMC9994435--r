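#' @name units
#' @title Unit registry and conversion
#'
#' @description
#' A small fixed registry of the units that appear in campus activity
#' ledgers and emission-factor tables. Every unit belongs to one dimension
#' (mass, volume, energy, distance, count, currency-free counts such as
#' animal head) and carries a factor to that dimension's SI anchor
#' (kg, m3, MJ, km, 1). Conversion is multiplication by a ratio of anchor
#' factors, so it is exact, associative and invertible up to floating point.
#'
#' Canonical internal units are metric: kg for mass, m3 for volume, MJ for
#' energy, km for distance. Imperial units (lb, gallon, mile, MMBtu) are
#' accepted on input and available for rendering.
NULL

# unit -> (dimension, factor to the dimension's SI anchor)
.unit_registry <- local({
  u <- rbind(
    data.frame(unit = c("kg", "g", "lb", "t", "ton", "MT"),
               dimension = "mass",
               to_si = c(1, 1e-3, 0.45359237, 1e3, 1e3, 1e3)),
    data.frame(unit = c("m3", "L", "gallon", "kgal"),
               dimension = "volume",
               to_si = c(1, 1e-3, 0.003785411784, 3.785411784)),
    data.frame(unit = c("MJ", "GJ", "kWh", "MWh", "MMBtu", "therm"),
               dimension = "energy",
               to_si = c(1, 1e3, 3.6, 3.6e3, 1055.05585262, 105.505585262)),
    data.frame(unit = c("km", "mile"),
               dimension = "distance",
               to_si = c(1, 1.609344)),
    data.frame(unit = c("head", "unit", "each", "meal"),
               dimension = "count",
               to_si = c(1, 1, 1, 1))
  )
  rownames(u) <- u$unit
  u
})

#' List the units the registry resolves
#'
#' @return data.frame with columns `unit`, `dimension`, `to_si`.
#' @export
unit_registry <- function() {
  df <- .unit_registry
  rownames(df) <- NULL
  df
}

#' Dimension of a unit symbol
#'
#' @param unit character vector of unit symbols.
#' @return character vector of dimensions ("mass", "volume", "energy",
#'   "distance", "count"); errors on an unknown symbol.
#' @export
unit_dimension <- function(unit) {
  i <- match(unit, .unit_registry$unit)
  if (anyNA(i)) {
    bad <- unique(unit[is.na(i)])
    stop("unresolvable unit(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  .unit_registry$dimension[i]
}

#' Convert quantities between units of the same dimension
#'
#' @param x numeric vector of quantities.
#' @param from,to unit symbols (scalar or vector, recycled against `x`).
#' @return numeric vector in units of `to`.
#' @examples
#' convert_unit(1, "lb", "kg")
#' convert_unit(1000, "gallon", "m3")
#' @export
convert_unit <- function(x, from, to) {
  i <- match(from, .unit_registry$unit)
  j <- match(to, .unit_registry$unit)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(from[is.na(i)], to[is.na(j)]))
    stop("unresolvable unit(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  di <- .unit_registry$dimension[i]
  dj <- .unit_registry$dimension[j]
  if (any(di != dj)) {
    k <- which(di != dj)[1L]
    stop(sprintf("cannot convert %s (%s) to %s (%s)",
                 from[[min(k, length(from))]], di[k],
                 to[[min(k, length(to))]], dj[k]), call. = FALSE)
  }
  x * .unit_registry$to_si[i] / .unit_registry$to_si[j]
}
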