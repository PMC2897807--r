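#' Create a minisatellite map
#'
#' A map is an identified non-empty sequence of unit-type symbols.
#'
#' @param id map identifier (unique within a dataset).
#' @param units character vector of unit symbols, or a single string.  A
#'   single string without whitespace is split into one-character units (the
#'   compact dialect used for published maps such as `"bcaccbb"`); use a
#'   vector or a space-separated string for multi-character symbols like
#'   `"4a"`.
#' @return an object of class `mini_map`.
#' @examples
#' mini_map("m1", "bcaccbb")
#' mini_map("m2", c("4a", "1", "1a", "2"))
#' @export
mini_map <- function(id, units) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("id must be a non-empty string")
  units <- map_units(units)
  structure(list(id = id, units = units), class = "mini_map")
}

#' Normalize unit-symbol input
#'
#' @param units character vector of tokens, a space-separated string, or a
#'   compact single-character string.
#' @return character vector of unit symbols.
#' @export
map_units <- function(units) {
  if (inherits(units, "mini_map")) return(units$units)
  units <- as.character(units)
  if (length(units) == 1) {
    units <- if (grepl("[[:space:]]", units)) {
      strsplit(trimws(units), "[[:space:]]+")[[1]]
    } else {
      strsplit(units, "")[[1]]
    }
  }
  if (length(units) == 0) stop("a map must contain at least one unit")
  check_symbols(units, allow_composite = TRUE)
  units
}

#' @export
print.mini_map <- function(x, ...) {
  cat(sprintf(">%s (%d units)\n%s\n", x$id, length(x$units),
              paste(x$units, collapse = " ")))
  invisible(x)
}

#' @export
format.mini_map <- function(x, ...) paste(x$units, collapse = " ")

# integer codes (1-based into cm$alphabet) for the C++ kernels
units_codes <- function(units, cm) {
  units <- map_units(units)
  idx <- match(units, cm$alphabet)
  if (anyNA(idx))
    stop("unit symbol(s) outside the cost-model alphabet: ",
         paste(unique(units[is.na(idx)]), collapse = ", "))
  idx
}

# per-position indel weights
units_weights <- function(units, cm) {
  unname(cm$indel_weight[units_codes(units, cm)])
}

as_map_list <- function(maps) {
  if (inherits(maps, "mini_map")) maps <- list(maps)
  if (!is.list(maps) || length(maps) == 0 ||
      !all(vapply(maps, inherits, logical(1), "mini_map")))
    stop("maps must be a list of mini_map objects")
  ids <- vapply(maps, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate map ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(maps) <- ids
  maps
}

#' Alphabet observed in a set of maps
#'
#' @param maps list of [mini_map()] objects.
#' @return sorted character vector of the unit symbols in use.
#' @export
map_alphabet <- function(maps) {
  maps <- as_map_list(maps)
  sort(unique(unlist(lapply(maps, `[[`, "units"))))
}
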