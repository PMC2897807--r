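#' Locate periodic "xyxy..." sub-arrays
#'
#' Scans a map left to right for maximal non-overlapping alternating arrays
#' of two distinct symbols.  An array must contain at least two full `xy`
#' periods (four units); an odd-length alternation contributes its longest
#' even-length prefix and leaves the trailing unit untouched.
#'
#' @param m a [mini_map()] (or unit string).
#' @return data frame with 0-based half-open interval columns `start`, `end`
#'   and the period symbols `x`, `y`; zero rows when no array is found.
#' @examples
#' find_xy_arrays(mini_map("m", "abcbcbd"))  # the bcbc block
#' @export
find_xy_arrays <- function(m) {
  u <- map_units(m)
  n <- length(u)
  out <- data.frame(start = integer(), end = integer(),
                    x = character(), y = character(), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= n - 3L) {
    x <- u[i]; y <- u[i + 1L]
    if (x != y) {
      j <- i + 2L
      while (j <= n && u[j] == u[j - 2L]) j <- j + 1L
      len <- j - i                       # maximal alternation length
      even <- len - (len %% 2L)
      if (even >= 4L) {
        out[nrow(out) + 1L, ] <- list(i - 1L, i - 1L + even, x, y)
        i <- i + even
        next
      }
    }
    i <- i + 1L
  }
  out
}

composite_token <- function(x, y) paste0("@", x, "+", y)

#' Derived costs for a composite double-copy type
#'
#' For a composite type `X = xy` the distance to each original type `z` is
#' the optimal duplication-history cost of `xy` emerging from (equivalently,
#' contracting to) `z`; the distance between two composites is the alignment
#' cost of their constituent two-unit maps.  A composite duplicates at the
#' ordinary `c_dup` (one double-copy event) and indels at twice the unit
#' indel cost because it spans two physical units.
#'
#' @param x,y constituent symbols, `x != y`, both in `costs$alphabet`.
#' @param costs the original [cost_model()].
#' @param others optional character vector of other composite tokens already
#'   present (distances filled in by [transform_dataset()]).
#' @return named numeric vector of distances from `@x+y` to every original
#'   symbol.
#' @export
build_composite_costs <- function(x, y, costs, others = NULL) {
  if (identical(x, y)) stop("composite constituents must differ")
  vapply(costs$alphabet, function(z) derivation_cost(c(x, y), z, costs),
         numeric(1))
}

#' Rewrite periodic arrays over composite types
#'
#' Applies [find_xy_arrays()] to every map and replaces each detected array
#' of `2k` units by `k` composite units `@x+y`; the cost model is extended
#' with rows for every composite in use (constituent distances from
#' [build_composite_costs()], composite-composite distances from two-unit
#' alignments) and per-symbol indel weight 2 for composites.  Maps without
#' arrays are returned unchanged.  The transformation is the optional
#' double-copy heuristic; expanding every composite back to `xy` recovers
#' the original even-prefix content exactly.
#'
#' @param maps list of [mini_map()] objects.
#' @param costs a [cost_model()] over the original alphabet.
#' @return list with `maps` (transformed) and `costs` (extended model).
#' @export
transform_dataset <- function(maps, costs) {
  maps <- as_map_list(maps)
  comp <- list()  # token -> c(x, y)
  new_maps <- lapply(maps, function(m) {
    arr <- find_xy_arrays(m)
    if (nrow(arr) == 0) return(m)
    u <- m$units
    pieces <- list()
    prev <- 0L
    for (r in seq_len(nrow(arr))) {
      tok <- composite_token(arr$x[r], arr$y[r])
      comp[[tok]] <<- c(arr$x[r], arr$y[r])
      if (arr$start[r] > prev) pieces[[length(pieces) + 1]] <- u[(prev + 1L):arr$start[r]]
      k <- (arr$end[r] - arr$start[r]) / 2L
      pieces[[length(pieces) + 1]] <- rep(tok, k)
      prev <- arr$end[r]
    }
    if (prev < length(u)) pieces[[length(pieces) + 1]] <- u[(prev + 1L):length(u)]
    mini_map(m$id, unlist(pieces))
  })
  if (length(comp) == 0) return(list(maps = new_maps, costs = costs))

  toks <- names(comp)
  ab <- c(costs$alphabet, toks)
  k0 <- length(costs$alphabet); kc <- length(toks)
  d <- matrix(0, k0 + kc, k0 + kc, dimnames = list(ab, ab))
  d[seq_len(k0), seq_len(k0)] <- costs$d_M
  for (t in seq_len(kc)) {
    xy <- comp[[t]]
    d[k0 + t, seq_len(k0)] <- build_composite_costs(xy[1], xy[2], costs)
    d[seq_len(k0), k0 + t] <- d[k0 + t, seq_len(k0)]
  }
  if (kc > 1) {
    for (t in seq_len(kc - 1)) for (s in (t + 1):kc) {
      v <- align_pair(mini_map("x", comp[[t]]), mini_map("y", comp[[s]]),
                      costs)$total_cost
      d[k0 + t, k0 + s] <- v
      d[k0 + s, k0 + t] <- v
    }
  }
  wt <- c(costs$indel_weight, setNames(rep(2, kc), toks))
  list(maps = new_maps,
       costs = cost_model(d, c_dup = costs$c_dup, c_ins = costs$c_ins,
                          c_del = costs$c_del, indel_weight = wt))
}

#' Expand composite units back to their constituents
#'
#' @param m a [mini_map()] possibly containing `@x+y` composite units.
#' @return the map with every composite expanded to `x y`.
#' @export
expand_composites <- function(m) {
  u <- map_units(m)
  out <- unlist(lapply(u, function(t) {
    if (startsWith(t, "@")) {
      parts <- strsplit(sub("^@", "", t), "+", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed composite token: ", t)
      parts
    } else t
  }))
  if (inherits(m, "mini_map")) mini_map(m$id, out) else out
}
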