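#' Minimum-cost duplication history of a unit string
#'
#' Cost of deriving the unit string `s` from a single seed unit of type
#' `seed` under the single-copy model: an ordered tree of tandem duplications
#' (each node splits into two adjacent copies at cost `c_dup`) in which every
#' node may additionally mutate once at the closed mutation cost.  Because
#' `d_M_closed` already prices arbitrary mutation chains, one effective
#' mutation per node loses no generality.
#'
#' The recurrence over intervals is
#' `D(s, c) = min over c' of d_M_closed(c, c') + E(s, c')` with
#' `E(s, c') = 0` when `s` is the single unit `c'`, and for `|s| > 1`
#' `E(s, c') = min over splits s = s1 s2 of c_dup + D(s1, c') + D(s2, c')`.
#'
#' @param s unit string (character vector of symbols, or compact string).
#' @param seed seed unit symbol.
#' @param costs a [cost_model()].
#' @param events if `TRUE`, also reconstruct one optimal history (tie-break:
#'   leftmost duplication split, lexicographically smallest intermediate
#'   symbol) and attach it as attribute `"events"`, a data frame with one row
#'   per mutation or duplication event whose `cost` column sums to the
#'   returned value.
#' @return non-negative derivation cost.
#' @examples
#' cm <- default_cost_model(c("x", "y"))
#' derivation_cost("yy", "x", cm)  # mutate then duplicate: 1.5
#' @seealso [oracle_derivation_cost()] for the brute-force search oracle.
#' @export
derivation_cost <- function(s, seed, costs, events = FALSE) {
  s <- map_units(s)
  sc <- units_codes(s, costs)
  cseed <- units_codes(seed, costs)
  if (length(cseed) != 1) stop("seed must be a single unit symbol")
  D <- .cpp_deriv_table(sc, costs$d_M_closed, costs$c_dup)
  total <- D[1, length(sc), cseed]
  if (!events) return(total)
  ev <- reconstruct_history(sc, cseed, D, costs)
  attr(total, "events") <- ev
  total
}

# one optimal history from the interval table; deterministic tie-breaks
reconstruct_history <- function(sc, cseed, D, costs) {
  dc <- costs$d_M_closed
  ab <- costs$alphabet
  n <- length(sc)
  rows <- list()
  tol <- 1e-9
  # symbol order for "lexicographically smallest" ties
  lex <- order(ab)
  emit <- function(kind, i, j, from, to, cost)
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, start = i, end = j, from = from, to = to, cost = cost,
      stringsAsFactors = FALSE)
  explain <- function(i, j, c) {
    if (i == j) {
      if (sc[i] != c) emit("mutation", i, j, ab[c], ab[sc[i]], dc[c, sc[i]])
      return(invisible())
    }
    # choose intermediate symbol c2: minimal dc(c,c2) + E(i,j,c2), lex ties
    best <- Inf; bc2 <- NA_integer_
    for (c2 in lex) {
      e <- Inf
      for (k in i:(j - 1)) {
        v <- D[i, k, c2] + D[k + 1, j, c2]
        if (v < e) e <- v
      }
      v <- dc[c, c2] + costs$c_dup + e
      if (v < best - tol) { best <- v; bc2 <- c2 }
    }
    if (bc2 != c) emit("mutation", i, j, ab[c], ab[bc2], dc[c, bc2])
    # leftmost optimal split
    e <- Inf
    for (k in i:(j - 1)) {
      v <- D[i, k, bc2] + D[k + 1, j, bc2]
      if (v < e - tol) e <- v
    }
    for (k in i:(j - 1)) {
      if (D[i, k, bc2] + D[k + 1, j, bc2] < e + tol) {
        emit("duplication", i, j, ab[bc2], ab[bc2], costs$c_dup)
        explain(i, k, bc2)
        explain(k + 1, j, bc2)
        return(invisible())
      }
    }
  }
  explain(1L, n, cseed)
  if (length(rows) == 0)
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      from = character(), to = character(), cost = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Cost of generating a run as offspring of a flanking unit
#'
#' A persistent flanking unit of type `x` (its own symbol fixed by the
#' alignment column it occupies) generates the adjacent run `r` as a sequence
#' of direct-child duplication blocks, each block being the leaf string of one
#' child subtree.  For non-empty `r` this minimum equals
#' `c_dup + derivation_cost(r, x)`: merging blocks under an unmutated root
#' enumerates exactly the same splits at the same `c_dup` price per block.
#' Costs are invariant under reversal, so the left and right side differ only
#' in orientation of `r`.
#'
#' @param x flanking seed symbol.
#' @param r unit string to generate (possibly empty: cost 0).
#' @param side `"left"` if `x` flanks the run on its left, `"right"` for the
#'   mirror case (computed on the reversed run).
#' @param costs a [cost_model()].
#' @return non-negative generation cost.
#' @export
flank_generation_cost <- function(x, r, side = c("left", "right"), costs) {
  side <- match.arg(side)
  if (length(r) == 1 && !nzchar(r)) r <- character(0)
  if (length(r) == 0) return(0)
  r <- map_units(r)
  if (side == "right") r <- rev(r)
  costs$c_dup + derivation_cost(r, x, costs)
}

#' Brute-force duplication-history oracle
#'
#' Exact minimum derivation cost via uniform-cost (Dijkstra) search over unit
#' strings reachable from the single seed unit by one tandem duplication
#' (insert an adjacent copy of a unit) or one single-step mutation priced by
#' the raw `d_M` (chains of steps reproduce the min-plus closure).  Intended
#' as an independent check of [derivation_cost()] on tiny instances; guarded
#' to `|s| <= 7` and alphabets of at most 4 symbols.
#'
#' @inheritParams derivation_cost
#' @param cost_bound prune states costlier than this bound.
#' @return exact minimum derivation cost.
#' @export
oracle_derivation_cost <- function(s, seed, costs, cost_bound = Inf) {
  s <- map_units(s)
  sc <- units_codes(s, costs)
  cseed <- units_codes(seed, costs)
  sigma <- length(costs$alphabet)
  if (length(sc) > 7 || sigma > 4)
    stop("oracle guard: use derivation_cost() for |s| > 7 or more than 4 symbols")
  n <- length(sc)
  dm <- costs$d_M
  key <- function(v) paste(v, collapse = ",")
  # vector-backed priority queue: pos maps state key -> slot index;
  # settled slots get cost Inf so which.min skips them
  pos <- new.env(parent = emptyenv())
  cost_v <- 0
  state_l <- list(cseed)
  done_v <- FALSE
  assign(key(cseed), 1L, envir = pos)
  relax <- function(v, nd) {
    if (nd > cost_bound || nd > best_target) return(invisible())
    kk <- key(v)
    i <- if (exists(kk, envir = pos, inherits = FALSE))
      get(kk, envir = pos) else 0L
    if (i > 0L) {
      if (!done_v[i] && nd < cost_v[i]) cost_v[i] <<- nd
    } else {
      j <- length(cost_v) + 1L
      cost_v[j] <<- nd; state_l[[j]] <<- v; done_v[j] <<- FALSE
      assign(kk, j, envir = pos)
    }
    invisible()
  }
  best_target <- if (identical(cseed, sc)) 0 else Inf
  repeat {
    i0 <- which.min(cost_v)
    d0 <- cost_v[i0]
    if (!is.finite(d0) || d0 > best_target + 1e-12 || d0 > cost_bound) break
    st <- state_l[[i0]]
    cost_v[i0] <- Inf
    done_v[i0] <- TRUE
    if (identical(st, sc)) { best_target <- min(best_target, d0); break }
    L <- length(st)
    for (i in seq_len(L)) {
      if (L < n) relax(append(st, st[i], after = i), d0 + costs$c_dup)
      for (c2 in seq_len(sigma)) {
        if (c2 == st[i]) next
        v <- st; v[i] <- c2
        relax(v, d0 + dm[st[i], c2])
      }
    }
  }
  best_target
}
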