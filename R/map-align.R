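#' Alignment direction modes
#'
#' `"both"` lets an unmatched run be generated from either flanking inherited
#' unit; `"lr"` (left-to-right) permits generation only from the left flank;
#' `"rl"` only from the right flank.  Restricting the direction can only
#' increase the optimal cost, which is what the directional-bias counts
#' measure.
#'
#' @param mode one of `"both"`, `"lr"` (or `"left_to_right"`), `"rl"` (or
#'   `"right_to_left"`).
#' @return canonical mode string.
#' @keywords internal
align_mode <- function(mode) {
  m <- match.arg(mode, c("both", "lr", "rl", "left_to_right", "right_to_left"))
  c(both = "both", lr = "lr", rl = "rl",
    left_to_right = "lr", right_to_left = "rl")[[m]]
}

mode_code <- function(mode) c(both = 0L, lr = 1L, rl = 2L)[[align_mode(mode)]]

#' Explain one unmatched run
#'
#' Minimum cost of one maximal unmatched run `r` given its flanking matched
#' units: the run is split into a prefix generated from the left flank, an
#' indel middle, and a suffix generated from the right flank
#' (`cost = gen(left, u) + c_id * |w| + gen(right, v)` minimized over splits
#' `r = u w v`).  An absent flank forces its segment empty; a direction
#' restriction removes the opposite flank's segment; with no flank at all the
#' run is pure indel.
#'
#' @param r unit string of the run (possibly empty).
#' @param left_flank,right_flank flanking matched unit symbols, or `NULL`
#'   when the run touches a map end.
#' @param run_map_role `"A"` if the run lies in the first map (indels priced
#'   at `c_del`: units lost relative to B) or `"B"` (`c_ins`).
#' @param mode see [align_pair()].
#' @param costs a [cost_model()].
#' @return list with `cost`, and the chosen segments `gen_left`, `indel`,
#'   `gen_right` (unit-string vectors).
#' @examples
#' cm <- default_cost_model(c("x", "y"))
#' explain_run("xx", "x", "y", costs = cm)$cost  # two duplications: 1.0
#' @export
explain_run <- function(r, left_flank = NULL, right_flank = NULL,
                        run_map_role = c("A", "B"), mode = "both", costs) {
  run_map_role <- match.arg(run_map_role)
  if (length(r) == 1 && !nzchar(r)) r <- character(0)
  r <- if (length(r)) map_units(r) else character(0)
  if (is.null(left_flank) && is.null(right_flank) && length(r) == 0)
    return(list(cost = 0, gen_left = character(0), indel = character(0),
                gen_right = character(0)))
  units <- c(left_flank, r, right_flank)
  if (length(units) == 0)
    return(list(cost = 0, gen_left = character(0), indel = character(0),
                gen_right = character(0)))
  codes <- units_codes(units, costs)
  wt <- units_weights(units, costs)
  p <- if (is.null(left_flank)) 0L else 1L
  i <- p + length(r) + 1L
  cid <- if (run_map_role == "A") costs$c_del else costs$c_ins
  res <- .cpp_run_explain(codes, costs$d_M_closed, costs$c_dup, cid, wt,
                          mode_code(mode), p, i)
  off <- p  # run occupies positions p+1 .. p+length(r) in `units`
  seg <- function(from, to) if (from > to) character(0) else units[from:to]
  list(cost = res$cost,
       gen_left = seg(off + 1, res$x),
       indel = seg(res$x + 1, res$y),
       gen_right = seg(res$y + 1, off + length(r)))
}

#' Optimal pairwise map alignment
#'
#' Finds the minimum-cost monotone matching between two maps.  Matched pairs
#' cost the closed mutation distance of their symbols; every maximal
#' unmatched run is explained by [explain_run()] with the map's own nearest
#' matched units as flanks (absent at map ends); the alignment with no
#' matches at all (both maps fully indel-priced) is included as a candidate.
#' Ties are broken deterministically: maximal number of matches, then
#' leftmost matches.
#'
#' @param A,B [mini_map()] objects (or unit strings, given ids `"A"`/`"B"`).
#' @param costs a [cost_model()]; all units must belong to its alphabet.
#' @param mode `"both"`, `"lr"` or `"rl"` duplication direction.
#' @return an object of class `map_alignment`: list with `map_a`, `map_b`,
#'   `matches` (data frame `a_pos`, `b_pos`, `cost`), `runs` (data frame with
#'   the run interval, chosen split, seed positions and cost), `total_cost`
#'   and `mode`.
#' @examples
#' cm <- default_cost_model(c("a", "b"))
#' align_pair(mini_map("m1", "ab"), mini_map("m2", "abb"), cm)$total_cost  # 0.5
#' @export
align_pair <- function(A, B, costs, mode = "both") {
  if (!inherits(A, "mini_map")) A <- mini_map("A", A)
  if (!inherits(B, "mini_map")) B <- mini_map("B", B)
  ca <- units_codes(A$units, costs)
  cb <- units_codes(B$units, costs)
  res <- .cpp_align_pair(ca, cb, costs$d_M_closed, costs$c_dup, costs$c_ins,
                         costs$c_del, units_weights(A$units, costs),
                         units_weights(B$units, costs), mode_code(mode))
  matches <- data.frame(a_pos = res$matches[, 1], b_pos = res$matches[, 2],
                        cost = res$match_costs)
  runs <- data.frame(
    map = c("A", "B")[res$run_map], start = res$run_start, end = res$run_end,
    gen_left_end = res$run_x, indel_end = res$run_y,
    left_seed = res$run_lf, right_seed = res$run_rf, cost = res$run_cost,
    stringsAsFactors = FALSE)
  structure(
    list(map_a = A, map_b = B, matches = matches, runs = runs,
         total_cost = res$total, mode = align_mode(mode)),
    class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(render_alignment(x), sep = "\n")
  invisible(x)
}

#' All pairwise alignment costs
#'
#' @param maps list of [mini_map()] objects with unique ids.
#' @param costs a [cost_model()].
#' @param mode see [align_pair()].
#' @param normalize divide each pairwise cost by the summed map lengths
#'   (`|A| + |B|`); raw costs by default.
#' @return symmetric numeric matrix with zero diagonal, dimnames = map ids.
#' @export
all_pairwise <- function(maps, costs, mode = "both", normalize = FALSE) {
  maps <- as_map_list(maps)
  if (length(maps) < 2) stop("need at least 2 maps")
  codes <- lapply(maps, function(m) units_codes(m$units, costs))
  wts <- lapply(maps, function(m) units_weights(m$units, costs))
  d <- .cpp_pairwise(codes, costs$d_M_closed, costs$c_dup, costs$c_ins,
                     costs$c_del, wts, mode_code(mode))
  dimnames(d) <- list(names(maps), names(maps))
  if (normalize) {
    len <- vapply(maps, function(m) length(m$units), numeric(1))
    d <- d / outer(len, len, `+`)
    diag(d) <- 0
  }
  d
}

#' Text rendering of a map alignment
#'
#' Two rows with matched units in the same column and `-` opposite unmatched
#' units, followed by one `arc` record per duplication-generated segment
#' (`seed position -> generated interval`, 0-based half-open) and one
#' `indel` record per indel segment.
#'
#' @param a a `map_alignment`.
#' @return character vector of lines.
#' @export
render_alignment <- function(a) {
  stopifnot(inherits(a, "map_alignment"))
  cols <- alignment_columns(a)
  toka <- ifelse(is.na(cols$a_pos), "-", a$map_a$units[cols$a_pos])
  tokb <- ifelse(is.na(cols$b_pos), "-", a$map_b$units[cols$b_pos])
  w <- pmax(nchar(toka), nchar(tokb))
  fmt <- paste0("%-", w, "s")
  out <- c(
    sprintf("# alignment %s vs %s  cost=%g  mode=%s", a$map_a$id, a$map_b$id,
            a$total_cost, a$mode),
    paste0(a$map_a$id, ": ",
           paste(mapply(sprintf, fmt, toka, USE.NAMES = FALSE), collapse = " ")),
    paste0(a$map_b$id, ": ",
           paste(mapply(sprintf, fmt, tokb, USE.NAMES = FALSE), collapse = " ")))
  if (nrow(a$runs)) {
    for (r in seq_len(nrow(a$runs))) {
      rn <- a$runs[r, ]
      mp <- rn$map
      if (rn$gen_left_end >= rn$start)
        out <- c(out, sprintf("arc %s:%d -> %s:[%d,%d)", mp, rn$left_seed - 1L,
                              mp, rn$start - 1L, rn$gen_left_end))
      if (rn$indel_end >= rn$gen_left_end + 1)
        out <- c(out, sprintf("indel %s:[%d,%d)", mp, rn$gen_left_end,
                              rn$indel_end))
      if (rn$end >= rn$indel_end + 1)
        out <- c(out, sprintf("arc %s:%d -> %s:[%d,%d)", mp, rn$right_seed - 1L,
                              mp, rn$indel_end, rn$end))
    }
  }
  out
}

# Column decomposition shared by rendering and pivot points.  Columns appear
# in map order; between two matches the unmatched units of A precede those of
# B; each run's cost is spread uniformly over its units.
alignment_columns <- function(a) {
  stopifnot(inherits(a, "map_alignment"))
  n <- length(a$map_a$units); m <- length(a$map_b$units)
  k <- nrow(a$matches)
  run_unit_cost <- function(map, pos) {
    for (r in seq_len(nrow(a$runs))) {
      rn <- a$runs[r, ]
      if (rn$map == map && pos >= rn$start && pos <= rn$end)
        return(rn$cost / (rn$end - rn$start + 1))
    }
    stop("internal: unmatched position not covered by any run")
  }
  rows <- list()
  add <- function(a_pos, b_pos, cost)
    rows[[length(rows) + 1]] <<- c(a_pos, b_pos, cost)
  pa <- 0L; pb <- 0L
  bounds_a <- c(a$matches$a_pos, n + 1L)
  bounds_b <- c(a$matches$b_pos, m + 1L)
  for (t in seq_len(k + 1L)) {
    na <- bounds_a[t]; nb <- bounds_b[t]
    if (na - pa - 1L > 0) for (p in (pa + 1L):(na - 1L))
      add(p, NA, run_unit_cost("A", p))
    if (nb - pb - 1L > 0) for (p in (pb + 1L):(nb - 1L))
      add(NA, p, run_unit_cost("B", p))
    if (t <= k) add(na, nb, a$matches$cost[t])
    pa <- na; pb <- nb
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("a_pos", "b_pos", "cost")
  df$a_consumed <- cumsum(!is.na(df$a_pos))
  df$b_consumed <- cumsum(!is.na(df$b_pos))
  df
}
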