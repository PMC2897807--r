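#' Pivot point of an alignment
#'
#' The normalized location at which half of the alignment's optimal cost has
#' accumulated.  Columns (matched pairs and unmatched run units, in map
#' order; a run's cost spread uniformly over its units) are scanned left to
#' right; the pivot column is the first whose cumulative cost reaches half
#' the total, and the value returned is the mean of the two maps' normalized
#' consumed-unit positions at that column.  Variation concentrated at the 3'
#' end pushes the pivot above 0.5, at the 5' end below.
#'
#' @param a a `map_alignment` from [align_pair()].
#' @return value in `[0, 1]`, or `NA` for a zero-cost (identical-map)
#'   alignment, which carries no location information.
#' @export
pivot_point <- function(a) {
  stopifnot(inherits(a, "map_alignment"))
  if (a$total_cost <= 1e-12) return(NA_real_)
  cols <- alignment_columns(a)
  cum <- cumsum(cols$cost)
  idx <- which(cum >= a$total_cost / 2 - 1e-12)[1]
  n <- length(a$map_a$units); m <- length(a$map_b$units)
  mean(c(cols$a_consumed[idx] / n, cols$b_consumed[idx] / m))
}

#' Shuffle the units of a map
#'
#' Uniform random permutation of the unit sequence (same multiset, same
#' length); uses R's random number generator, so results are reproducible
#' under [set.seed()] / `withr::with_seed()`.
#'
#' @param m a [mini_map()].
#' @return a shuffled [mini_map()] with the same id.
#' @export
shuffle_map <- function(m) {
  stopifnot(inherits(m, "mini_map"))
  mini_map(m$id, m$units[sample.int(length(m$units))])
}

#' Modular structure of a map
#'
#' Collapses every maximal run of equal adjacent units to a single unit
#' (e.g. `aaabbc` becomes `abc`).  Transitions between unit types are kept,
#' which is what carries the duplication-direction signal; the reduction is
#' idempotent.
#'
#' @param m a [mini_map()] or unit string.
#' @return object of the same kind with runs collapsed.
#' @export
modular_structure <- function(m) {
  u <- map_units(m)
  keep <- c(TRUE, u[-1] != u[-length(u)])
  if (inherits(m, "mini_map")) mini_map(m$id, u[keep]) else u[keep]
}

#' Equal-width histogram
#'
#' `bins` equal-width bins over `[lo, hi]`; bin membership follows the
#' half-open convention `[edge, next_edge)` with the last bin right-closed;
#' out-of-range values are clamped into the end bins.  An empty input gives
#' all-zero counts.
#'
#' @param values numeric vector (NAs dropped).
#' @param lo,hi range, `lo < hi`.
#' @param bins number of bins, at least 1.
#' @return list with `edges` (length `bins + 1`) and integer `counts`.
#' @export
map_histogram <- function(values, lo = 0, hi = 1, bins = 20) {
  if (bins < 1) stop("bins must be >= 1")
  if (!(lo < hi)) stop("lo must be < hi")
  edges <- seq(lo, hi, length.out = bins + 1)
  values <- values[!is.na(values)]
  counts <- integer(bins)
  if (length(values)) {
    idx <- floor((values - lo) / (hi - lo) * bins) + 1
    idx <- pmin(pmax(idx, 1), bins)
    tab <- tabulate(idx, nbins = bins)
    counts <- as.integer(tab)
  }
  list(edges = edges, counts = counts)
}

#' Scramble test for polar structural variation
#'
#' Computes the pivot point of every pairwise alignment of the dataset, then
#' repeats the computation on `iterations` randomized datasets in which the
#' units of every map are shuffled, and bins both sets of pivots into
#' histograms over `[0, 1]`.  Structure-free data yield pivots centred near
#' 0.5; variability concentrated at one map end shifts the real histogram
#' toward that end.
#'
#' @param maps list of [mini_map()] objects (at least 2).
#' @param costs a [cost_model()].
#' @param iterations number of scramble replicates (>= 1).
#' @param seed optional integer seed making the replicates reproducible.
#' @param bins histogram bins over `[0, 1]`.
#' @param mode see [align_pair()].
#' @return object of class `pivot_result`: `real_pivots`, `random_pivots`
#'   (list, one vector per replicate), `histograms` (data frame `bin_lo`,
#'   `bin_hi`, `count_real`, `count_random`), `n_skipped` (zero-cost pairs),
#'   plus the parameters used.
#' @export
structural_variation_test <- function(maps, costs, iterations = 2, seed = NULL,
                                      bins = 20, mode = "both") {
  maps <- as_map_list(maps)
  if (length(maps) < 2) stop("need at least 2 maps")
  if (iterations < 1) stop("iterations must be >= 1")
  run <- function() {
    real <- dataset_pivots(maps, costs, mode)
    rand <- lapply(seq_len(iterations), function(it)
      dataset_pivots(lapply(maps, shuffle_map), costs, mode))
    list(real = real, rand = rand)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  hr <- map_histogram(res$real$pivots, 0, 1, bins)
  hv <- map_histogram(unlist(lapply(res$rand, `[[`, "pivots")), 0, 1, bins)
  structure(
    list(real_pivots = res$real$pivots,
         random_pivots = lapply(res$rand, `[[`, "pivots"),
         histograms = data.frame(bin_lo = hr$edges[-(bins + 1)],
                                 bin_hi = hr$edges[-1],
                                 count_real = hr$counts,
                                 count_random = hv$counts),
         n_skipped = res$real$n_skipped,
         iterations = iterations, seed = seed, bins = bins, mode = mode),
    class = "pivot_result")
}

dataset_pivots <- function(maps, costs, mode) {
  ids <- names(maps)
  n <- length(maps)
  piv <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- pivot_point(align_pair(maps[[i]], maps[[j]], costs, mode))
    if (is.na(p)) skipped <- skipped + 1L else piv <- c(piv, p)
  }
  list(pivots = piv, n_skipped = skipped)
}

#' @export
print.pivot_result <- function(x, ...) {
  cat(sprintf("<pivot_result> %d informative pairs (%d zero-cost skipped), %d scramble replicate(s)\n",
              length(x$real_pivots), x$n_skipped, x$iterations))
  cat(sprintf("  mean real pivot   %.3f\n", mean(x$real_pivots)))
  rp <- unlist(x$random_pivots)
  if (length(rp)) cat(sprintf("  mean random pivot %.3f\n", mean(rp)))
  invisible(x)
}

#' Directional-bias counts
#'
#' Aligns every pair three times -- both duplication directions allowed,
#' left-to-right only, right-to-left only -- and counts the pairs whose
#' restricted cost strictly exceeds the unrestricted optimum: `E_l` for the
#' left-to-right restriction, `E_r` for right-to-left.  The normalized bias
#' `E_n = (E_l - E_r) / (E_l + E_r)` approaches +1 when right-to-left
#' duplications alone explain the data (so forbidding them hurts), -1 for
#' the mirror case, and 0 without directional preference.
#'
#' @param maps list of [mini_map()] objects (at least 2).
#' @param costs a [cost_model()].
#' @param tol strict-inequality tolerance on costs.
#' @return a [bias_result()].
#' @export
directional_bias_counts <- function(maps, costs, tol = 1e-9) {
  maps <- as_map_list(maps)
  if (length(maps) < 2) stop("need at least 2 maps")
  d_both <- all_pairwise(maps, costs, mode = "both")
  d_lr <- all_pairwise(maps, costs, mode = "lr")
  d_rl <- all_pairwise(maps, costs, mode = "rl")
  up <- upper.tri(d_both)
  bias_result(E_l = sum(d_lr[up] > d_both[up] + tol),
              E_r = sum(d_rl[up] > d_both[up] + tol))
}

#' Construct a directional-bias result from counts
#'
#' @param E_l,E_r non-negative counts of pairs whose left-to-right-only /
#'   right-to-left-only alignment cost exceeds the unrestricted optimum.
#' @param replicate_E_n optional numeric vector of scramble-replicate E_n
#'   values.
#' @return object of class `bias_result` with fields `E_l`, `E_r`, `E_n`
#'   (`(E_l - E_r) / (E_l + E_r)`, or 0 when both counts are 0).
#' @examples
#' bias_result(876, 0)$E_n   # +1: right-to-left duplications preferred
#' @export
bias_result <- function(E_l, E_r, replicate_E_n = NULL) {
  if (E_l < 0 || E_r < 0 || E_l != round(E_l) || E_r != round(E_r))
    stop("E_l and E_r must be non-negative integers")
  E_n <- if (E_l + E_r > 0) (E_l - E_r) / (E_l + E_r) else 0
  structure(list(E_l = as.integer(E_l), E_r = as.integer(E_r), E_n = E_n,
                 replicate_E_n = replicate_E_n),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("<bias_result> E_l=%d  E_r=%d  E_n=%+.4f\n", x$E_l, x$E_r, x$E_n))
  if (!is.null(x$replicate_E_n))
    cat(sprintf("  %d scramble replicates, mean E_n %+.4f\n",
                length(x$replicate_E_n), mean(x$replicate_E_n)))
  invisible(x)
}

#' Scramble test for duplication-direction bias
#'
#' Computes the directional-bias counts of the real dataset and of
#' `iterations` randomized datasets (units shuffled within each map).  By
#' default every dataset -- real and scrambled alike -- is first reduced to
#' its modular structure, the approximation that keeps the type transitions
#' carrying the direction signal while shortening the maps considerably.
#'
#' @inheritParams structural_variation_test
#' @param use_modular reduce maps via [modular_structure()] (default on).
#' @param bins histogram bins over `[-1, 1]`.
#' @return a [bias_result()] with `replicate_E_n`, plus `histograms` (data
#'   frame over `[-1, 1]` with the real E_n and replicate counts), `seed`,
#'   `iterations`, `use_modular`.
#' @export
directional_bias_test <- function(maps, costs, iterations = 25, seed = NULL,
                                  use_modular = TRUE, bins = 20) {
  maps <- as_map_list(maps)
  if (length(maps) < 2) stop("need at least 2 maps")
  if (iterations < 1) stop("iterations must be >= 1")
  reduce <- function(ms) if (use_modular) lapply(ms, modular_structure) else ms
  run <- function() {
    real <- directional_bias_counts(reduce(maps), costs)
    reps <- vapply(seq_len(iterations), function(it) {
      directional_bias_counts(reduce(lapply(maps, shuffle_map)), costs)$E_n
    }, numeric(1))
    list(real = real, reps = reps)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  h <- map_histogram(res$reps, -1, 1, bins)
  out <- bias_result(res$real$E_l, res$real$E_r, replicate_E_n = res$reps)
  out$histograms <- data.frame(bin_lo = h$edges[-(bins + 1)],
                               bin_hi = h$edges[-1],
                               count_random = h$counts)
  out$seed <- seed
  out$iterations <- iterations
  out$use_modular <- use_modular
  out
}
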