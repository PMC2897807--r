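#' Simulation parameters for map evolution
#'
#' Describes a lineage-evolution process over the model's event types.  Each
#' of `n_events` steps draws an event: a tandem duplication (probability
#' `p_dup`), a unit mutation (`p_mut`) or an insertion/deletion (`p_indel`).
#'
#' A duplication picks a template unit and inserts a fresh copy adjacent to
#' it: on the template's left with probability `beta` (a right-to-left
#' origin -- the new unit's template is its right neighbour) or on its right
#' otherwise.  Tandem expansion in vivo is burst-like (replication slippage
#' and unequal exchange repeatedly fire at a hotspot), so with probability
#' `burst` a duplication uses the copy created by the immediately preceding
#' duplication as its template instead of drawing a fresh uniform one; a
#' tract then grows in the `beta` direction, drifting stepwise away from its
#' inherited seed whenever a copy mutates.  Because an
#' unmutated single-unit copy is the same string whichever side it lands on,
#' the fresh copy immediately mutates with probability `dup_mut` (the
#' duplication-followed-by-mutation arc of the model); together with burst
#' growth this is what makes the direction parameter observable in the
#' resulting maps.  Mutation events pick a position with probability
#' proportional to `rank^(mut_end_bias - 1)` (rank = 1-based position): 1
#' is uniform, larger values skew variation toward the 3' (right) end.  Unit types arise from
#' point mutations of similar repeat sequences, so a mutating unit steps to
#' a *neighbouring* symbol in alphabet order (uniformly left or right,
#' clamped at the ends); the matching graded cost matrix is
#' [gradient_cost_model()].  Indels insert a uniform symbol at a uniform
#' slot or delete a uniform unit (never emptying the map).
#'
#' @param alphabet character vector of unit symbols.
#' @param root root map: unit string every lineage starts from.
#' @param n_events events per lineage.
#' @param p_dup,p_mut,p_indel event-type probabilities, summing to 1.
#' @param beta probability that a duplication places the copy to the left of
#'   its template (right-to-left origin); 0.5 is direction-neutral.
#' @param mut_end_bias position skew for mutations, `>= 1`; 1 is uniform.
#' @param dup_mut probability that a duplication's fresh copy immediately
#'   mutates.
#' @param burst probability that a duplication re-uses the previous
#'   duplication's template (hotspot persistence); any intervening mutation
#'   or indel event ends the burst.
#' @param seed optional master seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(alphabet, root, n_events = 30, p_dup = 0.8,
                       p_mut = 0.1, p_indel = 0.1, beta = 0.5,
                       mut_end_bias = 1, dup_mut = 0.1, burst = 0.85,
                       seed = NULL) {
  alphabet <- as.character(alphabet)
  check_symbols(alphabet)
  root <- map_units(root)
  if (!all(root %in% alphabet)) stop("root units must belong to the alphabet")
  p <- c(p_dup, p_mut, p_indel)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("p_dup, p_mut, p_indel must be non-negative and sum to 1")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (mut_end_bias < 1) stop("mut_end_bias must be >= 1")
  if (dup_mut < 0 || dup_mut > 1) stop("dup_mut must be in [0, 1]")
  if (burst < 0 || burst > 1) stop("burst must be in [0, 1]")
  if (n_events < 1) stop("n_events must be >= 1")
  structure(list(alphabet = alphabet, root = root, n_events = n_events,
                 p_dup = p_dup, p_mut = p_mut, p_indel = p_indel,
                 beta = beta, mut_end_bias = mut_end_bias, dup_mut = dup_mut,
                 burst = burst, seed = seed),
            class = "sim_params")
}

#' Evolve one map lineage
#'
#' Applies `params$n_events` random events to the root map; see
#' [sim_params()] for the event semantics.  Deterministic for a fixed
#' `params$seed`.
#'
#' @param params a [sim_params()].
#' @param id map identifier.
#' @param trace if `TRUE`, attach the event log as attribute `"events"`.
#' @return a [mini_map()].
#' @export
evolve_map <- function(params, id = "sim", trace = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  run <- function() evolve_map_impl(params, id, trace)
  if (is.null(params$seed)) run() else withr::with_seed(params$seed, run())
}

evolve_map_impl <- function(params, id, trace) {
  ab <- params$alphabet
  sigma <- length(ab)
  u <- params$root
  other <- function(sym) {
    if (sigma == 1) return(sym)
    i <- match(sym, ab)
    nb <- c(if (i > 1) i - 1L, if (i < sigma) i + 1L)
    ab[if (length(nb) == 1) nb else sample(nb, 1)]
  }
  log <- if (trace) vector("list", params$n_events) else NULL
  hot <- NA_integer_       # copy made by the previous duplication (hotspot)
  hot_left <- NA           # direction of the current burst
  for (ev in seq_len(params$n_events)) {
    kind <- sample(c("dup", "mut", "indel"), 1,
                   prob = c(params$p_dup, params$p_mut, params$p_indel))
    L <- length(u)
    if (kind == "dup") {
      continue_burst <- !is.na(hot) && stats::runif(1) < params$burst
      t <- if (continue_burst) hot else sample.int(L, 1)
      # a burst keeps the direction drawn at its initiation
      to_left <- if (continue_burst) hot_left
                 else stats::runif(1) < params$beta
      copy <- u[t]
      mutated <- stats::runif(1) < params$dup_mut
      if (mutated) copy <- other(copy)
      u <- if (to_left) append(u, copy, after = t - 1L)
           else append(u, copy, after = t)
      hot <- if (to_left) t else t + 1L  # the burst continues from the new copy
      hot_left <- to_left
      if (trace) log[[ev]] <- data.frame(
        event = "dup", pos = t,
        origin = if (to_left) "right_neighbor" else "left_neighbor",
        symbol = copy, mutated = mutated, stringsAsFactors = FALSE)
    } else if (kind == "mut") {
      hot <- NA_integer_
      w <- seq_len(L)^(params$mut_end_bias - 1)
      t <- sample.int(L, 1, prob = w)
      sym <- other(u[t])
      u[t] <- sym
      if (trace) log[[ev]] <- data.frame(
        event = "mut", pos = t, origin = NA_character_, symbol = sym,
        mutated = TRUE, stringsAsFactors = FALSE)
    } else {
      hot <- NA_integer_
      do_insert <- L == 1 || stats::runif(1) < 0.5
      if (do_insert) {
        slot <- sample.int(L + 1L, 1) - 1L
        sym <- sample(ab, 1)
        u <- append(u, sym, after = slot)
        if (trace) log[[ev]] <- data.frame(
          event = "ins", pos = slot + 1L, origin = NA_character_, symbol = sym,
          mutated = FALSE, stringsAsFactors = FALSE)
      } else {
        t <- sample.int(L, 1)
        sym <- u[t]
        u <- u[-t]
        if (trace) log[[ev]] <- data.frame(
          event = "del", pos = t, origin = NA_character_, symbol = sym,
          mutated = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  m <- mini_map(id, u)
  if (trace) attr(m, "events") <- do.call(rbind, log)
  m
}

#' Simulate a dataset of independent lineages
#'
#' Evolves `n_maps` independent lineages from the shared root; per-lineage
#' sub-seeds are drawn deterministically from the master seed, so the whole
#' dataset is reproducible bit for bit.
#'
#' @param params a [sim_params()] (its `seed` is the master seed).
#' @param n_maps number of maps (>= 2).
#' @return list of [mini_map()] objects with ids `sim_000`, `sim_001`, ...
#' @export
simulate_dataset <- function(params, n_maps) {
  stopifnot(inherits(params, "sim_params"))
  if (n_maps < 2) stop("n_maps must be >= 2")
  draw <- function() sample.int(2147483646L, n_maps)
  seeds <- if (is.null(params$seed)) draw()
           else withr::with_seed(params$seed, draw())
  maps <- lapply(seq_len(n_maps), function(k) {
    p <- params
    p$seed <- seeds[k]
    evolve_map(p, id = sprintf("sim_%03d", k - 1L))
  })
  as_map_list(maps)
}
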