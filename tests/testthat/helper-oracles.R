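# Brute-force oracles independent of the package's dynamic programs.
#
# Generation costs come from oracle_derivation_cost() (uniform-cost search
# over duplication/mutation moves) combined over explicit block partitions;
# alignments are enumerated over all monotone matchings with exhaustive
# run-split enumeration.  Only usable for tiny instances.

# memoised oracle generation cost of string r as offspring of seed x
make_oracle_gen <- function(cm) {
  cache <- new.env(parent = emptyenv())
  function(x, r) {
    if (length(r) == 0) return(0)
    key <- paste(c(x, "|", r), collapse = " ")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n <- length(r)
    # min over partitions of r into consecutive non-empty blocks
    best <- Inf
    parts <- function(i, acc) {
      if (i > n) { best <<- min(best, acc); return(invisible()) }
      if (acc >= best) return(invisible())
      for (j in i:n)
        parts(j + 1, acc + cm$c_dup +
                oracle_derivation_cost(r[i:j], x, cm, cost_bound = best))
      invisible()
    }
    parts(1, 0)
    cache[[key]] <- best
    best
  }
}

# run explanation cost by exhaustive split enumeration
oracle_run_cost <- function(r, lf, rf, role, mode, cm, gen) {
  n <- length(r)
  cid <- if (role == "A") cm$c_del else cm$c_ins
  best <- Inf
  for (a in 0:n) for (b in a:n) {
    u <- if (a >= 1) r[1:a] else character(0)
    w <- if (b >= a + 1) r[(a + 1):b] else character(0)
    v <- if (b < n) r[(b + 1):n] else character(0)
    if (length(u) > 0 && (is.null(lf) || mode == "rl")) next
    if (length(v) > 0 && (is.null(rf) || mode == "lr")) next
    cost <- cid * length(w) +
      (if (length(u)) gen(lf, u) else 0) +
      (if (length(v)) gen(rf, v) else 0)
    best <- min(best, cost)
  }
  best
}

# all monotone matchings (k positions of n against k of m, order-preserving)
monotone_matchings <- function(n, m) {
  out <- list(list(a = integer(0), b = integer(0)))
  for (k in seq_len(min(n, m))) {
    ca <- utils::combn(n, k, simplify = FALSE)
    cb <- utils::combn(m, k, simplify = FALSE)
    for (ia in ca) for (ib in cb)
      out[[length(out) + 1]] <- list(a = ia, b = ib)
  }
  out
}

# brute-force optimal alignment cost
oracle_align_cost <- function(ua, ub, cm, mode = "both", gen = NULL,
                              matchings = NULL) {
  if (is.null(gen)) gen <- make_oracle_gen(cm)
  n <- length(ua); m <- length(ub)
  if (is.null(matchings)) matchings <- monotone_matchings(n, m)
  dc <- cm$d_M_closed
  best <- Inf
  for (mt in matchings) {
    k <- length(mt$a)
    cost <- if (k) sum(dc[cbind(match(ua[mt$a], cm$alphabet),
                                match(ub[mt$b], cm$alphabet))]) else 0
    if (cost >= best) next
    runs_of <- function(u, pos, role) {
      bnds <- c(0L, pos, length(u) + 1L)
      tot <- 0
      for (t in seq_len(length(pos) + 1L)) {
        lo <- bnds[t] + 1L; hi <- bnds[t + 1L] - 1L
        if (lo > hi) next
        lf <- if (bnds[t] >= 1L) u[bnds[t]] else NULL
        rf <- if (bnds[t + 1L] <= length(u)) u[bnds[t + 1L]] else NULL
        tot <- tot + oracle_run_cost(u[lo:hi], lf, rf, role, mode, cm, gen)
      }
      tot
    }
    cost <- cost + runs_of(ua, mt$a, "A") + runs_of(ub, mt$b, "B")
    best <- min(best, cost)
  }
  best
}
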