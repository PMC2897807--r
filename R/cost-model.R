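#' Evolution-model costs for minisatellite maps
#'
#' A cost model holds the unit alphabet, the symmetric unit-mutation cost
#' matrix `d_M`, its min-plus (shortest mutation chain) closure `d_M_closed`,
#' and the positive event costs for duplication, insertion and deletion.  All
#' dynamic programs in the package price a mutation with the closed matrix, so
#' a chain of unit mutations is always charged its cheapest multi-step cost
#' even for non-metric user matrices.
#'
#' Unit symbols are opaque tokens (e.g. `"a"`, `"4a"`); they may be longer
#' than one character, must contain no whitespace, and must not start with
#' `"@"`, which is reserved for composite double-copy types.
#'
#' @param d_M square numeric matrix with identical row/column names (the
#'   alphabet), symmetric, zero diagonal, non-negative entries.
#' @param c_dup,c_ins,c_del positive event costs.  The model convention is
#'   `c_dup` below the mutation and indel costs, so that duplication is the
#'   preferred explanation of repeat expansion.
#' @param indel_weight optional named numeric vector of per-symbol indel
#'   weights (defaults to 1; composite double-copy symbols use 2 because they
#'   span two physical units).
#' @return an object of class `cost_model`.
#' @examples
#' cm <- default_cost_model(c("a", "b", "c"))
#' cm$d_M_closed
#' @export
cost_model <- function(d_M, c_dup = 0.5, c_ins = 1.5, c_del = 1.5,
                       indel_weight = NULL) {
  if (!is.matrix(d_M) || nrow(d_M) != ncol(d_M))
    stop("d_M must be a square matrix")
  alphabet <- rownames(d_M)
  if (is.null(alphabet) || !identical(alphabet, colnames(d_M)))
    stop("d_M must carry identical row and column names (the alphabet)")
  check_symbols(alphabet, allow_composite = TRUE)
  if (anyDuplicated(alphabet)) stop("duplicate symbols in alphabet")
  if (any(d_M < 0)) stop("d_M entries must be non-negative")
  if (any(abs(d_M - t(d_M)) > 1e-9)) stop("d_M must be symmetric")
  if (any(abs(diag(d_M)) > 1e-12)) stop("d_M must have a zero diagonal")
  for (v in c(c_dup = c_dup, c_ins = c_ins, c_del = c_del))
    if (!is.finite(v) || v <= 0)
      stop("duplication, insertion and deletion costs must be positive")
  if (is.null(indel_weight)) {
    indel_weight <- setNames(rep(1, length(alphabet)), alphabet)
  } else {
    if (!all(alphabet %in% names(indel_weight)))
      stop("indel_weight must name every alphabet symbol")
    indel_weight <- indel_weight[alphabet]
  }
  structure(
    list(alphabet = alphabet, d_M = d_M,
         d_M_closed = close_mutation_costs(d_M),
         c_dup = c_dup, c_ins = c_ins, c_del = c_del,
         indel_weight = indel_weight),
    class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("<cost_model> %d symbols: %s\n", length(x$alphabet),
              paste(x$alphabet, collapse = " ")))
  cat(sprintf("  c_dup=%g  c_ins=%g  c_del=%g\n", x$c_dup, x$c_ins, x$c_del))
  if (any(x$indel_weight != 1)) cat("  (per-symbol indel weights present)\n")
  invisible(x)
}

check_symbols <- function(tokens, allow_composite = FALSE) {
  if (length(tokens) == 0) stop("empty alphabet")
  bad <- !nzchar(tokens) | grepl("[[:space:]]", tokens)
  if (any(bad)) stop("unit symbols must be non-empty and contain no whitespace: ",
                     paste(unique(tokens[bad]), collapse = ", "))
  if (!allow_composite && any(startsWith(tokens, "@")))
    stop("the \"@\" prefix is reserved for composite double-copy symbols")
  invisible(tokens)
}

#' Min-plus closure of a mutation cost matrix
#'
#' All-pairs cheapest mutation chains (Floyd-Warshall in min-plus algebra).
#' Idempotent; never increases an entry; the result satisfies the triangle
#' inequality.
#'
#' @param d_M symmetric non-negative matrix with zero diagonal.
#' @return matrix of the same shape.
#' @export
close_mutation_costs <- function(d_M) {
  if (!is.matrix(d_M) || nrow(d_M) != ncol(d_M)) stop("d_M must be square")
  d <- d_M
  for (k in seq_len(nrow(d)))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

#' Default cost model over an alphabet
#'
#' Unit mutation cost 1 between any two distinct symbols, duplication 0.5,
#' insertion and deletion 1.5.  These defaults respect the model ordering
#' duplication < mutation <= indel; they are configuration, not constants of
#' the method.
#'
#' @param alphabet character vector of unit symbols.
#' @return a [cost_model()].
#' @export
default_cost_model <- function(alphabet) {
  alphabet <- as.character(alphabet)
  check_symbols(alphabet)
  k <- length(alphabet)
  d <- matrix(1, k, k, dimnames = list(alphabet, alphabet))
  diag(d) <- 0
  cost_model(d)
}

#' Graded cost model over an ordered alphabet
#'
#' Unit types derived from similar repeat sequences are cheap to exchange,
#' distant ones expensive: the mutation cost between the i-th and j-th
#' symbol is `step * |i - j|` (a metric, so it is its own closure).  This is
#' the natural model when the alphabet is ordered by unit-sequence
#' similarity, and it is what makes duplication direction identifiable --
#' with a uniform matrix every possible seed explains a diverged run equally
#' well.
#'
#' @inheritParams default_cost_model
#' @param step mutation cost between adjacent symbols.
#' @inheritParams cost_model
#' @return a [cost_model()].
#' @export
gradient_cost_model <- function(alphabet, step = 1, c_dup = 0.5,
                                c_ins = 1.5, c_del = 1.5) {
  alphabet <- as.character(alphabet)
  check_symbols(alphabet)
  k <- length(alphabet)
  d <- step * abs(outer(seq_len(k), seq_len(k), `-`))
  dimnames(d) <- list(alphabet, alphabet)
  cost_model(d, c_dup = c_dup, c_ins = c_ins, c_del = c_del)
}

#' Read a cost file
#'
#' Cost files are TSV: a header line `units<TAB>s1<TAB>...<TAB>sk`, then k
#' matrix rows `si<TAB>v1<TAB>...<TAB>vk`, then three lines
#' `duplication<TAB>x`, `insertion<TAB>x`, `deletion<TAB>x`.  Lines starting
#' with `#` are ignored.  Fields may equally be separated by runs of spaces.
#'
#' @param file path to a cost file, or `NULL` when `text` is given.
#' @param text cost-file content as a single string or character vector.
#' @return a [cost_model()].
#' @export
read_cost_file <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either file or text must be given")
    text <- readLines(file, warn = FALSE)
  } else if (length(text) == 1) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  keep <- !grepl("^\\s*(#|$)", text)
  lineno <- which(keep)
  rows <- lapply(text[keep], function(l) strsplit(trimws(l), "[\t ]+")[[1]])
  if (length(rows) == 0) stop("cost file is empty")
  hdr <- rows[[1]]
  if (hdr[1] != "units" || length(hdr) < 2)
    stop(sprintf("line %d: expected header 'units<TAB>s1...'", lineno[1]))
  alphabet <- hdr[-1]
  k <- length(alphabet)
  if (length(rows) != 1 + k + 3)
    stop(sprintf("expected %d matrix rows plus duplication/insertion/deletion lines, found %d content lines",
                 k, length(rows) - 1))
  d <- matrix(NA_real_, k, k, dimnames = list(alphabet, alphabet))
  for (r in seq_len(k)) {
    row <- rows[[1 + r]]
    ln <- lineno[1 + r]
    if (row[1] != alphabet[r])
      stop(sprintf("line %d: matrix row label '%s' does not match header symbol '%s'",
                   ln, row[1], alphabet[r]))
    if (length(row) != k + 1)
      stop(sprintf("line %d: expected %d values, found %d", ln, k, length(row) - 1))
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric matrix entry", ln))
    d[r, ] <- v
  }
  if (any(d < 0)) stop("validation: negative mutation cost entry")
  if (any(abs(d - t(d)) > 1e-9)) stop("validation: mutation cost matrix is asymmetric")
  extra <- rows[(1 + k + 1):(1 + k + 3)]
  vals <- setNames(rep(NA_real_, 3), c("duplication", "insertion", "deletion"))
  for (e in extra) {
    if (!e[1] %in% names(vals) || length(e) != 2)
      stop("validation: expected lines 'duplication', 'insertion', 'deletion' each with one value")
    vals[e[1]] <- suppressWarnings(as.numeric(e[2]))
  }
  if (anyNA(vals))
    stop("validation: missing or non-numeric duplication/insertion/deletion line")
  cost_model(d, c_dup = vals[["duplication"]], c_ins = vals[["insertion"]],
             c_del = vals[["deletion"]])
}

#' Write a cost model to a cost file
#'
#' @param cm a [cost_model()].
#' @param file path, or `NULL` to return the text invisibly.
#' @return the file content, invisibly.
#' @export
write_cost_file <- function(cm, file = NULL) {
  stopifnot(inherits(cm, "cost_model"))
  lines <- c(
    paste(c("units", cm$alphabet), collapse = "\t"),
    vapply(seq_along(cm$alphabet), function(r)
      paste(c(cm$alphabet[r], format(cm$d_M[r, ], trim = TRUE)), collapse = "\t"),
      character(1)),
    sprintf("duplication\t%s", format(cm$c_dup)),
    sprintf("insertion\t%s", format(cm$c_ins)),
    sprintf("deletion\t%s", format(cm$c_del)))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
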