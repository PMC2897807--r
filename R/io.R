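#' Read minisatellite maps from multi-FASTA
#'
#' The map dialect of FASTA: each record header is `>id [description]` and
#' the body lines carry whitespace-separated unit symbols (required for
#' multi-character symbols such as `"4a"`).  As a fallback for compact
#' published maps, a record whose entire body is a single line without
#' whitespace is split into one-character units.
#'
#' @param file path, or `NULL` when `text` is given.
#' @param text FASTA content as a single string or character vector of lines.
#' @return list of [mini_map()] objects (class `map_set`), with attributes
#'   `alphabet` (observed symbols) and `source`.
#' @export
read_maps_fasta <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either file or text must be given")
    text <- readLines(file, warn = FALSE)
  } else if (length(text) == 1) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  hdr <- grep("^>", text)
  if (length(hdr) == 0) stop("no FASTA records found")
  ends <- c(hdr[-1] - 1L, length(text))
  maps <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    id <- strsplit(sub("^>\\s*", "", text[hdr[k]]), "[[:space:]]+")[[1]][1]
    if (is.na(id) || !nzchar(id))
      stop(sprintf("record %d: empty id in header", k))
    body <- text[seq.int(hdr[k] + 1L, length.out = max(0L, ends[k] - hdr[k]))]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0)
      stop(sprintf("record '%s': empty body", id))
    units <- if (length(body) == 1 && !grepl("[[:space:]]", trimws(body))) {
      strsplit(trimws(body), "")[[1]]          # compact one-char dialect
    } else {
      unlist(strsplit(trimws(body), "[[:space:]]+"))
    }
    maps[[k]] <- mini_map(id, units)
  }
  ids <- vapply(maps, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate map id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  maps <- as_map_list(maps)
  structure(maps, class = c("map_set", "list"),
            alphabet = map_alphabet(maps),
            source = if (is.null(file)) NA_character_ else file)
}

#' Write maps as multi-FASTA (map dialect)
#'
#' @param maps list of [mini_map()] objects.
#' @param file path, or `NULL` to return the lines invisibly.
#' @return the lines, invisibly.
#' @export
write_maps_fasta <- function(maps, file = NULL) {
  maps <- as_map_list(maps)
  lines <- unlist(lapply(maps, function(m)
    c(paste0(">", m$id), paste(m$units, collapse = " "))))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' @export
print.map_set <- function(x, ...) {
  cat(sprintf("<map_set> %d maps, %d symbols: %s\n", length(x),
              length(attr(x, "alphabet")),
              paste(attr(x, "alphabet"), collapse = " ")))
  invisible(x)
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line is the taxon count; each row is the label (padded or truncated
#' to 10 characters in the strict dialect) followed by the distances with six
#' decimals.  `long_labels = TRUE` writes the relaxed dialect with full
#' labels separated by whitespace.
#'
#' @param dm symmetric matrix with dimnames.
#' @param file path, or `NULL` to return the lines invisibly.
#' @param long_labels use the relaxed (full-label) dialect.
#' @return the lines, invisibly.
#' @export
write_distance_matrix <- function(dm, file = NULL, long_labels = FALSE) {
  labels <- rownames(dm)
  if (is.null(labels)) stop("distance matrix needs labels")
  if (!long_labels) {
    short <- substr(labels, 1, 10)
    if (anyDuplicated(short))
      stop("label collision after truncation to 10 characters; use long_labels = TRUE")
    labels <- sprintf("%-10s", short)
  }
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(r)
               paste0(labels[r], if (long_labels) "\t" else "",
                      paste(sprintf("%.6f", dm[r, ]), collapse = "  ")),
               character(1)))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a PHYLIP square distance matrix
#'
#' Accepts both the strict 10-character-label dialect and the relaxed
#' whitespace-separated one.
#'
#' @param file path, or `NULL` when `text` is given.
#' @param text content as a string or character vector.
#' @return symmetric numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either file or text must be given")
    text <- readLines(file, warn = FALSE)
  } else if (length(text) == 1) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- text[nzchar(trimws(text))]
  n <- suppressWarnings(as.integer(trimws(text[1])))
  if (is.na(n) || length(text) != n + 1)
    stop("malformed PHYLIP matrix: bad taxon count")
  labels <- character(n)
  d <- matrix(NA_real_, n, n)
  for (r in seq_len(n)) {
    row <- text[r + 1]
    fields <- strsplit(trimws(row), "[[:space:]]+")[[1]]
    if (length(fields) == n + 1) {            # relaxed dialect
      labels[r] <- fields[1]
      vals <- suppressWarnings(as.numeric(fields[-1]))
    } else {                                  # strict: label = first 10 chars
      labels[r] <- trimws(substr(row, 1, 10))
      vals <- suppressWarnings(as.numeric(
        strsplit(trimws(substr(row, 11, nchar(row))), "[[:space:]]+")[[1]]))
    }
    if (length(vals) != n || anyNA(vals))
      stop(sprintf("malformed PHYLIP matrix row %d", r))
    d[r, ] <- vals
  }
  dimnames(d) <- list(labels, labels)
  d
}
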