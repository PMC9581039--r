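#' Unit alignment
#'
#' The central exchange type: a gapped multiple alignment whose rows are the
#' adjacent units of one tandem repeat, together with each unit's
#' half-open coordinates in the parent sequence (0-based).
#'
#' @param rows character vector of equal-length gapped rows (may be named
#'   with unit identifiers).
#' @param parent_id identifier of the parent sequence.
#' @param spans optional integer matrix (n x 2) of `[start, end)` unit
#'   coordinates; derived by stacking the degapped row lengths from
#'   `offset` when omitted.
#' @param alphabet a [alphabet()]; guessed from the rows if `NULL`.
#' @param parent_seq optional parent residue string; when supplied, every
#'   degapped row is checked against its span.
#' @param offset 0-based start of the first unit when `spans` is derived.
#' @return An object of class `unit_alignment` with fields `parent_id`,
#'   `rows`, `spans`, `alphabet`.
#' @export
unit_alignment <- function(rows, parent_id = "", spans = NULL,
                           alphabet = NULL, parent_seq = NULL, offset = 0L) {
  nm <- names(rows)
  rows <- toupper(as.character(rows))
  names(rows) <- nm
  if (length(rows) < 2L) ts_stop("need >= 2 units")
  if (length(unique(nchar(rows))) != 1L)
    ts_stop("alignment rows must have equal length")
  if (is.null(alphabet)) alphabet <- guess_alphabet(rows)
  degapped <- gsub("-", "", rows, fixed = TRUE)
  if (is.null(spans)) {
    ends <- offset + cumsum(nchar(degapped))
    spans <- cbind(start = c(offset, ends[-length(ends)]), end = ends)
  }
  spans <- matrix(as.integer(spans), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(spans) != length(rows))
    ts_stop("spans must have one row per unit")
  if (any(spans[, 2] - spans[, 1] != nchar(degapped)))
    ts_stop("span widths must match degapped row lengths")
  if (nrow(spans) > 1 && any(spans[-1, 1] < spans[-nrow(spans), 2]))
    ts_stop("unit spans must be ascending and non-overlapping")
  if (!is.null(parent_seq)) {
    for (i in seq_along(rows)) {
      sub <- substr(parent_seq, spans[i, 1] + 1L, spans[i, 2])
      if (!identical(sub, degapped[i]))
        ts_stop(sprintf("row %d does not match its parent span", i))
    }
  }
  if (is.null(names(rows)))
    names(rows) <- paste0("unit_", seq_along(rows))
  structure(list(parent_id = parent_id, rows = rows, spans = spans,
                 alphabet = alphabet),
            class = "unit_alignment")
}

#' @export
print.unit_alignment <- function(x, ...) {
  cat(sprintf("<unit_alignment> %s: %d units x %d columns\n",
              x$parent_id, length(x$rows), nchar(x$rows[1])))
  for (i in seq_along(x$rows))
    cat(sprintf("  %-12s %s  [%d,%d)\n", names(x$rows)[i], x$rows[i],
                x$spans[i, 1], x$spans[i, 2]))
  invisible(x)
}

# Character matrix view (units x columns).
ua_matrix <- function(ua) {
  do.call(rbind, lapply(ua$rows, .split_chars))
}

# Consensus unit length (columns with <= 50% gaps) without the pairwise
# comparability requirement of characteristics().
ua_unit_length <- function(ua) {
  sum(colMeans(ua_matrix(ua) == "-") <= 0.5)
}

#' Descriptive tandem-repeat characteristics
#'
#' Summarizes a unit alignment: consensus unit length (columns with at most
#' 50% gaps), number of units, descriptive divergence (one minus the mean
#' pairwise identity over columns where both rows have residues) and the
#' count of maximal gap runs per unit. The model-based divergence estimate
#' lives in [ml_divergence()]; this function is purely descriptive.
#'
#' @param ua a [unit_alignment()].
#' @return list with `unit_length`, `n_units`, `divergence`, `indel_counts`.
#' @export
characteristics <- function(ua) {
  M <- ua_matrix(ua)
  gap_frac <- colMeans(M == "-")
  unit_length <- sum(gap_frac <= 0.5)
  n <- nrow(M)
  ids <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    both <- M[i, ] != "-" & M[j, ] != "-"
    if (any(both)) ids <- c(ids, mean(M[i, both] == M[j, both]))
  }
  if (!length(ids)) ts_stop("degenerate alignment")
  indel_counts <- vapply(ua$rows, function(r) {
    runs <- rle(.split_chars(r) == "-")
    sum(runs$values)
  }, integer(1))
  list(unit_length = unit_length, n_units = n,
       divergence = 1 - mean(ids),
       indel_counts = unname(indel_counts))
}
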