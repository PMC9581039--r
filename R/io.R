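# Readers and writers: FASTA (via Biostrings), Stockholm 1.0, hit TSV,
# GFF3 export and the JSON model document. All writers are deterministic
# (stable key order, fixed float formatting).

#' Read a FASTA file
#'
#' Descriptions are split at the first whitespace for the identifier and
#' sequences are uppercased. Transparent gzip is supported.
#'
#' @param path FASTA file.
#' @param alphabet a [alphabet()]; guessed when `NULL`.
#' @param as_alignment return a named character vector keeping gap
#'   characters (for aligned FASTA) instead of [seq_record()]s.
#' @return list of [seq_record()]s, or a named character vector.
#' @export
read_fasta <- function(path, alphabet = NULL, as_alignment = FALSE) {
  if (!file.exists(path)) ts_stop(sprintf("cannot read '%s'", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  empty <- nchar(gsub("-", "", seqs, fixed = TRUE)) == 0
  if (any(empty))
    ts_stop(sprintf("empty record body for '%s'", ids[which(empty)[1]]))
  if (as_alignment) return(stats::setNames(seqs, ids))
  if (is.null(alphabet)) alphabet <- guess_alphabet(seqs)
  lapply(seq_along(ids), function(i)
    seq_record(ids[i], gsub("-", "", seqs[i], fixed = TRUE), alphabet))
}

#' Write sequences as FASTA
#' @param records list of [seq_record()]s or a named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (!is.character(records)) {
    nm <- vapply(records, function(r) r$id, character(1))
    records <- stats::setNames(
      vapply(records, function(r) r$residues, character(1)), nm)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Stockholm 1.0 alignment as a unit alignment
#'
#' Handles interleaved (multi-block) files; `#=GF`, `#=GS`, `#=GC` and
#' `#=GR` annotation lines are preserved verbatim in attribute
#' `"annotations"` and written back by [write_stockholm()]. Row names of
#' the form `id/start-end` (1-based inclusive, the Pfam convention) are
#' parsed into unit spans.
#'
#' @param path Stockholm file (single alignment).
#' @param alphabet optional [alphabet()].
#' @return a [unit_alignment()].
#' @export
read_stockholm <- function(path, alphabet = NULL) {
  if (!file.exists(path)) ts_stop(sprintf("cannot read '%s'", path))
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM 1\\.0", lines[1]))
    ts_stop("not a Stockholm 1.0 file (missing header)")
  seqs <- list(); ann <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^//", ln)) break
    if (ln == "" || grepl("^# ", ln)) next
    if (grepl("^#=", ln)) { ann <- c(ann, ln); next }
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      ts_stop(sprintf("malformed sequence line: '%s'", ln))
    seqs[[parts[1]]] <- paste0(seqs[[parts[1]]] %||% "", parts[2])
  }
  if (length(seqs) < 2) ts_stop("need >= 2 units")
  rows <- toupper(unlist(seqs))
  if (length(unique(nchar(rows))) != 1)
    ts_stop("mismatched row lengths in Stockholm alignment")
  spans <- NULL; parent <- ""
  m <- regmatches(names(rows),
                  regexec("^(.*)/(\\d+)-(\\d+)$", names(rows)))
  if (all(vapply(m, length, integer(1)) == 4)) {
    starts <- vapply(m, function(x) as.integer(x[3]), integer(1)) - 1L
    ends <- vapply(m, function(x) as.integer(x[4]), integer(1))
    parent <- m[[1]][2]
    ok <- all(ends - starts == nchar(gsub("-", "", rows, fixed = TRUE)))
    if (ok) spans <- cbind(start = starts, end = ends)
  }
  ua <- unit_alignment(rows, parent_id = parent, spans = spans,
                       alphabet = alphabet)
  attr(ua, "annotations") <- ann
  ua
}

#' @rdname read_stockholm
#' @param ua a [unit_alignment()] to write.
#' @export
write_stockholm <- function(ua, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  nm <- names(ua$rows)
  # attach Pfam-style coordinates when rows are not already labelled so
  if (!any(grepl("/\\d+-\\d+$", nm)))
    nm <- sprintf("%s/%d-%d", nm, ua$spans[, 1] + 1L, ua$spans[, 2])
  wid <- max(nchar(nm)) + 2L
  for (a in attr(ua, "annotations") %||% character(0)) writeLines(a, con)
  writeLines(sprintf("%-*s%s", wid, nm, ua$rows), con)
  writeLines("//", con)
  invisible(path)
}

# Read a unit alignment from either Stockholm or aligned FASTA, by content.
read_alignment <- function(path, alphabet = NULL) {
  first <- readLines(path, n = 1)
  if (length(first) && grepl("^# STOCKHOLM", first))
    read_stockholm(path, alphabet)
  else {
    rows <- read_fasta(path, as_alignment = TRUE)
    unit_alignment(rows, alphabet = alphabet)
  }
}

#' Write repeat hits to the canonical TSV
#'
#' Coordinates are 0-based half-open; floats carry 6 significant digits.
#' @param tab hit table from [hits_to_table()] / [search_database()].
#' @param path output file.
#' @export
write_hits_tsv <- function(tab, path) {
  out <- tab
  for (cn in c("viterbi_logodds", "forward_logodds", "pvalue"))
    out[[cn]] <- fmt_num(out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Export hits as GFF3
#'
#' One `repeat_region` feature per hit with `tandem_repeat_unit` children;
#' coordinates are converted to 1-based inclusive, the score column is the
#' forward log-odds rounded to 3 decimals.
#'
#' @param hits list of `repeat_hit` objects.
#' @param path output file.
#' @export
write_gff3 <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_along(hits)) {
    h <- hits[[k]]
    hid <- sprintf("tr%04d", k)
    sc <- sprintf("%.3f", h$forward_logodds)
    writeLines(paste(h$sequence_id, "tandemscan", "repeat_region",
                     h$start + 1L, h$end, sc, "+", ".",
                     sprintf("ID=%s;n_units=%d", hid, length(h$units$rows)),
                     sep = "\t"), con)
    for (u in seq_len(nrow(h$units$spans))) {
      writeLines(paste(h$sequence_id, "tandemscan", "tandem_repeat_unit",
                       h$units$spans[u, 1] + 1L, h$units$spans[u, 2], ".",
                       "+", ".",
                       sprintf("ID=%s.u%d;Parent=%s", hid, u, hid),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

.MODEL_SCHEMA <- "tandemscan-cphmm-1"

#' Serialize / deserialize a cpHMM as JSON
#'
#' The document stores the emission and transition matrices, wrap/exit
#' parameters, alphabet and a schema version; the round trip is lossless
#' to full double precision.
#'
#' @param cphmm a [circularize()]d model.
#' @param path JSON file.
#' @export
write_model_json <- function(cphmm, path) {
  p <- cphmm$base
  doc <- list(
    schema = .MODEL_SCHEMA,
    alphabet = list(kind = p$alphabet$kind,
                    symbols = p$alphabet$symbols,
                    background = unname(p$alphabet$background)),
    L = p$L,
    match_emissions = unname(p$match_emis),
    insert_emissions = unname(p$insert_emis),
    transitions = stats::setNames(
      lapply(colnames(p$trans), function(cn) unname(p$trans[, cn])),
      colnames(p$trans)),
    begin_weights = cphmm$begin_weights,
    exit_prob = cphmm$exit_prob,
    wrap = cphmm$wrap)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) ts_stop(sprintf("cannot read '%s'", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, .MODEL_SCHEMA))
    ts_stop(sprintf("model schema mismatch: expected '%s'", .MODEL_SCHEMA))
  need <- c("alphabet", "L", "match_emissions", "insert_emissions",
            "transitions", "begin_weights", "exit_prob", "wrap")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    ts_stop(sprintf("model document missing field(s): %s",
                    paste(miss, collapse = ", ")))
  bg <- stats::setNames(doc$alphabet$background, doc$alphabet$symbols)
  alpha <- if (identical(doc$alphabet$kind, "custom"))
    custom_alphabet(doc$alphabet$symbols, bg)
  else alphabet(doc$alphabet$kind, bg)
  trans <- do.call(cbind, doc$transitions[.TRANS_NAMES])
  colnames(trans) <- .TRANS_NAMES
  me <- as.matrix(doc$match_emissions)
  ie <- as.matrix(doc$insert_emissions)
  colnames(me) <- colnames(ie) <- alpha$symbols
  prof <- structure(list(L = as.integer(doc$L), alphabet = alpha,
                         match_emis = me, insert_emis = ie, trans = trans),
                    class = "profile_hmm")
  m <- structure(list(base = prof, begin_weights = doc$begin_weights,
                      exit_prob = doc$exit_prob, wrap = doc$wrap),
                 class = "cphmm")
  validate_cphmm(m, tol = 1e-6)
  m
}
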