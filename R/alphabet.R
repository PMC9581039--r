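#' Residue alphabets
#'
#' An alphabet bundles an ordered residue set with per-symbol background
#' frequencies. Two alphabets are shipped: the 20 amino acids (with average
#' database composition as background) and the 4 nucleotides (uniform
#' background). The gap character `-` is never part of an alphabet; ambiguity
#' codes (X, B, Z, N, ...) are not symbols either but are tolerated in
#' sequences and scored against the background distribution.
#'
#' @param kind `"aa"` or `"dna"`.
#' @param background Optional named frequency vector overriding the default;
#'   must cover every symbol and is renormalized to sum to 1.
#' @return An object of class `ts_alphabet` with fields `kind`, `symbols`
#'   and `background`.
#' @examples
#' aa <- alphabet("aa")
#' sum(aa$background)
#' @export
alphabet <- function(kind = c("aa", "dna"), background = NULL) {
  kind <- match.arg(kind)
  symbols <- if (kind == "aa") .AA_SYMBOLS else .DNA_SYMBOLS
  if (is.null(background)) {
    background <- if (kind == "aa") .AA_BACKGROUND else
      stats::setNames(rep(1 / 4, 4), .DNA_SYMBOLS)
  }
  if (!all(symbols %in% names(background)))
    ts_stop("background must name a frequency for every symbol")
  background <- background[symbols]
  if (any(background <= 0)) ts_stop("background frequencies must be positive")
  background <- background / sum(background)
  stopifnot(anyDuplicated(symbols) == 0L, !("-" %in% symbols))
  structure(list(kind = kind, symbols = symbols,
                 background = background),
            class = "ts_alphabet")
}

.AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average amino-acid composition of well-curated protein databases.
.AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0657, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)

.DNA_SYMBOLS <- c("A", "C", "G", "T")

#' @export
print.ts_alphabet <- function(x, ...) {
  cat(sprintf("<ts_alphabet> %s (%d symbols)\n", x$kind, length(x$symbols)))
  invisible(x)
}

#' @rdname alphabet
#' @param symbols ordered character vector of unique residue symbols
#'   (gap `-` excluded) for a custom alphabet; background defaults to
#'   uniform.
#' @export
custom_alphabet <- function(symbols, background = NULL) {
  symbols <- toupper(as.character(symbols))
  if (anyDuplicated(symbols) || "-" %in% symbols || length(symbols) < 2)
    ts_stop("symbols must be >= 2 unique non-gap characters")
  if (is.null(background))
    background <- stats::setNames(rep(1 / length(symbols), length(symbols)),
                                  symbols)
  background <- background[symbols]
  if (anyNA(background) || any(background <= 0))
    ts_stop("background must name a positive frequency for every symbol")
  structure(list(kind = "custom", symbols = symbols,
                 background = background / sum(background)),
            class = "ts_alphabet")
}

#' Guess the alphabet of a set of sequences
#'
#' Sequences whose residues are essentially all A/C/G/T are treated as DNA,
#' anything else as protein.
#' @param x character vector of residue strings.
#' @return A [alphabet()] object.
#' @export
guess_alphabet <- function(x) {
  ch <- unlist(strsplit(toupper(paste(x, collapse = "")), "", fixed = TRUE))
  ch <- ch[ch != "-"]
  if (length(ch) && mean(ch %in% c(.DNA_SYMBOLS, "N")) > 0.95)
    alphabet("dna") else alphabet("aa")
}

#' Sequence record
#'
#' A named residue string tied to an alphabet. Residues are uppercased;
#' characters outside the alphabet (ambiguity codes) are kept verbatim and
#' scored against the background at emission time.
#'
#' @param id sequence identifier.
#' @param residues residue string (no gap characters).
#' @param alphabet a [alphabet()] object; guessed from the residues if `NULL`.
#' @return An object of class `ts_seq`.
#' @export
seq_record <- function(id, residues, alphabet = NULL) {
  residues <- unname(toupper(gsub("[[:space:]]", "", residues)))
  if (grepl("-", residues, fixed = TRUE))
    ts_stop("residues must not contain gap characters")
  if (is.null(alphabet)) alphabet <- guess_alphabet(residues)
  structure(list(id = as.character(id), residues = residues,
                 alphabet = alphabet),
            class = "ts_seq")
}

#' @export
print.ts_seq <- function(x, ...) {
  cat(sprintf("<ts_seq> %s (%d residues, %s)\n", x$id, nchar(x$residues),
              x$alphabet$kind))
  invisible(x)
}

# Map residue characters to 1..K column indices; unknown symbols (ambiguity
# codes) map to K+1, which scoring treats as a background draw.
.symbol_index <- function(chars, alphabet) {
  idx <- match(chars, alphabet$symbols)
  idx[is.na(idx)] <- length(alphabet$symbols) + 1L
  idx
}

.split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
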