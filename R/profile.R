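# Profile HMM construction and circularization.

.TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DD", "DI")

#' Build a linear profile HMM from a unit alignment
#'
#' Match columns are those with at most 50% gaps (ties count as match).
#' Emissions and transitions are maximum-likelihood counts smoothed with
#' background-weighted pseudocounts: emission rows get
#' `(counts + w * background) / (total + w)`; each of the three moves out of
#' a state gets `w/3` added to its count. Residues in non-match columns are
#' emitted by the insert state of the preceding match column; non-match
#' columns before the first match column are not counted.
#'
#' @param ua a [unit_alignment()] with at least 2 units.
#' @param pseudocount_weight non-negative smoothing weight (default 1).
#' @return An object of class `profile_hmm` with fields `L`, `alphabet`,
#'   `match_emis` (L x K), `insert_emis` (L x K) and `trans` (L x 9 with
#'   columns MM, MI, MD, IM, II, ID, DM, DD, DI; row `i` describes moves
#'   from position-`i` states towards position `i + 1`).
#' @export
build_profile <- function(ua, pseudocount_weight = 1) {
  if (pseudocount_weight < 0) ts_stop("pseudocount_weight must be >= 0")
  M <- ua_matrix(ua)
  if (nrow(M) < 2L) ts_stop("need >= 2 units")
  alpha <- ua$alphabet
  K <- length(alpha$symbols)
  gap_frac <- colMeans(M == "-")
  is_match <- gap_frac <= 0.5
  if (!any(is_match)) ts_stop("no match columns")
  L <- sum(is_match)
  # map every column to the match position it belongs to (0 = before first)
  pos_of_col <- cumsum(is_match)

  emisM <- matrix(0, L, K, dimnames = list(NULL, alpha$symbols))
  emisI <- matrix(0, L, K, dimnames = list(NULL, alpha$symbols))
  tcount <- matrix(0, L, 9, dimnames = list(NULL, .TRANS_NAMES))

  for (r in seq_len(nrow(M))) {
    states <- character(0); poss <- integer(0)
    for (col in seq_len(ncol(M))) {
      ch <- M[r, col]; p <- pos_of_col[col]
      if (is_match[col]) {
        states <- c(states, if (ch == "-") "D" else "M"); poss <- c(poss, p)
        if (ch != "-" && ch %in% alpha$symbols) emisM[p, ch] <- emisM[p, ch] + 1
      } else if (ch != "-" && p >= 1L) {
        states <- c(states, "I"); poss <- c(poss, p)
        if (ch %in% alpha$symbols) emisI[p, ch] <- emisI[p, ch] + 1
      }
    }
    # terminal move towards the virtual position L+1 counts as X -> M
    states <- c(states, "M"); poss <- c(poss, L + 1L)
    for (k in seq_len(length(states) - 1L)) {
      mv <- paste0(states[k], states[k + 1])
      tcount[poss[k], mv] <- tcount[poss[k], mv] + 1
    }
  }

  w <- pseudocount_weight
  bg <- alpha$background
  norm_emis <- function(E) {
    tot <- rowSums(E)
    sm <- sweep(E, 2, w * bg, "+") / (tot + w)
    # w = 0 and no observations: fall back to background
    bad <- !is.finite(rowSums(sm)) | abs(rowSums(sm) - 1) > 1e-6
    if (any(bad)) sm[bad, ] <- matrix(bg, sum(bad), K, byrow = TRUE)
    sm
  }
  trans <- tcount
  for (g in list(1:3, 4:6, 7:9)) {
    blk <- tcount[, g, drop = FALSE] + w / 3
    tot <- rowSums(blk)
    blk <- blk / tot
    bad <- !is.finite(rowSums(blk))
    if (any(bad)) blk[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
    trans[, g] <- blk
  }
  structure(list(L = L, alphabet = alpha,
                 match_emis = norm_emis(emisM),
                 insert_emis = norm_emis(emisI),
                 trans = trans),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %d match columns, %s alphabet\n",
              x$L, x$alphabet$kind))
  invisible(x)
}

#' Circularize a linear profile HMM
#'
#' Transitions out of position-L states that would enter position L+1 are
#' redirected to position 1 (the wrap), the begin state connects to every
#' match state with equal weight 1/L, and every match state exits to the end
#' state with per-visit probability `exit_prob` (its remaining moves are
#' scaled by `1 - exit_prob`).
#'
#' @param p a [build_profile()] result.
#' @param exit_prob per-visit exit probability in (0, 1); default 0.05.
#' @param wrap `"full"` wraps M, I and D states at position L back to
#'   position 1 (default); `"match"` funnels all wrap mass into M1.
#' @return An object of class `cphmm`: `base` (the linear profile),
#'   `begin_weights`, `exit_prob`, `wrap`.
#' @export
circularize <- function(p, exit_prob = 0.05, wrap = c("full", "match")) {
  wrap <- match.arg(wrap)
  if (!is.numeric(exit_prob) || length(exit_prob) != 1 ||
      exit_prob <= 0 || exit_prob >= 1)
    ts_stop("exit_prob must be in (0, 1)")
  stopifnot(inherits(p, "profile_hmm"))
  structure(list(base = p, begin_weights = rep(1 / p$L, p$L),
                 exit_prob = exit_prob, wrap = wrap),
            class = "cphmm")
}

#' @export
print.cphmm <- function(x, ...) {
  cat(sprintf("<cphmm> L = %d, exit_prob = %g, wrap = %s\n",
              x$base$L, x$exit_prob, x$wrap))
  invisible(x)
}

# Effective transition matrix of a cphmm: row L targets position 1; under
# wrap = "match" all wrap mass from each state is funneled into M1.
cphmm_trans <- function(m) {
  tr <- m$base$trans
  if (m$wrap == "match") {
    L <- m$base$L
    tr[L, "MM"] <- tr[L, "MM"] + tr[L, "MD"]; tr[L, "MD"] <- 0
    tr[L, "IM"] <- tr[L, "IM"] + tr[L, "ID"]; tr[L, "ID"] <- 0
    tr[L, "DM"] <- tr[L, "DM"] + tr[L, "DD"] + tr[L, "DI"]
    tr[L, "DD"] <- 0; tr[L, "DI"] <- 0
  }
  tr
}

# Internal consistency checks used by tests and the JSON reader.
validate_cphmm <- function(m, tol = 1e-9) {
  p <- m$base
  stopifnot(abs(sum(m$begin_weights) - 1) < tol,
            all(abs(rowSums(p$match_emis) - 1) < tol),
            all(abs(rowSums(p$insert_emis) - 1) < tol))
  for (g in list(1:3, 4:6, 7:9))
    stopifnot(all(abs(rowSums(p$trans[, g, drop = FALSE]) - 1) < 1e-6))
  invisible(TRUE)
}
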