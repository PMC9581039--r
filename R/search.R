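# Circular profile HMM decoding: forward/Viterbi log-odds over a window,
# flanked scanning of whole sequences, and unit segmentation.
#
# All dynamic programming is done in natural-log space on log-odds
# (model emission minus null emission), so flanking null states contribute
# exactly zero per residue and scores compare repeat vs null on the same
# span. Reported scores are in bits.

#' Null (random-sequence) model
#'
#' I.i.d. residue emission frequencies used to normalize cpHMM scores.
#'
#' @param alphabet a [alphabet()]; its background becomes the null.
#' @return object of class `null_model` with field `freqs`.
#' @export
null_model <- function(alphabet) {
  structure(list(freqs = alphabet$background, alphabet = alphabet),
            class = "null_model")
}

#' @rdname null_model
#' @param records list of [seq_record()]s; frequencies are estimated from
#'   their residue composition with one pseudocount per symbol.
#' @export
null_from_seqs <- function(records) {
  stopifnot(length(records) > 0)
  alpha <- records[[1]]$alphabet
  ch <- unlist(lapply(records, function(r) .split_chars(r$residues)))
  cnt <- as.numeric(table(factor(ch, levels = alpha$symbols)))
  f <- (cnt + 1) / (sum(cnt) + length(alpha$symbols))
  structure(list(freqs = stats::setNames(f / sum(f), alpha$symbols),
                 alphabet = alpha),
            class = "null_model")
}

# Precompute log-space parameters for DP. Unknown symbols map to emission
# column K+1 with log-odds 0 (background under model and null alike).
model_pack <- function(m, null) {
  p <- m$base
  L <- p$L
  K <- length(p$alphabet$symbols)
  eps <- m$exit_prob
  lnull <- log(null$freqs)
  lodM <- cbind(log(p$match_emis) - rep(lnull, each = L), 0)
  lodI <- cbind(log(p$insert_emis) - rep(lnull, each = L), 0)
  tr <- cphmm_trans(m)
  lt <- log(tr)
  # per-visit exit: M-moves carry the remaining (1 - eps) mass
  lt[, c("MM", "MI", "MD")] <- lt[, c("MM", "MI", "MD")] + log1p(-eps)
  ltDD <- lt[, "DD"]
  # weight of the silent delete path i -> k (0 <= steps < L, circular);
  # -Inf entries are clamped so 0-step paths stay exactly 0
  safeDD <- pmax(ltDD, -745)
  d2 <- c(safeDD, safeDD)
  cs <- c(0, cumsum(d2))
  W <- matrix(-Inf, L, L)
  for (i in seq_len(L)) {
    steps <- (seq_len(L) - i) %% L
    W[i, ] <- cs[i + steps] - cs[i]
  }
  W[W < -700] <- -Inf
  Cfull <- exp(sum(safeDD))  # full delete-cycle weight
  if (Cfull >= 1 - 1e-12)
    ts_stop("degenerate model: delete-cycle probability ~ 1")
  list(L = L, K = K, alpha = p$alphabet, lodM = lodM, lodI = lodI,
       lt = lt, ltDD = ltDD, W = W, Cfull = Cfull,
       lbegin = log(m$begin_weights), lexit = log(eps))
}

# One forward/Viterbi pass over a window: all paths B -> E emitting the
# whole window. Returns the log-odds in nats.
window_dp <- function(pk, xidx, mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  L <- pk$L; lt <- pk$lt
  n <- length(xidx)
  if (n == 0) ts_stop("window must be non-empty")
  comb2 <- if (mode == "forward") lse2 else pmax
  comb3 <- if (mode == "forward") lse3 else pmax
  sMM <- shift1(lt[, "MM"]); sIM <- shift1(lt[, "IM"]); sDM <- shift1(lt[, "DM"])
  sMD <- shift1(lt[, "MD"]); sID <- shift1(lt[, "ID"]); sDD <- shift1(pk$ltDD)
  FM <- pk$lbegin + pk$lodM[, xidx[1]]
  FI <- rep(-Inf, L)
  FD <- .d_chain(pk, comb2(shift1(FM) + sMD, shift1(FI) + sID), mode)
  if (n > 1) for (j in 2:n) {
    FMn <- pk$lodM[, xidx[j]] +
      comb3(shift1(FM) + sMM, shift1(FI) + sIM, shift1(FD) + sDM)
    FIn <- pk$lodI[, xidx[j]] +
      comb3(FM + lt[, "MI"], FI + lt[, "II"], FD + lt[, "DI"])
    FM <- FMn; FI <- FIn
    FD <- .d_chain(pk, comb2(shift1(FM) + sMD, shift1(FI) + sID), mode)
  }
  if (mode == "forward") lse_vec(FM + pk$lexit) else max(FM + pk$lexit)
}

# Silent delete-state propagation with the circular wrap. `b` holds the
# entry mass into each D_i from emitting states of the same column.
# Forward sums the geometric series over full cycles exactly via 1/(1 - C);
# Viterbi needs two sweeps since the best path never completes a cycle.
.d_chain <- function(pk, b, mode) {
  L <- pk$L
  if (mode == "forward") {
    if (all(!is.finite(b))) return(rep(-Inf, L))
    lse_cols(pk$W + b) - log1p(-pk$Cfull)
  } else {
    v <- b
    prev <- c(L, seq_len(L - 1))
    for (pass in 1:2) for (i in seq_len(L)) {
      cand <- v[prev[i]] + pk$ltDD[prev[i]]
      if (cand > v[i]) v[i] <- cand
    }
    v
  }
}

#' Forward log-odds of a window under a cpHMM
#'
#' log2 of the total probability of the window under the circular model
#' (summed over all begin-to-end state paths) divided by its probability
#' under the i.i.d. null.
#'
#' @param cphmm a [circularize()]d model.
#' @param window residue string or [seq_record()].
#' @param null a [null_model()]; defaults to the alphabet background.
#' @return score in bits.
#' @export
forward_logodds <- function(cphmm, window, null = NULL) {
  .score_window(cphmm, window, null, "forward")
}

#' @rdname forward_logodds
#' @export
viterbi_logodds <- function(cphmm, window, null = NULL) {
  .score_window(cphmm, window, null, "viterbi")
}

.score_window <- function(cphmm, window, null, mode) {
  res <- if (inherits(window, "ts_seq")) window$residues else
    toupper(as.character(window))
  if (!nchar(res)) ts_stop("window must be non-empty")
  null <- null %||% null_model(cphmm$base$alphabet)
  pk <- model_pack(cphmm, null)
  xidx <- .symbol_index(.split_chars(res), cphmm$base$alphabet)
  window_dp(pk, xidx, mode) / log(2)
}

#' Scan a sequence for tandem-repeat hits
#'
#' Runs the flanked Viterbi decoder: null-emitting flank states surround the
#' circular repeat submodel with free entry/exit, so a hit's score is the
#' log-odds of repeat vs null over its own span. Each reported hit must
#' complete at least one wrap (>= 2 units) and score above `min_logodds`
#' bits. After the best-scoring hit is taken, the unclaimed flanks are
#' re-scanned, so hits are non-overlapping and reported left to right.
#'
#' @param cphmm a [circularize()]d model.
#' @param seq a [seq_record()] (alphabet must match the model).
#' @param null a [null_model()]; defaults to the model alphabet background.
#' @param min_units minimum decoded units per hit (>= 2).
#' @param min_logodds hit threshold in bits (strict; default 0).
#' @return list of `repeat_hit` objects: `sequence_id`, `start`/`end`
#'   (0-based half-open), `state_path`, `wrap_points`, `units`
#'   (a [unit_alignment()]), `viterbi_logodds`, `forward_logodds` (bits).
#' @export
viterbi_search <- function(cphmm, seq, null = NULL, min_units = 2,
                           min_logodds = 0) {
  stopifnot(inherits(cphmm, "cphmm"), inherits(seq, "ts_seq"))
  if (!identical(seq$alphabet$symbols, cphmm$base$alphabet$symbols))
    ts_stop("alphabet mismatch between model and sequence")
  if (min_units < 2) ts_stop("min_units must be >= 2")
  null <- null %||% null_model(cphmm$base$alphabet)
  pk <- model_pack(cphmm, null)
  chars <- .split_chars(seq$residues)
  if (!length(chars)) return(list())
  xidx <- .symbol_index(chars, cphmm$base$alphabet)
  hits <- .scan_region(pk, xidx, 0L, min_logodds * log(2))
  hits <- Filter(Negate(is.null), lapply(hits, function(h) {
    ua <- tryCatch(
      decode_units(h$path, seq$residues, pk$L, start = h$start,
                   alphabet = cphmm$base$alphabet, parent_id = seq$id),
      error = function(e) NULL)
    if (is.null(ua) || length(ua$rows) < min_units) return(NULL)
    win <- substr(seq$residues, h$start + 1L, h$end)
    nseg <- length(ua$rows)
    wp <- h$start + cumsum(ua$spans[, 2] - ua$spans[, 1])[-nseg]
    structure(list(sequence_id = seq$id, start = h$start, end = h$end,
                   state_path = h$path, wrap_points = wp, units = ua,
                   viterbi_logodds = h$score / log(2),
                   forward_logodds = window_dp(pk, xidx[(h$start + 1L):h$end],
                                               "forward") / log(2),
                   pvalue = NA_real_),
              class = "repeat_hit")
  }))
  hits[order(vapply(hits, function(h) h$start, integer(1)))]
}

#' @export
print.repeat_hit <- function(x, ...) {
  cat(sprintf(
    "<repeat_hit> %s [%d,%d) %d units  viterbi %.2f  forward %.2f bits\n",
    x$sequence_id, x$start, x$end, length(x$units$rows),
    x$viterbi_logodds, x$forward_logodds))
  invisible(x)
}

# Greedy non-overlapping hit extraction on xidx[region]; offset is the
# 0-based coordinate of the region start in the parent sequence.
.scan_region <- function(pk, xidx, offset, min_score_nats) {
  n <- length(xidx)
  if (n == 0) return(list())
  best <- .scan_viterbi(pk, xidx)
  if (is.null(best) || best$score <= min_score_nats + 1e-12) return(list())
  hit <- list(start = offset + best$start0, end = offset + best$end0,
              score = best$score, path = best$path)
  hit$path$res_idx <- hit$path$res_idx +
    ifelse(is.na(hit$path$res_idx), 0L, offset)
  c(.scan_region(pk, xidx[seq_len(best$start0)], offset, min_score_nats),
    list(hit),
    if (best$end0 < n)
      .scan_region(pk, xidx[(best$end0 + 1L):n], offset + best$end0,
                   min_score_nats))
}

# Layered Viterbi over one region. Layer 1 = no wrap taken yet, layer 2 =
# at least one wrap, so every reported path decodes to >= 2 units. Ties are
# broken by a fixed candidate order (B, then M before D before I, layer 1
# before layer 2), giving bit-reproducible tracebacks.
.scan_viterbi <- function(pk, xidx) {
  L <- pk$L; lt <- pk$lt; n <- length(xidx)
  NEG <- -Inf
  VM <- array(NEG, c(L, n + 1L, 2L)); PM <- array(0L, c(L, n + 1L, 2L))
  VI <- array(NEG, c(L, n + 1L, 2L)); PI <- array(0L, c(L, n + 1L, 2L))
  VD <- array(NEG, c(L, n + 1L, 2L)); PD <- array(0L, c(L, n + 1L, 2L))
  enc <- function(state, i, layer) ((layer - 1L) * 3L + (state - 1L)) * L + i
  best_end <- c(score = NEG, j = NA, i = NA)
  for (j in seq_len(n)) {
    jj <- j + 1L
    x <- xidx[j]
    for (l in 1:2) {
      for (i in seq_len(L)) {
        ip <- if (i == 1L) L else i - 1L
        wrapping <- (i == 1L)
        cand_v <- numeric(0); cand_p <- integer(0)
        if (l == 1L) {
          if (!wrapping) {
            cand_v <- c(0 + pk$lbegin[i],
                        VM[ip, jj - 1L, 1L] + lt[ip, "MM"],
                        VD[ip, jj - 1L, 1L] + lt[ip, "DM"],
                        VI[ip, jj - 1L, 1L] + lt[ip, "IM"])
            cand_p <- c(0L, enc(1L, ip, 1L), enc(3L, ip, 1L), enc(2L, ip, 1L))
          } else {
            cand_v <- 0 + pk$lbegin[i]; cand_p <- 0L
          }
        } else {
          if (wrapping) {
            cand_v <- c(VM[L, jj - 1L, 1L] + lt[L, "MM"],
                        VM[L, jj - 1L, 2L] + lt[L, "MM"],
                        VD[L, jj - 1L, 1L] + lt[L, "DM"],
                        VD[L, jj - 1L, 2L] + lt[L, "DM"],
                        VI[L, jj - 1L, 1L] + lt[L, "IM"],
                        VI[L, jj - 1L, 2L] + lt[L, "IM"])
            cand_p <- c(enc(1L, L, 1L), enc(1L, L, 2L), enc(3L, L, 1L),
                        enc(3L, L, 2L), enc(2L, L, 1L), enc(2L, L, 2L))
          } else {
            cand_v <- c(VM[ip, jj - 1L, 2L] + lt[ip, "MM"],
                        VD[ip, jj - 1L, 2L] + lt[ip, "DM"],
                        VI[ip, jj - 1L, 2L] + lt[ip, "IM"])
            cand_p <- c(enc(1L, ip, 2L), enc(3L, ip, 2L), enc(2L, ip, 2L))
          }
        }
        k <- which.max(cand_v)
        VM[i, jj, l] <- cand_v[k] + pk$lodM[i, x]
        PM[i, jj, l] <- cand_p[k]
        # insert states never change position or layer
        civ <- c(VM[i, jj - 1L, l] + lt[i, "MI"],
                 VD[i, jj - 1L, l] + lt[i, "DI"],
                 VI[i, jj - 1L, l] + lt[i, "II"])
        cip <- c(enc(1L, i, l), enc(3L, i, l), enc(2L, i, l))
        k <- which.max(civ)
        VI[i, jj, l] <- civ[k] + pk$lodI[i, x]
        PI[i, jj, l] <- cip[k]
      }
    }
    # silent delete chains for this column: layer 1 is linear (a wrap at
    # D_L -> D_1 promotes to layer 2), layer 2 is circular (two sweeps)
    for (i in seq_len(L)) {
      if (i > 1L) {
        ip <- i - 1L
        cand_v <- c(VM[ip, jj, 1L] + lt[ip, "MD"],
                    VD[ip, jj, 1L] + lt[ip, "DD"],
                    VI[ip, jj, 1L] + lt[ip, "ID"])
        cand_p <- c(enc(1L, ip, 1L), enc(3L, ip, 1L), enc(2L, ip, 1L))
        k <- which.max(cand_v)
        VD[i, jj, 1L] <- cand_v[k]; PD[i, jj, 1L] <- cand_p[k]
      }
    }
    for (pass in 1:2) for (i in seq_len(L)) {
      ip <- if (i == 1L) L else i - 1L
      lsrc <- if (i == 1L) c(1L, 2L) else 2L
      cand_v <- numeric(0); cand_p <- integer(0)
      for (ls in lsrc) {
        cand_v <- c(cand_v,
                    VM[ip, jj, ls] + lt[ip, "MD"],
                    VD[ip, jj, ls] + lt[ip, "DD"],
                    VI[ip, jj, ls] + lt[ip, "ID"])
        cand_p <- c(cand_p, enc(1L, ip, ls), enc(3L, ip, ls), enc(2L, ip, ls))
      }
      k <- which.max(cand_v)
      if (cand_v[k] > VD[i, jj, 2L]) {
        VD[i, jj, 2L] <- cand_v[k]; PD[i, jj, 2L] <- cand_p[k]
      }
    }
    sc <- max(VM[, jj, 2L])
    if (sc + pk$lexit > best_end["score"]) {
      best_end <- c(score = sc + pk$lexit, j = j, i = which.max(VM[, jj, 2L]))
    }
  }
  if (!is.finite(best_end["score"])) return(NULL)
  # traceback
  state <- 1L; i <- as.integer(best_end["i"]); l <- 2L
  j <- as.integer(best_end["j"])
  kinds <- character(0); poss <- integer(0); resi <- integer(0)
  repeat {
    kinds <- c(c("M", "I", "D")[state], kinds)
    poss <- c(i, poss)
    resi <- c(if (state %in% c(1L, 2L)) j else NA_integer_, resi)
    ptr <- switch(state, PM[i, j + 1L, l], PI[i, j + 1L, l], PD[i, j + 1L, l])
    consumed <- state %in% c(1L, 2L)  # M and I emitted residue j
    if (ptr == 0L) { jstart <- j; break }
    dec <- ptr - 1L
    pi_ <- dec %% L + 1L; dec <- dec %/% L
    ps <- dec %% 3L + 1L; pl <- dec %/% 3L + 1L
    state <- ps; i <- pi_; l <- pl
    if (consumed) j <- j - 1L
  }
  list(score = unname(best_end["score"]),
       start0 = jstart - 1L, end0 = as.integer(best_end["j"]),
       path = data.frame(kind = kinds, pos = poss, res_idx = resi,
                         stringsAsFactors = FALSE))
}

#' Segment a decoded state path into repeat units
#'
#' Cuts the path at wrap transitions (position L back to position 1); each
#' segment becomes one alignment row laid out in profile-column coordinates:
#' match residues in their column, deletions as gaps, insertions in extra
#' columns after their match column. Partial first/last units are padded
#' with gaps. Segments that emit no residues are dropped.
#'
#' @param path data frame with columns `kind` (M/I/D), `pos` (profile
#'   position) and `res_idx` (1-based residue index in `seq`, NA for D).
#' @param seq parent residue string.
#' @param L number of model match columns.
#' @param start 0-based start of the hit span.
#' @param alphabet,parent_id forwarded to [unit_alignment()].
#' @return a [unit_alignment()].
#' @export
decode_units <- function(path, seq, L, start = 0L, alphabet = NULL,
                         parent_id = "") {
  stopifnot(is.data.frame(path), nrow(path) > 0)
  res <- if (inherits(seq, "ts_seq")) seq$residues else as.character(seq)
  chars <- .split_chars(res)
  segs <- list()
  mcols <- rep("-", L); ins <- rep(list(character(0)), L); nres <- 0L
  flush <- function() {
    if (nres > 0L)
      segs[[length(segs) + 1L]] <<- list(m = mcols, i = ins, n = nres)
    mcols <<- rep("-", L); ins <<- rep(list(character(0)), L); nres <<- 0L
  }
  prev_pos <- NA_integer_
  for (k in seq_len(nrow(path))) {
    kind <- path$kind[k]; pos <- path$pos[k]
    if (!is.na(prev_pos) && prev_pos == L && pos == 1L &&
        kind %in% c("M", "D"))
      flush()
    if (kind == "M") {
      mcols[pos] <- chars[path$res_idx[k]]; nres <- nres + 1L
    } else if (kind == "I") {
      ins[[pos]] <- c(ins[[pos]], chars[path$res_idx[k]]); nres <- nres + 1L
    }
    prev_pos <- pos
  }
  flush()
  if (length(segs) < 2L) ts_stop("not a tandem repeat")
  ins_max <- vapply(seq_len(L), function(i)
    max(vapply(segs, function(s) length(s$i[[i]]), integer(1))), integer(1))
  rows <- vapply(segs, function(s) {
    paste(vapply(seq_len(L), function(i) {
      blk <- c(s$i[[i]], rep("-", ins_max[i] - length(s$i[[i]])))
      paste0(s$m[i], paste(blk, collapse = ""))
    }, character(1)), collapse = "")
  }, character(1))
  lens <- vapply(segs, function(s) s$n, integer(1))
  ends <- start + cumsum(lens)
  spans <- cbind(start = c(start, ends[-length(ends)]), end = ends)
  ua <- unit_alignment(rows, parent_id = parent_id, spans = spans,
                       alphabet = alphabet, parent_seq = res)
  # layout positions of the model match columns (insert columns interleave)
  attr(ua, "match_columns") <- cumsum(c(1L, 1L + ins_max[-L]))
  ua
}

#' Search a sequence database for a cpHMM
#'
#' Streams a FASTA file (or list of [seq_record()]s), scans each sequence
#' with [viterbi_search()], optionally computes homology p-values, applies
#' filters and returns the hit table. Output order is input order then
#' position, and identical inputs give byte-identical output files.
#'
#' @param cphmm a [circularize()]d model.
#' @param db FASTA path or list of [seq_record()]s.
#' @param null `NULL` (estimate background from the database, the default),
#'   a [null_model()], or `"alphabet"` for the fixed standard background.
#' @param min_units,min_unit_len,max_unit_len,min_logodds,max_pvalue
#'   hit filters; `NULL` disables a filter. `min_units` defaults to 2;
#'   `min_logodds` defaults to 8 bits, about twice the best score seen on
#'   residue-shuffled (composition-matched) sequences, so random sequences
#'   essentially never pass.
#' @param pvalue_draws permutation draws for [homology_lrt()] p-values;
#'   0 (default) leaves the p-value `NA` unless `max_pvalue` is set, in
#'   which case 199 draws are used.
#' @param seed RNG seed for the permutation p-values.
#' @param out_tsv,out_gff optional output paths (TSV and GFF3).
#' @return invisible data frame with columns sequence_id, start, end,
#'   n_units, unit_length, viterbi_logodds, forward_logodds, pvalue, units;
#'   the hit objects are attached as attribute `"hits"`.
#' @export
search_database <- function(cphmm, db, null = NULL, min_units = 2,
                            min_unit_len = NULL, max_unit_len = NULL,
                            min_logodds = 8, max_pvalue = NULL,
                            pvalue_draws = 0, seed = 1L,
                            out_tsv = NULL, out_gff = NULL) {
  records <- if (is.character(db)) read_fasta(db, cphmm$base$alphabet) else db
  if (is.null(null)) {
    null <- if (length(records)) null_from_seqs(records) else
      null_model(cphmm$base$alphabet)
  } else if (identical(null, "alphabet")) {
    null <- null_model(cphmm$base$alphabet)
  }
  if (pvalue_draws == 0 && !is.null(max_pvalue)) pvalue_draws <- 199
  model <- subst_model_symmetric(cphmm$base$alphabet)
  all_hits <- list()
  for (rec in records) {
    hits <- viterbi_search(cphmm, rec, null, min_units = min_units,
                           min_logodds = min_logodds)
    for (h in hits) {
      if (pvalue_draws > 0) {
        h$pvalue <- homology_lrt(h$units, model, null_draws = pvalue_draws,
                                 seed = seed + h$start)$pvalue
      }
      all_hits[[length(all_hits) + 1L]] <- h
    }
  }
  keep <- vapply(all_hits, function(h) {
    ulen <- ua_unit_length(h$units)
    (is.null(min_unit_len) || ulen >= min_unit_len) &&
      (is.null(max_unit_len) || ulen <= max_unit_len) &&
      length(h$units$rows) >= min_units &&
      (is.null(max_pvalue) || (!is.na(h$pvalue) && h$pvalue <= max_pvalue))
  }, logical(1))
  all_hits <- all_hits[keep]
  tab <- hits_to_table(all_hits)
  if (!is.null(out_tsv)) write_hits_tsv(tab, out_tsv)
  if (!is.null(out_gff)) write_gff3(all_hits, out_gff)
  attr(tab, "hits") <- all_hits
  invisible(tab)
}

#' Convert a list of repeat hits into the canonical hit table
#' @param hits list of `repeat_hit` objects.
#' @return data frame (0-based half-open coordinates).
#' @export
hits_to_table <- function(hits) {
  if (!length(hits)) {
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), n_units = integer(0),
                      unit_length = integer(0),
                      viterbi_logodds = numeric(0),
                      forward_logodds = numeric(0), pvalue = numeric(0),
                      units = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    sequence_id = vapply(hits, function(h) h$sequence_id, character(1)),
    start = vapply(hits, function(h) h$start, numeric(1)),
    end = vapply(hits, function(h) h$end, numeric(1)),
    n_units = vapply(hits, function(h) length(h$units$rows), numeric(1)),
    unit_length = vapply(hits, function(h)
      ua_unit_length(h$units), numeric(1)),
    viterbi_logodds = vapply(hits, function(h) h$viterbi_logodds, numeric(1)),
    forward_logodds = vapply(hits, function(h) h$forward_logodds, numeric(1)),
    pvalue = vapply(hits, function(h) h$pvalue, numeric(1)),
    units = vapply(hits, function(h) paste(h$units$rows, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
}
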