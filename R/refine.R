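# Iterative cpHMM refinement: decode units from hits, realign them under
# PIP, rebuild and re-circularize the profile, re-search, and keep the
# best-scoring model.

#' Iteratively refine a circular profile HMM
#'
#' Each round pools the unit sequences decoded from the current hits,
#' realigns them (progressive PIP by default), rebuilds the profile from
#' the realignment, circularizes it with the same exit probability, and
#' re-searches the sequences. A round is accepted only if the total
#' forward log-odds over all hits improves by at least `tol` bits, so the
#' reported trajectory is non-decreasing and the best-scoring model is
#' returned.
#'
#' @param cphmm starting model.
#' @param seqs list of [seq_record()]s (or FASTA path) to search.
#' @param rounds maximum refinement rounds (>= 1).
#' @param null a [null_model()]; defaults to estimating from `seqs`.
#' @param method realignment method, `"pip"` or `"mafft"`.
#' @param pseudocount_weight forwarded to [build_profile()].
#' @param min_units,min_logodds forwarded to [viterbi_search()].
#' @param tol minimal score gain (bits) to accept a round (1e-3).
#' @param rate_model,alpha forwarded to the realignment.
#' @return list of class `cphmm_refinement`: `model`, `hits`, `score`
#'   (total forward log-odds, bits), `trajectory` (accepted score after
#'   each round, non-decreasing), `candidate_scores`, `n_cycles`.
#' @export
refine_cphmm <- function(cphmm, seqs, rounds = 3, null = NULL,
                         method = c("pip", "mafft"), pseudocount_weight = 1,
                         min_units = 2, min_logodds = 0, tol = 1e-3,
                         rate_model = c("constant", "gamma"), alpha = 0.5) {
  method <- match.arg(method)
  rate_model <- match.arg(rate_model)
  if (rounds < 1) ts_stop("rounds must be >= 1")
  if (is.character(seqs)) seqs <- read_fasta(seqs, cphmm$base$alphabet)
  null <- null %||% null_from_seqs(seqs)
  search_all <- function(model) {
    hl <- list()
    for (s in seqs)
      hl <- c(hl, viterbi_search(model, s, null, min_units = min_units,
                                 min_logodds = min_logodds))
    hl
  }
  hits <- search_all(cphmm)
  score_of <- function(hl)
    if (length(hl)) sum(vapply(hl, function(h) h$forward_logodds,
                               numeric(1))) else -Inf
  best <- list(model = cphmm, hits = hits, score = score_of(hits))
  if (!length(hits)) {
    warning("no hits: returning the input model unchanged")
    return(structure(c(best, list(trajectory = numeric(0),
                                  candidate_scores = numeric(0),
                                  n_cycles = 0L)),
                     class = "cphmm_refinement"))
  }
  trajectory <- numeric(0); cand_scores <- numeric(0); cycles <- 0L
  for (r in seq_len(rounds)) {
    pooled <- .pool_hit_units(best$hits)
    cand_model <- tryCatch({
      ra <- .refine_realign(pooled, method, rate_model, alpha,
                            cphmm$base$alphabet)
      prof <- build_profile(ra, pseudocount_weight = pseudocount_weight)
      circularize(prof, exit_prob = cphmm$exit_prob, wrap = cphmm$wrap)
    }, error = function(e) NULL)
    cycles <- cycles + 1L
    if (is.null(cand_model)) { cand_scores <- c(cand_scores, NA); break }
    cand_hits <- search_all(cand_model)
    cand_score <- score_of(cand_hits)
    cand_scores <- c(cand_scores, cand_score)
    improved <- is.finite(cand_score) && cand_score > best$score + tol
    if (improved)
      best <- list(model = cand_model, hits = cand_hits, score = cand_score)
    trajectory <- c(trajectory, best$score)
    if (!improved) break
  }
  structure(list(model = best$model, hits = best$hits, score = best$score,
                 trajectory = trajectory, candidate_scores = cand_scores,
                 n_cycles = cycles),
            class = "cphmm_refinement")
}

#' @export
print.cphmm_refinement <- function(x, ...) {
  cat(sprintf("<cphmm_refinement> %d cycle(s), %d hits, score %.2f bits\n",
              x$n_cycles, length(x$hits), x$score))
  invisible(x)
}

# Stack the units of all hits as one alignment in model match-column
# coordinates (insert columns dropped) for guide-tree and rate estimation;
# keep the full degapped sequences for the realignment itself.
.pool_hit_units <- function(hits) {
  rows <- character(0); full <- character(0)
  for (h in seq_along(hits)) {
    ua <- hits[[h]]$units
    mc <- attr(ua, "match_columns")
    proj <- if (is.null(mc)) ua$rows else
      vapply(ua$rows, function(r)
        paste(.split_chars(r)[mc], collapse = ""), character(1))
    nm <- sprintf("h%d_%s", h, names(ua$rows))
    rows <- c(rows, stats::setNames(proj, nm))
    full <- c(full, stats::setNames(gsub("-", "", ua$rows, fixed = TRUE), nm))
  }
  list(proj = rows, full = full)
}

.refine_realign <- function(pooled, method, rate_model, alpha, alphabet) {
  if (method == "mafft") {
    ua0 <- unit_alignment(pooled$proj, alphabet = alphabet)
    return(realign_units(ua0, "mafft"))
  }
  proj_ua <- unit_alignment(pooled$proj, alphabet = alphabet)
  tree <- infer_guide_tree(proj_ua)
  params <- tryCatch({
    est <- estimate_indel_rates(proj_ua, tree)
    pip_params(est["lambda"], est["mu"], rate_model = rate_model,
               alpha = alpha)
  }, error = function(e) {
    # gapless pool: minimal deletion pressure, stationary length
    ml <- mean(nchar(pooled$full))
    pip_params(max(1e-4 * ml, 1e-4), 1e-4, rate_model = rate_model,
               alpha = alpha)
  })
  pip_align(pooled$full, tree = tree, params = params, alphabet = alphabet)
}
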