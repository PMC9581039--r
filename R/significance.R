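# Statistical evaluation of candidate tandem repeats: the homology
# likelihood-ratio test with an empirical permutation p-value, the
# maximum-likelihood divergence estimate, and overlap resolution.
#
# Under H1 the units of a column descend from one unobserved ancestor on a
# star tree (one branch of length t/2 per unit, so t is the expected
# pairwise divergence between units). Under H0 the residues are independent
# draws from the stationary frequencies. Because the ML estimate of t often
# sits on the boundary (t = 0), chi-square asymptotics do not apply and the
# p-value is computed by permuting residues within each row.

# Per-column residue count matrix (K x ncol). Ambiguity codes and gaps are
# treated as missing. Only columns with >= 1 residue are kept.
.column_counts <- function(ua) {
  M <- ua_matrix(ua)
  K <- length(ua$alphabet$symbols)
  idx <- matrix(match(M, ua$alphabet$symbols), nrow(M), ncol(M))
  C <- vapply(seq_len(ncol(M)), function(j)
    tabulate(idx[, j], nbins = K), integer(K))
  C[, colSums(C) >= 1L, drop = FALSE]
}

# H1 log-likelihood at divergence t (branch t/2 per unit):
# per column, sum_a pi_a prod_rows P(a -> x_r | t/2).
.star_loglik <- function(C, model, t) {
  lP <- log(prob_matrix(model, t / 2))
  lP[!is.finite(lP)] <- -745  # log(double.xmin): keeps 0 * log(0) at 0
  W <- lP %*% C                      # [ancestor, column]
  mx <- apply(W, 2, max)
  sum(mx + log(colSums(model$pi * exp(sweep(W, 2, mx, "-")))))
}

.fit_star <- function(C, model, t_max = 10, tol = 1e-6) {
  f <- function(t) .star_loglik(C, model, t)
  opt <- stats::optimize(f, c(0, t_max), maximum = TRUE, tol = tol)
  # compare against the boundaries so t-hat = 0 is returned exactly when
  # identical units make the likelihood decreasing in t
  cand_t <- c(opt$maximum, 0, t_max)
  cand_l <- c(opt$objective, f(0), f(t_max))
  k <- which.max(cand_l)
  list(t_hat = cand_t[k], lnL1 = cand_l[k])
}

#' Homology likelihood-ratio test for a tandem repeat
#'
#' Tests whether the units of an alignment share common ancestry. H1
#' evaluates each column as independent descent from an unobserved common
#' ancestor on a star tree at ML divergence `t`; H0 is independent draws
#' from the stationary frequencies. The statistic is `2 (lnL1 - lnL0)` and
#' the p-value is the add-one-corrected rank of the observed statistic
#' among `null_draws` statistics recomputed after shuffling the residues
#' within each row.
#'
#' @param ua a [unit_alignment()] with >= 2 units.
#' @param model a reversible `subst_model`; defaults to the symmetric model
#'   on the alignment's alphabet.
#' @param null_draws number of permutation draws (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list of class `homology_test`: `lnL1`, `lnL0`, `statistic`,
#'   `t_hat`, `pvalue`.
#' @export
homology_lrt <- function(ua, model = NULL, null_draws = 1000, seed = NULL) {
  if (length(ua$rows) < 2L) ts_stop("need >= 2 units")
  model <- model %||% subst_model_symmetric(ua$alphabet)
  C <- .column_counts(ua)
  if (!ncol(C) || !any(colSums(C) >= 2L)) ts_stop("degenerate alignment")
  lpi <- log(model$pi)
  stat_of <- function(C) {
    fit <- .fit_star(C, model)
    lnL0 <- sum(C * lpi)
    c(stat = 2 * (fit$lnL1 - lnL0), t_hat = fit$t_hat,
      lnL1 = fit$lnL1, lnL0 = lnL0)
  }
  obs <- stat_of(C)
  pvalue <- NA_real_
  if (null_draws > 0) {
    M <- ua_matrix(ua)
    pvalue <- with_seed(seed, {
      ge <- 0L
      for (d in seq_len(null_draws)) {
        Mp <- M
        for (r in seq_len(nrow(M))) {
          res <- which(M[r, ] != "-")
          Mp[r, res] <- M[r, res[sample.int(length(res))]]
        }
        uap <- ua
        uap$rows <- apply(Mp, 1, paste, collapse = "")
        Cp <- .column_counts(uap)
        if (stat_of(Cp)["stat"] > obs["stat"] + 1e-9) ge <- ge + 1L
      }
      (1 + ge) / (null_draws + 1)
    })
  }
  structure(list(lnL1 = unname(obs["lnL1"]), lnL0 = unname(obs["lnL0"]),
                 statistic = unname(obs["stat"]),
                 t_hat = unname(obs["t_hat"]), pvalue = pvalue),
            class = "homology_test")
}

#' @export
print.homology_test <- function(x, ...) {
  cat(sprintf("<homology_test> 2dlnL = %.3f, t-hat = %.4f, p = %s\n",
              x$statistic, x$t_hat,
              if (is.na(x$pvalue)) "NA" else format(x$pvalue)))
  invisible(x)
}

#' Maximum-likelihood divergence of a unit alignment
#'
#' The divergence `t` (expected substitutions per site between units)
#' maximizing the star-tree homology likelihood, searched on `[0, 10]`
#' to tolerance 1e-6.
#'
#' @inheritParams homology_lrt
#' @return the ML divergence estimate (scalar).
#' @export
ml_divergence <- function(ua, model = NULL) {
  model <- model %||% subst_model_symmetric(ua$alphabet)
  C <- .column_counts(ua)
  if (!ncol(C) || !any(colSums(C) >= 2L)) ts_stop("degenerate alignment")
  .fit_star(C, model)$t_hat
}

#' Resolve overlapping repeat annotations
#'
#' Two hits on the same sequence overlap when they share more than half of
#' the shorter span. Within each connected overlap cluster exactly one hit
#' is kept, chosen by lowest p-value, then highest forward log-odds, then
#' longest span, then leftmost start. The result is sorted by sequence then
#' start, and the operation is idempotent.
#'
#' @param hits either a list of `repeat_hit` objects or a hit table data
#'   frame with columns sequence_id, start, end, pvalue, forward_logodds.
#' @param max_overlap overlap fraction above which two hits conflict (0.5).
#' @return filtered hits, same type as the input.
#' @export
filter_overlaps <- function(hits, max_overlap = 0.5) {
  is_list <- !is.data.frame(hits)
  tab <- if (is_list) hits_to_table(hits) else hits
  n <- nrow(tab)
  if (n <= 1) return(hits)
  keep <- logical(n)
  pv <- ifelse(is.na(tab$pvalue), Inf, tab$pvalue)
  pri <- order(pv, -tab$forward_logodds, -(tab$end - tab$start), tab$start)
  # connected components of the overlap graph, per sequence
  comp <- seq_len(n)
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    if (tab$sequence_id[a] != tab$sequence_id[b]) next
    shared <- min(tab$end[a], tab$end[b]) - max(tab$start[a], tab$start[b])
    minlen <- min(tab$end[a] - tab$start[a], tab$end[b] - tab$start[b])
    if (shared > 0 && minlen > 0 && shared / minlen > max_overlap) {
      old <- comp[b]; comp[comp == old] <- comp[a]
    }
  }
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    keep[pri[pri %in% members][1]] <- TRUE
  }
  ord <- order(tab$sequence_id[keep], tab$start[keep])
  if (is_list) hits[keep][ord] else tab[which(keep)[ord], , drop = FALSE]
}
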