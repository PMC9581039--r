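#' Substitution models
#'
#' Reversible substitution models over an alphabet, used by the homology
#' likelihood-ratio test, guide-tree distances, PIP alignment and the
#' simulator. The default is the equal-exchangeability model stationary on
#' the alphabet background (Felsenstein-81 style; it reduces exactly to
#' Jukes--Cantor when the background is uniform, as for DNA and custom
#' alphabets), normalized to one expected substitution per site per unit
#' time, with closed-form transition probabilities. Arbitrary reversible
#' rate matrices can be supplied via `subst_model_matrix()`.
#'
#' @param alphabet a [alphabet()].
#' @param pi stationary frequencies; defaults to the alphabet background.
#' @return An object of class `subst_model` with fields `alphabet`, `pi`
#'   and a transition-probability backend.
#' @export
subst_model_symmetric <- function(alphabet, pi = NULL) {
  pi <- pi %||% alphabet$background
  pi <- pi / sum(pi)
  C <- 1 - sum(pi^2)  # saturation p-distance; rate normalizer beta = 1/C
  structure(list(kind = "symmetric", alphabet = alphabet,
                 pi = stats::setNames(as.numeric(pi), alphabet$symbols),
                 beta = 1 / C, saturation = C),
            class = "subst_model")
}

#' @rdname subst_model_symmetric
#' @param Q reversible rate matrix (rows sum to zero) over the alphabet
#'   symbols; rescaled so the expected substitution rate at stationarity
#'   is 1 per unit time.
#' @export
subst_model_matrix <- function(alphabet, Q, pi = NULL) {
  K <- length(alphabet$symbols)
  stopifnot(nrow(Q) == K, ncol(Q) == K)
  if (is.null(pi)) {
    # stationary distribution: left null vector of Q
    ev <- eigen(t(Q))
    i0 <- which.min(abs(ev$values))
    pi <- Re(ev$vectors[, i0]); pi <- pi / sum(pi)
  }
  if (any(pi <= 0)) ts_stop("stationary frequencies must be positive")
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  # symmetrize for a stable eigendecomposition (reversibility assumed)
  S <- diag(sqrt(pi)) %*% Q %*% diag(1 / sqrt(pi))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  structure(list(kind = "general", alphabet = alphabet,
                 pi = stats::setNames(pi, alphabet$symbols),
                 saturation = 1 - sum(pi^2),
                 evals = es$values,
                 U = diag(1 / sqrt(pi)) %*% es$vectors,
                 Uinv = t(es$vectors) %*% diag(sqrt(pi))),
            class = "subst_model")
}

#' Transition probability matrix P(t)
#'
#' @param model a `subst_model`.
#' @param t branch length in expected substitutions per site (>= 0).
#' @return K x K matrix, rows = ancestral state.
#' @export
prob_matrix <- function(model, t) {
  K <- length(model$alphabet$symbols)
  if (t < 0) ts_stop("branch length must be non-negative")
  if (model$kind == "symmetric") {
    e <- exp(-model$beta * t)
    P <- matrix((1 - e) * model$pi, K, K, byrow = TRUE)
    diag(P) <- diag(P) + e
  } else {
    P <- model$U %*% (exp(model$evals * t) * model$Uinv)
    P[P < 0] <- 0
    P <- P / rowSums(P)
  }
  dimnames(P) <- list(model$alphabet$symbols, model$alphabet$symbols)
  P
}

# Expected p-distance between ancestor and descendant at time t.
p_distance <- function(model, t) {
  P <- prob_matrix(model, t)
  sum(model$pi * (1 - diag(P)))
}

# ML distance from an observed p-distance under the model (closed-form
# inversion of the p-distance curve); capped at t_max.
ml_pair_distance <- function(p, model, t_max = 10) {
  C <- model$saturation
  if (p >= C * (1 - 1e-9)) return(t_max)
  min(-C * log(1 - p / C), t_max)
}
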