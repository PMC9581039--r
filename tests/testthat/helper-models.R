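# Shared fixtures and independent oracles. Everything is generated in code;
# the oracles are deliberately written in plain probability space with
# closed-form closures so they share no arithmetic with the package's
# log-space dynamic programming.

toy_cphmm <- function(exit_prob = 0.1) {
  dna <- alphabet("dna")
  em <- rbind(c(A = 0.9, C = 1 / 30, G = 1 / 30, T = 1 / 30),
              c(A = 1 / 30, C = 0.9, G = 1 / 30, T = 1 / 30))
  ie <- rbind(dna$background, dna$background)
  tr <- rbind(c(0.98, 0.01, 0.01, 0.9, 0.05, 0.05, 0.9, 0.05, 0.05),
              c(0.98, 0.01, 0.01, 0.9, 0.05, 0.05, 0.9, 0.05, 0.05))
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DD", "DI")
  p <- structure(list(L = 2L, alphabet = dna, match_emis = em,
                      insert_emis = ie, trans = tr),
                 class = "profile_hmm")
  circularize(p, exit_prob = exit_prob)
}

# Random small cpHMM over a 2-4 letter alphabet, built through the public
# profile constructor from random gapless unit rows.
random_cphmm <- function(L = sample(1:3, 1), K = sample(2:4, 1)) {
  syms <- LETTERS[seq_len(K)]
  alpha <- if (K == 4) alphabet("dna") else custom_alphabet(syms)
  syms <- alpha$symbols
  rows <- replicate(sample(2:4, 1),
                    paste(sample(syms, L, TRUE), collapse = ""))
  ua <- unit_alignment(rows, alphabet = alpha)
  pr <- build_profile(ua, pseudocount_weight = runif(1, 0.3, 2))
  circularize(pr, exit_prob = runif(1, 0.05, 0.3))
}

random_window <- function(m, n = sample(2:7, 1)) {
  paste(sample(m$base$alphabet$symbols, n, TRUE), collapse = "")
}

# Exhaustive-path oracle for window scores. Emission-state paths are
# enumerated explicitly; runs of silent delete states between emissions are
# summed in closed form with (I - D)^-1 (forward) or the unique simple
# cycle path (Viterbi). Returns bits.
enum_window_logodds <- function(m, null, window) {
  p <- m$base
  L <- p$L
  eps <- m$exit_prob
  tr <- p$trans
  tr[, c("MM", "MI", "MD")] <- tr[, c("MM", "MI", "MD")] * (1 - eps)
  x <- match(strsplit(toupper(window), "")[[1]], p$alphabet$symbols)
  n <- length(x)
  nf <- as.numeric(null$freqs)
  nxt <- function(i) if (i == L) 1L else i + 1L
  Dmat <- matrix(0, L, L)
  for (i in seq_len(L)) Dmat[i, nxt(i)] <- tr[i, "DD"]
  Clo <- solve(diag(L) - Dmat)
  Wmax <- matrix(0, L, L)
  for (i in seq_len(L)) for (k in seq_len(L)) {
    w <- 1; cur <- i
    while (cur != k) { w <- w * Dmat[cur, nxt(cur)]; cur <- nxt(cur) }
    Wmax[i, k] <- w
  }
  S <- 2L * L
  Ts <- matrix(0, S, S); Tv <- matrix(0, S, S)
  for (p1 in seq_len(L)) for (k1 in 1:2) {
    from <- p1 + (k1 - 1L) * L
    tM <- tr[p1, if (k1 == 1) "MM" else "IM"]
    tI <- tr[p1, if (k1 == 1) "MI" else "II"]
    tD <- tr[p1, if (k1 == 1) "MD" else "ID"]
    Ts[from, nxt(p1)] <- Ts[from, nxt(p1)] + tM
    Tv[from, nxt(p1)] <- max(Tv[from, nxt(p1)], tM)
    Ts[from, L + p1] <- Ts[from, L + p1] + tI
    Tv[from, L + p1] <- max(Tv[from, L + p1], tI)
    if (tD > 0) for (j in seq_len(L)) {
      Ts[from, nxt(j)] <- Ts[from, nxt(j)] + tD * Clo[nxt(p1), j] * tr[j, "DM"]
      Tv[from, nxt(j)] <- max(Tv[from, nxt(j)],
                              tD * Wmax[nxt(p1), j] * tr[j, "DM"])
      Ts[from, L + j] <- Ts[from, L + j] + tD * Clo[nxt(p1), j] * tr[j, "DI"]
      Tv[from, L + j] <- max(Tv[from, L + j],
                             tD * Wmax[nxt(p1), j] * tr[j, "DI"])
    }
  }
  emis <- function(s, xi) if (s <= L) p$match_emis[s, xi] / nf[xi] else
    p$insert_emis[s - L, xi] / nf[xi]
  total <- 0; best <- -Inf
  rec <- function(s, j, ws, wv) {
    if (j == n) {
      if (s <= L) {
        total <<- total + ws * eps
        if (wv * eps > best) best <<- wv * eps
      }
      return()
    }
    for (s2 in seq_len(S)) if (Ts[s, s2] > 0) {
      e <- emis(s2, x[j + 1L])
      rec(s2, j + 1L, ws * Ts[s, s2] * e, wv * Tv[s, s2] * e)
    }
  }
  for (i in seq_len(L)) {
    e <- emis(i, x[1])
    rec(i, 1L, m$begin_weights[i] * e, m$begin_weights[i] * e)
  }
  c(forward = unname(log2(total)), viterbi = unname(log2(best)))
}

# Rotate profile columns by k (new position i carries old position i + k).
rotate_cphmm <- function(m, k) {
  p <- m$base
  idx <- ((seq_len(p$L) - 1 + k) %% p$L) + 1
  p2 <- p
  p2$match_emis <- p$match_emis[idx, , drop = FALSE]
  p2$insert_emis <- p$insert_emis[idx, , drop = FALSE]
  p2$trans <- p$trans[idx, , drop = FALSE]
  circularize(p2, m$exit_prob, m$wrap)
}

# Independent pairwise PIP oracle on the 2-leaf star tree: closed-form
# column masses, exhaustive enumeration of all monotone alignments.
pip_pair_best <- function(sa, sb, bx, by, lambda, mu, model) {
  pi <- as.numeric(model$pi)
  Pa <- prob_matrix(model, bx); Pb <- prob_matrix(model, by)
  ea <- exp(-mu * bx); eb <- exp(-mu * by)
  Ba <- (1 - exp(-mu * bx)) / (mu * bx)
  Bb <- (1 - exp(-mu * by)) / (mu * by)
  ia <- match(strsplit(sa, "")[[1]], model$alphabet$symbols)
  ib <- match(strsplit(sb, "")[[1]], model$alphabet$symbols)
  nu <- lambda * (bx + by + 1 / mu)
  p_match <- function(x, y) (lambda / mu) * sum(pi * (ea * Pa[, x]) * (eb * Pb[, y]))
  p_ga <- function(x) lambda * bx * Ba * pi[x] +
    (lambda / mu) * sum(pi * (ea * Pa[, x]) * (1 - eb))
  p_gb <- function(y) lambda * by * Bb * pi[y] +
    (lambda / mu) * sum(pi * (1 - ea) * (eb * Pb[, y]))
  p_empty <- (lambda * bx * (1 - Ba) + lambda * by * (1 - Bb) +
                (lambda / mu) * (1 - ea) * (1 - eb)) / nu
  best <- -Inf
  na <- length(ia); nb <- length(ib)
  rec <- function(i, j, lp, m) {
    if (i > na && j > nb) {
      tot <- lp - lfactorial(m) + nu * (p_empty - 1)
      if (tot > best) best <<- tot
      return()
    }
    if (i <= na && j <= nb)
      rec(i + 1, j + 1, lp + log(p_match(ia[i], ib[j])), m + 1)
    if (i <= na) rec(i + 1, j, lp + log(p_ga(ia[i])), m + 1)
    if (j <= nb) rec(i, j + 1, lp + log(p_gb(ib[j])), m + 1)
  }
  rec(1, 1, 0, 0)
  best
}

# Sample one generative pass (B -> ... -> E) from a cpHMM; returns the
# lengths of the complete units emitted (between consecutive wraps).
sample_unit_lengths <- function(m, max_steps = 10000) {
  p <- m$base; L <- p$L; eps <- m$exit_prob
  pos <- sample.int(L, 1, prob = m$begin_weights)
  state <- "M"
  emitted <- 0L; unit_lens <- integer(0); since_wrap <- 0L; wrapped_once <- FALSE
  for (step in seq_len(max_steps)) {
    if (state == "M") {
      emitted <- emitted + 1L; since_wrap <- since_wrap + 1L
      if (runif(1) < eps) break
    } else if (state == "I") {
      emitted <- emitted + 1L; since_wrap <- since_wrap + 1L
    }
    tr <- p$trans[pos, ]
    mv <- switch(state,
                 M = sample(c("MM", "MI", "MD"), 1, prob = tr[1:3]),
                 I = sample(c("IM", "II", "ID"), 1, prob = tr[4:6]),
                 D = sample(c("DM", "DD", "DI"), 1, prob = tr[7:9]))
    adv <- substr(mv, 2, 2) != "I"
    newpos <- if (substr(mv, 2, 2) == "I") pos else if (pos == L) 1L else pos + 1L
    if (adv && pos == L) {  # wrap
      if (wrapped_once) unit_lens <- c(unit_lens, since_wrap)
      wrapped_once <- TRUE
      since_wrap <- 0L
    }
    state <- substr(mv, 2, 2)
    pos <- newpos
  }
  unit_lens
}

train_model_from_sim <- function(anc, n_units, t, seed,
                                 alpha = alphabet("aa"),
                                 pseudocount = 1, exit_prob = 0.05) {
  sim <- simulate_repeat(anc, n_units, t, 0, flank_lengths = c(0L, 0L),
                         seed = seed, alphabet = alpha)
  ua <- unit_alignment(sim$truth$units, alphabet = alpha)
  circularize(build_profile(ua, pseudocount), exit_prob)
}

random_protein <- function(n, alpha = alphabet("aa")) {
  paste(sample(alpha$symbols, n, TRUE, prob = alpha$background),
        collapse = "")
}
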