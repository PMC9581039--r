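# Evolutionary realignment of tandem-repeat units under the Poisson Indel
# Process (PIP): insertions arrive as a Poisson process with rate lambda
# along the guide tree (plus root mass lambda/mu), every character dies at
# rate mu, and substitutions follow the package's reversible models. The
# progressive aligner merges subalignments up the guide tree with a
# three-state dynamic program that maximizes the exact PIP column
# likelihood, including the alignment-length factor nu^m / m!.

#' PIP model parameters
#'
#' @param lambda insertion rate (events per unit time per sequence), > 0.
#' @param mu deletion rate (events per unit time per character), > 0.
#' @param rate_model `"constant"` or `"gamma"` (gamma-distributed indel
#'   rate variation across columns).
#' @param alpha gamma shape parameter (default 0.5).
#' @param n_rate_categories number of discretized gamma categories (4).
#' @return object of class `pip_params`.
#' @export
pip_params <- function(lambda, mu, rate_model = c("constant", "gamma"),
                       alpha = 0.5, n_rate_categories = 4) {
  rate_model <- match.arg(rate_model)
  if (!is.numeric(lambda) || lambda <= 0) ts_stop("lambda must be > 0")
  if (!is.numeric(mu) || mu <= 0) ts_stop("mu must be > 0")
  if (!is.numeric(alpha) || alpha <= 0) ts_stop("alpha must be > 0")
  structure(list(lambda = lambda, mu = mu, rate_model = rate_model,
                 alpha = alpha, n_rate_categories = as.integer(n_rate_categories)),
            class = "pip_params")
}

# Mean rates of k equal-probability categories of a Gamma(shape, shape)
# distribution (mean 1), the usual discretization for rate variation.
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1) return(1)
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  r <- k * (stats::pgamma(bounds[-1], shape = alpha + 1, rate = alpha) -
              stats::pgamma(bounds[-(k + 1)], shape = alpha + 1, rate = alpha))
  r / mean(r)
}

.pip_rates <- function(params) {
  if (params$rate_model == "gamma")
    discrete_gamma_rates(params$alpha, params$n_rate_categories)
  else 1
}

# Character survival probability over a branch of length b: probability
# that a character inserted uniformly along the branch is still alive at
# the bottom.
pip_beta <- function(b, mu) {
  x <- mu * b
  ifelse(x < 1e-10, 1, (1 - exp(-x)) / x)
}

#' Estimate PIP indel rates from an initial alignment
#'
#' Event-counting estimator: the deletion rate is the number of maximal gap
#' runs across all rows per unit of (tree length x mean ungapped row
#' length); the insertion rate follows from stationarity of the expected
#' sequence length under PIP, `E[length] = lambda / mu`. Both rates are
#' floored at 1e-4 and the deletion rate is capped at 10.
#'
#' @param ua a [unit_alignment()] with at least one gap.
#' @param tree guide tree (`phylo`) with positive total branch length.
#' @return named numeric vector `c(lambda, mu)`.
#' @export
estimate_indel_rates <- function(ua, tree) {
  runs <- sum(vapply(ua$rows, function(r) {
    rl <- rle(.split_chars(r) == "-"); sum(rl$values)
  }, integer(1)))
  if (runs == 0) ts_stop("initial alignment should have at least one gap")
  meanlen <- mean(nchar(gsub("-", "", ua$rows, fixed = TRUE)))
  tlen <- max(sum(tree$edge.length), 1e-8)
  mu <- min(max(runs / (tlen * meanlen), 1e-4), 10)
  lambda <- max(mu * meanlen, 1e-4)
  c(lambda = lambda, mu = unname(mu))
}

#' Infer a guide tree over repeat units
#'
#' Pairwise maximum-likelihood distances under the module's substitution
#' model (closed-form inversion of the p-distance over shared ungapped
#' sites), then neighbor-joining with negative branch lengths clamped to
#' zero and midpoint rooting. With fewer than 3 units a star tree is built
#' directly from the pairwise distance.
#'
#' @param ua a [unit_alignment()].
#' @param model a `subst_model` (defaults to symmetric on the alphabet);
#'   only its alphabet size enters the distance formula.
#' @return a rooted `phylo` tree whose tips are the unit names.
#' @export
infer_guide_tree <- function(ua, model = NULL) {
  model <- model %||% subst_model_symmetric(ua$alphabet)
  M <- ua_matrix(ua)
  n <- nrow(M)
  labs <- names(ua$rows)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    both <- M[i, ] != "-" & M[j, ] != "-"
    p <- if (any(both)) mean(M[i, both] != M[j, both]) else 0
    D[i, j] <- D[j, i] <- ml_pair_distance(p, model)
  }
  if (n < 3) {
    txt <- sprintf("(%s:%f,%s:%f);", labs[1], D[1, 2] / 2, labs[2], D[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  tr <- tryCatch({
    t0 <- ape::nj(stats::as.dist(D))
    t0$edge.length[t0$edge.length < 0] <- 0
    phangorn::midpoint(t0)
  }, error = function(e) phangorn::upgma(stats::as.dist(D)))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# ---- progressive PIP internals -------------------------------------------

# Per-merge constants for one branch and one rate category.
.branch_terms <- function(model, b, mu_g) {
  list(P = prob_matrix(model, b),
       e = exp(-mu_g * b),
       beta = pip_beta(b, mu_g),
       b = b)
}

# Merge two child states at an internal node. A state carries the aligned
# rows, and per rate category the column likelihood vectors G (K x m,
# P(leaf data below | char present at node)), the accumulated
# branch-insertion mass A (length m), and the all-dead-below vector z (K).
.pip_merge <- function(X, Y, bx, by, prep) {
  model <- prep$model; K <- prep$K
  ncat <- length(prep$rates)
  mx <- ncol(X$G[[1]]); my <- ncol(Y$G[[1]])
  subtree_len <- X$tlen + Y$tlen + bx + by
  accM <- matrix(0, mx, my)
  accX <- numeric(mx); accY <- numeric(my)
  nu_g <- numeric(ncat)
  pre <- vector("list", ncat)
  for (g in seq_len(ncat)) {
    lam <- prep$lambda * prep$rates[g]; mu <- prep$mu * prep$rates[g]
    tx <- .branch_terms(model, bx, mu); ty <- .branch_terms(model, by, mu)
    hx <- tx$e * (tx$P %*% X$G[[g]])          # K x mx
    hy <- ty$e * (ty$P %*% Y$G[[g]])
    dxg <- (1 - tx$e) + tx$e * as.vector(tx$P %*% X$z[[g]])
    dyg <- (1 - ty$e) + ty$e * as.vector(ty$P %*% Y$z[[g]])
    fx <- tx$beta * as.vector(model$pi %*% X$G[[g]])
    fy <- ty$beta * as.vector(model$pi %*% Y$G[[g]])
    nu_g[g] <- lam * (subtree_len + 1 / mu)
    accM <- accM + (t(hx * model$pi) %*% hy) * (lam / mu) / nu_g[g]
    accX <- accX + (X$A[[g]] + lam * bx * fx +
                      (lam / mu) * as.vector((model$pi * dyg) %*% hx)) / nu_g[g]
    accY <- accY + (Y$A[[g]] + lam * by * fy +
                      (lam / mu) * as.vector((model$pi * dxg) %*% hy)) / nu_g[g]
    pre[[g]] <- list(hx = hx, hy = hy, dx = dxg, dy = dyg, fx = fx, fy = fy,
                     lam = lam, mu = mu, tx = tx, ty = ty)
  }
  lnu <- log(mean(nu_g))
  lpM <- log(accM / ncat) + lnu
  lpX <- log(accX / ncat) + lnu
  lpY <- log(accY / ncat) + lnu

  moves <- .pip_dp(lpM, lpX, lpY)

  # assemble merged rows and per-column quantities along the chosen path
  nX <- length(X$rows); nY <- length(Y$rows)
  m <- length(moves$op)
  rowsX <- matrix("-", nX, m); rowsY <- matrix("-", nY, m)
  Xmat <- do.call(rbind, lapply(X$rows, .split_chars))
  Ymat <- do.call(rbind, lapply(Y$rows, .split_chars))
  G <- lapply(seq_len(ncat), function(g) matrix(0, K, m))
  A <- lapply(seq_len(ncat), function(g) numeric(m))
  for (c0 in seq_len(m)) {
    op <- moves$op[c0]; ci <- moves$ix[c0]; cj <- moves$iy[c0]
    if (op != 3L) rowsX[, c0] <- Xmat[, ci]
    if (op != 2L) rowsY[, c0] <- Ymat[, cj]
    for (g in seq_len(ncat)) {
      pg <- pre[[g]]
      if (op == 1L) {
        G[[g]][, c0] <- pg$hx[, ci] * pg$hy[, cj]
        A[[g]][c0] <- 0
      } else if (op == 2L) {
        G[[g]][, c0] <- pg$hx[, ci] * pg$dy
        A[[g]][c0] <- X$A[[g]][ci] + pg$lam * bx * pg$fx[ci]
      } else {
        G[[g]][, c0] <- pg$dx * pg$hy[, cj]
        A[[g]][c0] <- Y$A[[g]][cj] + pg$lam * by * pg$fy[cj]
      }
    }
  }
  z <- lapply(seq_len(ncat), function(g) {
    pg <- pre[[g]]
    ((1 - pg$tx$e) + pg$tx$e * as.vector(pg$tx$P %*% X$z[[g]])) *
      ((1 - pg$ty$e) + pg$ty$e * as.vector(pg$ty$P %*% Y$z[[g]]))
  })
  rows <- c(apply(rowsX, 1, paste, collapse = ""),
            apply(rowsY, 1, paste, collapse = ""))
  names(rows) <- c(names(X$rows), names(Y$rows))
  list(rows = rows, G = G, A = A, z = z, tlen = subtree_len)
}

# Three-move DP over column counts. The exact score of a path with k
# columns includes -log(k!), handled with a third (length) dimension; for
# very large merges a 2-D approximation with running length max(i,j) is
# used instead. Tie-break: match > gap-in-Y > gap-in-X side (M > X > Y).
.pip_dp <- function(lpM, lpX, lpY, max_cells = 2e7) {
  mx <- nrow(lpM); my <- ncol(lpM)
  KD <- mx + my + 1L
  exact <- (mx + 1) * (my + 1) * KD <= max_cells
  if (exact) {
    S <- array(-Inf, c(mx + 1L, my + 1L, KD))
    PT <- array(0L, c(mx + 1L, my + 1L, KD))
    S[1, 1, 1] <- 0
    lk <- log(seq_len(KD - 1L))
    for (i in 0:mx) for (j in 0:my) {
      if (i == 0 && j == 0) next
      cm <- if (i > 0 && j > 0) S[i, j, ] else rep(-Inf, KD)
      cx <- if (i > 0) S[i, j + 1L, ] else rep(-Inf, KD)
      cy <- if (j > 0) S[i + 1L, j, ] else rep(-Inf, KD)
      cand <- cbind(if (i > 0 && j > 0) cm + lpM[i, j] else cm,
                    if (i > 0) cx + lpX[i] else cx,
                    if (j > 0) cy + lpY[j] else cy)
      # shift in k: new column count = k + 1
      cand <- cand[-KD, , drop = FALSE]
      pick <- max.col(cand, ties.method = "first")
      val <- cand[cbind(seq_len(KD - 1L), pick)]
      val <- val - lk
      S[i + 1L, j + 1L, -1L] <- val
      PT[i + 1L, j + 1L, -1L] <- ifelse(is.finite(val), pick, 0L)
    }
    k <- which.max(S[mx + 1L, my + 1L, ])
    score <- S[mx + 1L, my + 1L, k]
    if (!is.finite(score))
      stop("non-finite PIP likelihood: no alignment has positive probability")
    i <- mx; j <- my
    op <- integer(0); ix <- integer(0); iy <- integer(0)
    while (i > 0 || j > 0) {
      mv <- PT[i + 1L, j + 1L, k]
      if (!length(mv) || mv == 0L)
        stop("PIP traceback failed (non-finite column likelihoods)")
      op <- c(mv, op)
      ix <- c(if (mv != 3L) i else NA_integer_, ix)
      iy <- c(if (mv != 2L) j else NA_integer_, iy)
      if (mv != 3L) i <- i - 1L
      if (mv != 2L) j <- j - 1L
      k <- k - 1L
    }
    list(op = op, ix = ix, iy = iy, score = score)
  } else {
    S <- matrix(-Inf, mx + 1L, my + 1L); S[1, 1] <- 0
    PT <- matrix(0L, mx + 1L, my + 1L)
    for (i in 0:mx) for (j in 0:my) {
      if (i == 0 && j == 0) next
      pen <- -log(max(i, j))
      cand <- c(if (i > 0 && j > 0) S[i, j] + lpM[i, j] else -Inf,
                if (i > 0) S[i, j + 1L] + lpX[i] else -Inf,
                if (j > 0) S[i + 1L, j] + lpY[j] else -Inf)
      pick <- which.max(cand)
      S[i + 1L, j + 1L] <- cand[pick] + pen
      PT[i + 1L, j + 1L] <- pick
    }
    i <- mx; j <- my
    op <- integer(0); ix <- integer(0); iy <- integer(0)
    while (i > 0 || j > 0) {
      mv <- PT[i + 1L, j + 1L]
      op <- c(mv, op)
      ix <- c(if (mv != 3L) i else NA_integer_, ix)
      iy <- c(if (mv != 2L) j else NA_integer_, iy)
      if (mv != 3L) i <- i - 1L
      if (mv != 2L) j <- j - 1L
    }
    list(op = op, ix = ix, iy = iy, score = S[mx + 1L, my + 1L])
  }
}

.pip_leaf_state <- function(name, residues, prep) {
  chars <- .split_chars(residues)
  K <- prep$K
  G0 <- matrix(0, K, length(chars))
  idx <- match(chars, prep$model$alphabet$symbols)
  for (c0 in seq_along(chars)) {
    if (is.na(idx[c0])) G0[, c0] <- 1 else G0[idx[c0], c0] <- 1
  }
  ncat <- length(prep$rates)
  list(rows = stats::setNames(residues, name),
       G = rep(list(G0), ncat),
       A = rep(list(numeric(length(chars))), ncat),
       z = rep(list(numeric(K)), ncat),
       tlen = 0)
}

#' Progressive PIP alignment of ungapped unit sequences
#'
#' Aligns the units up the guide tree. At every internal node a three-state
#' dynamic program (match / gap in one child / gap in the other) maximizes
#' the PIP likelihood of the merged columns: substitution likelihood by
#' pruning, insertion intensity proportional to `lambda x branch length`
#' plus root mass `lambda / mu`, survival probability
#' `beta(b) = (1 - exp(-mu b)) / (mu b)`, and the alignment-length factor.
#' Under gamma rate variation the column likelihood is averaged over the
#' discretized categories. All input residues are preserved in order.
#'
#' @param units named character vector of ungapped unit sequences (>= 2).
#' @param tree rooted guide tree (`phylo`) with tips matching the unit
#'   names; multifurcations are folded left-to-right with zero-length
#'   internal branches. Defaults to a star tree with branch length 0.2.
#' @param params a [pip_params()].
#' @param model a `subst_model`; defaults to symmetric.
#' @param alphabet used when `model` is `NULL`.
#' @return a [unit_alignment()] (rows in input order); the PIP log
#'   likelihood of the returned alignment is in attribute `"loglik"`.
#' @export
pip_align <- function(units, tree = NULL, params = NULL, model = NULL,
                      alphabet = NULL) {
  units <- toupper(units)
  if (length(units) < 2) ts_stop("need >= 2 units")
  if (any(nchar(units) == 0)) ts_stop("zero-length input unit")
  if (is.null(names(units))) names(units) <- paste0("unit_", seq_along(units))
  if (is.null(alphabet)) alphabet <- guess_alphabet(units)
  model <- model %||% subst_model_symmetric(alphabet)
  params <- params %||% pip_params(mean(nchar(units)) * 0.05, 0.05)
  if (is.null(tree)) {
    txt <- paste0("(", paste(sprintf("%s:0.2", names(units)), collapse = ","),
                  ");")
    tree <- ape::read.tree(text = txt)
  }
  if (!all(sort(tree$tip.label) == sort(names(units))))
    ts_stop("guide tree tips must match unit names")
  # zero-length branches give indel events zero intensity and make any gap
  # column impossible; floor them so degenerate trees stay alignable
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmax(tree$edge.length, 1e-4)
  prep <- list(model = model, K = length(model$alphabet$symbols),
               lambda = params$lambda, mu = params$mu,
               rates = .pip_rates(params))
  state <- .pip_node_state(tree, length(tree$tip.label) + 1L, units, prep)
  rows <- state$rows[names(units)]
  ua <- unit_alignment(rows, alphabet = alphabet)
  attr(ua, "loglik") <- pip_loglik(ua, tree, params, model)
  if (!is.finite(attr(ua, "loglik")))
    stop(sprintf("non-finite PIP likelihood (lambda=%g, mu=%g, %d units)",
                 params$lambda, params$mu, length(units)))
  ua
}

# Recursive postorder merge; multifurcations folded with zero-length
# pseudo-branches on the accumulated side.
.pip_node_state <- function(tree, node, units, prep) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    nm <- tree$tip.label[node]
    return(.pip_leaf_state(nm, units[[nm]], prep))
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  blens <- tree$edge.length[tree$edge[, 1] == node]
  acc <- .pip_node_state(tree, kids[1], units, prep)
  bacc <- blens[1]
  for (k in seq_along(kids)[-1]) {
    st <- .pip_node_state(tree, kids[k], units, prep)
    acc <- .pip_merge(acc, st, bacc, blens[k], prep)
    bacc <- 0
  }
  acc
}

#' PIP log-likelihood of a fixed alignment
#'
#' Evaluates the full PIP likelihood of an existing unit alignment on a
#' guide tree (same column machinery as the progressive aligner, without
#' any optimization), including the length factor and the empty-column
#' normalizer.
#'
#' @param ua a [unit_alignment()]; row names must match the tree tips.
#' @param tree rooted `phylo` guide tree.
#' @param params a [pip_params()].
#' @param model a `subst_model`; defaults to symmetric.
#' @return log-likelihood (natural log).
#' @export
pip_loglik <- function(ua, tree, params = NULL, model = NULL) {
  model <- model %||% subst_model_symmetric(ua$alphabet)
  params <- params %||% pip_params(mean(nchar(gsub("-", "", ua$rows))) * 0.05,
                                   0.05)
  rates <- .pip_rates(params)
  K <- length(model$alphabet$symbols)
  M <- ua_matrix(ua)
  rownames(M) <- names(ua$rows)
  m <- ncol(M)
  tlen <- sum(tree$edge.length)
  ntip <- length(tree$tip.label)
  colscore <- 0
  consts <- numeric(length(rates))
  per_g <- vector("list", length(rates))
  for (g in seq_along(rates)) {
    lam <- params$lambda * rates[g]; mu <- params$mu * rates[g]
    walk <- function(node) {
      if (node <= ntip) {
        row <- M[tree$tip.label[node], ]
        G <- matrix(0, K, m)
        idx <- match(row, model$alphabet$symbols)
        for (c0 in seq_len(m)) {
          if (row[c0] == "-") next
          if (is.na(idx[c0])) G[, c0] <- 1 else G[idx[c0], c0] <- 1
        }
        return(list(G = G, A = numeric(m), empty = row == "-",
                    z = numeric(K), S0 = 0))
      }
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      blens <- tree$edge.length[tree$edge[, 1] == node]
      acc <- walk(kids[1]); bacc <- blens[1]
      for (k in seq_along(kids)[-1]) {
        st <- walk(kids[k]); bk <- blens[k]
        tx <- .branch_terms(model, bacc, mu)
        ty <- .branch_terms(model, bk, mu)
        hx <- tx$e * (tx$P %*% acc$G) +
          matrix((1 - tx$e) * acc$empty, K, m, byrow = TRUE)
        hy <- ty$e * (ty$P %*% st$G) +
          matrix((1 - ty$e) * st$empty, K, m, byrow = TRUE)
        fx <- tx$beta * as.vector(model$pi %*% acc$G)
        fy <- ty$beta * as.vector(model$pi %*% st$G)
        A <- ifelse(!acc$empty & st$empty, acc$A + lam * bacc * fx, 0) +
          ifelse(acc$empty & !st$empty, st$A + lam * bk * fy, 0)
        z <- ((1 - tx$e) + tx$e * as.vector(tx$P %*% acc$z)) *
          ((1 - ty$e) + ty$e * as.vector(ty$P %*% st$z))
        S0 <- acc$S0 + st$S0 +
          lam * bacc * ((1 - tx$beta) + tx$beta * sum(model$pi * acc$z)) +
          lam * bk * ((1 - ty$beta) + ty$beta * sum(model$pi * st$z))
        acc <- list(G = hx * hy, A = A, empty = acc$empty & st$empty,
                    z = z, S0 = S0)
        bacc <- 0
      }
      acc
    }
    root <- walk(ntip + 1L)
    nu <- lam * (tlen + 1 / mu)
    pt <- root$A + (lam / mu) * as.vector(model$pi %*% root$G)
    p0 <- (root$S0 + (lam / mu) * sum(model$pi * root$z)) / nu
    per_g[[g]] <- list(pt = pt, nu = nu, p0 = p0)
    consts[g] <- nu * (p0 - 1)
  }
  nu_g <- vapply(per_g, function(x) x$nu, numeric(1))
  mix <- Reduce(`+`, lapply(per_g, function(x) x$pt / x$nu)) / length(per_g)
  sum(log(mix) + log(mean(nu_g))) - lfactorial(m) + mean(consts)
}

#' Realign the units of a tandem repeat
#'
#' Strips gaps and realigns the unit sequences with progressive PIP (the
#' evolutionary indel model) or with the external MAFFT aligner.
#' For PIP, the guide tree defaults to [infer_guide_tree()] from the
#' initial alignment and the indel rates default to
#' [estimate_indel_rates()] (which requires at least one gap in the
#' initial alignment; supply `params` to skip estimation). MAFFT is only
#' shelled out to when the binary is on the PATH.
#'
#' @param ua a [unit_alignment()].
#' @param method `"pip"` or `"mafft"`.
#' @param params a [pip_params()]; estimated from `ua` when `NULL`.
#' @param model a `subst_model` (PIP only).
#' @param tree optional guide tree (`phylo` or newick path), e.g. from an
#'   external phylogeny program.
#' @param rate_model,alpha,n_rate_categories forwarded to [pip_params()]
#'   when `params` is `NULL`.
#' @return a new [unit_alignment()] over the same parent spans.
#' @export
realign_units <- function(ua, method = c("pip", "mafft"), params = NULL,
                          model = NULL, tree = NULL,
                          rate_model = c("constant", "gamma"), alpha = 0.5,
                          n_rate_categories = 4) {
  method <- match.arg(method)
  rate_model <- match.arg(rate_model)
  units <- stats::setNames(gsub("-", "", ua$rows, fixed = TRUE),
                           names(ua$rows))
  if (any(nchar(units) == 0)) ts_stop("zero-length input unit")
  if (method == "mafft") {
    if (Sys.which("mafft") == "") ts_stop("external tool missing: mafft")
    fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(paste0(">", names(units), "\n", units), fin)
    system2("mafft", c("--auto", "--quiet", fin), stdout = fout)
    aln <- read_fasta(fout, ua$alphabet, as_alignment = TRUE)
    rows <- aln[names(units)]
  } else {
    if (is.character(tree)) tree <- ape::read.tree(tree)
    if (is.null(tree)) tree <- infer_guide_tree(ua)
    model <- model %||% subst_model_symmetric(ua$alphabet)
    if (is.null(params)) {
      est <- estimate_indel_rates(ua, tree)
      params <- pip_params(est["lambda"], est["mu"], rate_model = rate_model,
                           alpha = alpha, n_rate_categories = n_rate_categories)
    }
    out <- pip_align(units, tree = tree, params = params, model = model,
                     alphabet = ua$alphabet)
    rows <- out$rows
  }
  res <- unit_alignment(rows, parent_id = ua$parent_id, spans = ua$spans,
                        alphabet = ua$alphabet)
  attr(res, "params") <- params
  res
}
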