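# Internal numeric and error helpers.

# User-facing errors carry class ts_user_error so the CLI can map them to
# exit status 1 (internal faults exit 2).
ts_stop <- function(msg, call. = FALSE) {
  stop(structure(class = c("ts_user_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Vectorized log(exp(a) + exp(b)) that tolerates -Inf.
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

lse3 <- function(a, b, c) lse2(lse2(a, b), c)

# log-sum-exp down the columns of a matrix.
lse_cols <- function(M) {
  m <- apply(M, 2, max)
  fin <- is.finite(m)
  out <- rep(-Inf, ncol(M))
  if (any(fin))
    out[fin] <- m[fin] +
      log(colSums(exp(sweep(M[, fin, drop = FALSE], 2, m[fin], "-"))))
  out
}

lse_vec <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

# Rotate a vector so that element `1` becomes the element previously at L
# (predecessor lookup for position i-1 with circular wrap).
shift1 <- function(v) c(v[length(v)], v[-length(v)])

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 6-significant-digit float formatting used by all tabular writers.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}
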