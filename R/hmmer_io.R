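# Minimal HMMER3 text-profile dialect: the header block, the HMM symbol
# line, and per-node match-emission / insert-emission / transition lines
# with negative natural-log probabilities ('*' = probability zero).
# Only what is needed to exchange profiles; rich records (STATS, MAP
# annotations, ...) are skipped with a warning where relevant.

#' Read a HMMER3 text profile
#'
#' @param path profile file (single model).
#' @return a `profile_hmm` (probabilities exponentiated from the stored
#'   negative log values). The 7 HMMER transitions map onto the package's
#'   9-move set with the unused D->I and I->D moves set to zero.
#' @export
read_hmmer_profile <- function(path) {
  if (!file.exists(path)) ts_stop(sprintf("cannot read '%s'", path))
  lines <- readLines(path)
  if (!length(lines) || !grepl("^HMMER3", lines[1]))
    ts_stop("line 1: not a HMMER3 text profile")
  hmm_at <- grep("^HMM\\s", lines)[1]
  if (is.na(hmm_at)) ts_stop("malformed header: no HMM line")
  syms <- strsplit(trimws(sub("^HMM", "", lines[hmm_at])),
                   "[[:space:]]+")[[1]]
  K <- length(syms)
  alpha <- if (K == 20) alphabet("aa") else if (K == 4) alphabet("dna") else
    ts_stop(sprintf("line %d: unsupported alphabet size %d", hmm_at, K))
  if (!identical(syms, alpha$symbols))
    ts_stop(sprintf("line %d: unexpected symbol order", hmm_at))
  lp <- function(fields, where) {
    v <- suppressWarnings(ifelse(fields == "*", Inf, as.numeric(fields)))
    if (anyNA(v)) ts_stop(sprintf("line %d: non-numeric field", where))
    exp(-v)
  }
  i <- hmm_at + 2L  # skip the transition-name line
  # optional COMPO line, then the node-0 insert/transition block
  if (i <= length(lines) && grepl("^\\s*COMPO", lines[i])) i <- i + 1L
  is_node_line <- function(j) {
    f1 <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1]][1]
    grepl("^[0-9]+$", f1)
  }
  while (i <= length(lines) && !grepl("^//", lines[i]) && !is_node_line(i))
    i <- i + 1L
  nodes <- list()
  while (i <= length(lines) && !grepl("^//", lines[i])) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!grepl("^[0-9]+$", f[1])) { i <- i + 1L; next }
    node <- as.integer(f[1])
    if (length(f) < K + 1) ts_stop(sprintf("line %d: truncated match line", i))
    me <- lp(f[2:(K + 1)], i)
    if (i + 2L > length(lines))
      ts_stop(sprintf("line %d: truncated node block", i))
    fi <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    if (length(fi) < K) ts_stop(sprintf("line %d: truncated insert line", i + 1L))
    ie <- lp(fi[1:K], i + 1L)
    ft <- strsplit(trimws(lines[i + 2L]), "[[:space:]]+")[[1]]
    if (length(ft) < 7) ts_stop(sprintf("line %d: truncated transition line", i + 2L))
    tr <- lp(ft[1:7], i + 2L)
    nodes[[node]] <- list(me = me, ie = ie, tr = tr)
    i <- i + 3L
  }
  if (!length(nodes)) ts_stop("profile has no nodes")
  L <- length(nodes)
  me <- t(vapply(nodes, function(n) n$me, numeric(K)))
  ie <- t(vapply(nodes, function(n) n$ie, numeric(K)))
  tr7 <- t(vapply(nodes, function(n) n$tr, numeric(7)))
  trans <- cbind(MM = tr7[, 1], MI = tr7[, 2], MD = tr7[, 3],
                 IM = tr7[, 4], II = tr7[, 5], ID = 0,
                 DM = tr7[, 6], DD = tr7[, 7], DI = 0)
  # final node: HMMER stores '*' for m->d / d->d; renormalize defensively
  for (g in list(1:3, 4:6, 7:9)) {
    s <- rowSums(trans[, g, drop = FALSE])
    s[s == 0] <- 1
    trans[, g] <- trans[, g, drop = FALSE] / s
  }
  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  colnames(me) <- colnames(ie) <- alpha$symbols
  structure(list(L = L, alphabet = alpha, match_emis = me,
                 insert_emis = ie, trans = trans),
            class = "profile_hmm")
}

#' Write a profile in the minimal HMMER3 text dialect
#'
#' Emits a header, a node-0 insert/transition block with background
#' emissions, and the per-node lines; [read_hmmer_profile()] reads the
#' result back to within 1e-6.
#'
#' @param p a `profile_hmm`.
#' @param path output file.
#' @param name model name recorded in the header.
#' @export
write_hmmer_profile <- function(p, path, name = "tandemscan_profile") {
  fmtv <- function(v) paste(sprintf("%10.6f", ifelse(v <= 0, Inf, -log(v))),
                            collapse = "  ")
  K <- length(p$alphabet$symbols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("HMMER3/f [tandemscan | minimal dialect]",
               paste0("NAME  ", name),
               paste0("LENG  ", p$L),
               paste0("ALPH  ", if (K == 20) "amino" else "DNA")), con)
  writeLines(paste0("HMM          ",
                    paste(sprintf("%-9s", p$alphabet$symbols),
                          collapse = " ")), con)
  writeLines(paste("           m->m      m->i      m->d      i->m",
                   "     i->i      d->m      d->d"), con)
  bg <- p$alphabet$background
  writeLines(paste0("  COMPO  ", fmtv(bg)), con)
  writeLines(paste0("         ", fmtv(bg)), con)
  writeLines(paste0("         ",
                    fmtv(c(0.99, 0.005, 0.005, 0.99, 0.01, 1, 0))), con)
  for (i in seq_len(p$L)) {
    writeLines(sprintf("  %5d  %s", i, fmtv(p$match_emis[i, ])), con)
    writeLines(paste0("         ", fmtv(p$insert_emis[i, ])), con)
    tr <- p$trans[i, c("MM", "MI", "MD", "IM", "II", "DM", "DD")]
    writeLines(paste0("         ", fmtv(tr)), con)
  }
  writeLines("//", con)
  invisible(path)
}
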