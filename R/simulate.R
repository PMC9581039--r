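# Synthetic tandem repeats with known ground truth. Units evolve
# independently from a common ancestral unit on a star tree (matching the
# homology-test H1), short indels follow a geometric length law, and flanks
# are i.i.d. background — every downstream stage can be benchmarked without
# external data.

#' Simulate one repeat-bearing sequence
#'
#' Each unit is the ancestral unit evolved for `divergence_t` expected
#' substitutions per site under `model` (so two units are separated by
#' `2 * divergence_t`). With probability `indel_prob` per site an indel is
#' applied: equally likely an insertion (background residues) or deletion,
#' with geometric length of mean `1 / indel_geom_p` (default 2, the
#' short-indel regime typical of repeat units). Flanks are i.i.d.
#' background draws. Fully reproducible from `seed`.
#'
#' @param ancestral_unit residue string of the ancestral unit.
#' @param n_units number of units (>= 2).
#' @param divergence_t ancestor-to-unit branch length, substitutions/site.
#' @param indel_prob per-site indel probability in `[0, 0.2]`.
#' @param model a `subst_model`; defaults to symmetric on `alphabet`.
#' @param flank_lengths integer pair: left/right flank lengths.
#' @param seed integer seed.
#' @param alphabet a [alphabet()]; guessed from the unit when `NULL`.
#' @param indel_geom_p geometric length parameter for indels (0.5).
#' @param id identifier for the emitted sequence.
#' @return list with `record` (a [seq_record()]) and `truth` (class
#'   `simulated_repeat`: ancestral unit, unit strings, `true_spans`,
#'   divergence, indel settings, seed).
#' @export
simulate_repeat <- function(ancestral_unit, n_units, divergence_t,
                            indel_prob = 0, model = NULL,
                            flank_lengths = c(20L, 20L), seed = NULL,
                            alphabet = NULL, indel_geom_p = 0.5,
                            id = "sim") {
  if (n_units < 2) ts_stop("n_units must be >= 2")
  if (divergence_t < 0) ts_stop("divergence_t must be >= 0")
  if (indel_prob < 0 || indel_prob > 0.2)
    ts_stop("indel_prob must be in [0, 0.2]")
  ancestral_unit <- toupper(ancestral_unit)
  if (is.null(alphabet)) alphabet <- guess_alphabet(ancestral_unit)
  model <- model %||% subst_model_symmetric(alphabet)
  syms <- alphabet$symbols
  bg <- alphabet$background
  with_seed(seed, {
    P <- prob_matrix(model, divergence_t)
    anc_idx <- match(.split_chars(ancestral_unit), syms)
    if (anyNA(anc_idx)) ts_stop("ancestral unit has non-alphabet residues")
    units <- character(n_units)
    for (u in seq_len(n_units)) {
      ch <- syms[vapply(anc_idx, function(a)
        sample.int(length(syms), 1L, prob = P[a, ]), integer(1))]
      if (indel_prob > 0) {
        out <- character(0); s <- 1L
        while (s <= length(ch)) {
          if (stats::runif(1) < indel_prob) {
            len <- stats::rgeom(1, indel_geom_p) + 1L
            if (stats::runif(1) < 0.5) {
              ins <- sample(syms, len, replace = TRUE, prob = bg)
              out <- c(out, ch[s], ins); s <- s + 1L
            } else {
              s <- s + len  # deletion starting at this site
            }
          } else {
            out <- c(out, ch[s]); s <- s + 1L
          }
        }
        if (!length(out)) out <- sample(syms, 1L, prob = bg)
        ch <- out
      }
      units[u] <- paste(ch, collapse = "")
    }
    flanks <- lapply(flank_lengths, function(fl)
      paste(sample(syms, fl, replace = TRUE, prob = bg), collapse = ""))
    body <- paste(units, collapse = "")
    residues <- paste0(flanks[[1]], body, flanks[[2]])
    ends <- flank_lengths[1] + cumsum(nchar(units))
    spans <- cbind(start = c(flank_lengths[1], ends[-n_units]), end = ends)
    rec <- seq_record(id, residues, alphabet)
    # reconstruction check: spans recover the mutated units exactly
    stopifnot(identical(
      vapply(seq_len(n_units), function(u)
        substr(residues, spans[u, 1] + 1L, spans[u, 2]), character(1)),
      units))
    truth <- structure(list(ancestral_unit = ancestral_unit,
                            n_units = n_units, divergence_t = divergence_t,
                            indel_prob = indel_prob,
                            flank_lengths = flank_lengths,
                            true_spans = spans, units = units, seed = seed),
                       class = "simulated_repeat")
    list(record = rec, truth = truth)
  })
}

#' Simulated unit alignment at known divergence
#'
#' Gapless star-tree simulation used for divergence-recovery checks:
#' `n_units` rows of `n_cols` sites, each evolved for `branch_t` from a
#' background-drawn ancestor.
#'
#' @param n_units,n_cols dimensions.
#' @param branch_t ancestor-to-unit branch length.
#' @param model a `subst_model`.
#' @param alphabet a [alphabet()].
#' @param seed integer seed.
#' @return a [unit_alignment()].
#' @export
simulate_unit_alignment <- function(n_units, n_cols, branch_t,
                                    model = NULL, alphabet = alphabet("aa"),
                                    seed = NULL) {
  model <- model %||% subst_model_symmetric(alphabet)
  syms <- alphabet$symbols
  with_seed(seed, {
    P <- prob_matrix(model, branch_t)
    anc <- sample.int(length(syms), n_cols, replace = TRUE,
                      prob = model$pi)
    rows <- vapply(seq_len(n_units), function(u)
      paste(syms[vapply(anc, function(a)
        sample.int(length(syms), 1L, prob = P[a, ]), integer(1))],
        collapse = ""), character(1))
    unit_alignment(rows, parent_id = "simulated", alphabet = alphabet)
  })
}

#' Benchmark set of positive and shuffled negative sequences
#'
#' Positives carry one planted repeat each; negatives are residue-shuffled
#' copies of freshly simulated positives, so composition is preserved while
#' tandem structure is destroyed.
#'
#' @param n_pos,n_neg counts (>= 0).
#' @param ancestral_unit,n_units,divergence_t,indel_prob,flank_lengths,model,alphabet
#'   forwarded to [simulate_repeat()]; `n_units` may be a range to sample.
#' @param seed integer seed.
#' @param fasta_path,truth_path optional output files (FASTA and TSV).
#' @return invisible list with `records` and `truth` (data frame: id,
#'   label, start, end, n_units).
#' @export
make_benchmark <- function(n_pos, n_neg, ancestral_unit, n_units = 4,
                           divergence_t = 0.1, indel_prob = 0,
                           flank_lengths = c(20L, 20L), model = NULL,
                           alphabet = NULL, seed = 1L,
                           fasta_path = NULL, truth_path = NULL) {
  if (n_pos < 0 || n_neg < 0) ts_stop("counts must be >= 0")
  if (is.null(alphabet)) alphabet <- guess_alphabet(ancestral_unit)
  records <- list(); rows <- list()
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_pos + n_neg)
    for (i in seq_len(n_pos)) {
      nu <- if (length(n_units) > 1) sample(n_units, 1) else n_units
      sim <- simulate_repeat(ancestral_unit, nu, divergence_t, indel_prob,
                             model, flank_lengths, seed = seeds[i],
                             alphabet = alphabet,
                             id = sprintf("pos_%03d", i))
      records[[length(records) + 1L]] <- sim$record
      rows[[length(rows) + 1L]] <- data.frame(
        id = sim$record$id, label = "positive",
        start = sim$truth$true_spans[1, 1],
        end = sim$truth$true_spans[nu, 2], n_units = nu,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_neg)) {
      nu <- if (length(n_units) > 1) sample(n_units, 1) else n_units
      sim <- simulate_repeat(ancestral_unit, nu, divergence_t, indel_prob,
                             model, flank_lengths, seed = seeds[n_pos + i],
                             alphabet = alphabet, id = sprintf("neg_%03d", i))
      shuf <- paste(sample(.split_chars(sim$record$residues)), collapse = "")
      records[[length(records) + 1L]] <-
        seq_record(sprintf("neg_%03d", i), shuf, alphabet)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("neg_%03d", i), label = "negative",
        start = NA_integer_, end = NA_integer_, n_units = NA_integer_,
        stringsAsFactors = FALSE)
    }
  })
  truth <- do.call(rbind, rows) %||%
    data.frame(id = character(0), label = character(0), start = integer(0),
               end = integer(0), n_units = integer(0))
  if (!is.null(fasta_path)) write_fasta(records, fasta_path)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(records = records, truth = truth))
}
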