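---
title: "Detecting and realigning tandem repeats with circular profile HMMs"
author: "tandemscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and realigning tandem repeats with circular profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemscan)
```

# The problem

Tandem repeats (TRs) are adjacent, approximately repeated units in protein
and DNA sequences — armadillo repeats (~42-residue helical units) and
leucine-rich repeats are classic protein examples. Annotating them is hard
because units diverge through substitutions and short indels, and because a
repeat may start and end anywhere inside a unit. `tandemscan` detects a
*specific* repeat family, described by an alignment of its units, across
arbitrary sequence databases, evaluates the statistical evidence that the
detected units are genuinely homologous, and realigns units under an
explicit evolutionary indel model.

# The circular profile HMM

A profile HMM built from a unit alignment has one match state $M_i$ per
consensus column (columns with at most 50% gaps; a tie counts as a match
column), plus insert states $I_i$ and delete states $D_i$. Emissions and
transitions are maximum-likelihood counts with background-weighted
pseudocounts (weight $w$, default 1): emission rows are
$(\text{counts} + w\,\pi)/(\text{total} + w)$ and each of the three moves
out of a state receives $w/3$ pseudo-observations. The distinctive step
is the *circularization*: transitions leaving position $L$ re-enter
position 1, so one pass through the model can emit arbitrarily many
adjacent units. The begin state connects to every match state with equal
weight $1/L$, and every match-state visit exits to the end state with
probability $\varepsilon$ (default 0.05, exposed everywhere), so repeats
may begin and end at any match position, giving gap-padded partial first
and last units.

Scores are log-odds in bits against an i.i.d. null: the emission term of
every residue is divided by its null frequency, so null-emitting flank
states around the repeat submodel contribute exactly zero and a hit's
score compares "repeat" versus "random sequence" over the hit's own span.
The Viterbi score uses the single best state path; the forward score sums
all paths by log-sum-exp. Both are exact: the circular chain of silent
delete states is resolved in closed form (the full-cycle weight $C < 1$
contributes a geometric factor $1/(1-C)$ to the forward recursion, and a
best path never completes a full silent cycle in the Viterbi recursion).
Ambiguity codes (X, B, Z, N, ...) are emitted from the background under
model and null alike, contributing zero log-odds, and are preserved
verbatim in output.

Scanning a database is $O(\text{sequence length} \times \text{model
states})$ per sequence. Multiple hits per sequence are found greedily: the
best-scoring pass is reported, then the unclaimed flanks are re-scanned,
so hits never overlap. A reported hit must complete at least one wrap
(at least 2 units) and beat the score threshold. Viterbi ties are broken
deterministically (begin first, then match before delete before insert),
so identical inputs give byte-identical outputs.

**Phase invariance.** Rotating the profile columns by $k$ relabels which
column is "position 1" and therefore rotates the repeat phase relative to
the model; with the equal-weight begin/end construction the forward
log-odds of any window is exactly invariant under this rotation (machine
precision; tested). Note that rotating the *window string* instead is not
an exact invariance: a window cut commutes with the model only for paths
without indel events at the cut.

**Score threshold.** The default database-search threshold is 8 bits.
It was calibrated once against residue-shuffled (composition-matched)
sequences, whose best scores stay below ~5 bits, while even short diverged
repeats score hundreds of bits; the primitive `viterbi_search()` keeps the
bare "positive log-odds" rule so toy models remain explorable.

# Homology significance

A TR is considered real if its units share common ancestry. For each
alignment column the alternative $H_1$ treats the residues as independent
descendants of one unobserved ancestor on a star tree with branch length
$t/2$ per unit — so $t$ is the expected pairwise divergence between units —
under a reversible substitution model:
$$P(\text{column} \mid t) = \sum_a \pi_a \prod_{\text{rows } r}
P_{a \to x_r}(t/2).$$
The null $H_0$ scores the same residues as independent background draws.
The statistic is $2(\ln L_1 - \ln L_0)$ at the maximum-likelihood $t$
(bounded search on $[0, 10]$ substitutions/site, tolerance $10^{-6}$, with
the boundary $t = 0$ checked explicitly so identical units give exactly
$\hat t = 0$).

Because $\hat t$ frequently sits on the $t = 0$ boundary, chi-square
asymptotics do not hold; the p-value is empirical: the residues of each
row are permuted within the row (gap positions fixed) `null_draws` times
(default 1000) and the add-one-corrected rank of the observed statistic is
reported, counting strictly greater null statistics. Strict counting is
what makes the degenerate case behave correctly — permuting identical rows
changes nothing, so every null draw ties and the p-value is
$1/(\text{draws}+1)$ — while under a continuous null statistic ties have
measure zero and the test is exactly calibrated (verified by simulation:
the rejection rate at $\alpha = 0.05$ over 200 null replicates sits inside
the exact binomial 95% interval).

The default substitution model is the equal-exchangeability model
stationary on the alphabet background (for uniform backgrounds — DNA and
custom alphabets — this is exactly Jukes–Cantor), normalized to one
expected substitution per site per unit time, with closed-form transition
probabilities. A background-stationary model matters here: with a
uniform-stationary model the two-row statistic depends only on the match
*count*, the permutation null becomes heavily tied, and the test loses
calibration. Any user-supplied reversible rate matrix is accepted through
`subst_model_matrix()` (eigendecomposition backend); no empirical protein
exchangeability matrix is bundled.

Overlapping annotations (e.g. from searches with several models) are
resolved by `filter_overlaps()`: hits sharing more than half of the
shorter span form clusters, and one hit per connected cluster is kept
(lowest p-value, then highest forward log-odds, then longest span, then
leftmost). The operation is idempotent.

# Realignment under the Poisson Indel Process

Unit alignments are short and dominated by short indels, so unit borders
are easy to get wrong. `realign_units()` realigns the (degapped) units
either with MAFFT (external binary, used only if present) or with
progressive PIP, an explicit evolutionary indel model. Under PIP,
insertions arrive as a Poisson process with rate $\lambda$ along the guide
tree plus a root mass $\lambda/\mu$, and every character dies at rate
$\mu$. A character inserted on a branch of length $b$ survives to the
branch bottom with probability $\beta(b) = (1 - e^{-\mu b})/(\mu b)$. The
likelihood of an alignment with $m$ columns is
$$p(A) = \varphi(m)\prod_{c} p(c), \qquad
\varphi(m) = \frac{\nu^m}{m!} e^{\nu(p_\varnothing - 1)},\quad
\nu = \lambda\big(\|\tau\| + 1/\mu\big),$$
where $p(c)$ sums, over all insertion points dominating the column's
residues, the insertion intensity times the pruning likelihood of the
leaves (with death terms for gap subtrees), and $p_\varnothing$ is the
empty-column probability.

The progressive aligner merges child subalignments bottom-up with a
three-move dynamic program (match / gap in one child / gap in the other)
over the exact column masses. The length factor $\nu^m/m!$ makes the score
depend on the final column count, so the DP carries the running column
count as a third dimension and is exact; for merges whose DP volume would
exceed ~2e7 cells a documented 2-D approximation using $\max(i, j)$ as
the running length takes over (TR units are short, so the exact path is
the one exercised in practice). Ties break match > gap-in-second-child >
gap-in-first-child. Every input residue is preserved in order. The exact
optimality of the DP is anchored by a test that enumerates *all* pairwise
alignments of short units and scores them with independently written
closed-form two-leaf formulas; the DP attains the enumerated maximum to
$10^{-9}$.

Supporting estimates, all from the initial alignment as inputs:

* **Guide tree** — pairwise ML distances (closed-form inversion of the
  p-distance under the substitution model, capped at 10), neighbor
  joining, negative branches clamped to zero, midpoint rooting; with
  fewer than 3 units a star tree. A user-supplied newick tree (e.g. from
  an external ML program) is accepted instead. Branch lengths are floored
  at $10^{-4}$ inside the aligner: a zero-length tree gives indel events
  zero intensity and would make any gap column impossible.
* **Indel rates** — an event-counting estimator: $\hat\mu$ = (maximal gap
  runs across rows) / (tree length × mean ungapped row length), and
  $\hat\lambda = \hat\mu \times$ mean row length from PIP's stationary
  length $E[\ell] = \lambda/\mu$. Rates are floored at $10^{-4}$ ($\mu$
  capped at 10). A gapless initial alignment carries no indel information
  and is rejected with an explicit error, unless rates are supplied.
* **Rate variation** — optionally the indel rates are scaled by
  discretized gamma categories (4 equal-probability categories of
  $\Gamma(\alpha, \alpha)$, category means; shape default $\alpha = 0.5$)
  and the column likelihood is averaged across categories, with the length
  factor taken at the category-mean intensity. As $\alpha \to \infty$ this
  reproduces the constant-rate likelihood (checked at $\alpha = 10^3$ to
  $10^{-4}$).

`refine_cphmm()` closes the loop: decode units from the current hits,
realign the pooled units (guide tree and rates estimated from the units
projected onto the model's match columns), rebuild and re-circularize the
profile, re-search, and accept the new model only if the total forward
log-odds across hits improves by at least $10^{-3}$ bits. The accepted
trajectory is therefore non-decreasing and the best model is returned.

# The simulator

`simulate_repeat()` generates ground-truthed repeat sequences: each unit
evolves independently from an ancestral unit for `divergence_t` expected
substitutions per site (a star tree, matching the homology test's $H_1$,
whose $t$ is then twice the simulated branch length), indels strike each
site with probability `indel_prob` (insertion or deletion with equal
probability, geometric lengths of mean 2 — the short-indel regime typical
of TR units), and flanks are i.i.d. background. `make_benchmark()` emits
labeled positives plus residue-shuffled negatives, which preserve
composition while destroying tandem structure. The simulator does *not*
reproduce unit duplication/loss, gene conversion, heterogeneous
column-wise selection or compositional bias along real proteins — passing
recovery tests therefore demonstrates correctness of the inference
machinery under the stated generative model, not field performance on any
particular proteome.

Default study conditions used by the recovery checks (chosen once):
20-residue amino-acid units, 3–5 units per repeat, ancestor-to-unit
branch 0.1 (≈18% pairwise unit divergence), 20-residue flanks, 200
positives and 200 negatives; the homology-test calibration uses 200 null
replicates of 2×30-column alignments with 99 permutations each; divergence
recovery uses 10 units × 200 columns. These sizes make the whole suite
reproducible on a laptop in a few minutes.

# Numerical and degenerate-input choices

* Internal arithmetic is natural-log with log-sum-exp; reported scores are
  bits. Probabilities of zero are clamped at $\log$-double-min where a
  $0 \times \log 0$ product must vanish.
* The HMMER3 text reader covers the minimal dialect (header, HMM symbol
  line, per-node emission/transition lines, `*` = zero); its 7 transitions
  map onto the 9-move set with $I{\to}D$ and $D{\to}I$ zero. Parse errors
  name the offending line.
* Coordinates are 0-based half-open everywhere internally and in TSV;
  GFF3 output is 1-based inclusive with `repeat_region` parents and
  `tandem_repeat_unit` children.
* Decoded segments that emit no residues (pure-delete wraps, possible only
  in pathological models) are dropped before units are counted.
* `exit_prob` must lie strictly in $(0,1)$; `wrap = "match"` restricts
  wrapping to re-enter at $M_1$ only, funneling all wrap mass there.

# Known limitations

* The homology test ships no empirical amino-acid exchangeability matrix;
  the background-stationary model is a deliberately simple default and
  power on real proteins improves with a user-supplied matrix.
* Simultaneous multi-hit decoding is replaced by greedy non-overlapping
  extraction; hit p-values are conditional on the decoded segmentation.
* E-values over database size are not computed; significance comes from
  the per-hit homology test.
* The PIP mixture over gamma categories treats the alignment-length factor
  at the category-mean intensity; this is exact for constant rates and a
  documented approximation otherwise.
* Codon alphabets are not supported.
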