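# tandemscan

Detection, statistical evaluation and evolutionary realignment of tandem
repeats (TRs) in protein and DNA sequences, built around **circular
profile hidden Markov models (cpHMMs)**.

Tandem repeats — adjacent, approximately repeated units such as armadillo
repeats or leucine-rich repeats — diverge through substitutions and short
indels, and a repeat region may begin and end anywhere inside a unit.
`tandemscan` is for researchers who have a known repeat family (a seed
alignment of its units, e.g. from Pfam, or a HMMER3 profile) and want to
find, segment, score and curate its occurrences across sequence databases.

## The model

A linear profile HMM with match/insert/delete states (M<sub>i</sub>,
I<sub>i</sub>, D<sub>i</sub>) is built from the unit alignment (match
columns = ≤50% gaps; background-weighted pseudocounts) and then
*circularized*: transitions out of position *L* re-enter position 1, the
begin state B connects to every match state with equal weight 1/L, and
every match-state visit exits to the end state E with probability ε
(default 0.05). One pass B → (≥1 circuit) → E therefore emits arbitrarily
many adjacent units, entering and leaving at any match position.

Hits are scored by log-odds against a random-sequence null,

> score = log₂ P(window | cpHMM) / P(window | i.i.d. background),

with both the best single path (Viterbi) and the all-paths sum (forward)
reported; the silent delete cycle is handled in closed form, so both are
exact. A detected region is *statistically significant* if its units share
common ancestry, tested by a likelihood-ratio test: each column is modeled
as independent descent from an unobserved ancestor on a star tree at ML
divergence t̂ (branch t/2 per unit), against independent background draws,
with an empirical within-row permutation p-value. Detected units can be
realigned under the **progressive Poisson Indel Process** (insertion rate
λ along the guide tree, per-character death rate μ, survival
β(b) = (1−e^(−μb))/(μb), optional gamma-distributed indel-rate variation
with shape α = 0.5), which also enables iterative refinement of the cpHMM.

## Worked example

```r
library(tandemscan)
aa <- alphabet("aa")

# a seed alignment of known repeat units (here: simulated from a
# 15-residue ancestral unit at ~10% divergence)
seed  <- simulate_repeat("MKLVNDRSTWQEYFH", n_units = 5, divergence_t = 0.1,
                         seed = 42, alphabet = aa)
units <- unit_alignment(seed$truth$units, alphabet = aa)
model <- circularize(build_profile(units), exit_prob = 0.05)

# a small database: 2 repeat-bearing sequences + 1 shuffled decoy
bench <- make_benchmark(2, 1, "MKLVNDRSTWQEYFH", n_units = 4,
                        divergence_t = 0.1, seed = 11, alphabet = aa)
hits  <- search_database(model, bench$records)
hits[, c("sequence_id", "start", "end", "n_units",
         "viterbi_logodds", "forward_logodds")]
#>   sequence_id start end n_units viterbi_logodds forward_logodds
#> 1     pos_001    19  82       6        159.7609        162.0583
#> 2     pos_002    20  80       4        166.0461        166.7436

attr(hits, "hits")[[2]]$units
#> <unit_alignment> pos_002: 4 units x 15 columns
#>   unit_1       MKLVNDRSTWQEYFH  [20,35)
#>   unit_2       MKLVNDNSIWQEYFH  [35,50)
#>   unit_3       QKLVNDRVTWQEYFH  [50,65)
#>   unit_4       MKLVNDRSTWQEYFH  [65,80)

homology_lrt(attr(hits, "hits")[[2]]$units, null_draws = 199, seed = 1)
#> <homology_test> 2dlnL = 230.023, t-hat = 0.1366, p = 0.005
```

The shuffled decoy is not reported (it scores below the 8-bit default
threshold). The two repeat regions are segmented into their units —
coordinates are 0-based half-open; `pos_001` picks up gap-padded partial
first/last units, which is expected since the model may enter and exit
mid-unit. The homology test estimates ~0.14 substitutions/site between
units and rejects the "unrelated columns" null at the smallest p-value
199 permutations can give (add-one corrected: 1/200 = 0.005).

Realignment and refinement:

```r
ra  <- realign_units(attr(hits, "hits")[[1]]$units, method = "pip")
ref <- refine_cphmm(model, bench$records, rounds = 3)
```

## Command line

A thin wrapper over the same functions is installed as `exec/tandemscan`:

```sh
tandemscan build    --msa units.sto --out model.json
tandemscan search   --model model.json --db seqs.fasta \
                    --min-units 2 --min-logodds 8 --out hits.tsv --gff hits.gff3
tandemscan filter   --hits hits.tsv --max-pvalue 0.05 --out kept.tsv
tandemscan realign  --stockholm units.sto --method pip --rate-model gamma --alpha 0.5 \
                    --out realigned.sto
tandemscan refine   --model model.json --db seqs.fasta --rounds 3 --out refined.json
tandemscan simulate --unit MKLVNDRSTWQEYFH --n-pos 50 --n-neg 50 --seed 1 \
                    --out-fasta bench.fa --out-truth truth.tsv
```

Formats: FASTA, Stockholm 1.0 (annotation write-through), HMMER3 text
profiles (minimal dialect), TSV hit tables (0-based half-open), GFF3
(1-based, `repeat_region` + `tandem_repeat_unit`), JSON model documents.

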