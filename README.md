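# colorseeds

Design and certification of spaced seeds for mapping SOLiD color-space
reads.

## What problem this solves

SOLiD reads are reported in color space: a primer base followed by colors,
each encoding a pair of adjacent bases.  Seed-based read mappers filter
candidate loci with *spaced seeds* — patterns like `####-##-####` of required
color matches (`#`, weight *w* = 10 here) and don't-cares (`-`, span *s* =
12) — and their performance hinges on how well the seeds fit the color-level
error structure: a SNP appears as **two adjacent color mismatches**, a
reading error as an isolated mismatch biased toward the read end and toward
phases five positions apart, and a base indel as a color indel usually
preceded by a color mismatch.

`colorseeds` is a toolkit for people designing such seeds.  It provides:

* **Position-restricted seeds**: each seed carries an explicit set *P* of
  0-based read offsets where it may hit, trading nothing in guarantees for a
  smaller index and hits steered away from the noisy read tail.
* **Probabilistic alignment models** (finite-state transducers over
  match/mismatch/indel symbols): a 3-state SNP/indel model, a period-5
  reading-error model with a rising positional error profile, and their
  dominance product (defaults: SNP 0.0085, indel 0.0015, periodic error
  0.02, baseline 0.01→0.1).
* **Exact sensitivity** — P(family hits an alignment drawn from the model) —
  by dynamic programming over the product of the family hit automaton and
  the model, with a brute-force enumeration oracle.
* **Lossless certification** — does the family hit *every* alignment within
  a budget of *k* SNPs, *h* reading errors and *j* indels, or within a total
  cost *C* (match 0, mismatch 2, second adjacent mismatch 1, indel 4,
  post-indel mismatch 0)?  A minimal-cost DP over the seed automaton answers
  in seconds and reconstructs a cheapest missed alignment when the answer is
  no.
* **Seed search**: uniform sampling of gap layouts and position sets plus
  hill climbing, scoring by sensitivity (lossy mode) or by selectivity among
  certified candidates (lossless mode).
* **A synthetic read generator** with csfasta/QUAL I/O reproducing the
  error structure above, and quality-correlation statistics
  (`c(i) = E((Q_j - Q̄)(Q_{j+i} - Q̄)) / σ_Q²`).

## Worked example

Certify the shipped 3-member positioned family of weight 10 (24 allowed
positions, read length 34) and evaluate it under the full alignment model:

```r
library(colorseeds)

fam <- read_seed_file(system.file("extdata", "lossless-10-24p.seeds",
                                  package = "colorseeds"), m = 34)
fam
#> <seed_family> 3 member(s), m=34
#>   ####-##-#### @ {0,1,2,3,4,5,6,7,8,18,19,20}
#>   #-########-# @ {2,12,15,16,18,19,20,21}
#>   ####-#-------#-#### @ {0,1,11,14}

check_lossless(fam, cost_budget(7), m = 34)
#> <lossless_verdict> LOSSLESS  (min missed cost 8, threshold 7)
```

Lossless at cost 7 means every alignment combining 1 indel + 1 SNP (cost
4 + 3), 1 indel + 1 reading error (4 + 2), 2 SNPs (3 + 3) or 1 SNP + 2
reading errors (3 + 2 + 2) is guaranteed to be hit; the cheapest alignment
the family can miss costs 8.  Push the budget past the design point and the
verdict flips, with a concrete counterexample (`1` match, `0` mismatch, `I`
indel):

```r
check_lossless(fam, cost_budget(9), m = 34, witness = TRUE)
#> <lossless_verdict> NOT lossless  (min missed cost 8, threshold 9)
#>   witness: 1111111111101110111011111111101111

compute_sensitivity(fam, build_default_model(34), m = 34)
#> <sensitivity_result> value=0.9903376671  (m=34, automaton states=567)

background_hit_probability(fam, 34)
#> [1] 2.213898e-05
```

So under the default error model the family detects 99.03% of read
alignments while a random background position survives the filter with
probability 2.2e-5.  Encoding round-trips are one call each:

```r
encode_to_colors("GATTACA", "T")
#> <color_read> m=7  T1230311
```

A thin command-line wrapper (`inst/scripts/colorseeds`) exposes the same
functionality as subcommands `evaluate`, `lossless-check`, `simulate`,
`quality-stats` and `design` (exit code 1 on a failed certification, 2 on
usage errors).

## Layout

* `R/colorspace.R` — encoding/decoding, qualities, simulator, csfasta/QUAL
* `R/seeds.R` — seed parsing, placements, seed files
* `R/automata.R` — alignment DFAs: seed automaton, position chain, products
* `R/models.R` — probability transducers and their products
* `R/sensitivity.R`, `R/lossless.R` — the two frameworks' DPs and oracles
* `R/design.R` — sampling + hill-climbing search
* `vignettes/seed-design.Rmd` — models, conventions and design choices
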