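---
title: "Designing and certifying spaced seeds for SOLiD color-space reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and certifying spaced seeds for SOLiD color-space reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorseeds)
```

## The problem

SOLiD sequencers report reads in *color space*: a primer base followed by a
sequence of colors, each encoding a pair of adjacent bases.  Mapping such
reads with seed-based filtration is attractive because the encoding separates
error types — a true SNP appears as **two adjacent color mismatches**, while
an isolated color mismatch is a **reading error** — but it requires seeds
designed for the color-level error structure.  Two empirical artifacts of the
chemistry matter: the reading-error rate **rises along the read**, and
quality values (hence errors) are **correlated at lags that are multiples of
5**, because each ligation round determines positions five apart.

`colorseeds` designs and certifies *position-restricted spaced seeds* for
this setting: each seed `\pi` (a pattern over `#` = required color match and
`-` = don't care, with weight *w* and span *s*) is paired with an explicit
set *P* of 0-based read offsets at which it may hit.  Restricting positions
keeps the index small and steers hits away from the error-prone read tail.

## The color code

Published descriptions fix only the *properties* of the SOLiD code, not the
table itself.
We use the standard dibase table: bases are coded A=0, C=1, G=2, T=3 and the
color of a dimer is the XOR of the two base codes.  This satisfies every
stated property: identical bases give color 0, the code is invertible given
the primer base, a base substitution XORs the two adjacent colors by the same
nonzero value (one color at the read end), and *n* consecutive substitutions
change at most *n*+1 consecutive colors.  The table is pluggable in
principle; nothing downstream depends on more than these properties.

## Alignment models

Alignments are strings over {match `1`, mismatch `0`, indel `I`} generated by
probability transducers (finite-state machines whose transitions carry a
probability and an emission distribution; they subsume HMMs).

**SNP/indel model** (3 states: Match, SNP, Indel; `build_snp_indel_model`).
From every state the next state is SNP with `p_snp`, Indel with `p_indel`,
Match otherwise.  Entering and leaving the SNP state emits a mismatch with
probability 1 (the two adjacent colors of a SNP); the SNP self-loop emits a
0.75/0.25 mismatch/match mixture (color matches can occur inside runs of
consecutive SNPs).  A transition into the Indel state emits a mismatch with
probability 0.75 (a color indel is preceded by a color mismatch in 3/4 of
cases) and match otherwise; every transition out of or looping on Indel emits
an indel symbol.  Two edges are claimed by two rules at once; we resolve
SNP→Indel by the leaving-SNP rule (mismatch with probability 1) and
Indel→SNP by the outgoing-from-Indel rule (indel with probability 1), the
latter being stated as universal.

**Reading-error model** (`build_reading_error_model`).  States are (error
level ℓ ∈ 0..5, phase φ ∈ 0..4); the phase advances mod 5 each color.  A
transition consumed at a *marked* phase (φ < ℓ) emits a mismatch with the
periodic error probability `p_err`; with probability `p_s` per step the
level rises irreversibly by one, marking one more phase.  Phases are marked
cumulatively from phase 0 upward — tracking the exact identity of marked
phases is not expressible in the (level, phase) state space, and no stated
property depends on it; the builder is pluggable if a different topology is
wanted.  The switching probability `p_s` has no published value; we default
to 0.05 and expose it as a config key.

**Position profile** (`apply_position_profile`).  The rising baseline enters
as a product with a linear (m+1)-state automaton: at step *i* the mismatch
emission of every transition becomes max(own rate, `p_err'(i)`), with the
match mass absorbing the difference.  The profile shape is linear between
the start (0.01) and end (0.1) defaults — the published constraint is only
that it is increasing.

**Superposition** (`product_models`).  The full model is the product of the
two sources: transition probabilities multiply and each symbol pair emits
the dominant symbol (indel ≻ mismatch ≻ match), masses for the same symbol
adding up.

Default parameters: `p_snp` = 0.0085, `p_indel` = 0.0015, `p_err` = 0.02,
baseline 0.01→0.1 — the standard SOLiD parameterization used for the
designed families shipped in `inst/extdata/`.

## Sensitivity (lossy framework)

`compute_sensitivity` computes the probability that an alignment of length
*m* drawn from the model contains a hit of the family, as a forward dynamic
program over pairs (model state × automaton state): O(m · |model| · |Q| ·
|A|), never enumerating strings.  The hit automaton (`family_to_dfa`) is
built directly over the family's placements — a state records which placement
windows overlapping the current read position are still viable — and
minimized; its size tracks the interval-graph overlap depth of the
placements (`overlap_depth`).  The classical compact seed automaton
(`seed_to_dfa`) is built by subset construction over the seed-prefix NFA
followed by Moore minimization, so its size never exceeds the optimal
(w+1)·2^(s−w) bound, which we assert in tests rather than reproducing the
original state-indexing scheme.  `brute_force_sensitivity` (explicit
enumeration plus a direct placement scan) is the independent oracle; DP and
oracle agree to 1e−10 on hundreds of random instances.

Selectivity is reported as one minus the probability of hitting an i.i.d.
uniform background alignment (match probability 1/4), computed by the same
DP with a Bernoulli model.

## Lossless certification

A family is *lossless* for a budget if it hits **every** alignment within
the budget.  Budgets come in three forms: plain mismatch counts
(`mismatch_budget`), event counts (`event_budget`: at most *k* SNPs = disjoint
adjacent mismatch pairs, *h* isolated mismatches, *j* indels), and total
cost (`cost_budget`) under the scheme: match 0, mismatch 2, a mismatch
directly following a mismatch 1 (an isolated SNP totals 3), indel 4, a
mismatch directly following an indel 0.  The four error combinations the
shipped family is certified for — 1 indel + 1 SNP, 1 indel + 1 reading
error, 2 SNPs, 1 SNP + 2 reading errors — have maximum total cost 7.

Certification runs a minimal-cost dynamic program (`min_cost_dp`) over the
product of the family automaton with the constraint automaton (event
budgets; built by determinizing a small counting NFA) or the weighted
3-state context automaton (cost budgets): for each state and step, the
minimal cost needed to reach it; the family is lossless iff at the horizon
every state that would witness a miss costs more than the budget.  Two
rolling rows give O(|Q|·|A|) space; witness reconstruction (opt-in,
O(m·|Q|) memory) returns the lexicographically smallest cheapest missed
alignment under match < mismatch < indel.  `brute_force_lossless`
re-derives verdicts by explicit enumeration with independent in-budget
predicates (a greedy run-decomposition for event budgets, a left-to-right
cost fold for cost budgets).

### Indel bookkeeping

Seed positions are **read coordinates**.  An indel column — a color inserted
into or deleted from the read — sits *between* read positions: it does not
advance the position counter, it kills every placement window already in
progress (seeds must be placed between indels), and it leaves windows
starting at or after the current position untouched.  Consequently an
alignment with *j* indels has *m* + *j* columns, and the certification DP
scans completion (read position *m*) at every horizon from *m* to *m* + *j*.
This choice is forced by the published certification of the
`3-Lossless-10-24p` family: under the alternative convention (indel columns
consuming read positions) that family has a concrete missed alignment of
cost 7 — an indel shifts all later windows by one — whereas in read
coordinates all five published certifications verify, in under ten seconds.
The context automaton starts in the after-match state, so a leading mismatch
always costs 2, and after the free post-indel mismatch the context returns
to after-match (the free mismatch belongs to the indel event, not to a
subsequent SNP pair).

The read length for certifying the shipped families defaults to m = 34, the
read length of the experiments that produced them; a positioned family
lossless at m stays lossless at every larger m (tested), so this is the
conservative choice.

## Seed search

`design_seeds` samples gap layouts uniformly (s − w gap slots among the
interior positions, spans up to the configured maximum) and position subsets
of the requested size, scores candidates — sensitivity in lossy mode;
certification followed by selectivity ranking in lossless mode — and
hill-climbs the best candidates with two elementary moves: shift one gap by
one slot, swap one allowed position for an unused one.  Only strictly
improving moves are accepted, so the returned score never drops below the
input's; ties in the final ranking break by higher selectivity, then pattern
order.  The published method names sampling plus local optimization but no
distribution, acceptance rule or schedule; uniform sampling with strict hill
climbing and explicit candidate/step budgets was chosen for reproducibility
— the whole search is a deterministic function of the problem's `rng_seed`.
On a toy problem small enough for exhaustive search (m = 10, w = 3, s ≤ 5,
two positions) the search provably attains the global optimum (tested).

## The synthetic read generator

`simulate_reads` emulates the technology's error structure on a reference:
SNPs as XOR pairs on adjacent colors, color indels preceded by a forced
color mismatch with probability 0.75, reading errors at a per-position rate
that rises linearly (0.01 → 0.1) with a +0.02 periodic elevation on one
phase in five, and qualities carrying a lag-5 correlation of 0.6 — the
magnitude reported for real SOLiD data.  What it does **not** emulate:
reverse-strand reads (the design problem is strand-agnostic), real quality
model fits, base-composition bias, or correlated error bursts beyond the
period-5 structure.  Passing recovery tests therefore demonstrates that the
statistics the models are built on are correctly injected and estimated, not
that the models fit any particular instrument run.

## Numerical choices and problem sizes

Exhaustive cross-checks enumerate all 2^m (or 3^m) alignments for m ≤ 12
(m ≤ 9 with indels); randomized suites use 200 instances at those sizes with
fixed seeds.  Stochasticity invariants are enforced at 1e−12 (transitions)
and 1e−9 (total probability by enumeration); DP-vs-oracle equivalence at
1e−10.  Degenerate inputs are defined, not errors: an empty position set is
legal (sensitivity 0, never lossless), an empty constraint language makes
every family trivially lossless, and strings longer than the declared
horizon are outside every contract.

## Known limitations

* Model parameters are not estimated from data; they are inputs.
* The lossy and lossless frameworks are separate objectives; combined
  lossy/lossless design is out of scope.
* Very large spans (s − w > 28) exceed the bitmask subset construction.
* The search is a local optimizer; it inherits no global guarantee beyond
  the exhaustively checked toy regime.
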