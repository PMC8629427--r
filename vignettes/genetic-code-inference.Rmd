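---
title: "Decoding a genome's genetic code from profile alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a genome's genetic code from profile alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscope)
```

## The inference problem

A genetic code assigns each of the 64 codons one of 20 amino acid meanings
(or stop). Codon reassignments — a codon switching its amino acid, or
moving between sense and stop — have evolved repeatedly in bacteria,
yeasts and organelles, and misannotating them corrupts every translated
protein. `codonscope` infers the code of a single organism from its
nucleotide sequence alone, by asking, for each codon, which amino acid
best explains the conservation profile of the positions that codon
occupies in recognizable protein domains.

## Generative model and its assumptions

The input sequence is split into non-overlapping chunks (100 kb by
default, a practical limit for protein search tools on long
translations), translated in all six frames under the standard code with
stops as `X`, and searched against a database of protein-domain profile
HMMs. Each aligned profile consensus column $C$ carries emission
probabilities $P(A \mid C)$ over the 20 amino acids. Because columns are
treated independently, an alignment reduces to a set of (codon instance,
consensus column) pairs; all pairs for codon $Z$ form the set
$C{\to}Z = \{C_1 \dots C_N\}$.

Columns are imagined drawn from the pool of all aligned columns, with
affinity for $Z$ proportional to their emission for $Z$'s true amino acid
$A$:

$$P(C_i \mid A) = \frac{P(A \mid C_i)\, P(C_i)}{P(A)},$$

with $P(A)$ the occurrence-weighted mean emission over all columns aligned
to this genome — a genome-specific background that absorbs compositional
bias. For the 21 decoding models $M$ (20 amino acids plus a nonspecific
model `?` that draws columns at random):

$$P(C{\to}Z \mid M) = \begin{cases}
\prod_i P(A{=}M \mid C_i)\,P(C_i)\,/\,P(A{=}M) & M \text{ an amino acid}\\
\prod_i P(C_i) & M = \texttt{?}
\end{cases}$$

and with a uniform prior the posterior is the normalized likelihood. The
$\prod_i P(C_i)$ factor and the prior are common to all 21 models and
cancel; the implementation never represents $P(C_i)$. The test suite
verifies this algebra against a brute-force evaluator that keeps the
$P(C_i)$ factors explicit.

Key assumptions: unambiguous translation (one meaning per codon), no
explicit stop-codon model (`?` is the expected call for stops, which
should have few aligned columns), independence of consensus columns, and
a preliminary standard-code translation good enough for homology to be
found — an organism whose code diverged radically would break that
bootstrap.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `evalue_max` | 1e-10 | E-value | per-domain significance cutoff, strict `<` |
| `pp_min` | 0.95 | posterior fraction | per-residue alignment certainty; at 0.95 only the `*` code passes |
| `cap_fraction` | 0.01 | fraction | over-representation cap per consensus column |
| `threshold` | 0.9999 | posterior | decoding probability needed to assign an amino acid |
| `chunk_len` | 100000 | nt | chunk size before translation |

The decoding threshold must exceed 0.5: posteriors sum to one, so any
threshold above 0.5 guarantees a unique winner and `assign_codon()`
rejects smaller values. The E-value filtered is the per-domain
*independent* E-value (a switch selects the conditional one); filtering
"domain hits" is the natural reading when a query carries several domains.

## Filtering and downsampling choices

The per-residue posterior codes emitted by the search program are bins:
digit $d$ covers $((d-0.5)/10, (d+0.5)/10]$ and `*` covers $(0.95, 1]$. A
pair passes when its entire bin lies at or above `pp_min`, so the default
keeps exactly the `*` code.

Repetitive elements (e.g. pseudogene families) can flood one codon with
copies of a single column. The cap removes the excess: with at least 100
total columns, no column may exceed `floor(cap_fraction × N)` occurrences
(never reduced below one — a column that legitimately aligned keeps a
vote); below 100 every unique column is reduced to one occurrence, and
exactly 100 falls through to cap 1 either way. The cap is always computed
from the pre-downsampling total, which makes the operation idempotent.
Once pairs are aggregated to per-column counts the occurrences are
exchangeable, so "remove random occurrences" reduces to
`count = min(count, cap)` and the operation is deterministic; the
`rng_seed` argument is retained for interface stability only.

The background can be computed after (default) or before downsampling
(`background_mode`); after downsampling, the background sees the same
column multiset the likelihood does, which keeps the two consistent when
repetitive artifacts were removed.

## Numerical choices and degenerate inputs

* Emission and background vectors are clamped at $\varepsilon = 10^{-6}$
  and renormalized when parsed or constructed, so no log of zero can occur
  and a single column's log-ratio contribution is bounded; profiles built
  without entropy weighting are strictly positive anyway, but synthetic or
  degenerate profiles need the floor. The clamp is why the textbook
  worked examples (posterior $20/21$ for one fully conserved column at
  ratio 20) hold only to ~1e-4: competitor models retain clamp-sized
  likelihoods.
* All likelihoods are accumulated in log space and normalized by
  subtracting the maximum before exponentiation.
* An empty association set yields the uniform posterior $1/21$ for all
  models, hence `?`.
* Codons containing IUPAC ambiguity codes translate to `X` and are never
  counted: the model needs an unambiguous 64-way codon identity. In-frame
  stops translated as `X` *are* counted — they are the signal for stop
  codon reassignment.
* Codons straddling chunk boundaries are lost (at most two per boundary
  per frame); chunking happens before translation and chunks are not
  stitched.
* `which.max` tie-breaking (first of equal posteriors) is irrelevant at
  any legal threshold, since a tie cannot exceed 0.5.

## What the synthetic generator emulates

`make_profiles()` draws each consensus column's emission vector from a
mixture: with probability 0.8 a "strong" Dirichlet with mean 0.6 on a
designated amino acid (concentration 50), else a weak symmetric
Dirichlet(1). Mean conservation of 0.6 with a 20% weak admixture mirrors
what entropy-weighting-off profile builds look like for ordinary conserved
domains: informative but far from deterministic columns. `make_genome()`
emits genes as paths through a domain's columns — each column emits an
amino acid from its own distribution, encoded as a codon under the
configured code and codon-usage weights — with AT-rich intergenic spacers
(GC 0.35, Poisson length 60) and genes alternating strands. The defaults
(200 genes × 200 columns = 40,000 coding codons through 25 domains) give
every sense codon a few hundred aligned columns under uniform usage,
comparable per-codon support to a small real genome. The emulator replays
the ground-truth pairs with top alignment certainty and, optionally,
corrupts a chosen fraction by substituting random columns, imitating
pseudogene/misalignment artifacts.

What it does **not** emulate: alignment boundary errors and local
misalignments (corruption is column substitution, not frameshift), the
search program's E-value distribution (emulated significance is fixed at
1e-20), insertion/deletion structure, GC-driven amino acid composition
bias, and paralog/contamination structure. Passing the synthetic
benchmarks therefore demonstrates the statistics of the decoder — error
control, power as a function of evidence, parameter recovery under
alternative codes — not robustness to every artifact of real genomes,
where accuracy can differ for biological reasons.

## The subsampling benchmark

`make_codon_pools()` builds, for every sense codon, a pool of at least
2,000 columns conserved for the codon's true amino acid (same
strong/weak mixture as above). `subsample_experiment()` draws 1,000
random subsamples (with replacement; a switch allows without-replacement
when the pool permits) at each size in {1..50, 100, 500}, decodes each at
threshold 0.9999, and classifies it as true (correct amino acid), false
(incorrect amino acid), or uninferred; per-codon error is F/(T+F+U) and
power is T/(T+F+U). The vectorized implementation is cross-checked
against the per-codon `decoding_posterior()` path in the test suite.
`scripts/acceptance.R` runs exactly this protocol and reports the maximum
per-codon error over all sizes and the minimum per-codon power at 34
columns. Randomness flows from one run seed through named substreams
(profiles / genome / noise / pools / subsampling).

Problem sizes throughout (2,000-column pools, 1,000 reps, 40,000-codon
recovery genomes) were chosen as the smallest scale at which the
benchmark's Monte-Carlo noise is negligible relative to the quantities
reported; they run in a few minutes on one CPU.

## tRNA isotype classification

The classifier predicts the charged amino acid of a tRNA gene from
identity elements, the nucleotides aminoacyl-tRNA synthetases recognize.
Rulesets are declarative (required vs. support elements as
position→allowed-base maps in a YAML config), so clade-specific rules can
be added without code changes:

* **bacterial_arg_met** — Arg: A20 in the D-loop and A/G73 discriminator;
  Met: A73 and *not* A20, with acceptor-stem pairs G2:C71 and C3:G70 as
  support. The two cannot both fire (A20 vs. not-A20), which the tests
  assert by exhaustive enumeration.
* **bacterial_trp** — G73 and not A20; A/G1:U72 as support.
* **bacterial_gln** — weak 1:72 pair, A37, A/G73, not A20; G2:C71, G3:C70,
  G38 and G10 as support. "Weak" is defined as any pair other than G:C or
  C:G (A:U, U:A, G:U, U:G, or a mismatch) — the standard thermodynamic
  reading, since weaker definitions are not universal.
* **bacterial_gly** — G1:C72, C2:G71, G3:C70 and U73.
* **yeast_ser_leu** — only Leu and Ser tRNAs carry a long (>12 nt)
  variable loop in eukaryotes; within long-loop records, Leu requires A73
  with A35 and G37, and anything else is called Ser, with non-G73 serine
  calls flagged as reduced confidence (serine tRNAs typically carry G73
  but tolerate any discriminator).

Support pairs for methionine are taken at positions 2:71 and 3:70
(standard numbering); sources sometimes quote the same pairs as "2:70,
3:69" under shifted numbering, and the positions are configurable per
ruleset should a different convention be needed.

Structure parsing walks the cloverleaf from a tRNAscan-SE-style
bracket string: acceptor stem (first helix, 7 bp), D-arm, anticodon arm,
variable loop, T-arm, discriminator. Position 20 is located by anchoring
on the conserved G18–G19 dinucleotide inside the D-loop; if the anchor is
absent or ambiguous, or the loop length is outside 5–11 nt, the D-loop is
flagged unusual and classification abstains rather than guesses. Unknown
bases at required positions likewise yield `unassigned` — the rules never
guess.

## Known limitations

* Ambiguous decoding (one codon, two meanings) is outside the model; the
  expected symptom is a codon with many aligned columns and no model above
  threshold.
* Noncanonical amino acids, alternative start codons, and
  context-dependent stop readthrough are not modeled.
* Rare codons may simply lack evidence (`?` with small N); the benchmark
  quantifies how many columns are needed.
* Pseudogene-rich genomes can contribute misleading in-frame stop
  alignments; the downsampling cap mitigates but does not remove this.
* The six-frame bootstrap assumes the standard-code translation preserves
  enough homology for profile search to find domains.

## Session

```{r}
sessionInfo()
```
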