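---
title: "EST-bridge annotation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EST-bridge annotation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The annotation model

`estbridge` annotates short cDNA inserts transitively: clone → EST →
annotated reference. The rationale is statistical as much as
biological. A 300–400 nt single-pass insert from an under-sequenced
taxon rarely reaches significance against a protein database, both
because it is short and because its nearest database neighbours are
deeply diverged. An EST hit, however, (i) certifies that the insert is
transcribed somewhere, (ii) is usually longer than the insert, so the
*EST* can be re-searched with more statistical power, and (iii) taps
collections with far broader taxonomic coverage.

The pipeline is a funnel with a built-in consistency check:

1. **Pass 1**: every clone vs. the raw EST database, exact local
   alignment, keep hits with E ≤ `e_threshold`.
2. **Cleaning**: vector/primer screening of the matched ESTs only.
3. **Pass 2**: clones vs. the validated (trimmed) survivors, same
   threshold. The effective database length — and therefore every
   E-value — is recomputed for the smaller subject set.
4. **Consensus**: keep clone–EST pairs present in both passes.

Why two passes? Public EST collections are appreciably contaminated
with cloning-vector and sequencing-primer stretches. A clone that
itself carries vector sequence will "match" any contaminated EST through
the shared vector, not through homology. Such a link cannot survive
pass 2, because the vector has been trimmed from the subject side. The
suppression is measurable: on a generated bundle with 25 % contamination
on both sides, link precision rises from ≈ 0.33 after pass 1 to ≈ 0.998
after consensus (this is computed, not assumed, by the acceptance
suite).

Consensus has two defensible readings and both are implemented:
`"pair"` (default, stricter: the same clone–EST pair must recur) and
`"clone"` (any pass-2 pair whose clone matched in pass 1). The package
asserts neither as "the" correct reading; `consensus_mode` switches.

## Alignment engine and E-value statistics

The engine (`src/sw.cpp`) is exact affine-gap Smith–Waterman (Gotoh
recurrences), no seeding or banding — inputs here are desk-scale and
exactness is what the sensitivity argument rests on. Conventions:

* A gap of length *k* costs `gap_open + (k − 1)·gap_extend`: the first
  gapped position is charged `gap_open`. (This is the convention under
  which the package's reference example — +3/−3 with
  `gap_open = gap_extend = 2` behaving as linear −2 per base — holds.)
* One optimal traceback is reported; DP ties break diagonal > up > left,
  so results are reproducible to the byte.
* Default nucleotide scores +2/−3, gaps 5/2; protein BLOSUM62, gaps
  11/1. The BLOSUM62 matrix is extended so that `*` (stop) scores +1
  against itself and −4 against residues: translate-through alignments
  remain defined and cross stop codons at a penalty.
* In nucleotide mode, N scores as a mismatch against everything
  (including N), so masked or ambiguous stretches cannot seed
  alignments. Ambiguity codes other than N are normalized to N on input
  with a warning.
* Coordinates are 0-based half-open internally (C++), 1-based inclusive
  in every report.

Significance uses the Karlin–Altschul form `E = K·m·n·e^(−λS)` with the
summed database length as *n* (amino-acid lengths, i.e. len/3, in the
translated modes, with *m* the query's longest frame). Gapped λ and K
have no closed form, and published constants assume a different gap
convention, so the built-in values for the two named default schemes
were estimated by the package's own calibration (`calibrate_scheme()`):
fit a Gumbel distribution to optimal local scores of several thousand
random pairs; then λ = 1/β and K = e^(μ/β)/(m·n). The frozen values are
λ = 0.572, K = 0.150 (nucleotide 2/−3, 5/2) and λ = 0.210, K = 0.020
(BLOSUM62 11/1 on uniform-random peptides). The calibration is honest
to about a factor of two across the length regimes used here; the test
suite checks order-of-magnitude correctness (decoy hit counts within 3×
of expectation), which is what a threshold of 10⁻² actually requires.

`e_threshold` defaults to 10⁻² everywhere — deliberately permissive, as
suits a sensitivity-first strategy whose false positives are then
filtered structurally (consensus) rather than statistically. Both
passes share the threshold by construction; `p2_e_threshold` exists but
overriding it is discouraged.

## Why nucleotide mode is the default bridge search

Single-pass reads carry indels. One indel shifts the reading frame, so
a single-frame protein comparison loses everything downstream of it,
while a DNA alignment absorbs it as one gap. The 6×6-frame translated
mode (`search_mode = "translated"`) recovers much of this but at 36×
the cost and with shorter effective segments. The acceptance suite
quantifies the effect under deep divergence (33 % substitutions, 420 nt,
1–3 indels): nucleotide-mode recovery is unchanged by the indels (ratio
1.0), single-frame protein comparison drops below half. For the
annotation *transfer* step the translated mode is the right tool — there
the subjects are curated references and the signal is protein-level —
so that stage always runs tBLASTx-style.

## Contamination screening

Screening follows VecScreen's intent: a stringent +1/−5 scheme (gaps
3/3) so that only near-exact vector stretches score, with a lower bar
(16) for matches whose footprint reaches within 25 nt of either end and
a higher one (24) internally. Each contaminant record is re-aligned
iteratively with previous matches masked, so multiple fragments per
sequence are found; overlapping calls merge. Trimming removes terminal
regions; an internal region splits the sequence and the longest clean
fragment is kept; results shorter than `min_len` (100 nt — below which
local-alignment statistics are unreliable) are rejected outright rather
than masked. Rejection (not N-masking) is what makes the pass-1 → pass-2
funnel counts meaningful.

## Annotation transfer, direct assignment, rollup

Best-hit transfer takes the single highest-scoring qualifying reference
per EST; ties break (score desc, E asc, subject id asc) and every losing
qualifying hit is retained in an audit attribute, since conflicting
annotations across multiple hits are expected at this divergence.
"Direct" assignment emulates exact-match orthology mapping; literal
exactness is untenable on noisy reads, so it is operationalised as ≥
95 % nucleotide identity over ≥ 80 % of the EST (both configurable).
The category rollup truncates each assignment's `/`-joined hierarchy
path to `hierarchy_level` components; `"hypothetical"` is always its own
category. The hierarchy is a flat two-column TSV (leaf, path) so the
stage runs offline and is trivially testable.

## Candidate screening and in-silico PCR

Keyword extraction is case-insensitive whole-word matching over a
keyword column shipped alongside the protein FASTA (an offline stand-in
for keyword retrieval from a curated protein database). Matched
proteins are aligned against all six frames of every clone; each
candidate carries the protein region covered by the alignment. That
region — not the whole protein — is then re-searched against the entire
protein collection: if fewer than 90 % of the top hits (default
`top_n = 50`) share the candidate's activity (unlabelled hits count as
consistent, mirroring "a few hits of unidentified function"), the
candidate is *contradicted*; no hits at all is *undetermined*; regions
under 20 aa are never ruled on. In-silico PCR strips primer strings of
whitespace and 5′/3′ decorations (printed primers frequently contain
typeset spaces), requires an exact 5-base 3′ clamp with 0 mismatches
elsewhere by default (stringent annealing), scans both strands, and
reports products spanning the forward primer's 5′ end through the
reverse primer's 5′ end.

## The synthetic study

`sim_config()` defaults define the conditions everything is validated
under: 142 clones with lognormal lengths around a median of 396 nt; 20 %
orphans (no homolog anywhere); 3 clones that are back-translated
fragments of enzymes for the four target activities; the remaining
clones are fragments of 25 reference families (700–900 nt, cycled so
every family is covered). The EST database holds 300 fragments (85 % of
family length, guaranteeing clone–EST overlap) at 15 % substitution and
0.5 % indel rate; 10 % of ESTs carry vector/primer segments, of which
10 % are essentially pure vector (and must be rejected, not trimmed);
10 % of ESTs are near-exact copies — the material for direct assignment,
set to mirror a direct-assignment rate of roughly one EST in ten. All
contamination fragments are read from the vector's cloning-site end, so
contaminated reads genuinely cross-match, which is what makes the
consensus experiment meaningful. A single seed fans out to fixed
per-component substreams, so regenerating one component never perturbs
another and bundles are byte-reproducible.

What the generator does *not* emulate: transcript-abundance structure,
chromatogram-level error profiles, chimeric clones, and the sheer scale
and redundancy of public EST collections. Passing tests therefore
demonstrate the machinery — recovery under divergence and frameshift
noise, contamination suppression, correct bookkeeping — not performance
against any particular year's databases, whose funnel numbers are
unreproducible in principle.

## Problem sizes and runtime

The shipped validation uses the default bundle (142 clones × 300 ESTs,
25 references, 24 proteins), a 100-pair frameshift simulation, an
800-query decoy calibration and a 200-pair oracle comparison; the full
suite runs in minutes on one core, the end-to-end pipeline itself in
about two. The engine does ~0.5·10⁹ DP cells/s; scaling to larger EST
sets is linear in clones × ESTs × lengths.

## Known limitations

* λ/K are calibrated for the default schemes; custom scoring falls back
  to conservative placeholder constants unless `calibrate_scheme()` is
  run — E-values for exotic schemes should be treated as relative.
* Edge-length corrections (finite-size effects) are folded into the
  empirical K rather than modelled; E-values for very short queries are
  conservative.
* The per-EST best hit is taken per reference record, not per HSP
  chain; chained/tiled alignments are out of scope.
* `clone` consensus mode, `screen_only` trimming and the translated
  bridge mode are provided for sensitivity analysis; defaults follow the
  stricter readings.
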