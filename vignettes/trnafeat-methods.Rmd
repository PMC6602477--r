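---
title: "Methods: consensus features, distributions and penalty scoring of tRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus features, distributions and penalty scoring of tRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnafeat)
```

# Overview

`trnafeat` analyses sets of transfer RNA genes on the community-standard
Sprinzl coordinate system.  Its pipeline has four stages, each usable on
its own:

1. **Curation** — a six-rule filter reduces raw tRNAscan-SE predictions to
   an analysis-ready set of genes plausibly active in cytosolic
   translation.
2. **Distributions** — nucleotide and base-pair counts per Sprinzl
   position, grouped by clade, species, isotype, anticodon, or bit-score
   focus.
3. **Consensus features** — each position (and base pair) is summarized by
   a tiered IUPAC ambiguity code under two frequency thresholds, and a
   clade's consensus can be compared against its domain's.
4. **Penalty scoring** — query tRNAs are aligned to a position-specific
   reference profile and scored per position as penalties `p = q - r`,
   which are zero exactly where the query matches the reference's modal
   state and negative elsewhere.

Everything operates on a `trna_set` (annotation table plus an aligned
symbol matrix) and a `trna_taxonomy` (a validated tree with the three
domains as top-level clades).  All randomness in the package lives in the
synthetic generator and is seed-controlled.

# The Sprinzl coordinate system

The canonical vocabulary is fixed package data produced by
`sprinzl_positions()`: positions 1–76, the inserted D-loop labels `17a`,
`20a`, `20b`, and the variable-arm labels `e11`–`e17` (5' strand),
`e1`–`e5` (loop) and `e27`–`e21` (3' strand, descending so that `e1k`
pairs `e2k`), 98 labels in total.  Keeping the list in one place means it
can be amended without touching any algorithm if a user's aligner emits a
different e-label set — the one genuinely open point of the coordinate
system, since covariance-model aligners differ in which variable-arm
columns they call match states.

Alignment input uses a Stockholm dialect with a single `#=GC RF` line:
`x` columns are match states mapped in order onto the canonical labels,
`.` columns are inserts.  Residues in insert columns are preserved in a
side channel but take no part in distributions or consensus calling;
the mapping is deterministic and aligner-agnostic.

`default_pair_table()` carries the cloverleaf stems (acceptor 1:72–7:66,
D 10:25–13:22, anticodon 27:43–31:39, T 49:65–53:61, variable arm
e11:e21–e17:e27) and the classic tertiary contacts (8:14, 9:23, 10:45,
15:48, 18:55, 19:56, 22:46, 26:44, 54:58).  Pair orientation is always
(5' position, 3' position), and a pair code `X:Y` reads 5' base : 3'
base.

Gaps are first-class symbols throughout: a position absent from a gene is
`-`, it is counted in distributions, it can be the modal state of a
position, and the consensus vocabulary has a zero-tier feature (`ABSENT`)
for gap-dominated positions.  Histogram denominators therefore include
gaps; display layers may hide the gap fraction but the consensus
computation needs it.

# Curation filter

Six rules, applied in a fixed order used for attribution when a gene
trips several: (i) Chordata genes flagged as outside the high-confidence
set, (ii) predicted pseudogenes, (iii) predicted truncations, (iv) fungal
genes below 50 bits, (v) all other genes below 25 bits, (vi) NUMT-derived
predictions.  Rules i, ii, iii and vi consume annotation flags —
recomputing the upstream classifiers (the high-confidence filter, the
pseudogene model, NUMT detection) is deliberately out of scope, so the
flags travel with the input.  Fungi and Chordata membership is resolved
by walking the species' lineage in the supplied taxonomy; rank strings
are not trusted beyond tree structure, and a gene whose taxid does not
resolve is an error rather than a guess.

"Below" is a strict inequality: a fungal gene at exactly 50.0 bits is
kept, at 49.9 it is removed; likewise 25.0 versus 24.9 for everything
else.  Rules iv and v are mutually exclusive by construction (v applies
only outside Fungi), so the removal counts partition the input exactly —
a conservation law the tests check on randomized fixtures.

# Consensus features

For a selection of genes, each position yields a frequency vector over
`A, C, G, U, -` (pairs: over the 25 ordered symbol pairs).  Codes are
scanned tier by tier — zero ambiguity (`A`, `C`, `G`, `U`, `ABSENT`;
pairs `A:U`, `U:A`, `G:C`, `C:G`, `G:U`, `U:G`), then partial ambiguity
(`R`, `Y`, `W`, `S`, `M`, `K`; pairs `R:Y`, `Y:R`, `S:S`, `W:W`), then
high ambiguity (`B`, `D`, `H`, `V`; pairs `PAIRED`, `MISMATCHED`) — and
the first qualifying code is returned.  A code qualifies when **every
component** (each base, or each base pair, in its set) has frequency at
least `min_component` (default 5%) and the components **together** reach
`min_total` (default 90%).  If nothing qualifies the position is a
no-call, rendered `N` (pairs `NN`).

```{r classify-example}
d <- as_position_distribution(c(A = 46, G = 44, C = 5, U = 5), "57")
classify(d)
```

Design choices worth stating explicitly:

* **Within-tier ties** follow the listed code order.  For
  `{A: 0.85, G: 0.08, C: 0.07}` both `R` (0.93) and `M` (0.92) qualify;
  `R` is returned because it precedes `M` in the scan.
* **Partial pair codes cover only properly paired combinations**:
  `R:Y = {A:U, G:C, G:U}`, `Y:R = {U:A, C:G, U:G}`, `S:S = {G:C, C:G}`,
  `W:W = {A:U, U:A}`.  This keeps the tiers nested (every zero-tier pair
  lies in some partial code, and every partial code inside `PAIRED`) and
  matches the reading of these codes as "a purine–pyrimidine *pair*",
  not as an arbitrary juxtaposition of a purine and a pyrimidine.
* **`PAIRED` and `MISMATCHED` are single-component codes**: only the
  combined 90% threshold applies, since they have no meaningful component
  decomposition.  `MISMATCHED` is exactly the ten ordered non-gap pairs
  outside the six canonical pairings.
* **Gaps never contribute to a base-containing code**; pairs with a gap
  on either side count in the denominator but match nothing except the
  paired no-call.
* **The component rule is applied uniformly**, including to the
  three-base codes `B/D/H/V`.  A consequence that is easy to miss: a
  distribution like `{A: 0.85, U: 0.06, G: 0.045, C: 0.045}` calls `W`
  (both components ≥ 5%, total 91%), not a no-call — the two-base codes
  are scanned in full before any three-base code is considered.
* **Threshold comparisons are inclusive** ("at least 5%", "reach 90%")
  and evaluated on count ratios with an absolute `1e-9` tolerance, so
  boundary distributions (e.g. exactly 10 of 200) classify as their
  rational values dictate, free of double-rounding artifacts.

`consensus_table()` classifies all 98 positions and every pair of the
active pair table; positions inside a scored pair keep their single
entry, and the display layer decides which to show.
`compare_to_domain()` reduces a clade-versus-domain comparison to three
verdicts per position: `exact` (codes equal), `more_specific` (the
clade's base set is a strict subset of the domain's), and
`less_specific_or_different` (everything else, including a no-call on
either side only).  The three-way split is deliberate: collapsing
`more_specific` into either of the other categories would assert a
directionality the underlying comparison does not have.

# Reference profiles and penalty scoring

The original analysis scores queries with covariance models; rebuilding a
profile SCFG is out of scope here, so the reference model is a
position-specific log-odds profile over the Sprinzl match positions,
with positional independence as the declared (and documented)
simplification — base-pair terms are not part of `q` or `r`.  From a
reference selection of `n` aligned genes, with Laplace pseudocount
`alpha` (default 1) over the five-symbol alphabet and a flat 0.25
background:

$$ b(x, i) = \log_2 \frac{(c(x,i) + \alpha) / (n + 5\alpha)}{0.25} $$

`r_i` is the maximum of `b(·, i)`, attained by the modal symbol.  The
per-position penalty of an aligned query is `p_i = b(q_i, i) - r_i`,
which is zero exactly when the query carries the modal symbol (or ties
its bit value, as in a uniform column) and negative otherwise.  Defining
`r` as the maximum attainable emission value is the unique reading under
which the zero upper bound holds *by construction*; whether the original
system instead uses the model's best-path emission score cannot be
resolved from its description, and this definition is flagged here for
that reason.  The gap symbol has its own emission row, so a deleted
position is penalized like any rare symbol via `b(-, i)`; with
`alpha → ∞` all emissions converge and every penalty goes to zero, a
continuity property the tests exercise.

**Alignment.**  Queries (50–120 nt; anything outside that range is
rejected as an implausible mature tRNA) are aligned globally to the
98-position series by a Gotoh-style dynamic program.  Matched positions
emit `b(symbol, i)`.  Deleted positions emit the profile's own gap state
`b(-, i)` — *not* a generic affine cost.  This keeps the aligner and the
penalty model consistent: positions that are usually absent in the
reference (the 17a/20a/20b inserts, the variable arm) are skipped at the
same cost the reference sequences themselves pay, whereas a generic
affine deletion cost makes such columns expensive to skip and lets the
optimal alignment drift around them, corrupting the positional numbering
precisely where substitutions sit next to gap-dominated columns.
Insertions (query residues with no Sprinzl label) are charged affine
`gap_open + k · gap_extend`; by default `gap_open` is set one bit above
the largest per-position substitution loss in the profile, so that
relabelling a substituted base as an insertion can never score better
than keeping it aligned.  Insertions are excluded from per-position
penalties (no label exists for them) and reported in a side channel.
Ties are broken deterministically: match over deletion over insertion,
which places gaps leftmost.  Note that in runs of identical columns the
*placement* of a deletion inside the run is inherently ambiguous; the
resulting symbol map is still unique whenever neighbouring columns
differ.

For multi-sequence query groups, penalties are averaged per position.  A
bitchart assembles: row 1, the reference consensus features; row 2, the
reference modal symbols; one row per query group with the group's modal
symbol and mean penalty per position.  The heatmap colour of the original
visualization maps directly onto the penalty value; no further
normalization is applied (none is defined for it).

# Synthetic data generator

`fixture_spec()` / `generate_trnas()` produce fully annotated,
Sprinzl-aligned gene sets so that every module is testable without any
download.  The defaults describe a generic cytosolic tRNA population:

* per-position categorical distributions holding a fixed modal sequence
  at 91% with the three alternative bases at 3% each — strong but not
  absolute conservation, comparable to a conserved position in a
  single-clade, single-isotype selection; the insert labels and the
  variable arm are absent in 97% of genes;
* isotypes uniform over the 20 standard amino acids, with the isotype's
  representative anticodon written at positions 34–36 so annotation and
  sequence agree;
* bit scores from a normal with mean 60 and standard deviation 10,
  truncated at zero and rounded to 0.1 bit (the precision score tables
  report), spanning the realistic range of cytosolic gene scores;
* species uniform over a fixed toy taxonomy (three domains, two phyla
  each — Eukaryota carries Fungi and Chordata so the lineage-dependent
  filter rules are exercisable — two genera per phylum, two species per
  genus);
* optional independent Bernoulli flags (pseudogene, truncation, NUMT,
  non-high-confidence) at stated rates.

Positions are sampled independently, scores independently of sequence
content, and flags independently of everything: sufficient for testing
filters, foci, distributions, consensus calling and scoring, but **not**
a model of real tRNA covariation, modification, intron structure, or the
correlation between sequence quality and score.  Passing tests on this
generator therefore demonstrate algorithmic correctness, not biological
performance on real genomes.

`planted_consensus` overwrites chosen positions with distributions that
realize a stated feature code (components sharing 96% by default, every
non-member below the 5% component threshold); realizability is validated
at specification time by classifying the exact target distribution, so an
impossible plan fails before any sampling.  `mutate_modal()` builds query
sequences at an exact Hamming distance from the reference modal sequence
and refuses no-op substitutions and gap-modal positions, both of which
would silently weaken a "k substitutions, k penalties" test.

# Numerical and interface choices

* Frequencies are exact count ratios; threshold tests add an absolute
  `1e-9` tolerance (exact for any realistic `n`, since frequencies are
  multiples of `1/n`).
* Score foci are half-open `[min, max)`, so complementary foci partition
  a gene set exactly.
* The clade-group cap (ten per comparison) is enforced at the command
  layer; the library functions accept any number, treating the cap as a
  presentation constraint.
* Exports are deterministic: fixed column order, 6-significant-digit
  floats, provenance headers limited to tool version, command and input
  digests (no timestamps), so reruns are byte-identical.
* `taxonomy_summary()` reports, for each ancestor of the selected clade,
  the ancestor's gene count and the selected clade's share of it — the
  reading under which a clade's row at the domain level answers "how much
  of the domain's data does this clade contribute".
* The Newick writer quotes reserved characters and emits internal clade
  labels; single-leaf clades yield a valid one-leaf tree.  Round-trips
  are tested against an independent parser (`ape`).

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
classification is cross-checked against a brute-force oracle on 10,000
random distributions; planted-consensus recovery uses 200 genes per seed
over 50 seeds; the aligner is compared with exhaustive alignment
enumeration on randomized profiles and queries of up to 8 positions and
symbols (sizes at which enumeration over all monotone match sets is
exact); threshold sweeps use counts out of 2,000 so that half-percent
steps are integral.  These sizes were chosen so each property is checked
exactly or with overwhelming coverage while the whole suite stays
interactive.

# Known limitations

* Positional independence in the scoring model: base-pair covariation is
  visible to the consensus and distribution modules but not to `q`/`r`.
* The curation filter is only as good as the upstream flags it consumes.
* How the original system scores query insertions and deletions per
  position is not documented; the choices here (gap-state deletions,
  profile-scaled insertion costs, insertions excluded from penalties)
  are principled but not a reimplementation.
* The e-label set of the canonical vocabulary may need adjustment to
  match a particular aligner's match-column convention.
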