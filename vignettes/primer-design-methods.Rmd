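---
title: "Designing and evaluating degenerate 16S primers with primarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating degenerate 16S primers with primarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`primarch` implements the desk half of archaeal metabarcoding primer
development: scanning a taxonomically annotated rRNA reference alignment
for conserved stretches, building degenerate primers under a strict
acceptance scheme, simulating PCR for primer pairs, and classifying query
OTUs as novel taxa from best-hit identities. This vignette explains the
models and procedures, the parameters that matter, the synthetic data the
tests rest on, and the numerical choices made where the method left room.

## Degenerate matching model

A degenerate primer is a mixture of all plain-sequence expansions of an
IUPAC pattern (`R` = A/G, `B` = C/G/T, ...; degeneracy = product of
per-position set sizes). `primarch` matches optimistically: primer
position *i* matches template base *b* iff *b* lies in the base set at
*i*. Under this semantics the mismatch count of the pattern equals the
minimum Hamming distance over all expansions — the property the test
suite verifies by brute-force enumeration — and matches the behaviour of
TestPrime-style in-silico PCR tools, which treat an ambiguity code as
"any of these bases will be present in the primer mix".

Mismatches in the final bases of a primer's 3′ end block polymerase
extension far more strongly than internal ones, so every mismatch count
carries a second number: mismatches inside the 3′-terminal zone (default
width 2, configurable). For a reverse-orientation primer — stored, as in
any primer catalogue, 5′→3′ on the minus strand — comparison happens on
the plus strand via the reverse complement, and the 3′ zone maps to the
*leftmost* compared positions. Inosine in published primer sequences is
normalized to N at parse time, since it pairs with all four bases.

## The acceptance scheme

Stretch selection requires (length) an ungapped consensus longer than
17 bp — implemented as ≥ 18 — and (conservation) < 25% mismatches to the
target-group consensus in every representative sequence. Candidate
primers over a stretch must then satisfy, against the full reference set:

| check | requirement | default threshold | level |
|---|---|---|---|
| terminal coverage | no 3′-terminal mismatch | ≥ 99.5% of targets | hard |
| mismatch coverage | < 2 total mismatches | ≥ 99.5% of targets | hard |
| rare-phylum inclusivity | no rare target phylum wholly uncovered | none excluded | hard |
| non-target specificity | terminal mismatch or > 1 internal | > 99.5% of non-targets | hard |
| GC content | mean GC over expansions in 40–60% | — | warning |
| melting temperature | mean Tm in 56–62 °C | — | warning |
| degeneracy | < 50% degenerate positions | — | hard |

Rare phyla are all target-domain phyla outside a configurable exemption
(defaults: Euryarchaeota, Crenarchaeota — the two historically
well-covered groups); a phylum counts as excluded when none of its
members is covered at the terminal-and-total allowance. Candidates
failing only the specificity check are kept in a separate *near-miss*
tier: such primers amplify beyond the target group but remain useful when
paired with a fully specific partner, so the pairing stage can still use
them. The GC and Tm checks are warnings rather than vetoes because the
published primer catalogue itself violates a strict GC reading (e.g. a
well-performing forward primer with mean GC ≈ 65%); setting
`strict_physchem = TRUE` escalates them. Whether the 40–60% figure was
ever meant as GC content or as an AT:GC ratio is ambiguous in the
literature; `primarch` reports GC content and leaves the verdict soft.

Melting temperature defaults to the basic formula
Tm = 64.9 + 41·(n~GC~ − 16.4)/L per expansion, which is linear in the GC
count, so its minimum, mean and maximum over expansions are exact without
enumeration; a nearest-neighbor method (unified parameters, 50 mM Na⁺,
0.5 µM oligo) is available and enumerates expansions under a cap. GC
extremes likewise come from per-position set membership, never from
enumeration.

## Window scanning: segmentation before selection

The conservation criterion alone cannot segment an alignment: a fully
conserved stretch flanked by random columns would keep absorbing flanks,
because one extra random column adds at most 1/(L+1) to any sequence's
mismatch fraction. The scanner therefore works in two stages.

**Stage one (segmentation).** For each column, take the set of bases at
frequency ≥ `segmentation_floor` (default 0.05) among the column's
non-gap characters. A column *anchors* a stretch when this set has at
most three members — at least one base is effectively absent, which is
exactly what distinguishes a constrained column (even a degenerate one
like `Y` or `B`) from free-running background, where all four bases
circulate. Columns whose majority character is a gap always break
stretches. A single non-anchor column flanked by anchors is bridged, so
an isolated N position inside an otherwise constrained stretch (common in
published primers) does not split it. Candidate stretches are maximal
anchor runs at least `min_ungapped_length` wide.

**Stage two (selection).** Within each stretch the per-sequence criterion
is applied: the window is emitted if every target representative has a
mismatch fraction below `max_consensus_mismatch` (default 0.25) against
the majority-rule consensus, gaps counting as mismatches. If the full
stretch fails, its maximal passing sub-windows are emitted (largest
feasible end per start, windows contained in an earlier one dropped).
Majority ties break deterministically in base order A < C < G < T; the
consensus is majority-rule rather than strict because a strict consensus
is undefined at any polymorphic column.

Primer construction then maps each window column to the minimal IUPAC
code covering all bases at frequency ≥ `frequency_floor` (default 0.005,
the complement of the 99.5% coverage goal) among target sequences, gaps
ignored. Candidate sub-windows are enumerated at lengths 18–20 — the
range spanned by the published catalogue — in both orientations
("whenever feasible, forward and reverse"), and overlapping passing
candidates reduce to the best by highest mismatch coverage, then lowest
degeneracy, then leftmost start.

## In-silico PCR

Binding sites are located by exhaustive scan of every offset on the plus
strand (the reverse primer as its reverse complement), under allowances
of at most 1 total and 0 terminal mismatches by default — the strict
end of TestPrime-like settings; coverage tables report both the
0-mismatch and ≤ 1-mismatch columns. For a primer pair, every forward
site pairs with every non-overlapping downstream reverse site; the
product spans both primer footprints, and per forward site the shortest
in-bounds product is primary, others are flagged alternative. Catalogue
positions (1-based, ungapped, 5′-most plus-strand base on a nominated
reference) are treated as nominal annotations for span arithmetic, not
recomputed against any particular reference organism.

## Novelty classification

Query OTUs are compared to references by global Needleman–Wunsch
alignment with affine gaps (match +1, mismatch −1, a gap of length *k*
costing 5 + 2*k*), implemented in C++ and cross-checked in the tests
against both an independent R dynamic program and a reference aligner.
Identity is matching columns divided by alignment columns *excluding
terminal gap runs*: internal indels count against identity, overhangs do
not — approximating the `usearch_global` definition used for this
analysis in practice. The best hit maximizes this identity; a k-mer
prefilter (default k = 8) orders candidates by shared-k-mer count and
skips zero-share candidates only once the running best exceeds 0.9, a
level a zero-share candidate cannot reach (it needs a difference in
every k-window, capping identity near 1 − 1/k). Ties break by
lexicographic reference id.

Best-hit identities map to novelty ranks on the ladder
97 / 95 / 92 / 89 / 86 / 83% for new species / genus / family / order /
class / phylum. Boundary values go to the *less novel* bin (exactly 97%
is a known species): the thresholds are published as delineation points
without a tie rule, and crediting the known taxon at the boundary is the
conservative choice. Only queries of at least 450 bases are classified
by default, mirroring the practice of restricting identity-based calls
to long, alignable OTU representatives; the cutoff is configurable.

## Synthetic data and what the tests show

The generator emulates the structure of a dereplicated SILVA-style
reference: defaults of 1901 target (Archaea) and 8647 non-target
(Bacteria) representatives — the reference-set sizes of the original
design substrate — over a 1500-column, gap-light alignment (full-length
16S; tests and the acceptance script use smaller explicit configurations
where their setups say so). The taxonomy plants rare archaeal phyla of
1–5 members to exercise the inclusivity check. Background columns draw a
per-domain anchor base or a uniform base according to
`background_entropy` (1 = fully random columns); gaps appear outside
motif columns at `gap_prob` (default 0.02). Planted motifs are carried
by every in-scope sequence as a random expansion; violation modes mutate
a 3′-terminal base, two non-terminal bases, share the motif with the
non-target domain, or plant an under-length stretch. Violation positions
and off-pattern bases are scattered independently per sequence, so no
single off-pattern base accumulates column frequency — otherwise primer
construction would simply absorb a frequent variant into a wider code,
which is correct design behaviour but would dissolve the planted
violation. All randomness flows through one seeded stream; the
generator restores the caller's RNG state.

The generator is deliberately simple: iid background, no secondary
structure, no correlated evolution, no chimeras, point substitutions
only for query OTUs (with the consequence that realized identities are
exact when (1 − identity)·length is integral). Passing tests therefore
demonstrate correctness of the algorithms under planted truth — not that
any particular primer will perform on real communities, where
amplification bias, template secondary structure and taxonomic
mis-annotation all intrude.

Problem sizes in the suite are chosen for sharp statistics at desk
scale: planted-recovery runs use 150–4000 target sequences over 20
seeds; violation runs use 4000 targets so a 1% planted violation sits
well clear of both the 0.5% criterion boundary and the 0.5%
construction floor; novelty recovery uses 200 queries of 600 nt at
bin-midpoint identities.

## Known limitations

No thermodynamic secondary-structure screening (hairpins, dimers) — the
acceptance scheme never included it. Dereplication identity (matching
columns over the shorter sequence's length, vsearch-style) is computed
by global alignment, which is quadratic per pair; the greedy clustering
is meant for reference curation at moderate n, not for clustering reads.
The scanner is fully automatic; any visual pre-screening a curator might
apply on top of it is out of scope. Exact agreement with any external
in-silico PCR service's mismatch accounting is not claimed; allowances
and zone widths are explicit parameters instead.
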