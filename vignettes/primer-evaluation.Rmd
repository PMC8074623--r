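---
title: "Designing and evaluating universal metabarcoding primers in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating universal metabarcoding primers in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscope)
```

## The problem

Environmental DNA (eDNA) metabarcoding identifies many taxa in parallel from
one mixed sample by amplifying a short, variable marker region with a single
"universal" primer pair and matching the resulting sequences against a
reference database. A good universal pair must balance two competing
quantities on its target clade:

* the **coverage index** $B_c = \dfrac{\text{amplified taxa}}{\text{target taxa}}$ —
  how much of the clade the primers anneal to, and
* the **specificity index** $B_s = \dfrac{\text{identified taxa}}{\text{amplified taxa}}$ —
  how many amplified taxa have an amplicon that is unique to them, so a read
  can be assigned unambiguously.

`ampliscope` implements the complete in-silico side of this workflow:
loading annotated reference databases, enumerating candidate primer pairs,
screening their physico-chemistry, running mismatch-tolerant in-silico PCR,
computing $B_c$/$B_s$ with taxonomic resolution of ambiguities, comparing
markers in a multi-marker (Venn) analysis, and profiling nucleotide
diversity along the gene to locate variable regions between conserved
flanks. A seeded synthetic-data generator produces databases with fully
known ground truth so that every stage of the pipeline is testable without
downloading a reference snapshot.

## The unit "taxon"

Curated rRNA databases mix records identified to species with records
identified only to genus. The index denominator counts one unit per species
present, plus one unit per *unique genus* — a genus that has genus-level
records but no species-level record under it. Genus-level records whose
genus is already represented by species contribute no unit of their own,
and records identified only to family or above are excluded from the
denominator altogether (they are still scanned during amplification). This
choice keeps the denominator interpretable as "distinct taxa the database
can in principle resolve"; it is configurable only by editing the taxonomy,
not by a switch, because all downstream statistics assume it.

## In-silico PCR semantics

A primer pair amplifies a record when the forward primer matches a site on
one strand and the reverse complement of the reverse primer matches a
downstream site on the same strand, delimiting an insert whose length falls
within the configured bounds (default 50–200 bp; the insert excludes both
primer sites). Matching is degeneracy-aware and mismatch-tolerant:

* an IUPAC degenerate primer base (e.g. `W`, `R`) matches any target base in
  its set, *even when zero mismatches are allowed* — degeneracy is part of
  the primer, not an error budget;
* a target `N` is matched by nothing except a primer `N` (an unknown
  reference base should not create spurious coverage);
* at most `max_mismatches` positions per primer site may mismatch, and the
  last `three_prime_strict` positions at each primer's 3′ end must match
  exactly, because 3′ mismatches are what actually abort extension;
* both strands are scanned, and every valid site pair is reported.

Internally coordinates are 0-based half-open; every emitted table uses
1-based inclusive positions on the scanned strand.

Taxon-level logic then works on the *set of distinct insert sequences* per
taxon. A taxon is amplified when any of its records yields a hit, and
identified when none of its inserts is exactly equal (string equality after
upper-casing and U→T normalization; no alignment) to an insert of another
taxon. Taxa connected by shared inserts form ambiguity groups, labelled by
the lowest common rank of their members (genus, family, or higher) via the
taxonomy's lineages. Non-amplified taxa are split into two failure modes:
records that lack the target region entirely (neither primer-site flank
found at ≤ 3 mismatches — the probe tolerance is a parameter) versus
records that contain the region but escape the primers' mismatch budget.
The two modes have different remedies — sequencing effort versus primer
redesign — which is why the report keeps them apart.

Indices are reported rounded half-up to two decimals (percentages to whole
percent), the precision at which such indices are conventionally quoted;
raw fractions are always retained alongside.

## Melting temperature and the filter rules

Candidate pairs are screened with nearest-neighbour thermodynamics using
the SantaLucia (1998) unified stacking parameters:

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/4)} - 273.15 + 16.6\log_{10}[\mathrm{Na^+}]$$

with $\Delta H$ in kcal/mol, $\Delta S$ in cal/(K·mol), $R = 1.987$
cal/(K·mol), salt default 0.05 M. The default convention omits the
duplex-initiation terms and uses a total strand concentration of
$C_T = 1.5\times10^{-5}$ M. This mirrors the behaviour of the widely used
web oligonucleotide-properties calculator, so published primer $T_m$ values
computed there are reproduced; the flagship cephalopod 18S pair below comes
out at 59.3 °C / 61.8 °C. Setting `include_initiation = TRUE` and
`strand_conc_molar = 5e-8` gives the textbook SantaLucia parameterization
instead (several degrees lower for 20-mers). Both constants are exposed
because no single convention is canonical across calculators; what matters
for filtering is that both primers of a pair are computed under the same
one. Degenerate primers are rejected by `melting_temperature()` — a
degenerate primer is a mixture of oligos with different $T_m$s, and
averaging them would suggest a precision the number does not have.

Two named criteria regimes are shipped. `genbank_strict` requires the lower
of the two primer $T_m$s in 59–69 °C, $|\Delta T_m| < 3$ °C, GC fraction
0.50–0.60 per primer, at most 3 G/C among the five most-3′ bases (a strong
GC clamp promotes mispriming), homopolymers shorter than 4 and tandem
dinucleotide repeats shorter than 4. `silva_relaxed` widens $T_m$ to
45–70 °C and GC to 0.45–0.65 and disables the structural rules — the
regime used when the strict screen returns nothing on a more divergent
database. The clamp window of five bases is a standard convention; the rule
set only fixes the *count* threshold. Self-complementarity is scored as the
longest perfectly complementary antiparallel run over all alignment
offsets, for self-dimers (`self_complementarity(p, p)`) and cross-dimers;
full thermodynamic hairpin folding is out of scope.

```{r thermo}
filter_primer_pairs(tibble::tibble(
  name = "Ceph18S",
  forward = "CGCGGCGCTACATATTAGAC",
  reverse = "GCACTTAACCGACCGTCGAC"
))[, c("name", "fwd_tm_celsius", "rev_tm_celsius", "pass")]
```

## Candidate discovery

Enumeration is seeded from the observed data rather than from the $4^{20}$
word space: every 20-mer present in a record (either strand) is a candidate
word, retained when it occurs exactly in at least a `strict_quorum`
fraction of records. Retained words are then paired in convergent
orientation and kept when at least a `sensitivity_quorum` fraction of
records amplifies within the mismatch budget. Each surviving pair is
re-scored by the in-silico PCR engine itself, so the reported `est_bc` and
`est_bs` are exactly what a standalone evaluation of that candidate
returns. Ranking is by $B_c$ then $B_s$, descending, with an alphabetical
tie-break for reproducibility. The quadratic pairing stage caps the word
list at the 500 best-supported words — conserved-flank words in a real
database number far fewer, and the cap keeps the stage tractable on a
laptop. Three presets mirror the two enumeration regimes: `genbank_exact`
(quorums 0.7/0.9, 0 mismatches), `genbank_mm3` (0.7/0.9, 3 mismatches, two
strict 3′ matches) and `silva_relaxed` (0.5/0.7, 3 mismatches, two strict
3′ matches). The two GenBank settings are two independent runs; merging
their outputs is left to the user because union and intersection answer
different questions.

## Multi-marker complementarity

`venn_complementarity()` tabulates the exclusive regions of two or three
markers' taxon sets over a common universe, plus the complement covered by
no marker. In identification mode the universe is first restricted to taxa
amplified by *all* markers — identification failures are then attributable
to resolution, not to annealing. Raw counts are exact and sum to the
universe size; percentages are rounded half-up, so their sum can drift by
±1 %, which is why the counts are always emitted alongside. Taxa are
matched across databases by taxid; a name-based fallback is left to the
caller's curation because automated binomial matching silently conflates
synonyms.

## Nucleotide diversity profile

`sliding_pi()` computes per-window nucleotide diversity over a multiple
alignment: $\pi = \frac{\sum_{i<j} d_{ij}}{\binom{n}{2} \bar L}$, where
$d_{ij}$ counts differing valid site pairs and $\bar L$ is the mean number
of valid paired sites. Sites with gaps or ambiguity codes are excluded
pair-by-pair (*pairwise deletion*, default) or column-wise (*complete
deletion*, via `deletion = "complete"`); pairwise deletion is the default
because rRNA alignments are gap-rich and complete deletion can discard most
of a variable region. The window (default 99 columns) slides in alignment
coordinates with a 10-column step; large-indel column ranges can be removed
first; each window's bounds are projected to 1-based positions on the
ungapped reference sequence, and windows containing no reference base are
skipped. The profile makes the conserved-flank/variable-insert structure of
a good marker visible at a glance:

```{r pi, fig.width = 6, fig.height = 3}
sim <- simulate_reference(sim_config(seed = 1))
prof <- sliding_pi(sim$alignment, reference_id = names(sim$alignment)[1])
autoplot(prof)
```

## The synthetic-data generator

`simulate_reference()` builds a database whose evaluation outcome is known
by construction. Each species receives a distinct random insert flanked by
the configured primer annealing sites inside random padding; planted
ambiguous pairs share one insert; missing-region taxa get records with no
amplicon at all; per-taxon primer-site mismatches are drawn from a
configured distribution and placed in the forward site away from its 3′
end, so a mismatch budget below the planted count must fail and one at or
above it must succeed. Within-taxon record variation touches only the
padding, never primer sites or insert, keeping the planted truth exact. All
sampling flows through R's RNG seeded once from the config, and the global
RNG state is restored afterwards; identical seeds give byte-identical
files.

The defaults describe a desk-scale analogue of a curated cephalopod 18S
snapshot: 6 families × 2 genera × 3 species (36 species), two records per
species, one genus-only taxon per ten species, inserts of 131–196 bp
between the flagship pair's annealing sites, 8 % of taxa carrying four
primer-site mismatches, 7 % of taxa lacking the region, and 2 same-genus
plus 2 same-family ambiguous pairs — proportions chosen to mirror the
outcome structure of a real snapshot (roughly 85 % amplified, 78 %
identified) at one-third scale. What the generator deliberately does *not*
emulate: phylogenetically correlated sequence evolution, length variation
in the conserved flanks, chimeras, and the long-tailed record-per-taxon
counts of real archives. Passing the recovery suite therefore demonstrates
that the engine's set logic and matching semantics are exact, not that any
particular real-world index value will be reproduced.

## Numerical and design choices

* Rounding is half-up (away from zero) at the reported precision, not
  banker's rounding: `coverage_index(1, 8)` is 0.13.
* Ambiguity components use exact string equality of inserts; a single
  substitution separates taxa. Near-identical inserts are a biological
  reality the index definition ignores by design.
* Ties in candidate ranking are broken alphabetically; hit tables are
  emitted in record/strand/position order — all outputs are deterministic.
* Degenerate bases in *targets* other than `N` (e.g. an `R` in a reference
  sequence) match any primer base whose set intersects theirs.
* The test suite exercises the engine against an independent character-set
  brute-force matcher on 500 randomized cases, recovers planted ground
  truth exactly over 20 generator seeds, and checks monotonicity of the
  matching rules; problem sizes (records of 60–600 bp, databases of 40–80
  records) were chosen so the full suite runs in about a minute.

## Limitations

The engine evaluates primers against reference databases; it does not
predict amplification efficiency, polymerase kinetics, chimera formation or
the behaviour of degenerate primer *mixtures* beyond set matching. Tm
calculation covers non-degenerate oligos at a single monovalent salt
concentration — no Mg²⁺ or dNTP corrections. Identification is
insert-equality against the database at hand; it cannot model taxa missing
from the reference, which empirically dominate assignment failures.
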