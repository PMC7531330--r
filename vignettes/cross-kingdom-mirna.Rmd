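---
title: "Cross-kingdom miRNA analysis with xkmir: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-kingdom miRNA analysis with xkmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xkmir)
```

# The scientific question

Diet-derived plant microRNAs have been reported in mammalian sera and
tissues, raising the question of whether they can regulate human
transcripts the way endogenous miRNAs do. Animal miRNA targeting is driven
almost entirely by the seed — the 5' region of the mature miRNA, canonically
positions 2–8 — so a plant miRNA whose 5' end is identical to a human seed at
the same positions is a candidate *functional analog* of that human miRNA.
`xkmir` implements the computational arm of this hypothesis end to end:

1. **Seed comparison** — find every human–plant pair of mature miRNAs with a
   perfect, same-position match in one of the three canonical seed frames.
2. **Similarity profiling** — contrast whole-sequence global identity of
   human versus plant miRNAs with a random background, to show that seed
   identity is not an artifact of overall sequence similarity.
3. **Candidate selection** — restrict matched human miRNAs by validated
   target evidence, gene-set over-representation and cancer-role
   annotations, and map the selection back to the distinct plant partners.
4. **Target scanning** — miRanda-style two-phase prediction of plant-miRNA
   binding sites on transcripts of interest (e.g. the oncogenic lncRNAs
   MALAT1 and NEAT1).
5. **Differential expression** — the count-based statistics used on
   transfection RNA-Seq: median-of-ratios normalization, per-gene Fisher's
   exact test, Benjamini–Hochberg FDR and a fold-change filter.

Every stage has a seeded synthetic generator that plants ground truth, so
the full pipeline is testable with no downloads.

# Seed frames and the matching rule

Three frames are compared, each at fixed 1-based positions on the mature
sequence: the 6mer (2–7), the 7mer (2–8) and the offset-6mer (3–8). A pair
is a match when human and plant subsequences are identical *at the same
frame*; sliding or offset matching is deliberately not performed, because
the biological claim is positional mimicry of the seed.

Two reporting rules are worth spelling out:

* **Subsumption.** A 7mer (2–8) identity implies both 6mer identities, so
  such pairs are reported as `F2_8` alone.
* **2–7 plus 3–8 implies 2–8.** Because the two 6mer frames jointly cover
  positions 2–8, a pair matching both necessarily matches the 7mer, and the
  classifier reports `F2_8`. Curated tables sometimes label such pairs with
  the two 6mer types instead; the packaged regression fixture preserves
  those printed labels while `classify_pair()` reports the subsumed frame.
  This is an intentional, documented divergence.

`match_all()` indexes plant miRNAs by their frame seeds (a hash join) but is
required — and property-tested — to equal the naive all-pairs double loop.
Output ordering is lexicographic in (human id, plant id) so runs are
byte-reproducible. For uniform random sequences the expected fraction of
pairs matching any frame is $2 \cdot 4^{-6} - 4^{-7}$ by
inclusion–exclusion (the 7mer event is the intersection of the two 6mer
events); the test suite checks observed collision counts against this rate
at ±3σ.

The packaged fixture (`read_seed_fixture()`) contains the 20 human / 7
plant curated pairs used as the selection regression target. One caveat it
illustrates: a single plant *family* name can appear with two different
7mer seeds, which no single sequence can satisfy — plant identifiers in
such curated tables are family-level. Sequence-level pipeline tests
therefore use generated universes with planted truth, and `run_discovery()`
accepts a precomputed match table so curated fixtures can drive the
selection stages directly.

# Global similarity scoring

No standard exists for a bare "percent similarity" between two short RNAs,
and published decade-bin counts from unspecified aligners cannot be
reproduced without knowing their gap and denominator conventions. `xkmir`
uses the simplest defensible definition: a global alignment maximizing the
number of identically matched positions (match +1, mismatch 0, gap 0), with

$$\mathrm{identity} = 100 \times \frac{\text{matches}}{\text{alignment length}},$$

where, among alignments achieving the maximal match count, the shortest one
(fewest gap columns) defines the denominator. This scheme is symmetric,
equals 100 iff the sequences are identical, and is validated against
exhaustive enumeration of all global alignments for short sequences. Decade
histograms (60–70 … 90–100) and a seeded i.i.d.-uniform background with
lengths resampled from the query length distribution support the
true-versus-random contrast. Because the scoring convention is a package
choice, externally published bin counts are explicitly *not* treated as
verification targets.

# miRanda-style target scanning

Phase 1 is a Smith–Waterman local alignment of the *reversed* miRNA
(3'→5') against the transcript (5'→3') under complementarity scoring:

| parameter | default | meaning |
|---|---|---|
| `wc_reward` | +5 | A:U and G:C pair |
| `wobble_reward` | +2 | G:U wobble pair |
| `mismatch_penalty` | −3 | any other juxtaposition |
| `gap_open` / `gap_extend` | −9 / −4 | affine gaps |
| `seed_scale` | 4 | multiplier on substitution scores at miRNA positions `scale_span` |
| `scale_span` | 2–8 | the seed frames this pipeline is about |
| `score_threshold` | 140 | minimum reported alignment score |
| `energy_threshold` | 0 kcal/mol | maximum reported duplex MFE |

The pair rewards, gap penalties, scale factor and score threshold follow
the constants commonly cited for the miRanda tool; the scale span is this
package's choice (the seed region), and every value is overridable through
`scan_params()`. A perfect 21-nt complement therefore scores
$7 \times 5 \times 4 + 14 \times 5 = 210$. Overlapping candidate sites are
reduced to the best-scoring non-overlapping set, best first, ties resolved
leftmost; coordinates are 1-based inclusive and a site's reported
"position" is its start. Note that with a 4-fold-scaled seed the default
threshold of 140 *can* be reached by gapped chance alignments on long
random sequences; planted-truth tests use a stringent threshold of 180,
and real analyses should treat the alignment score as a candidate filter
whose specificity comes from the energy phase.

Phase 2 evaluates each candidate with an intermolecular, pseudoknot-free
nearest-neighbor duplex model: stacking increments for adjacent base pairs,
size-dependent bulge and interior-loop penalties with a Ninio asymmetry
term (capped at 3.0 kcal/mol), a duplex initiation term (+4.10 kcal/mol)
and a +0.50 kcal/mol terminal penalty for A:U/G:U closing pairs. Loops
longer than 30 nt are disallowed; single-nucleotide bulges retain the
flanking helix stack, as is standard. A reported duplex must contain at
least one stacked pair; otherwise the no-duplex sentinel `NA` is returned.
Two published parameter sets ship as plain-text tables
(`nn_table("turner2004")`, default, and `nn_table("turner1999")`, the
vintage of miRanda-era folding code) and any TSV in the same layout can be
substituted. Simplifications relative to full folding engines — no
sequence-dependent terminal-mismatch or 1×1/1×2/2×2 interior-loop tables,
no dangling ends, no symmetry correction for homodimers — are deliberate:
the dynamic programme is exactly checkable against exhaustive structure
enumeration (done for all strand pairs up to 10 nt, 200 seeds), it is
strand-exchange symmetric, and its energies track full-model values
closely enough for ranking candidate sites. Published site MFEs computed
with other engines should be compared qualitatively, not to the decimal.

```{r duplex-example}
duplex_mfe("GCGCGC", "GCGCGC")   # 5 GC stacks + initiation
```

# Candidate selection

Validated interactions are filtered by a strong-evidence whitelist
(luciferase reporter assay, Western blot, RT-qPCR) after case-insensitive
canonicalization through a packaged synonym table. Over-representation of
the resulting gene list in user-supplied gene sets uses the upper-tail
hypergeometric probability with Benjamini–Hochberg adjustment across sets;
each set is intersected with the background universe before testing. A
general-purpose hypergeometric test was chosen over reimplementing any
specific enrichment web service: service-specific statistics (e.g. modified
EASE-style scores) and annotation snapshots are not reproducible offline,
so their printed p-values are not targets. The decision rule that turns
enrichment plus literature roles into a final human-miRNA shortlist is
curatorial, not algorithmic; the package exposes the filters
(`strong_evidence_targets()`, `overrepresentation()`, `read_role_table()`)
and reproduces a given shortlist's plant mapping exactly
(`select_analog_pairs()`).

# Differential expression

The DE stage starts from a gene × sample integer count matrix.

* **Normalization** is median-of-ratios: per gene, the geometric mean
  across samples; per sample, the factor is the median over genes of
  count/geometric-mean. Genes with a zero in any sample are excluded from
  factor computation but kept in the matrix. Note the scaling law this
  implies: multiplying one of $n$ samples by $c$ multiplies its factor by
  $c^{(n-1)/n}$ and every other factor by $c^{-1/n}$ (geometric means move
  too); the tests assert this law and cross-check factors against an
  independent reference implementation.
* **Testing** pools replicates per condition (sums of rounded normalized
  counts) and applies a two-sided Fisher's exact test per gene against the
  pooled totals — the only 2×2 construction consistent with a per-gene
  exact test. Genes with zero pooled counts in both conditions are not
  tested and are excluded from the BH family.
* **Fold change** is the ratio of mean normalized counts with a
  pseudo-count of ε = 0.5 in numerator and denominator, so zeros are
  finite; `significant ⇔ q ≤ 0.05 and max(fc, 1/fc) ≥ 1.5` by default.
* **Biotypes** (protein-coding / lncRNA / other) come from a user-supplied
  annotation table with an `other` fallback; the summary reports biotype
  proportions over significant calls.

**A calibration caveat that matters.** Fisher's exact test models sampling
(technical) variation only. Pooling biological replicates discards their
between-replicate variance, so under substantial biological overdispersion
the test is anticonservative: in the packaged simulations at NB dispersion
0.1, a planted run calls not only 98/100 planted genes (all in the planted
direction) but also a double-digit percentage of null genes. This is a
property of the published procedure, not an implementation artifact —
dispersion-based models exist precisely to fix it, and are out of scope
here. The null-calibration test therefore runs at the generator's default
dispersion (see below), where the test's assumptions hold and the
empirical false-call rate at q ≤ 0.05 ∧ FC ≥ 1.5 stays below the nominal
rate.

# The synthetic generators

The generators define the study conditions under which the pipeline is
validated:

* `gen_mirna_universe()` — i.i.d. uniform-base sequences of 16–24 nt (the
  mature-miRNA length range); planted pairs overwrite the plant frame with
  the human seed, so planted truth holds by construction rather than by
  rejection sampling.
* `gen_transcript_with_sites()` — i.i.d. background at configurable GC;
  planted sites are exact reverse complements of their miRNA.
* `gen_count_matrix()` — log-normal baseline abundances (sdlog 1.5) scaled
  to a 10⁶ expected library size, per-sample log-normal library factors
  (sdlog 0.1), NB counts with dispersion 0.01 by default and 3+3
  replicates. The default dispersion corresponds to a biological
  coefficient of variation of 0.1, the standard guidance for genetically
  identical cultured cell lines; planted-recovery runs that model noisier
  biology use dispersion 0.1 explicitly. DE genes receive a ±log2fc shift
  of the treated mean with random recorded sign.

Each generator is a pure function of its parameter record including the
seed (`withr::with_seed`; the caller's RNG state is untouched), and emits a
truth record used by the planted-recovery tests.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: phylogenetic correlation between miRNA family
members (real seed matches are highly clustered in families), composition
bias and repeat structure of real transcripts, isoform-level count
ambiguity, and sample-level batch effects. The synthetic results validate
the algorithms, not the biology.

# Numerical and engineering choices

* Sequences are strictly normalized on input (T→U, uppercase); ambiguity
  codes are an error, never silently skipped, because seed matching is
  exact string identity.
* All orderings are deterministic (radix/byte order); reruns with
  identical inputs produce byte-identical tables.
* Alignment tie-breaks: smallest window start, then shortest alignment.
  Duplex DP and its enumeration oracle share parameter data but no code
  path.
* Test problem sizes: seed-matching oracle equivalence on universes up to
  200×200 over 100 seeds; duplex enumeration up to 10-nt strands over 200
  seeds; Fisher enumeration to totals of 500; null calibration on 50
  matrices of 2000 genes × (3+3); similarity profiling on 20-sequence
  query sets.

# Known limitations

* The duplex model's absolute energies omit terminal-mismatch and special
  small-loop tables; rankings are robust, absolute values differ from full
  folding engines by roughly the magnitude of those terms.
* Fisher-exact DE is anticonservative under biological overdispersion (see
  above); it is implemented because it is the procedure under study.
* The similarity percentage depends on an explicitly chosen alignment
  convention; cross-tool bin counts are not comparable.
* Whole-kingdom plant prefix lists stand in for any curated
  edible-species whitelist when running at full scale; the selection
  stages accept user-supplied annotations for narrower definitions.
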