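---
title: "Classifying editing outcomes in dual-guide exon-excision amplicons"
author: "dualguide package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying editing outcomes in dual-guide exon-excision amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualguide)
```

## The problem

A dual-guide CRISPR therapy places two SaCas9 cuts in the introns flanking a
disease exon (the motivating application is excision of the murine *Dmd*
exon 23 in a Duchenne muscular dystrophy model).  Productive repair excises
the exon and fuses the flanking introns; everything else is non-productive
and, worse, usually blocks re-cutting: an indel at one cut site before the
second site is cleaved, an indel at both sites without excision, inversion of
the excised fragment, or integration of AAV vector backbone into the break.
Long-read amplicon sequencing of the target region makes these outcomes
directly observable: a single circular-consensus read spans the whole
amplicon (~800 bp unedited, ~450 bp after excision), so each read can be
assigned to exactly one outcome class.

`dualguide` implements that assignment as a reusable, tested pipeline:

1. **Locus model** — the amplicon reference, the two guide sites (located by
   protospacer + NNGRRT PAM, blunt cut 3 nt 5′ of the PAM), and the expected
   deletion and inversion products.
2. **Feature derivation** — diagnostic 25-mers spanning each informative
   junction, plus every 25-mer of each AAV backbone in both orientations.
3. **Demultiplexing and filtering** — internal 8-mer barcode pairs, then a
   mean-quality (maq ≥ Q20) and length (≥ 400 nt) filter.
4. **Classification** — edit-distance-tolerant k-mer matching and a fixed
   precedence that maps feature presence/absence to one of eight categories.
5. **Reporting** — per-category counts/percentages and amplicon-size QC.
6. **qPCR arithmetic** — standard curves, percent exon-skipped transcripts,
   vector genomes per host genome, Pfaffl ratios.

A seeded synthetic-read generator stands in for the deposited sequencing
data, providing libraries with known per-read truth.

## The locus model and its products

Cut positions are stored as inter-base counts (0 … reference length), which
are invariant to 1-based/0-based conventions; intervals such as the exon are
1-based inclusive, the R/Bioconductor idiom.  With cuts at inter-base
positions $c_5 < c_3$ on reference $R$:

* deletion product $= R[1..c_5] \cdot R[c_3{+}1..]$, so its length is
  $|R| - (c_3 - c_5)$ — for the default 833-bp amplicon with a 387-bp
  inter-cut distance, 446 bp;
* inversion product $= R[1..c_5] \cdot \mathrm{revcomp}(R[c_5{+}1..c_3])
  \cdot R[c_3{+}1..]$, length-preserving.

```{r locus}
loc <- synthetic_locus(seed = 1)
loc
```

`synthetic_locus()` builds the default study locus: a random 833-bp amplicon
with the 5′ guide on the plus strand, the 3′ guide on the minus strand, a
213-bp exon between the cuts, and two synthetic AAV backbones (2,000 and
1,800 bp — scaled-down stand-ins for real vector genomes, which the package
accepts as FASTA).  Sequences are resampled from the seed until both guides
are unique and the derived feature sets at k = 17 and k = 25 are diagnostic.

## Diagnostic features

```{r features}
fs <- derive_features(loc)   # k = 25, max_dist = 2, 3 k-mers per junction
fs
```

Each junction (intact 5′ site, intact 3′ site, excision seam, the two
inversion seams) gets `n_per_junction = 3` staggered k-mers centered on the
junction (shifts ±4, constrained so at least ⌊k/3⌋ bases remain on each
side).  Staggering tolerates clustered sequencing errors: a read is only
scored "site disrupted" if *every* staggered k-mer misses.  Exon-internal
k-mers distinguish excision from retention.  AAV features take every k-mer
of each backbone in both orientations (stride 1), mirroring detection of any
25-nt contiguous backbone sequence.

At build time the set is validated: no k-mer may serve two features, and no
edited-product or AAV k-mer may occur in the unedited reference within the
matching tolerance — otherwise the set is rejected as non-diagnostic.

## Matching and classification

A feature is *hit* if any of its k-mers occurs in the read or its reverse
complement within `max_dist` Levenshtein edits (substitutions + indels;
default 2, i.e. "up to two mismatches or indels").  The engine splits each
k-mer into `max_dist + 1` pieces, so any true occurrence contains one piece
verbatim (pigeonhole); exact piece lookups are then verified with Myers'
bit-parallel algorithm on a padded window.  The search is therefore exact
for the configured distance, not heuristic, and is cross-checked in the test
suite against an exhaustive sliding-window `adist()` oracle and against
`Biostrings::matchPattern(with.indels = TRUE)`.

Categories are assigned by fixed precedence, most specific evidence first:

| precedence | evidence | category |
|---|---|---|
| 1 | any AAV backbone k-mer | `aav_integration` |
| 2 | any inversion junction | `inversion` |
| 3 | excision seam, no exon sequence | `delta_exon` |
| 4 | exon present, both cut sites disrupted | `indel_both` |
| 5 | only 5′ site disrupted | `indel5` |
| 6 | only 3′ site disrupted | `indel3` |
| 7 | both cut sites intact | `unedited` |
| — | anything else | `unclassified` |

AAV evidence dominates because backbone k-mers cannot occur in the locus
(checked at build time); inversion precedes the exon logic because
inversions retain exon sequence.  The partition is total: every read gets
exactly one category, and percentages are computed over all classified
reads including `unclassified`.

**Sensitivity limit.** A junction indel of size ≤ `max_dist` is
indistinguishable from sequencing error — the intact-site k-mer still
matches — so such events are read as `unedited`.  Equally, an excision
product carrying a junction indel larger than `max_dist` loses the seam
feature and falls to `unclassified`.  Both limits are inherent to any
edit-tolerant presence/absence assay, not implementation choices.

## The synthetic-read generator

`simulate_library()` draws each read's category i.i.d. from configurable
proportions.  The defaults are the midpoints of the per-library outcome
ranges reported for CRISPR-treated cardiac libraries (unedited 82–86%, 5′
indels 9.9–13.4%, 3′ indels ~2%, both-site indels ~0.5%, productive excision
0.43–0.67%, inversion 0.03–0.06%, AAV integration 0.38–1.11%), normalized to
a proper distribution:

```{r props}
round(100 * sim_config()$proportions, 3)
```

Molecules are built per category, wrapped in per-sample 8-mer barcodes,
emitted in random orientation (50/50), and passed through the error model.

**Junction indels** are drawn from a truncated geometric size distribution
(p = 0.3) with deletions:insertions 3:1, plus preset events — the commonly
observed 4-bp downstream and 11-bp upstream junction deletions.  Two
choices make the generator emit *detectable* events by construction:

* **Size floor 3** (one above the default matching tolerance): smaller
  indels are invisible to the assay by the sensitivity limit above, so a
  generator drawing them would label molecules with distinctions no
  edit-tolerant classifier can make.
* **Detectability guard** (`detect_margin = 2`): a drawn indel is accepted
  only if the resulting junction differs by more than 2 edits — on either
  strand — from the unedited junction *and* from the excision/inversion
  seams.  Without the guard, an inserted run occasionally duplicates
  flanking sequence (landing within 2 edits of the intact site), and about
  1 junction in 5,000 lands within 2 edits of an inversion seam; such
  molecules are genuinely ambiguous at the molecular level.

**AAV integration** molecules insert a backbone fragment (uniform
100–1,600 nt, either orientation) at a cut junction of either the deletion
product or the uncut reference, capped so the template stays below 1,700 nt
(PCR-amplifiable; the largest reported integrated read was 1,721 bp).

**Errors** are per-base i.i.d. substitutions/insertions/deletions (default
0.5%/0.25%/0.25%, a ~Q20 CCS-like total of 1%) with Phred qualities drawn
N(27, 5) truncated to [2, 41] — qualities are *uninformative about the
realized errors*, a deliberate simplification.  The generator is bit-exact
reproducible for a given seed.

What the simulator does **not** model: PCR amplification bias against long
AAV-integrated templates (so recovery tests compare against simulated, not
biological, truth), chimeric reads, instrument-specific error kinetics, and
quality/error correlation.  Passing recovery tests therefore demonstrates
correctness of the classification machinery under the stated error model,
not performance on real instrument data.

## Filters

The maq filter computes mean read quality on the error-probability scale,
$Q = -10\log_{10}\left(\tfrac1n \sum_i 10^{-q_i/10}\right)$, the
error-rate-faithful interpretation of a minimum-average-quality threshold
(a read that is half Q30/half Q10 has mean error 5.05% ≈ Q13, not Q20).
The arithmetic-mean-of-Phred alternative is available via
`maq_method = "phred"`.  Both boundaries are inclusive; the 400-nt length
floor is applied after barcode trimming.  Demultiplexing matches both 8-mer
barcode windows within 1 substitution (no indels in an 8-mer window), in
either read orientation; barcode sets must be pairwise separated by more
than twice that radius.

## Parameter optimization against an untreated control

`optimize_params()` classifies an unedited control library over a
(k, max_dist) grid and minimizes the fraction of reads assigned to any
non-`unedited` category, breaking ties toward larger tolerance, then
smaller k.  On a 400-read control at the default error profile the
diagnostics table looks like:

| k | max_dist | objective |
|---|---|---|
| 17 | 0 | ~0.21 |
| 17 | 1 | ~0.008 |
| 17 | 2 | ~0.07 (spurious AAV hits) |
| 25 | 0 | ~0.31 |
| 25 | 1 | ~0.02 |
| 25 | 2 | 0 |

Two regimes are visible.  With no tolerance, ~1% sequencing error produces
heavy false "site disrupted" calls.  With k = 17 at tolerance 2, the
stride-1 AAV screen loses specificity — a random 17-mer is too likely to
sit within 2 edits of one of several thousand backbone 17-mers — so the
objective *rises* again.  The optimizer consequently selects k = 25 with
2 edits, and monotone improvement with tolerance holds at that k.  This is
the package's declared objective; the original analysis states only that
parameters were optimized against the untreated sample.

## Quantification arithmetic

Standard curves are least-squares fits $C_q = m\log_{10}(\text{copies}) + b$
with amplification factor $A = 10^{-1/m}$ and efficiency $E = A - 1$
(slope −3.3219 ⇒ perfect doubling).  Percent exon-skipped transcripts is
$100\,\Delta/(\Delta + \text{FL})$ from absolute copies of the exon-deleted
and full-length targets.  Vector genomes per host genome divides transgene
copies by host genome equivalents (single-copy-gene assay; a gDNA standard
mass converts at 6.6 pg per diploid genome, the conventional figure, and a
`ploidy` flag — off by default — halves allele counts if desired).  The
Pfaffl ratio $E_t^{\Delta C_{q,t}} / E_r^{\Delta C_{q,r}}$ uses the
control-minus-sample sign convention, so ratios above 1 mean enrichment in
the sample.  Technical replicates are combined by mean Cq before
conversion.

## Numerical and design notes

* Matching k-mers are limited to 64 bases (one machine word for the
  bit-parallel verifier); `max_dist` must be below k.
* Reported hit offsets are exact for distance-0 hits and accurate to within
  `max_dist` otherwise (ties broken toward the leftmost discovered
  placement).
* Ambiguity codes (N) are rejected in references and backbones at load
  time; in reads, non-ACGT bases simply never match (they count as edits).
* The length-distribution mode is computed on 10-bp bins to damp indel
  jitter; percentages print at 2 decimals, 4 below 0.01%.
* Problem sizes used by the bundled checks: zero-error recovery at
  n = 5,000; noisy recovery at n = 20,000 across 3 seeds; oracle
  equivalence on 200 random cases at distances 0–3; optimization on a
  400-read control over {17, 25} × {0, 1, 2}.  These sizes give 3·SE bands
  tight enough to detect percentage-point biases while keeping a full run
  in minutes on one CPU.

## Known limitations

* Indels at a cut site are detected, not reconstructed — no allele table or
  base-level breakpoint refinement (alignment-based tools cover that need).
* Reads carrying features of multiple events (e.g. AAV fragment plus an
  inversion seam) are resolved by precedence, not reported multiply; the
  per-read evidence column retains the full hit list.
* The maq interpretation and the category precedence are declared package
  conventions where the original description is silent; both are
  configurable at the API level (`maq_method`, per-feature match results
  are available from `match_features()` for custom rules).
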