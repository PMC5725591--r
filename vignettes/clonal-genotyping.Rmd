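---
title: "Methods: clonal SNV genotyping, chimera inference and genotype relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal SNV genotyping, chimera inference and genotype relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotyper)
```

# Scope and model

`clonotyper` analyses single-nucleotide variants called jointly across
several clones of a vegetatively propagated cultivar. The genetic model is
deliberately simple: each clone is a diploid genome differing from the
reference by germline-like variants shared across the cultivar (varietal)
plus rare somatic mutations private to a clone lineage (clone-specific).
The package takes a multi-sample VCF as its starting point; read alignment
and variant calling are upstream concerns.

## The filter cascade

The retention rules operate per site, report **all** violated rules (no
short-circuiting), and are strict inequalities so boundary behaviour is
deterministic — a site at exactly FS = 10 passes the FS rule.

| rule | default | reason code |
|---|---|---|
| repeat-region mask (BED) | — | `IN_REPEAT` |
| >= 3 alleles each supported by >= 3 reads, or a MULTI genotype | 3 reads | `SPURIOUS_ALLELE` |
| per-clone depth < 15 | 15 reads | `LOW_COVERAGE` / `INADEQUATE_COVERAGE_ANY_CLONE` |
| Fisher strand FS > 10 | 10 (phred) | `HIGH_FS` |
| quality by depth QD < 10 | 10 | `LOW_QD` |
| abs(ReadPosRankSum) > 2 | 2 | `BAD_READ_POS` |
| homozygous call with > 2 opposite-allele reads | 2 reads | `DISCORDANT_HOM` |

Three decisions here were genuinely open:

- **Coverage is per clone.** The quoted thresholds mention both a coverage
  cut and an "adequately covered in every clone" exclusion with a single
  number; one per-clone rule realises both readings, and the count is
  reported under both reason codes for traceability.
- **ReadPosRankSum is two-sided by default.** A signed one-sided cut (`> 2`)
  discards only alternate alleles clustered at one read end, which is
  almost certainly a typographical artefact of the source material; the
  symmetric `|x| > 2` is the default and `rprs_two_sided = FALSE` restores
  the literal rule. Likewise the *initial* (pre-recalibration) preset's
  rank-sum band is taken as outside `[-2, 2.5]`; the printed "`<2 and
  >2.5`" would discard essentially every site.
- **Absent annotations pass.** Callers omit rank-sum statistics at sites
  without heterozygous carriers; failing on absence would discard the
  entire homozygous-alternate varietal class.

The earlier hard-filter preset (`preset = "initial_hard_filter"`: QUAL <
100, depth outside 0.5–3 times the 30-fold mean, SB > 0, FS < 1,
ReadPosRankSum outside [-2, 2.5], AF < 0.2) is wired and individually
testable but not recommended; it exists to document the recalibration
starting point.

## Concordance partition

Genotype equality means identical unordered allele pairs, not merely equal
categories — two heterozygotes with different alternate alleles are
different genotypes. With three (generally *n*) called, biallelic
genotypes per site: all equal → varietal (all homozygous-reference → not a
variant); exactly one clone deviating from the genotype shared by all
others → clone-specific, attributed to that clone with *its* genotype as
the reported category (so a site where two clones share a variant and one
is reference contributes to the homozygous-reference clone-specific row);
anything else → excluded as discordant. MISSING and MULTI genotypes are a
precondition violation: such sites must have been removed by the cascade.

## Effect annotation

Each biallelic SNV is placed against every transcript of an overlapping
gene model: `UPSTREAM`/`DOWNSTREAM` within 5,000 nt of the transcription
start/end (strand-aware; the upstream window is the stated convention and
the downstream window mirrors it, matching the annotator default of the
era), `INTRON` with 2-bp `SPLICE_SITE_DONOR`/`SPLICE_SITE_ACCEPTOR`
windows (GT–AG convention; the wider 3–8 bp "splice region" is not
modelled), `UTR_5_PRIME`/`UTR_3_PRIME`, and codon-level calls on the
coding strand with the standard genetic code. A 5'UTR change creating a
new ATG additionally emits `START_GAINED`. A disrupted initiator codon is
`START_LOST` unless the alternate codon is in a configurable
alternative-start set (default empty), in which case it is
`NON_SYNONYMOUS_START`; a changed terminator that remains a stop is
`SYNONYMOUS_STOP`. Impact classes are a fixed function of category (HIGH
for start/stop/splice disruption, LOW for silent and start-related,
MODERATE for missense, MODIFIER for non-coding placements).

Validation is dual-route: `classify_effects()` uses codon-index
arithmetic, while `classify_effects_reference()` independently applies
the variant to the chromosome sequence, rebuilds the spliced CDS and UTRs
from both genomes, translates both with `Biostrings::translate()` and
diffs the products. The test suite and the acceptance script require 100%
category agreement over thousands of stratified random gene/SNV pairs on
both strands; strand symmetry is additionally property-tested by
reverse-complementing the genome.

## Chimera inference

Tissues are modelled as linear mixtures of the two meristem layers: a
tissue with L1 cell fraction $\alpha_t$ shows expected alternate-allele
fraction $f_t = \alpha_t\,x_1 + (1-\alpha_t)\,x_2$ where $x_i \in \{0,
0.5, 1\}$ is the layer's diploid dosage state. Defaults are $\alpha =
0.5$ for leaf and berry skin (both layers contribute) and $\alpha = 0$
for berry flesh (L2 only). The true layer proportions of mixed tissues
are unknown; any $\alpha \in (0,1)$ reproduces the qualitative
intermediate-fraction signature, and the weights are configurable and
echoed in output.

Inference is exhaustive least squares over the nine $(x_1, x_2)$ pairs.
A chimeric solution ($x_1 \neq x_2$) is accepted only when it improves the
squared error of the best concordant solution by at least the decision
margin $\tau$ (default 0.01, well below the 0.125 separation the default
weights induce between a true chimera and its best concordant
competitor, and well above the ~0.003 noise floor at the 0.03 assay
noise level); ties therefore resolve conservatively to non-chimeric.
States 0 and 1 always carry an explicit "hom/hemizygous indistinguishable"
flag — allelic fractions cannot measure copy number, and a hemizygous
deletion would look identical. At least two distinct tissue weights are
required; otherwise the system is unidentifiable and the function refuses
to answer.

## Panel classification and marker subsets

Genotype classes are equivalence classes of exact profile equality.
Composite chimeric tokens (`"CC~CT"`, read "L2 homozygous C over L1
heterozygous C/T") are first-class states: equality is token equality,
because chimeric states are precisely what distinguishes one published
genotype class. Rows containing MISSING tokens are excluded and reported
rather than imputed. Labels follow first appearance; a canonical mode
(descending member count, ties by profile order) gives reproducible
reports. The minimal discriminating subset search is exhaustive by
increasing size up to 20 markers (at 10 markers the worst case is
$2^{10}$ subset checks), returns every witness of the minimal size, and a
greedy forward selection is also reported for wider panels.

## Distances, trees, networks

The allele-sharing distance treats each locus as a diploid allele
multiset: $D = 1 - \frac{1}{L}\sum_\ell |p_\ell \cap q_\ell|/2$. Chimeric
tokens contribute the union of their layer alleles as a heterozygote. $D$
is a bounded symmetric premetric; the triangle inequality is not claimed.

UPGMA is implemented in the package because two details are contractual:
node height is exactly half the merge distance (ultrametricity is
asserted in tests), and ties in the minimum distance break
deterministically toward the lexicographically smallest label pair, so
degenerate (all-equal) matrices resolve reproducibly. On tie-free random
matrices the topology is cross-checked against an independent
average-linkage implementation. Bootstrap supports resample loci with
replacement (1,000 replicates by default), rebuild distance and tree, and
count exact clade recovery; a cherry supported by a single locus out of
ten is recovered with probability $1 - 0.9^{10} \approx 65.1\%$, which
the suite verifies analytically. Neighbour joining (`ape::nj`) is offered
as an alternative because the source material is ambiguous about which
was drawn; UPGMA is the stated procedure.

The median-joining network starts from the relaxed minimum spanning
network (every co-minimal connection kept, Kruskal by weight class) under
Hamming distance on tokens, then repeatedly adds quasi-median (majority
consensus) profiles of mutually connected triples when they strictly
reduce the total spanning cost, and finally prunes inferred nodes that no
longer pay for themselves. At loci where all three parents disagree the
quasi-median branches into one candidate per state (capped at two such
loci per triple). With `epsilon = 0` the network provably contains all
observed profiles and embeds a minimum spanning tree, both asserted in
tests. Inferred nodes carry frequency 0; observed nodes carry class sizes.

# The synthetic-data module

The generators are first-class, tested code and define the validation
conditions:

- **Cohort** (`generate_cohort`): a miniature genome (2 chromosomes of
  250 kb, GC 0.35, 20 multi-exon genes per chromosome with planted ATG/TAA
  codons, ~10% repeat-masked) and `n_sites` planted variants whose class
  proportions default to the published three-clone table —
  varietal 636,323 : clone-specific 12,886/7,914/8,070 : discordant 368,
  with the published genotype mixes inside each class (varietal
  homozygous-alternate : heterozygous = 524,899 : 111,424). Counts are
  apportioned by largest remainder so they sum exactly. Depths are
  negative binomial (mean 30, matching the stated ~30-fold filtered
  coverage; size 10), left-truncated at the coverage floor for
  intended-PASS sites; heterozygous allele depths are binomial at 0.5,
  homozygous calls carry 0–2 opposite reads. Annotations are drawn inside
  the passing bands, and ReadPosRankSum is emitted only at sites with a
  heterozygous carrier. `fail_rates` plants extra records that each
  violate exactly one named rule, giving the cascade an exact truth table.
- **Panel** (`generate_panel`): 98 accessions over 10 markers in seven
  classes A–G with counts 1/31/2/31/2/21/10. Only A = 1, B = 31, C = 2,
  D = 31, E = 2 are published constraints; the F/G split 21/10 is a
  generator default, and two marker names are synthetic placeholders. The
  profile matrix is a labelled reconstruction encoding the published
  constraints (two markers private to A, three chimeric states private to
  E, class C separable only through its two markers) and is constructed so
  the minimal discriminating subset has size exactly 6 — four forced
  markers, one of A's two, one of E's three.
- **Chimera assays** (`generate_chimera_assays`): per locus and tissue,
  the mixing-model expectation plus Gaussian noise (default sd 0.03,
  the level at which the recovery criterion is specified), truncated to
  [0, 1].

All generators seed the global RNG once per call; identical config and
seed give byte-identical output files.

**What the simulations do not emulate:** alignment and mapping bias,
strand artefacts behind the FS/SB annotations (values are drawn, not
caused), linkage between neighbouring sites, INDELs and structural
variants, multi-transcript genes, and real repeat families. Passing tests
therefore demonstrate that the *rules and estimators* are implemented
correctly and are mutually consistent — not that the thresholds are
optimal for any particular sequencing run.

# Problem sizes and numerical choices

The test suite validates at desk scale: 50,000-site cohorts for
filter/partition truth recovery, over 2,000 stratified gene/SNV pairs for
the dual-route effect check, 450 loci (9 state pairs × 50) for chimera
recovery, 1,000 bootstrap replicates. Tie tolerance in UPGMA is 1e-12 on
distances; JSON reports keep full precision while text reports round
percentages to one decimal for display.

# Known limitations

- Hemizygosity is undetectable by design; chimera states 0 and 1 are
  reported with an explicit ambiguity flag.
- The genotype-concordance partition assumes the sample set is exactly
  the clones of one cultivar; population structure is out of scope.
- The effect annotator handles SNVs only (no INDELs, no multi-nucleotide
  substitutions) and a single genetic code.
- The median-joining implementation targets panels of ~15 loci and a
  handful of classes; it is not tuned for hundreds of haplotypes.
- Published genome-scale counts that depend on the real reference
  annotation (gene-set sizes and the like) are outside what desk-scale
  simulation can reproduce; the package checks those only where the
  published table itself is the input.
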