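---
title: "Methods: simulating and analysing a reconstituted Brassica napus gene pool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a reconstituted Brassica napus gene pool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rsgenepool` models the computational side of a germplasm-innovation design
in which the genome of the young allotetraploid oilseed crop *Brassica
napus* (A^n^A^n^C^n^C^n^) is "reconstituted" by introgressing subgenomic
variation from *B. rapa* (A^r^A^r^) and *B. carinata* (B^c^B^c^C^c^C^c^),
followed by several rounds of mass recurrent selection mediated by dominant
genic male sterility (DGMS). Because no deposited genotypes exist for such
material, the package couples every analysis stage to a forward simulator
with known ancestry truth, so each procedure can be tested against the
quantity it is supposed to recover.

## The breeding model

**Genome.** The diploidized genome carries two homologues for each of the 10
A and 9 C chromosomes. B-genome material from *B. carinata* is modelled as
hemizygous presence/absence segments on the 8 B chromosomes: the study
material is essentially 2n = 38 AACC with occasional small B introgressions,
and full hexaploid meiosis is outside the model's scope. Hemizygous
segments have no pairing partner, so they do not recombine and each B
chromosome's content transmits to half of the gametes.

**Recombination.** Crossovers per chromosome are Poisson with mean equal to
the chromosome's map length in Morgans, positions uniform on the physical
map, no interference. This is the simplest defensible meiosis model; the
breeding design itself gives no information that would justify an
interference model. Map lengths default to roughly one Morgan per
chromosome, the order observed in *Brassica* linkage maps.

**Sterility system.** A single dominant locus controls male sterility:
Msms plants are pollen-sterile and serve only as seed parents; fertile
plants are msms. Because sterile x sterile matings are impossible
(sterile plants set no pollen) and sterile plants cannot self, every mating
is Msms x msms and progeny segregate 1:1 sterile:fertile. The simulator
enforces this structurally; `sim_dgms_progeny()` exposes the segregation
model in isolation.

**Selection.** Mass selection acts on a weighted index over one or more
additive traits. Each trait has QTL sampled among the marker loci,
per-allele effects drawn from a normal distribution, an intercept that
keeps trait values on a positive scale (so relative gains are well
defined, as for oil or glucosinolate content), and an environmental
variance derived from the base population's genetic variance and the
trait's narrow-sense heritability. The study describes multi-trait visual
plus indoor selection without a formula, so a configurable linear index is
used and recorded as an assumption. Truncation selection retains the
configured fraction of sterile and of fertile candidates separately each
round.

**Scale.** Defaults are desk-scale while preserving the design's structure:
20 DGMS founder lines, 20 inbred lines per polymorphic subpopulation
(Poly-A^r^: A subgenome polymorphic, C mostly C^n^; Poly-C^c^: the
converse), 200 plants per round, five rounds, a few hundred marker loci.
The original population sizes were deliberately increased over rounds and
are not published, so the per-round size is a single configurable number.
Tests and the demo use smaller sizes again (60-120 plants, 100-400
markers, 2-5 rounds) purely as the package's own choice of problem size.

**Founder allele pools.** Each marker locus carries a configurable number
of alleles shared among the taxa whose genomes include that locus (A:
*B. rapa* and *B. napus*; C: *B. carinata* and *B. napus*; B: *B. carinata*
only), with a configurable proportion of taxon-private alleles. Private
alleles are the substrate of provenance analysis; a small novel-allele rate
adds mutant alleles absent from all founders during meiosis. Every carrier
taxon is guaranteed at least one allele per locus, which slightly perturbs
the private-allele expectation but keeps frequency profiles well defined.

## What the simulator does and does not emulate

The generator reproduces the features the downstream procedures rely on:
taxon-private alleles at multi-allelic loci, mosaic A+C genomes with sparse
hemizygous B segments, 1:1 DGMS segregation, additive trait response,
SSR-style multi-locus amplification (one assay can interrogate several
genome-specific loci) and missing calls. It does not emulate cytogenetic
events (aneuploidy, chromosome loss), epigenetic change, transposon
activation, genotyping error beyond missingness, linkage disequilibrium
structure inherited from real pedigrees, or cross-amplification of one
taxon's locus in a genome that lacks it. Passing recovery tests therefore
demonstrates the correctness of the procedures under their stated
assumptions, not their robustness to every artefact of real SSR/GBS data.

## Provenance rules

A marker's amplified loci are assigned jointly from (a) which reference
taxa its alleles appear in and (b) the genome(s) its primer aligns to:
alleles confined to *B. napus*/*B. carinata* with a C alignment define a C
locus; alleles confined to *B. napus*/*B. rapa* with an A alignment define
an A locus; a split into a carinata-involved and a rapa-involved group
with A and C alignments defines an A locus plus a C locus; presence in all
three taxa with A and B alignments defines an A/B locus pair. Implementation
decisions where the published rules are silent:

* *Presence threshold.* An allele counts as present in a taxon if observed
  in at least one reference sample (`min_count` parameter for stricter
  settings). New-type (gene-pool) samples never contribute to reference
  presence.
* *Consistency.* Rapa presence without an A alignment, or carinata
  presence without a B/C alignment, is flagged `conflict`, never silently
  assigned.
* *Split assays.* Under the A+C split rule, alleles seen only in
  *B. napus* cannot be attributed to either amplified locus without
  fragment-size information, which the data model does not carry; they are
  left unplaced and classified `shared` (non-specific). This is
  conservative: it can miss an A^n^/C^n^-specific call but cannot create a
  false species-specific one.
* *Multi-hit alignments.* Two hits on different chromosomes of one genome
  are resolved by the genetic-map chromosome when provided, otherwise the
  marker is `unassigned` with a reason.
* *Alleles seen in no reference taxon* (novel material only): the locus
  falls back on the alignment if it is single-genome, so novel alleles can
  still be reported at it.

Allele origin then reads off the presence pattern (rapa-only at an A locus
= A^r^-specific, etc.); B-locus alleles are B^c^-specific; alleles in two
or more reference taxa are shared; alleles absent from all references are
novel. Locus identifiers are scoped per assay, so counts of "loci with
specific introgression" tally assays' loci, not genome labels.

## Diversity statistics

Gene diversity is the plain plug-in estimator $D = 1 - \sum_i p_i^2$
(the common PowerMarker-style default); the small-sample correction
$2n/(2n-1)$ is available as an option. Nei's (1972) standard distance
$D = -\ln(J_{xy} / \sqrt{J_x J_y})$, with identities summed over
co-defined loci, is the default; the 1983 D~A~ distance is switchable
because distance-software defaults differ. Degenerate inputs are handled
explicitly: zero shared identity is capped at a configurable maximum
(default 10) with a warning, and accession pairs with no co-defined locus
at all (taxa whose genomes share no amplifying marker) receive the same
cap with a message rather than an error, so distance matrices stay total.

Accession-level clustering treats each accession as a population of one
diploid sample (frequencies in {0, 0.5, 1}) — the variant actually used for
individual-level trees is rarely documented, and this choice is recorded in
the outputs. Neighbor joining is implemented in-package with a
deterministic tie-break (the joined pair with the lexicographically
smallest sorted label pair) so runs are reproducible; additive matrices
are recovered exactly, which the test suite checks against an independent
tree library. For partitioned statistics, A/B-assigned loci count as
A-genome markers.

## Introgression calling

GBS-style matrices from multiple reference genomes are harmonized through
a precomputed match table (the original marker-to-marker BLAST criteria
are not published, so the package consumes the table rather than
recomputing it); matched alternative-reference markers collapse onto the
primary coordinates, unmatched ones are kept as additional species-specific
markers, and one-to-many matches are dropped with a message. A B-genome
marker is flagged *B. carinata*-specific when every traditional *B. napus*
panel sample is missing at it. The missing-rate filter is strict
("less than 50%"): a marker missing in exactly half the samples is
removed.

Difference calls compare unordered allele sets against the recurrent
parent; for homozygous DH lines this reduces to allele inequality, and a
heterozygous call differing from the parent's also counts as differing so
the rule stays total. Markers at which the parent is missing are missing
for every line. The per-line fraction is differs/(differs+same); the
population union counts a marker once regardless of how many lines differ,
the only reading under which a union near 100% can coexist with a mean
per-line fraction near 50%.

Segments are marker-supported spans: consecutive supporting markers (and,
optionally, up to `max_gap_markers` interruptions) merge, the segment runs
from the first to the last supporting marker, and its reported length is
`end - start`, the distance between the outermost supporting markers — the
convention under which a span whose ends are printed coordinates
reproduces the printed kb figure. Coordinates are 1-based inclusive
internally; BED export converts to 0-based half-open. Flagged B markers
support segments through the line's own amplified call, because the parent
is structurally missing there.

## Trait gains

Genetic gain between rounds is the relative change in the mean,
$\Delta G = (\mu_n - \mu_i)/\mu_i$, stored as a signed fraction and
rendered as percent on request; a zero baseline is an explicit error. Gain
matrices over all generation pairs satisfy
$\Delta G(i \to n) = -\Delta G(n \to i)/(1 + \Delta G(n \to i))$, which the
tests verify. Generation comparisons default to one-way ANOVA — the
original report names no test — with a Kruskal-Wallis alternative, and the
ANOVA falls back to ranks when within-generation variance is degenerate.
The library reports p-values and makes no significance decision.

Two documented inconsistencies in the source material are deliberately
not adjudicated: the seed-number improvement between the third and fifth
round is reported as both 3.3% and 5.3% in adjacent sentences, and the
glucosinolate decline is quoted once in percent and once in µmol/g. Trait
records therefore carry their unit explicitly.

## Numerical and reproducibility choices

All randomness flows through a single seeded generator per entry point;
package calls never disturb the caller's RNG state, and identical seeds
give byte-identical outputs. Frequency-sum validation uses a 1e-6
tolerance; NJ tie detection uses 1e-12. Writers refuse to overwrite
without an explicit flag, every run can echo its resolved configuration
(seeds included) beside its outputs, and all output formats are plain text.
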