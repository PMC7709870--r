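---
title: "Analyzing UV mutagenesis: spectra, strand asymmetry, and damage maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing UV mutagenesis: spectra, strand asymmetry, and damage maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvspectra)
```

## Scope and model

`uvspectra` analyzes somatic mutation catalogs from UV-mutagenized cells
(yeast isolates sequenced after repeated irradiation, or UV-associated
tumors) to characterize which mutation classes behave like the products of
bulky, repairable DNA lesions. The chain is: catalog hygiene and event
partitioning; pyrimidine-strand classification; spectra; transcriptional
asymmetry with sequence-composition normalization; damage-map tallies from
endonuclease sequencing reads; and cohort-level enrichment statistics. A
forward simulator of the lesion → repair → bypass process generates every
input the chain consumes, with complete truth bookkeeping.

The mechanistic picture behind both the statistics and the simulator:

1. UV forms lesions at specific dinucleotides — CPDs and 6-4 photoproducts
   at the four dipyrimidines, plus atypical photoproducts at TA and AC
   dinucleotides.
2. Nucleotide excision repair removes lesions before they can mutate.
   Transcription-coupled repair acts only on the transcribed strand (TS)
   of genes, so in repair-proficient cells a lesion on the TS survives
   with lower probability than one on the non-transcribed strand (NTS).
   Loss of global-genomic repair raises survival on both strands (TS still
   lower); loss of transcription-coupled repair equalizes them.
3. Translesion synthesis across a surviving lesion fixes a mutation at one
   or both lesion bases — a single substitution or a tandem double.

A mutation class caused by such a lesion therefore shows an excess of
events on the strand where its lesion survives longer, once strand
sequence composition is controlled for.

## Catalog conventions

**Support and uniqueness filters.** Calls are kept when supported by
strictly more than 45% of covering reads (`filter_support`, threshold
configurable), which selects fully clonal heterozygous variants in diploid
isolates. Variants shared by two or more isolates predate the mutagenesis
or are artifacts and are removed from all isolates
(`filter_sample_unique`). Mitochondrial records are dropped by a
configurable chromosome deny-list.

**Partitioning.** Within one isolate and chromosome, maximal runs of
adjacent substituted positions merge: runs of two become tandem events,
runs of three triples (`partition_events`). Phase is assumed rather than
read-checked — adjacent same-isolate calls at clonal support are treated
as one chromosomal event. Pre-merged rows with length-2 or length-3
alleles route directly to the corresponding category. Runs longer than
three go to a `complex` bin so that counts are conserved exactly; with
realistic mutation densities they essentially never occur.

**Pyrimidine-strand classification.** Every single substitution is
reported on the strand carrying the mutated pyrimidine; purine-reference
records are reverse-complemented, context included (`classify_snv`). The
dipyrimidine category asks where the mutated base sits inside a
dipyrimidine: if its 5' neighbor (on the pyrimidine strand) is a
pyrimidine, the base is the 3' member of a dimer (`THREE_PRIME`);
otherwise if its 3' neighbor is a pyrimidine it is the 5' member
(`FIVE_PRIME`); otherwise `NONE`. When both neighbors are pyrimidines the
category is ambiguous; the package defaults to `THREE_PRIME` — UV lesions
mutagenize the 3' position of a dimer far more often, and the observed
class inventory is dominated by 3'-position events — with
`dipyr_tie = "five_prime"` available. A non-exclusive "both" accounting
was rejected because it breaks the exact agreement between dipyrimidine
marginals and spectrum marginals that the tests assert.

**Tandem canonicalization.** A tandem substitution and its reverse
complement are one class (AC>TT ≡ GT>AA). The canonical label takes the
orientation with the lexicographically smaller reference dinucleotide
(ties: smaller alternate; full palindromic ties keep the plus
orientation), and the chosen orientation is recorded — it later determines
which genomic strand carries the event for asymmetry analysis.

## Transcriptional asymmetry

For each class, events inside genes are assigned NTS or TS by comparing
the pyrimidine-bearing genomic strand (for tandems: the strand carrying
the canonical reference dinucleotide) with the gene's mRNA-identical
strand. Regions transcribed on both strands are excluded from both event
assignment and frequency counting, as are deny-listed genes (for yeast,
the repetitive rDNA- and CUP1-overlapping genes, which attract artifactual
calls). Intergenic events are counted and reported but not tested.

Counts are normalized by `f_NTS` and `f_TS`, the number of occurrences of
the class's sequence context on each strand over the analyzed transcribed
regions, and the ratio `(n_NTS/f_NTS)/(n_TS/f_TS)` is tested by a 1-df
chi-square goodness-of-fit. The expected split is proportional to the
strand frequencies (`null = "freq"`): since the ratio is
frequency-normalized, the null hypothesis must be too. An even split
(`null = "even"`) is available for comparison; with the near-balanced
compositions of large gene sets the two agree closely. No continuity
correction is applied. Classes below the count threshold (defaults: 30 for
single-nucleotide classes, 19 for yeast tandems, 1000 for human tandems)
are reported untested, and Bonferroni correction uses the number of
classes actually tested in the run, not the full class universe.
Palindromic-reference tandem classes (e.g. TA>NN) have no resolvable
strand orientation and are flagged untested.

The pooled (genome-wide) ratio treats all genic events as one meta-class,
normalizing by the summed frequencies of the distinct contexts involved,
so it is a mutation-density ratio: events per available site on each
strand.

Expression stratification ranks genes by expression (stable tie-break on
gene id), splits them into four equal bins, and reruns the full analysis
on the top and bottom bins with bin-specific frequency tables.

## Damage maps

Damage-endonuclease sequencing cleaves immediately 5' of a lesion and
ligates the sequencing adaptor to the cut, so the sequenced strand is
synthesized from the damaged template. Under the default convention the
lesion dinucleotide occupies the two nucleotides immediately upstream of
the read's 5' terminus on the strand opposite the read (`lesion_site`,
`offset = -2`, `lesion_strand_side = "opposite"`). Both parameters are
configurable because library chemistries differ in the cut-to-lesion
offset; applying the pipeline to an external dataset requires validating
the offset against that protocol. Reads whose implied site runs off the
contig are dropped and counted. Dinucleotides are read 5'→3' on the lesion
strand, and treated/control comparison works on fractions of total with a
rank over a configurable dinucleotide subset.

## Simulator design

Lesions, not mutations, are the primitive: one simulated truth set drives
the mutation pipeline and the damage-map pipeline, which is what makes
exact round-trip tests possible. Repair is collapsed to a single
per-strand survival probability rather than kinetic repair curves — enough
to generate the asymmetry structure the statistics consume, and
analytically invertible, so recovery tests can check the estimate against
the planted odds. Doses are independent rounds with no clonal lineage, so
isolates share no mutations, matching the single-isolate-uniqueness
filter. Positions transcribed on both strands use the TS survival
probability; intergenic lesions use the NTS value (no transcription-coupled
repair applies).

Default parameters and why:

* `genome_length` 200 kb, `gc_fraction` 0.38 — a desk-scale genome at the
  yeast G+C composition.
* `repair_preset`: WT `s_NTS = 0.5, s_TS = 0.25`; rad16 (global repair
  lost) `0.95 / 0.15`; rad26 (transcription-coupled repair lost)
  `0.5 / 0.5`. These give pooled asymmetry folds near 2, 6, and 1 —
  the qualitative ordering repair genetics dictates, with the WT fold in
  the 2–3× range seen for canonical UV classes.
* Lesion classes: CPD formation is uniform over dipyrimidines; 6-4PP
  formation follows the endonuclease cutting preference TC > TT > CC > CT;
  the TA photoproduct forms at TA and mutates the 3' adenine to thymine
  (read as T>A at NTA on the opposite strand); the AC photoproduct yields
  AC>TT and AC>CT tandems and A>T singles, with formation set so AC>TT
  tandems run about twice the CC>TT level. Outcome weights put C>T and T>C
  at the top of the single-nucleotide spectrum. These are tunables chosen
  to echo the observed rank orders, not claims about photochemistry.
* Expression is log-normal; read support is Beta(40, 30), scattering
  around the heterozygous 0.5 with essentially no mass below the 0.45
  filter.

What the simulator does **not** emulate: chromatin and replication-timing
covariates, clonal phylogenies, sequencing error, alignment artifacts, and
kinetic repair. Passing tests therefore demonstrate that the statistics
recover planted mechanistic structure from idealized catalogs; they do not
certify behavior on real data with those additional structures.

## Numerical and policy choices

* Strand frequencies use exact integer tallies; contexts containing N and
  contig-edge windows are excluded and counted.
* The chi-square test is undefined at zero total count (`tested = FALSE`);
  a zero TS count with nonzero frequencies yields an `Inf` ratio sentinel.
* Holm-Sidak step-down is computed as `1 - (1 - p_(i))^(m - i + 1)` with a
  running maximum; the tests check it against a brute-force oracle.
* The Mann-Whitney comparison uses the exact distribution for tie-free
  small samples and mid-rank normal approximation under ties.
* Reporter dilutions are stored as the multiplicative factor restoring a
  plate count to the undiluted suspension (a 10⁻⁵ plating is
  `dil = 1e5`), so `(n_sel · dil_sel) / (n_perm · dil_perm)`; plate-count
  equations in the literature are typographically ambiguous about
  inversion, so the convention is fixed here and shown with a worked
  example in the function documentation.
* Odds ratios apply no continuity correction by default (the ≥10
  occurrence filter makes zero cells rare); `continuity = 0.5` is
  available. Cohort sizes can be supplied explicitly for carrier-only
  tables.

## Problem sizes

The shipped tests and the acceptance script run simulations of 30–150 kb
genomes with 5–8 isolates and 10–15 doses, giving 500–3000 events per
scenario — enough that recovery intervals are a few percent wide while the
whole suite stays fast on one CPU. The same code scales linearly to
genome-sized catalogs.

## Known limitations

* Tandem phase is assumed from adjacency, not read-backed.
* The damage-map offset convention must be validated per protocol before
  applying to external sequencing data.
* Palindromic-reference tandem classes cannot be strand-assigned.
* The intergenic flank comparison uses fixed-width flanks and is reported
  descriptively, without its own test machinery.
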