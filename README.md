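# uvspectra

Analysis of UV-induced mutation spectra, transcriptional strand asymmetry,
and photoproduct damage maps.

## The problem

Ultraviolet light damages DNA mostly at dipyrimidine sequences (TT, TC,
CT, CC), forming cyclobutane pyrimidine dimers (CPDs) and 6-4
photoproducts. Error-prone bypass of these lesions leaves the classic UV
signature — C>T and CC>TT changes at dipyrimidines — but mutation catalogs
from UV-mutagenized yeast and from skin cancers also contain abundant
substitutions that do not fit it: T>C, T>A at non-dipyrimidine contexts,
and AC>TT tandem changes. `uvspectra` implements the analysis chain used to
characterize such catalogs and to decide whether a mutation class behaves
like the product of a bulky, repairable UV lesion:

* **Mutation catalog** — read TSV/VCF call tables; filter by read-support
  fraction (strictly >45% by default) and single-isolate uniqueness; merge
  adjacent substitutions into tandem/triple events; normalize every single
  substitution to the pyrimidine-bearing strand with its trinucleotide
  context and dipyrimidine category; canonicalize tandem labels so AC>TT
  and GT>AA are one class.
* **Spectra** — 96-class trinucleotide spectra, dipyrimidine tables,
  NTA-context summaries, tandem spectra, flanking-base frequency matrices,
  and per-isolate strain comparisons (Welch t-tests with Holm-Sidak
  step-down correction).
* **Transcriptional asymmetry** — the diagnostic statistic. For a mutation
  class with `n_NTS`, `n_TS` events on the non-transcribed and transcribed
  strands of genes, and strand context frequencies `f_NTS`, `f_TS` over the
  same gene set,

  ```
  ratio = (n_NTS / f_NTS) / (n_TS / f_TS)
  ```

  with a 1-df chi-square test against the frequency-proportional expected
  split, Bonferroni correction over tested classes, per-class count
  thresholds (30 for single classes; 19 yeast / 1000 human for tandems),
  deny-list gene exclusions, exclusion of regions transcribed on both
  strands, and optional expression-quartile stratification. A ratio above 1
  marks preferential removal of lesions from the transcribed strand by
  transcription-coupled repair — the fingerprint of a bulky lesion.
* **Damage map** — convert damage-endonuclease sequencing (UVDE-seq) read
  positions to lesion dinucleotide sites (the lesion sits immediately
  upstream of the read 5' terminus on the opposite strand, configurable),
  tally the 16 dinucleotides, and compare treated versus no-UV control.
* **Enrichment** — reporter mutation frequencies from plate counts,
  reversion frequencies with the zero-count maximum-estimate convention,
  exact Mann-Whitney comparisons, cutaneous-versus-acral per-tumor
  frequency ratios, and odds ratios for recurrent driver mutations in
  skin versus non-skin cancer sample tables (≥10 occurrences).
* **Synthetic data** — a forward simulator of the lesion → repair → bypass
  process. Lesions form at target dinucleotides, survive repair with
  per-strand probabilities (s_TS < s_NTS in repair-proficient cells),
  and draw bypass outcomes; one truth table drives both the mutation and
  the damage-map pipelines, so every analysis stage is testable by
  parameter recovery.

## Worked example

```r
library(uvspectra)

cfg <- sim_config(seed = 7, genome_length = 100000, n_genes = 60,
                  n_isolates = 6, n_doses = 10, genotype = "WT")
gg  <- generate_genome(cfg)
sim <- simulate_mutation_tables(cfg, gg$genome, gg$genes)

calls <- filter_chroms(filter_sample_unique(filter_support(sim$calls)))
part  <- partition_events(calls)
part
#> Event partition of 607 mutation records
#>   singles: 533  tandems: 37  triples: 0  indels: 0  complex: 0

cls <- classify_snv(part$singles, gg$genome)
class_fractions(build_spectrum(cls))[3:5, ]
#>   pyr_class count  fraction
#> 3       C>T   189 0.3545966
#> 4       T>A    85 0.1594747
#> 5       T>C   259 0.4859287

run_asymmetry(cls, gg$genome, gg$genes, mode = "single", min_count = 10)
#> Transcriptional asymmetry (single mode, min count 10)
#>   genic events: 349  intergenic: 184  excluded: 0
#>   tested classes: 16
#>   pooled NTS/TS ratio: 1.549 (chi2 = 16.20, p = 5.71e-05)
```

The spectrum is dominated by T>C and C>T with T>A third, T>A events sit
almost entirely in NTA contexts, and the pooled mutation density is higher
on the non-transcribed strand — the three hallmarks the pipeline is built
to quantify. The asymmetry ratio reflects the simulator's planted 2:1
strand survival odds diluted by TA-photoproduct mutations, whose causative
lesion lies on the strand opposite the mutated pyrimidine.

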