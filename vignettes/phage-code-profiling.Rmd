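---
title: "Linking phages to CPR hosts and profiling their genetic code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking phages to CPR hosts and profiling their genetic code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecode)
```

## The problem

Saccharibacteria, Gracilibacteria and Absconditabacteria (collectively
"SGA") are reduced-genome lineages of the bacterial Candidate Phyla
Radiation. Gracilibacteria and Absconditabacteria translate with the
alternative genetic code 25, in which the canonical stop codon TGA encodes
glycine; Saccharibacteria use the standard bacterial code 11. Little is
known about the phages that infect these lineages, and an immediate
question about any candidate phage is *which code its genome is written
in*: a phage dense with in-frame TGA codons can only be decoded by a
code-25 host, while a phage that avoids in-frame TGA and terminates its
genes with TAA/TAG (or backs a TGA stop up with a nearby TAA/TAG) is
translatable under either code.

phagecode implements the two analyses this question requires, end to end,
on plain FASTA/TSV inputs:

1. **Host linking by CRISPR spacer matching.** CRISPR arrays store
   spacer copies of past phage encounters, so a spacer-protospacer match
   ties a phage to the host genome carrying the array. The package
   detects arrays, builds a dereplicated spacer database, matches it
   against candidate phages under strict thresholds, and flags phages
   co-targeted by both SGA and non-SGA bacteria.
2. **Genetic-code profiling.** Each phage is ORF-called twice, under
   codes 11 and 25, and the difference in coding density between the two
   predictions (Δd, in percentage points) classifies it as clearly
   alternatively coded (`code25`) or compatible with the standard code
   (`code11_compatible`).

A third, supporting module classifies each host genome's CRISPR-Cas
system subtype from its cas gene content and computes the genome fraction
devoted to defense loci.

## The ORF model and its assumptions

`find_orfs()` is a deterministic maximal-ORF caller: in each of the six
frame/strand combinations an ORF runs from the first start codon
(ATG/GTG/TTG) after the previous stop codon to the next in-frame stop,
inclusive; ORFs running into a contig edge are kept and marked as lacking
a terminal stop. Codons containing ambiguity characters are never a
start, never a stop, and break any ORF that would span them — a single
rule that keeps results deterministic on assemblies with N runs.

This deliberately replaces a trained gene finder (GC frame statistics,
RBS models, start-site scoring) with exact, brute-force-checkable
semantics. The dual-code signal the package measures depends on the
*stop-codon landscape* — removing TGA from the stop set can only extend
or merge ORFs — not on start-site precision, so a maximal-ORF model is
sufficient and has the advantage that an independent enumeration oracle
can verify every call, which the test suite does.

Two consequences of the model are worth stating:

* **Monotonicity.** For every sequence, the code-25 density is at least
  the code-11 density, and every code-11 ORF nests inside exactly one
  code-25 ORF on the same strand and frame. Both are asserted as
  properties over thousands of random and generated sequences.
* **Density saturation at short ORF cutoffs.** With a 90 nt minimum ORF
  length, the union of maximal ORFs over six frames covers ≥95% of *any*
  dense sequence under either code — chance ORFs alone saturate the
  union, and Δd collapses to a few points regardless of the true code.
  Density profiling therefore uses a 100-codon (300 nt) floor, a
  conventional chance-ORF suppression threshold at which the two regimes
  separate by an order of magnitude (Δd ≈ 50–70 points for genomes
  written in code 25 with 30% TGA-glycine usage, versus ≈ 2–5 points for
  code-11 genomes). `find_orfs()` itself keeps the standard 90 nt
  default for gene-level outputs; `profile_code()` defaults to 300 nt.
  Both are configurable.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `min_orf_len` (`find_orfs`) | 90 | nt | minimum reported ORF, terminal stop included |
| `min_orf_len` (`profile_code`) | 300 | nt | long-ORF floor for density estimation (see above) |
| `size_floor` | 20000 | bp | sequences at or below this length are `not_evaluated` |
| `delta_threshold` | 10 | percentage points | Δd at or above which a sequence is called `code25` |
| `min_coverage` | 0.95 | fraction | minimum spacer coverage of a match |
| `max_mismatch` | 1 | count | maximum substitutions in a match |
| `k_seed` | 8 | nt | exact seed length for array detection |
| `min_spacers` | 3 | count | minimum spacers per reported array |
| `min_repeat_identity` | 0.90 | fraction | mean repeat-to-consensus identity |
| `max_spacer_identity` | 0.60 | fraction | spacer similarity above which evidence is `low` |
| `window` | 10 | codons | backup-stop scan range downstream of a terminus |

Δd is measured in *percentage points* of coding density, not relative
change: densities are themselves fractions near one, and an additive
scale keeps the 10-point call threshold interpretable across genome
sizes. The 20 kb size floor exists because density estimates on short
sequences are noisy enough to make the call unreliable; such sequences
are reported but left uncalled.

The matcher scans both strands and anchors partial-coverage windows at
the spacer ends (terminal truncation, as in short-read BLAST-style
alignments), not at interior deletions: at ≥95% coverage and ≤1
mismatch, gapped alignments of 20–40 nt spacers have no room to outscore
ungapped ones, so the package uses an exact ungapped Hamming model whose
every hit can be re-derived by enumeration. Overlapping candidate hits on
one strand are merged keeping minimal mismatches, then maximal matched
length, then the leftmost window. Spacers under 15 nt are refused
(matches would be spurious); under 20 nt a warning is raised.

## Array detection and the evidence proxy

`detect_arrays()` is a CRT-style seed-and-extend detector: an exact 8-mer
recurring at a period compatible with one repeat plus one spacer
(43–115 nt) seeds a candidate chain, which is extended column-wise across
all copies while columns stay unanimous; a single discordant column is
absorbed when followed by three unanimous ones, tolerating isolated point
mutations. Candidates must have at least four repeat copies of 23–55 nt,
spacers of 20–60 nt, and mean repeat identity ≥0.90 against the column
consensus. An array is `high` evidence when it additionally has at least
three spacers whose maximal pairwise identity is below 0.60 —
near-identical "spacers" indicate a tandem repeat, not a CRISPR locus.
These thresholds approximate the high-confidence tiers of dedicated
CRISPR finders; they are a declared proxy, not a reimplementation, and
all of them are configurable.

Spacer databases are dereplicated by exact full-length string identity.
Reverse complements are *not* collapsed: matching scans both strands
anyway, so orientation only affects database size, and collapsing would
discard the orientation bookkeeping that `shared_spacers()` reports.

## CRISPR-Cas subtyping and the defense budget

`classify_cas()` applies gene-content rules to the cas labels found in a
genome: cas9+csn2+cas1+cas2 → II-A; cas9+cas1+cas2 without csn2 → II-C1;
cpf1+cas1+cas4+cas2 → V-A; cas10+cas7+cas5+csm2 → III-A;
cas10+cas7+cas5+cmr5 → III-B. All satisfied rules are returned, because
genomes with multiple cas loci exist; a genome with no high-evidence
array is always `incomplete`. Labels are pooled per genome by default —
fragmented assemblies scatter one system across scaffolds — with a
per-scaffold mode available. `crispr_budget()` reports the union (not
the sum) of cas gene and array intervals as absolute bases and as a
genome fraction.

## What the generator emulates — and what it does not

`simulate_genome()` writes dense prokaryote-like sequence: genes of mean
900 nt (start codon, flat-usage sense codons, terminal stop from the
code's stop set) covering ~90% of the genome, separated by uniform-random
intergenic stretches. Under code 25, each glycine is spelled TGA with
probability `tga_gly_fraction` (default 0.3), which is what makes the
genome unreadable in code 11; with probability `backup_stop_prob`
(default 0.8) a TAA/TAG backup stop is planted within ten in-frame codons
downstream of a terminus, reproducing the backup-stop-rich termini of
dual-code-viable genomes. Arrays and labeled cas operons are spliced
between gene units, never inside genes. `simulate_phage_set()` plants
protospacer copies of scheduled spacers at non-genic positions with a
controlled number of substitutions. Everything is a pure function of the
seed.

Two generator details are deliberate design choices rather than
simplifications:

* **Repeat boundary guard.** Spacer bases immediately adjacent to the
  planted repeat copies are resampled so that no boundary column is
  unanimous across copies. Without this, flanking bases can agree across
  all copies by chance, and the true repeat boundary becomes
  mathematically unidentifiable for *any* consensus-extension detector —
  the planted decomposition would not be a well-defined ground truth.
* **Interior mismatch placement.** Injected protospacer mismatches go to
  positions inside every admissible matching window (end-anchored
  truncation can drop up to 5% of either spacer end), so the scheduled
  mismatch count is the effective Hamming distance at every coverage-
  compliant alignment and sensitivity/specificity expectations are exact.

The generator does not attempt realistic phage genome architecture (gene
order, module structure), codon usage bias (a usage-table hook exists in
the gene writer), GC skew, repeated elements other than CRISPR arrays, or
read-level artifacts. Passing tests on generated data therefore
demonstrate the correctness of the algorithms under the stated model, not
performance on real metagenome assemblies — in particular, real array
detection must cope with degenerate repeats and insertion/deletion
variation that the planted arrays exhibit only in attenuated form.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and 1-based inclusive in
  GFF3 output; minus-strand features report forward-strand coordinates.
* Prevalence percentages use half-up rounding to one decimal
  (16/44 → 36.4); R's default banker's rounding is not used.
* Array overlap resolution keeps the candidate with more repeats, then
  the longer span, then the leftmost; consensus ties at a column go to
  the alphabetically first base. All tie-breaks are deterministic.
* Empty inputs: an empty phage set yields empty hit/link tables but a
  complete array and prevalence report; a sequence without start codons
  has density 0; an all-N or too-short sequence yields no ORFs.
* The pipeline is single-threaded by contract; outputs are a pure
  function of (inputs, config, seed), and two identical runs produce
  byte-identical output trees (asserted in the test suite, manifest
  included).

## Problem sizes used for validation

The test suite and the acceptance script validate against: six 30 kb
host genomes and twelve 24 kb phages with nine scheduled protospacers
(the "small world"); a 50-phage cohort of 21 kb genomes (25 per code)
for classification accuracy; 1,000 random spacer/target pairs and 200
random 2 kb sequences for brute-force oracle equivalence; and 1,000
random sequences for the density monotonicity property. These sizes make
the full validation run in a few minutes on one core while keeping every
statistical check comfortably away from its decision boundaries (the
cohort's Δd values sit at ≈50–70 points against a 10-point threshold).

## Known limitations

* The ORF caller has no start-site model: reported gene starts are the
  first start codon of the segment, which overestimates gene length when
  an upstream in-frame start precedes the true one. Density and terminus
  analyses are insensitive to this; downstream protein work would not be.
* The evidence proxy is tuned to planted and textbook-like arrays;
  highly degenerate repeats (indels between copies) are out of reach of
  the ungapped column model.
* Spacer matching reports no E-values; significance rests on the length
  and threshold argument (a ≥26 nt match at ≤1 mismatch is effectively
  never spurious, and the false-positive property test confirms zero
  chance hits against 50 kb random targets).
* `run_pipeline()` assumes single-scaffold genomes when no
  scaffold-to-genome map is supplied.

## A worked example

```{r example, eval = FALSE}
world <- simulate_world(seed = 1)
run <- run_pipeline(pipeline_config(seed = 1),
                    genomes = world$genomes, phages = world$phages,
                    cas_annotations = world$cas_annotations,
                    host_map = world$host_map)
run
tidy(run)          # per-phage: density pair, call, hits, co-targeting
glance(run)        # one-row run summary
autoplot(run$profiles)   # the density-delta histogram
```
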