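---
title: "Detecting dietary plant miRNAs in plasma small RNA-seq: models and methods"
author: "xenomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dietary plant miRNAs in plasma small RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant microRNAs have repeatedly been reported in human plasma, presumably
taken up through diet, and in some cases shown to regulate host genes — the
cross-kingdom RNAi hypothesis. Detecting such exogenous miRNAs (xenomiRs) in
plasma small RNA-seq data is statistically delicate: the exogenous signal is
a sliver (on the order of 1% of trimmed reads) of a host-dominated read
pool, most exogenous species appear at a handful of copies in a minority of
samples, and the main failure modes are host sequences masquerading as plant
miRNAs and adapter fragments masquerading as either. `xenomir` implements
the full inference chain — detection, cross-kingdom seed transfer, duplex
target prediction, enrichment — as reusable, tested components, together
with a ground-truthed cohort simulator so every stage can be validated at
desk scale.

## The detection model

Reads are trimmed, quality-filtered, and assigned directly against catalogs
of mature miRNA sequences rather than whole genomes. This is a deliberate
fidelity trade-off: genome alignment followed by miRNA-locus quantification
requires multi-gigabase references and external aligners, while at desk
scale the catalog of matures (with precursors carried as annotation) is the
reference. Consequences of the choice are documented below under
limitations.

Assignment is conservative by construction (*host wins*): a read is called
exogenous only if it matches a plant mature within the mismatch tolerance
**and** matches nothing host-side — neither a host mature nor a host decoy
sequence. This mirrors the field's standard control, where candidate plant
miRNAs are required to have zero alignment hits against the host genome.
The decoy set plays the role of host background sequence; one decoy carries
the library adapter so that adapter-contaminated artifacts fall on the host
side of the decision. Independently, `adapter_contamination_check()` flags
any catalog record sharing a long (default 10 nt) exact substring with an
adapter or its reverse complement; flagged records are excluded from
reporting.

Matching uses an exact k-mer-seeded index verified by full Hamming
comparison. The configured seed length (default `k = 12`) is clamped at
lookup time to `floor(L / (m + 1))` for the shortest query length `L` and
mismatch tolerance `m`; by the pigeonhole principle this guarantees every
qualifying hit contains an exact seed, so index lookup is provably
equivalent to a brute-force scan (and is tested against one). Ties between
equally good hits resolve to the fewest mismatches, then the
lexicographically smallest id; a read counts once, for its single best
assignment, with no fractional multi-mapping. U and T are identical
everywhere, and reads are matched in sequenced orientation only, since
small RNA libraries are stranded.

A miRNA is called **present** in a sample when at least
`min_reads_presence` (default 1) reads are assigned to it — the one-read
rule is the field's detection convention for low-abundance xenomiRs, and it
is exactly why the host-exclusion side must be strict. Cohort summaries
report, per plant miRNA, the number of samples present, maximum and median
counts, and a relative-abundance quantile: the rank of its count within the
pooled host-miRNA counts of the same sample.

## Seed classes and cross-kingdom transfer

Mature positions are numbered 1-based from the 5' end; the seed is
positions 2–7 (6mer) or 2–8 (7mer-m8). Target-site strings are written
5'→3' on the mRNA as reverse complements of the seed; the A of the 7mer-A1
and 8mer classes is the target-site position-1 adenosine appended 3' of the
site string. For a mature with positions 2–7 `AGUUGG` this yields
`site6 = CCAACT` and `site7A1 = CCAACTA`.

Cross-kingdom transfer assumes miRNAs with identical seeds target
overlapping gene sets. Seed matching is exact Watson–Crick identity on site
strings — no G:U wobble, no mismatches — because identity is the only
relation the underlying hypothesis demonstrates; "similar" seeds without a
quantitative similarity model would be arbitrary. The minimal class
required is configurable (default 6mer) and each match is labeled with its
strongest class. Since the A1 adenosine is appended to every site string,
7mer-A1 identity coincides with 6mer identity and 8mer with 7mer-m8; the
hierarchy is reported explicitly. Curated targets of seed-matched host
miRNAs (a miRTarBase-style two-column table) are unioned per plant miRNA
with per-gene provenance retained.

## Duplex model and scoring

Candidate sites are anchored at exact occurrences of the 6mer site in each
annotated gene region (5'UTR, CDS, 3'UTR) and evaluated by an
intermolecular RNA:RNA duplex dynamic program over a window (default 30 nt)
extending upstream of the anchor, where the miRNA 3' region pairs.

The energy model is nearest-neighbor: antiparallel non-crossing pair sets,
stack free energies for adjacent pairs, an affine penalty
(`loop_open = 3.0` kcal/mol plus `loop_ext = 0.3` per unpaired nucleotide,
gaps capped at 30 nt) for interior loops and bulges, no intramolecular
structure, no pseudoknots, no dangling ends, fixed 37 °C. Watson–Crick
stack energies are the ten published nearest-neighbor parameters expanded
to all doublets by symmetry; stacks involving G:U wobbles use simplified
generic values (−1.2 kcal/mol with one wobble pair, −0.5 with two) — a
deliberate simplification, weaker than any Watson–Crick stack, chosen over
reproducing the full wobble table. The table ships as a versioned data file
(`extdata/nn_stacks_v1.tsv`) so the parameterization is inspectable and
replaceable. A lone pair and the empty structure both score zero, so the
minimum free energy is never positive. The dynamic program is
`O(m^2 n^2)`, exact over this structure space, and is tested for equality
against exhaustive enumeration of all valid pair sets on short sequences.

The complementarity score is a declared, deterministic function of the MFE
structure: 15 points per Watson–Crick pair at miRNA positions 2–8, 5 per
Watson–Crick pair elsewhere, 2 per G:U pair, −3 per loop/bulge event. The
weights are calibrated so that a perfect seed (7 × 15 = 105) plus
substantial 3' pairing (≥ 7 further pairs) clears 140, making the shipped
default thresholds — MFE ≤ −14 kcal/mol and score ≥ 140 — a stringent
joint filter in which a seed-only site always fails and a perfect-
complement site always passes. Both thresholds and the weights are
config-overridable. The score is an explicit stand-in for unpublished
scoring schemes of web-based target predictors, not a claim of equivalence
to any of them.

## Enrichment

Enrichment of predicted target sets uses the upper-tail hypergeometric
probability `P(X >= k)` for `k` query genes in a term of size `K`, query
size `n`, background `N`. The conservative EASE variant (upper tail at
`k − 1`, defined for `k > 0`) is available because annotation-portal
implementations differ and the choice is rarely documented; both modes are
first-class. The background defaults to all genes in the annotation map,
overridable. Terms with zero overlap are suppressed, matching how such
tables are conventionally reported, and Benjamini–Hochberg adjusted values
are computed across the tested terms alongside raw p-values.

## What the simulator emulates — and what it does not

The generator encodes the statistical regime the pipeline targets:

* a host-dominated pool with a background plant fraction of ~1% of reads
  (`xeno_fraction_mean = 0.01`), spread over non-spiked plant catalog
  entries;
* one ubiquitous high-copy exogenous miRNA, Poisson with mean 1000
  copies/sample — the "thousand-copy, present in every run" regime;
* sporadic exogenous miRNAs present in a minority of samples
  (Bernoulli prevalence) at 1–4 copies (uniform), the "fewer than four
  copies in a few dozen samples" regime;
* single-end 50-nt reads laid out as insert + 3' adapter + poly-A pad,
  with the TruSeq small RNA 3' adapter as default — read length and
  platform are declared defaults, not inferred from any dataset;
* independent per-base substitution errors on the insert (default 0.001),
  no indels;
* Phred+33 qualities with a Q38 plateau and a configurable degraded tail,
  plus an optional fraction of uniformly low-quality reads (default 0) to
  exercise the quality filter.

Reference catalogs are generated by rejection sampling with a mutual
Hamming-distance guarantee: every pair of matures, and every plant mature
against every host mature/decoy window, differs by at least
`2·max_mismatches + 1` positions. This makes host exclusion and
mismatch-tolerant assignment unambiguous by construction, which is what
lets recovery tests demand exact count equality at error rate 0.

The simulator does **not** model: plasma degradome fragments or other
non-miRNA small RNA; sequence homology between host and plant families
(real catalogs contain near-identical cross-kingdom homologs, which the
distance guarantee deliberately removes); indels; UMIs; ligation or PCR
bias; multi-mapping within miRNA families. Passing recovery tests
therefore demonstrate the correctness of the pipeline's logic under its
stated assumptions — not that real plasma data would yield the same
sensitivity, where homologous families and degradation products make both
the assignment and the host-exclusion step genuinely harder.

## Numerical and design choices

* **Trimming**: leftmost qualifying adapter occurrence wins (shortest
  plausible insert — the small-RNA convention); the adapter may run off
  the 3' end with partial overlap ≥ `min_overlap` (default 6) and mismatch
  fraction ≤ 0.1. Length window 16–28 nt and mean-Phred ≥ 20 are declared
  defaults; drop reasons are reported with precedence too_short >
  too_long > low_quality. Trimming an adapter-free read is the identity.
* **Determinism**: every stochastic stage draws from a seed derived from
  the single configured `rng_seed` (linear-congruential fold kept below
  2^31), per sample, so identical configurations give byte-identical
  FASTQ files and reports.
* **Degenerate inputs**: empty read sets give all-zero profiles; genes
  without a seed-site occurrence give empty prediction frames with stable
  column types; enrichment with a query disjoint from every term returns
  an empty, well-typed table.
* **Overlapping duplex anchors** are evaluated independently and all
  passing sites are reported, flagged when they overlap the previously
  reported site.
* **Presence counting** uses mature-sequence matches only; precursors are
  carried as annotation. Where a detection rule could count precursor-only
  hits, this package deliberately does not: a precursor-length match
  cannot come from a sequenced ~22-nt read.
* **Ambiguity of "close" seeds** is resolved as identity at the 6mer class
  or better; the class is a parameter, identity is not.

## Problem sizes

The shipped tests validate the pipeline at the following scales, chosen as
representative desk-scale conditions: full-cohort recovery on 20 samples ×
50,000 reads (error rates 0.001 and 0); specificity on host-only cohorts of
10 × 20,000 reads; assignment-oracle agreement on 10^4 reads against a
70-record catalog; duplex-DP/enumeration equality on 200 random pairs up to
10 nt; hypergeometric/enumeration equality on every universe up to N = 12;
and end-to-end determinism on 5 × 5,000-read runs. The simulator's default
cohort (`sim_config()`) is 20 × 50,000 reads.

## Known limitations

* Catalog-based matching cannot discover novel miRNAs and does not model
  genomic multi-mapping; it presumes curated mature catalogs.
* The wobble stack energies are simplified constants; absolute MFE values
  are comparable within this package's model, not against full
  thermodynamic folding engines (results agree qualitatively: perfect
  ~20-mer helices sit far below the −14 kcal/mol threshold in both).
* The complementarity score is a package definition; external score
  thresholds from unpublished schemes cannot be replicated bit-exactly.
* Enrichment p-values depend on the annotation map and background supplied
  by the user; published enrichment tables from web portals are generally
  not reproducible without their exact annotation versions.
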