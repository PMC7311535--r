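---
title: "Reduced-representation mutational signature detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-representation mutational signature detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutread)
```

# The problem

A mutational signature is a probability distribution over the 96
single-base-substitution channels: the six pyrimidine-strand substitutions
(C>A, C>G, C>T, T>A, T>C, T>G) crossed with the sixteen combinations of
5' and 3' flanking bases. A tumor's observed spectrum is modelled as a
non-negative mixture of known signatures, and the mixture weights
("exposures") are the quantity of clinical interest. Whole-genome
sequencing gives tens of thousands of somatic SNVs per tumor — far more
than needed: exposures are ratios, and a random subset of mutations
estimates them almost as well. Reduced-representation sequencing (RR-seq)
exploits this by sequencing only the fragments that a double restriction
digest plus size selection reproducibly yields, cutting cost by orders of
magnitude and, because the loci are fixed by the enzymes, making libraries
comparable between samples and usable on degraded (FFPE) DNA.

This package implements the computational side of that design: simulating
the digest to choose an enzyme pair, building spectra, refitting
exposures, filtering variant calls, and preprocessing the UMI/barcode
reads. All components are exercised end to end on synthetic data with
exact truth tables.

# In-silico digestion

`find_sites()` reports every IUPAC-compatible occurrence of an enzyme's
recognition sequence on the top strand, overlapping matches included, and
places the cut at *match start + cut offset* (PstI `CTGCA^G`: offset 5;
ApoI `R^AATTY`: offset 1). Numerical and representational choices:

* **Coordinates** are 0-based half-open internally; BED is native, VCF
  positions are shifted on ingest.
* **Cut coordinate**: the top-strand cut point only. Fragment length is
  the distance between adjacent top-strand cuts. Protocols differ on
  whether fragment boundaries should be cut points or site boundaries;
  the discrepancy is at most the site length (≤ 5 bp here) and is
  immaterial against a 100 bp size window, so the simpler convention is
  used and stated.
* **Palindromy**: catalog recognitions are their own IUPAC
  reverse complements, so a top-strand scan is exhaustive; a
  both-strand-scan property test verifies this.
* **N handling**: matches spanning an `N` are rejected. Assembly gaps are
  runs of `N` and must not spawn sites. Lowercase (soft-masked) sequence
  is matched normally — repeat masking is not a digestion phenomenon.
* **Terminal fragments**: contig ends do not emit half-fragments. A
  terminal fragment has only one restriction end, cannot receive both
  enzyme-specific adapters, and so cannot be amplified; the same argument
  motivates the retention rule below.

`size_select()` keeps fragments with length in `[min_len, max_len]`,
inclusive on both boundaries (the window is stated in the protocol
literature without inclusivity; an inclusive reading is the least
surprising and costs at most the boundary lengths), and by default only
fragments whose two ends come from *different* enzymes. With Y-adapters
keyed to each enzyme's overhang, a same-end fragment gets the same adapter
on both ends and is not PCR-amplifiable; `require_mixed_ends = FALSE`
accommodates other chemistries. The default window is 350–450 bp, chosen
so the complete library construct still fits a standard paired-end
sequencing run.

# Spectra and refitting

`build_spectrum()` classifies each SNV by its genomic trinucleotide,
reverse-complementing purine-reference substitutions onto the pyrimidine
strand. The canonical channel order is substitution-major, then 5' base,
then 3' base, each alphabetical; signature tables are harmonized to this
order *by label*, never positionally. SNVs whose context is
undeterminable (missing flank, `N` in context) are excluded and logged,
not fatal; a reference allele contradicting the genome is an error, since
it indicates mismatched inputs rather than bad data.

`fit_exposures()` solves `min ‖Sᵀx − p‖₂, x ≥ 0` with a Lawson–Hanson
active-set solver written for this package, then rescales `x` to sum to
one. The spectrum is normalized to frequencies before fitting; fitting
raw counts differs only by a positive scale factor, which NNLS passes
through linearly, so the normalized exposures are identical either way —
the choice is one of numerical hygiene, not of model. An all-zero NNLS
solution (possible when the spectrum is orthogonal to every signature) is
an explicit error rather than a silent zero profile, because the
downstream cosine comparison is undefined on zero vectors. No sparsity
penalty is added: plain NNLS is the estimator.

`cosine_similarity()` is the inner product over the product of Euclidean
norms, clamped to `[-1, 1]` against floating-point overshoot; zero
vectors are rejected. For the non-negative vectors used here the value
lies in `[0, 1]`: 1 for identical profiles, 0 for profiles with disjoint
support.

The solver is verified three ways: against an established NNLS
implementation on random rectangular problems, against an exhaustive
simplex grid search (step 1e-3) for 2–3 signature mixtures, and by
parameter recovery from multinomially sampled spectra.

# The two screening experiments

`stability_experiment()` asks how many mutations are enough: for each
sample it refits exposures from random subsets (without replacement) of
increasing size and records the cosine similarity to the full-set
profile. A sample contributes to a subset size only if it has at least
that many usable mutations, so small samples never drag down large-subset
summaries. On synthetic six-signature cohorts the curve rises and
plateaus by roughly 500 mutations — the behaviour that justifies reduced
sequencing in the first place. Replicates default to 10 per size; the
whole experiment is reproducible from a single seed.

`screen_combinations()` ranks enzyme pairs: digest, size-select, restrict
each sample's mutations to the retained fragments, refit, and compare to
the full-set profile. Reported per pair: mean and sd of cosine across
samples, mean recovered-mutation count, fragment count and covered bp. A
pair retaining no fragments is *flagged*, reported with zero yield and an
`NA` mean — an undefined cosine is never averaged as if it were a bad
one. Samples whose restricted spectrum is empty are likewise excluded
from that pair's mean and counted. `region_restrict_experiment()` is the
same computation for fixed BED regions (e.g. exome capture designs), so
capture-based alternatives can be compared on the same footing.
Down-sampling-based shallow-WGS simulation requires alignments and a
caller and is out of scope; published summaries of such simulations are
external comparators only.

# Read preprocessing

The library layout puts, on each mate, a 4 bp UMI, then a 6 bp inner
(sample) barcode, then the residual restriction tag, then genomic insert.
Processing order matches the laboratory order of operations and runs
entirely pre-alignment:

1. **Clone filter** — PCR duplicates are pairs identical in both UMIs
   *and* both remaining sequences (exact match, no UMI error correction;
   users wanting network-based UMI collapse should do so downstream — the
   divergence point is documented, deliberately). The first occurrence is
   kept; UMIs are trimmed from retained reads.
2. **Demultiplexing** — a pair is assigned when both mates' barcodes
   match one map entry within `max_mismatch` (default 1, an assumption —
   mismatch tolerances are rarely reported) and no other entry matches;
   ambiguity goes to `unassigned`. Maps with entries closer than
   `2·max_mismatch + 1` Hamming cannot guarantee unique assignment and
   are rejected outright.
3. **RAD-tag check** — mate 1 must begin with the first enzyme's residual
   tag and mate 2 with the second's, *or* mirrored, since a fragment
   ligates into the sequencing construct in either orientation. Defaults
   `TGCAG`/`AATTY` follow from the cut geometry of PstI (`CTGCA^G`) and
   ApoI (`R^AATTY`); both are configurable because observed read prefixes
   depend on adapter design. Tags are genomic sequence and stay on the
   read.
4. **Quality filter** — sliding window of 15% of the read length; a pair
   is dropped if any window's mean Phred falls below 10 in either mate
   (standard RAD-processing defaults).

# Somatic-variant filtering

Every expression in the filter ledger is read as a *rejection trigger*:
the record is removed as soon as any rule fires. This is the only
polarity consistent across the ledger — `VariantAlleleCountControl > 1`,
for instance, must reject germline-contaminated calls, not accept them —
and it is stated prominently because the expressions alone do not carry
their polarity. Inequalities are applied exactly as written, strict or
inclusive, including the `≥ 7 / < 0.05 / ≥ 0.2` strand-bias compound
whose three clauses are conjunctive. Missing metrics fail conservatively
with a dedicated rule name. Cohort presets carry the minimum
variant-supporting reads and VAF per library type and caller
(`mutread_ff` 5/0.03, `wes` 7/0.01, `swgs10x` 5/0.11, `mutread_ffpe`
10/0.13, `strelka_ff` 20/0.11, `strelka_ffpe` 11/0.03); the
control-depth minimum is a cohort-level setting (20 for matched trios, 10
for lower-coverage FFPE-only cohorts) and therefore an argument, not part
of the preset. Read-level criteria (minimum mapping/base quality,
overlapping-mate consensus) belong to the upstream caller configuration
and are out of scope here.

# Synthetic data: what it does and does not emulate

`make_genome()` plants concrete recognition sites at requested positions
in a random background and *rejection-samples the background* until the
planted enzymes match nowhere else (bounded at 1000 rounds, then an
error). The point is exactness: truth tables of sites, cuts and fragments
are guaranteed, not probabilistic, so digestion tests can assert set
equality. `sample_mutations()` draws channels from the mixture
`exposures %*% sigs` (multinomial), then places each mutation uniformly
on a genome position with the matching pyrimidine-strand context, at
distinct positions (somatic-SNV semantics). `simulate_reads()` emits the
full read layout with per-molecule UMIs drawn unique per distinct
molecule, so the simulated duplication rate is recovered *exactly* by the
clone filter.

The default signature set, `synthetic_signatures()`, is six deterministic
distributions each concentrating 90% of its mass on one 16-channel block
with a triangular shape plus a uniform floor; pairwise cosine < 0.05.
It is a synthetic stand-in for a small cohort-specific signature panel —
real signature sets (e.g. the six known for esophageal adenocarcinoma)
are published elsewhere and are not reproduced here; any COSMIC-layout
TSV loads via `load_signatures()`.

What the generators deliberately do not model: sequencing errors beyond
none (reads are error-free at Q40), FFPE deamination damage (C>T at CpG),
partial digestion, methylation-sensitive cutting, and mapping ambiguity.
Consequently, passing tests demonstrate the *computational* correctness
of each step and the statistical behaviour of refitting under sampling
noise — they do not demonstrate robustness to platform artifacts, which
on real data is the job of the variant filter and of upstream QC.

# Problem sizes and determinism

Test and experiment scales were chosen to exercise the statistics while
staying desk-sized: genomes of 10–60 kb, cohorts of 3–4 samples, 200–5000
mutations per sample, 10–50 replicates per condition, 200 random
sequences (≤ 10 kb) for the digestion oracle, and a step-1e-3 simplex
grid for the NNLS oracle. Every stochastic generator requires a seed, and
experiment drivers take one seed governing the whole run; repeated
invocations are bit-identical. The exhaustive-oracle comparisons
(digestion, NNLS) are exact, not tolerance-based; statistical assertions
(recovery, plateau) use fixed seeds and tolerances wide enough for
Monte-Carlo error at the stated replicate counts.

# Known limitations

* The mixed-ends retention rule and terminal-fragment exclusion encode
  one adapter chemistry; both are togglable but the defaults are
  opinionated.
* Exposure uncertainty is not quantified (no bootstrap); refits from very
  few mutations are reported as-is and should be interpreted with the
  stability curve in hand.
* The clone filter's exact-match semantics undercount duplicates in the
  presence of sequencing errors in UMIs or reads.
* De novo signature discovery (NMF) is out of scope; only refitting to a
  supplied signature matrix is implemented.
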