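# mutread

Mutational signatures — the characteristic distributions of single-base
substitutions over their trinucleotide contexts that mutational processes
leave in a genome — are usually estimated from whole-genome sequencing,
which is too expensive for large cohorts and often impossible for degraded
clinical (FFPE) material. A cheaper route is reduced-representation
sequencing (RR-seq / ddRAD-style): digest the genome with two restriction
enzymes, size-select the fragments, and sequence only that reproducible
subset of loci. If the recovered mutations are an unbiased sample of the
genome-wide mutational spectrum, a few hundred of them suffice to refit the
signature profile.

`mutread` implements the computational machinery for planning and
analysing such experiments:

* **In-silico double digestion** (`find_sites()`, `digest_genome()`,
  `size_select()`): IUPAC-aware restriction-site scanning, fragment
  construction between adjacent cut points, and inclusive size-window
  selection with a mixed-ends retention rule, for any enzyme pair from the
  packaged catalog (PstI `CTGCA^G`, ApoI `R^AATTY`, and others).
* **96-channel SBS spectra** (`build_spectrum()`): pyrimidine-strand
  trinucleotide classification of SNVs, optionally restricted to the
  retained fragments.
* **Signature refitting** (`fit_exposures()`, `cosine_similarity()`):
  non-negative least squares (Lawson–Hanson) solving

  `min ||S' x − p||₂  subject to  x ≥ 0`,

  where the rows of `S` are signature probability vectors and `p` the
  observed spectrum; exposures are rescaled to sum to one. Profiles `P`,
  `Q` are compared with `cossim(P,Q) = Σ PᵢQᵢ / (‖P‖₂ ‖Q‖₂)`.
* **Experiment drivers** (`stability_experiment()`,
  `screen_combinations()`, `region_restrict_experiment()`): profile
  stability under random mutation subsets, and ranking of enzyme
  combinations (or fixed target regions such as exome designs) by cosine
  similarity of the restricted refit to the full-set profile.
* **Read preprocessing** (`clone_filter()`, `demultiplex()`,
  `radtag_check()`, `quality_filter()`): UMI-exact PCR-clone removal,
  inner-barcode demultiplexing, residual restriction-tag verification and
  sliding-window quality filtering for the `[UMI][barcode][tag][insert]`
  read layout.
* **Somatic-variant filtering** (`apply_filters()`, `filter_variants()`,
  `filter_vcf()`): the rejection-rule ledger (control-allele leakage,
  mapping/base-quality rules, strand-bias compound) plus cohort presets
  for minimum variant reads, VAF and control depth.
* **Synthetic data** (`make_genome()`, `sample_mutations()`,
  `simulate_reads()`): genomes with exactly known planted sites, SNV sets
  drawn from known exposure mixtures, and reads with known sample of
  origin and duplication status, making the whole pipeline testable
  end to end without external data.

## Worked example

Plan a PstI/ApoI library on a synthetic genome, and check how well the
fragment-restricted mutations recover the signature profile:

```r
library(mutread)

sigs <- synthetic_signatures()                  # 6 well-separated signatures
gen  <- make_genome(30000,
                    sites = data.frame(enzyme = rep(c("PstI", "ApoI"), 15),
                                       pos = round(seq(500, 28500, length.out = 30))),
                    seed = 42)
frags <- size_select(digest_genome(gen$genome, "PstI", "ApoI"),
                     min_len = 350, max_len = 1500)
nrow(frags); sum(frags$length)
#> 29 fragments, 27996 bp covered

truth <- c(0.6, 0.2, 0.1, 0.05, 0.03, 0.02)
snvs  <- sample_mutations(gen$genome, sigs, truth, 500, seed = 43)
full  <- fit_exposures(build_spectrum(snvs, gen$genome), sigs)
rr    <- fit_exposures(build_spectrum(snvs, gen$genome, regions = frags), sigs)
full
#> <exposure_profile> 6 signatures, 500 mutations, residual 0.03896
#> SynthSig1 SynthSig2 SynthSig3 SynthSig4 SynthSig5 SynthSig6
#>    0.5631    0.2209    0.0935    0.0652    0.0408    0.0164
cosine_similarity(rr, full)
#> 0.9999
cosine_similarity(full, truth)
#> 0.9981
```

The refit from the 460 mutations falling inside the retained fragments is
nearly indistinguishable from the full-set profile (cosine 0.9999), which
is exactly the property an enzyme-pair screen optimises.

A thin command-line wrapper over these functions ships in
`inst/cli/mutread.R` (subcommands `digest`, `spectrum`, `fit`, `cossim`,
`filter`); run it with `Rscript` and `--help`-style usage is printed on
wrong input.

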