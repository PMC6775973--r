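# cobascan

Comparative genomics of lytic marine phages with short direct terminal
repeats (DTRs), for virologists and viral-ecology bioinformaticians working
with cobavirus-like podoviruses: linear ~40 kb genomes at ~47% G+C whose ends
carry a 159–173 bp DTR and whose two divergently transcribed genome arms are
separated by a bidirectional rho-independent terminator.

The package implements the full analysis chain as tested, reusable R code:

* **Termini** — direct (and diagnostic inverted) terminal-repeat detection by
  end-anchored prefix/suffix comparison; anchoring of a reference DTR in
  related genomes at 70–100% identity; reorientation of mis-ordered
  assemblies so the DTR 5' end defines position zero; terminus evidence from
  alignment-start pileups (z-score against a uniform-start null).
* **Read recruitment** — quality trimming (Q20 ends, mean Q20, ≥30 bp),
  a built-in seed-and-extend aligner (or SAM ingestion from an external
  mapper via the NM tag), and the presence/abundance statistics: a phage is
  *present* in a sample when at least 75% of its genome is covered by reads
  of at least 90% identity, and its relative abundance is

  ```
  abundance = aligned bases / genome size (bp) / library size (Gb)
  ```

* **Protein clustering** — all-vs-all Smith–Waterman (BLOSUM62, 11/1) with
  Karlin–Altschul bitscores/e-values, thresholded at e ≤ 1e-5 and bits ≥ 50,
  partitioned by an implemented Markov clustering (inflation 2.0).
* **Terminator scanning** — stem-loop enumeration under a transparent
  stability model with the conventional |ΔG| ≥ 10.5 kcal/mol cutoff and
  downstream poly-T requirement; opposite-strand calls merge into
  bidirectional terminators.
* **Genome distance** — ≥ 34 kb completeness filter, fragment-based
  nucleotide identity (an ANI surrogate), and OPTSIL-style F-linkage
  clustering (F = 0.5) for species delineation.
* **Synthetic data** — a simulator of phage genomes (planted DTRs,
  GC-rich DTR 5' regions, bidirectional terminator cassettes), diverged
  relatives, and mixed phage communities with per-read error models and a
  planted-truth table, so every stage is testable without downloads.

## Worked example

Simulate an enrichment-like sample containing a phage and a close relative
(99.6% expected identity), then detect the genome's DTR, profile the sample,
and measure intergenomic identity:

```r
library(cobascan)

ref <- simulate_genome(genome_spec(seed = 1))        # 40 kb, GC 0.47, DTR 170 bp
rel <- diverge_genome(ref, subst_rate = 0.004, seed = 2)
com <- simulate_community(community_spec(
  members = list(ref, rel), weights = c(0.7, 0.3),
  total_bases = 2e6, subst_rate = 0.01, seed = 3))

find_terminal_repeat(ref)[, c("genome_id", "length", "mismatches",
                              "three_start", "three_end")]
#>    genome_id length mismatches three_start three_end
#> 1 simphage_1    170          0       39830     40000

profile_sample(com$reads, list(ref), clean_params = NULL,
               recruit_params = recruit_params(alt_identities = c(0.95, 1.0)),
               sample_id = "enrichment_S1")[
  , c("genome_id", "identity_cutoff", "breadth", "mean_depth",
      "abundance_per_gb", "present")]
#>    genome_id identity_cutoff breadth mean_depth abundance_per_gb present
#> 1 simphage_1            0.90  0.9993      50.00            25000    TRUE
#> 2 simphage_1            0.95  0.9993      49.96            24981    TRUE
#> 3 simphage_1            1.00  0.9988       9.24             4620    TRUE

fragment_identity(ref, rel)
#> identity: 0.9954   aligned_fraction: 1.00
```

Reading the output: the genome's 170 bp terminal repeat is found with zero
mismatches at both ends; the reference recruits reads from both community
members at ≥ 90% identity (mean depth 50×, abundance 25,000 per Gb of
library), but at the 100% cutoff only the error-free reads of the focal
phage remain (depth 9.2×) — the breadth/abundance columns are monotone
non-increasing in the identity cutoff, the signature used to distinguish a
resident population from cross-recruitment by relatives. The fragment
identity of 99.5% against the relative matches its planted 0.4% divergence.

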