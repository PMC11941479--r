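# mpindex

Quantifying co-transcriptional pri-miRNA processing by the Microprocessor
(Drosha/DGCR8) from stranded chromatin-associated RNA-seq.

## The problem

Chromatin-associated RNA-seq is enriched for nascent transcripts. When the
Microprocessor crops a pri-miRNA hairpin co-transcriptionally, the excised
hairpin leaves the chromatin fraction while the flanking transcript stays,
so an efficiently processed locus shows a coverage trough over the hairpin.
`mpindex` turns that trough into a per-locus statistic, the
**Microprocessor Processing Index**:

```
MPI = -log2( (mean hairpin depth + 1) / (mean flank depth + 1) )
```

Depth is averaged over trimmed scoring regions: the hairpin minus its outer
5 nt, and two 95 nt flank cores separated from the hairpin core by 10 nt
gaps that absorb alternative Drosha cleavage (100 nt flanks minus the 5 nt
nearest the hairpin). MPI well above 0 means efficient processing; near 0
or negative means inefficient or absent processing. Condition-level MPI is
the mean over replicates, and `ΔMPI = MPI(mutant) − MPI(reference)` is
negative when processing is reduced in the mutant — the readout of interest
for Microprocessor dosage mutants (e.g. *DGCR8* heterozygotes).

Loci are kept only if they (1) are not mirtrons, (2) produce a detected
mature miRNA, (3) have reference flank depth ≥ 2, and (4) have flank means
within 4-fold of each other; every exclusion is audited with its failing
filter(s). Auxiliary tools test for the basal UG motif at position −14
upstream of the 5p miRNA and compute exact hypergeometric category
enrichment (e.g. primate-specific miRNAs among dysregulated ones). A
simulator generates coverage with known per-locus processing efficiency so
the whole pipeline validates by parameter recovery, offline.

The package is for transcriptomics analysts working with fractionated
(chromatin) RNA-seq of cell lines or tissues, who have hairpin annotations
(BED6 or miRBase GFF3) and stranded coverage (indexed BAM or bedGraph
pairs) grouped into conditions with replicates.

## Worked example

Simulate a two-genotype experiment (processing efficiency 0.8 in WT, 0.5
in HET, 60 loci, 2 replicates each), run the pipeline on the files it
wrote, and score efficiency recovery:

```r
library(mpindex)

cfg <- sim_config(n_loci = 60, replicates_per_condition = 2,
                  efficiency_by_condition = list(WT = 0.8, HET = 0.5),
                  seed = 42)
rec <- run_recovery(cfg, "demo_run")
rec$result
#> MPI result: 60 loci, 4 samples, reference 'WT'
#>   survivors after filters: 54

head(rec$result$loci[, c("locus_id", "mpi_WT", "mpi_HET", "dmpi_HET",
                         "pass", "processed_in_ref")], 4)
#>      locus_id mpi_WT mpi_HET dmpi_HET  pass processed_in_ref
#> 1 simmir-0001  2.314  0.9979   -1.316 FALSE             TRUE
#> 2 simmir-0002  2.257  1.0288   -1.228  TRUE             TRUE
#> 3 simmir-0003  2.236  0.9741   -1.262  TRUE             TRUE
#> 4 simmir-0004  2.288  0.9750   -1.313  TRUE             TRUE

surv <- rec$report[rec$report$survivor, ]
round(tapply(abs(surv$error), surv$condition, mean), 4)
#>    HET     WT
#> 0.0055 0.0024
```

Reading the output: at λ = 100 reads/nt the closed-form expectation is
MPI ≈ 2.27 at p = 0.8 and ≈ 0.99 at p = 0.5, so the per-locus values above
sit where they should; every surviving locus has `dmpi_HET < 0`, the
signature of reduced processing in the mutant; and the back-estimated
efficiencies land within ~0.005 of the simulated truth. Six of the 60 loci
were excluded by the audit trail in `rec$result$audit` (simulated mirtrons
and undetected loci; `simmir-0001` here is one of them).

Single components work standalone:

```r
mpi_sample(3, 15)               # -log2(4/16) = 2
hypergeom_enrichment(10, 5, 4, 4)  # 0.02380952
```

On real data, replace the simulated directory with your own manifest and
annotations:

```r
loci <- load_annotations("hairpins.gff3", format = "gff3")
res <- run_mpi(read_manifest("manifest.tsv"), loci, reference = "WT",
               detected = load_id_list("detected_matures.txt"),
               mirtrons = load_id_list("mirtrons.txt"))
write_mpi_tsv(res, "mpi_out")
```

A command-line wrapper with subcommands `compute`, `simulate`, `recover`,
`enrich` and `motif` is installed at
`system.file("scripts", "mpindex", package = "mpindex")`.

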