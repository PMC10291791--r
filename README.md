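# IntronProfiler

Positional profiling of intronic variants flanking exons in exome
sequencing callsets.

Exome capture reads past exon boundaries, so a conventional exome callset
contains hundreds of thousands of intronic variants concentrated in the
first ~200 bp of each intron. Their reliability and interest vary sharply
with distance from the splice sites: coverage decays away from the exon,
the false-call proportion rises as an S-shaped curve inverse to depth,
and specific offsets (the ±2 splice dinucleotide, the ±5 pathogenic hot
spot, the ±9 boundary neighbourhood) behave differently from their
surroundings. IntronProfiler is for bioinformaticians and clinical
genomics analysts who want that positional structure made explicit from
standard inputs (annotated VCFs plus a GFF3/GTF/BED12 gene annotation).

## What it computes

For every called variant the package assigns a **symmetric splice-site
offset**: a variant d bases 3′ of an exon end (donor side, +d) or d bases
5′ of an exon start (acceptor side, −d) falls in bucket d ∈ {1, …, W},
W = 200 by default. Variants exonic in any transcript are exonic;
intronic variants beyond W of every boundary are deep-intronic. Within an
intron each base belongs to its nearer splice site only.

Variants are classified **pass/false** by GATK-style hard filters —
SNV: `QD < 2.0 | FS > 60.0 | MQ < 40.0 | MQRankSum < −12.5 |
ReadPosRankSum < −8.0 | DP < 20 | DV < 8`; indel: `QD < 2.0 | FS > 200.0
| ReadPosRankSum < −20.0 | DP < 20 | DV < 8` — and a variant seen in
several samples is counted once (pass if it passes in ≥1 sample, by
default). Pass variants are flagged **deleterious** when population
AF < 0.05, CLINSIG is not Benign/Likely_benign, and the present
in-silico scores satisfy `CADD > 10`, SPIDEX `dpsi_zscore ≥ 2`,
`dbscSNV > 0.6`.

Per bucket d the package tabulates raw/pass/false/deleterious counts, the
false proportion FP(d) = false/raw, and mean depth; it then tests
positional differences (paired t-tests on per-sample counts, Fisher's
exact tests on pooled pass/false tables, BH adjustment over each
matrix), compares flanking-vs-exonic FP, and computes paired-t sample
sizes from the noncentral t distribution
(power = P(|T′(n−1, dz·√n)| > t\_crit)).

A seeded **synthetic cohort generator** emulates the field-typical
structure (intensity minimum at ±2, peak at ±9, depth decay with midpoint
near d = 50, depth-driven QC failure, deleterious enrichment at ±5) and
emits a per-position truth table, so the full pipeline is testable with
no data access.

## Worked example

```r
library(IntronProfiler)

cfg <- syntheticConfig(seed = 1)          # 20 samples, 50 genes, W = 200
sim <- cmdSimulate(cfg, "sim")            # GFF3 + 20 VCFs + truth.tsv

vs   <- readVcfCohort(sim$vcfs)
uvs  <- dedupUnique(vs)                   # "counted as 1" across samples
prof <- buildProfile(uvs, sim$ann)
prof
#> PositionProfile over d = 1..200
#>   flanking raw: 43411  pass: 21909  deleterious: 193
#>   argmax(pass) = 9, argmin(pass, d<=150) = 2
```

The cohort contains 117,980 records collapsing to 55,233 unique variants
(31,773 pass / 23,460 false). The pass profile peaks at offset ±9 and is
lowest (within 150 bp) at ±2, recovering the generator's design; the
busiest bucket looks like:

```r
head(profileTable(prof)[order(-profileTable(prof)$pass_count), ], 1)
#>  d raw_count pass_count false_count        fp mean_depth deleterious_count
#>  9       372        335          37 0.0994624   118.7384                 2
```

Empirical FP tracks the designed FP curve (Spearman ρ = 0.981) and is
inverse to depth (ρ = −0.981); the deleterious profile peaks at ±5. The
flanking region's FP exceeds the exonic FP by 0.416 on average
(paired t, p = 2.5 × 10⁻³¹ on 20 samples):

```r
fl  <- perSampleFp(vs, sim$ann, "intronic_flanking")
exn <- perSampleFp(vs, sim$ann, "exonic")
flankingVsExonicFpTest(fl$fp, exn$fp, fl$pooled, exn$pooled)

powerSampleSize(0.5, alpha = 0.05, power = 0.95)   # 54 samples
```

A thin command-line wrapper (`inst/exec/intronprofiler`) exposes the same
stages as `simulate`, `profile`, `stats` and `report` subcommands; the
`profile` stage writes the four per-position tables, partition totals and
a run log listing every effective threshold with its source.

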