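# figsex

Sex identification of fig (*Ficus carica* L.) by PCR markers, as a fully
simulated and tested pipeline.

Fig is gynodioecious: female trees bear the commercial fruit, while
"male" trees (caprifigs) carry stamens and short-styled gall flowers. Only
females are worth planting, so telling seedlings apart years before
flowering matters to breeders. Two sex-linked loci make that possible:

* **AGAMOUS (AG)** — male genomes carry extra *AG* alleles whose 759-bp
  coding sequence retains a 15-bp stretch in exon 7 that is deleted in the
  conserved 744-bp allele present in both sexes. Using the 15-bp sequence
  itself as a forward primer and the reverse complement of the last 20
  coding bases as a reverse primer yields a **146-bp product in males only**
  (the AG-Marker, a presence/absence SCAR assay).
* **RAN1 (HMA7)** — a copper-transporting P-type ATPase in the sex-linked
  region. Its 3015-bp CDS carries 15 catalogued SNP sites; 12 of them are
  sex-discriminating: males are heterozygous (a double-base peak, IUPAC
  ambiguity code in the Sanger consensus) and females homozygous at every
  one. A 608-bp amplicon inside exon 2 covers 6 of the 12 sites (the
  RAN1-Marker); all-heterozygous means male, all-homozygous means female.

The package builds seeded synthetic versions of both loci and of the plant
panels (27 male + 24 female cultivars; two F1 populations of 242 and 85
seedlings), then *rediscovers* the markers from those panels: global
affine-gap alignment finds the diagnostic indel, a universal het/hom screen
classifies the SNP sites, in-silico PCR with IUPAC-degenerate primers
predicts every published product size, and the callers and segregation
statistics validate both assays against the truth tables.

## Worked example

```r
library(figsex)

models  <- buildLocusModels(seed = 1)
primers <- figPrimers()                      # the nine published primer pairs

# the AG-Marker amplifies the male allele only
amplify(genomicSeq(models$ag$male_ag2), primers[["AG-Marker"]])[, 1:4]
#>   template start  end length
#> 1 template  5100 5245    146
nrow(amplify(genomicSeq(models$ag$female), primers[["AG-Marker"]]))
#> [1] 0

# rediscover the indel and re-derive the marker from the panel alone
panel <- buildCultivarPanel(seed = 1, models = models)
ind <- findDiagnosticIndels(panel, "AG_cds")
ind[, c("sequence", "length", "present_in", "position")]
#>          sequence length present_in position
#> 1 CAGGAGGAGGAAGCT     15       male      614
designPresenceMarker(ind[1, ], models$ag$male_ag2)
#> PrimerPair 'presence-marker': F CAGGAGGAGGAAGCT / R TTACACTAATTGGAGGGCCA (expected 146 bp)

# SNP screen over the 51 cultivars: 12 of 15 sites discriminate
v <- screenSnpSites(panel, models$ran1$sites)
table(v$verdict)
#> discriminating        invalid
#>             12              3
v$label[v$verdict == "invalid"]
#> [1] "seq000259_9823"  "seq000259_9855"  "seq000259_10377"

# F1 population 1: call every seedling with both markers and tally
pop1  <- buildF1Population(242, seed = 1, fixedCounts = c(110, 132),
                           models = models, population = "pop1")
calls <- callPanel(pop1, primers, models$ran1$sites)
tallyPopulation(calls[calls$marker == "consensus", ], "pop1")
#>   population n_female n_male n_ambiguous n_failed ratio_text chi2   p_value
#> 1       pop1      110    132           0        0      1:1.2    2 0.1572992
```

The ratio string `1:1.2` and the chi-square of exactly 2 (not rejecting the
1:1 Mendelian expectation of the female ga/ga x male GA/ga cross) match the
published tallies; AG-Marker and RAN1-Marker calls agree for every sample
(`concordance()` returns 1).

A thin command-line wrapper covers the same pipeline
(`inst/scripts/figsex forge|amplify|screen|call|report`); see
`figsexCLI("help")`.

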