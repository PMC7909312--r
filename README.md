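# SRNaseScreen

Screening and genetic validation of S-RNase candidates in gametophytic
self-incompatibility (GSI).

## The problem

In S-RNase-based GSI (citrus, Solanaceae, Rosaceae, Plantaginaceae), the
pistil rejects pollen whose haploid S allele matches either pistil S
allele; the female determinant is a style-expressed T2-family
ribonuclease (S-RNase). Finding the S-RNase among the many T2 RNases in
a style transcriptome is a multi-criterion screen: true S-RNases are

* **class III** of the T2 RNase family (nearest labelled reference by
  p-distance, where identity = 1 − p-distance),
* outside **low-polymorphic subclusters** (LPSCs — groups of
  near-identical paralogs lacking the allelic diversity to encode S
  specificity),
* **basic** (isoelectric point above ~7, against acidic classes I/II),
* catalytically intact (**two conserved CAS histidines**),
* structurally canonical (**exactly one intron, inside the
  hypervariable (HV) region** of the protein alignment),
* **pistil-specific** in tissue expression panels, and
* inherited like an S haplotype in **reciprocal semi-compatible
  crosses**.

The genetic signature is the core of the package. In a semi-compatible
cross `S1Sx × S1Sy` only `S1Sy` and `SxSy` progeny occur (pollen
carrying `S1` is rejected), so a marker tracking the paternal unique
allele is present in *all* progeny (1:0), maternal-side S markers
segregate 1:1, unlinked hemizygous markers segregate 3:1, and the two
maternal haplotype markers are perfectly complementary across progeny.
Observed present/absent counts are tested against 1:1 and 3:1 with the
Pearson chi-square statistic (df = 1, no continuity correction),

χ² = Σᵢ (Oᵢ − Eᵢ)² / Eᵢ,  P = Pr(χ²₁ ≥ χ²),

and a rule set maps the reciprocal-cross patterns to S-haplotype roles
(`shared_S`, `unique_S(parent)`, `unlinked_het_both`,
`unlinked_het_one`, `homozygous_non_S`).

Every stage is testable offline: a synthetic-data module generates a
three-class protein family with planted pI bias, CAS knockouts, an
LPSC, genomic sequences with planted GT..AG introns, reciprocal GSI
cross datasets with known marker roles, tissue panels, and
negative-binomial count matrices with a planted down-regulated S-RNase.

## Worked example

```r
library(SRNaseScreen)

## chi-square segregation test on observed counts (58 present, 23 absent)
segregationTest(58, 23, "1:1")
#> $chi2           $df        $p
#> [1] 15.12346    [1] 1      [1] 0.0001007042

## semi-compatible GSI cross: only two genotypes, at 1:1
cross <- gsiCross(SGenotype("S1", "Sx"), SGenotype("S1", "Sy"),
                  n = 10000, seed = 7)
table(paste(progenyTable(cross)$maternal, progenyTable(cross)$paternal))
#> S1 Sy Sx Sy
#>  4900  5100

## full synthetic screen with planted truth
res <- runSyntheticPipeline(seed = 1)
res$designated
#> [1] "cIII_1" "cIII_2" "cIII_3"
as.data.frame(res$roles)[, c("marker", "presentFwd", "absentFwd",
                             "presentRev", "absentRev", "role")]
#>   marker presentFwd absentFwd presentRev absentRev              role
#> 1 cIII_1         36        45         46        49          shared_S
#> 2 cIII_2         45        36         95         0  unique_S(mother)
#> 3 cIII_3         81         0         49        46  unique_S(father)
#> 4 cIII_4         59        22         70        25 unlinked_het_both
#> 5 lpsc_1         81         0         95         0  homozygous_non_S
```

The segregation P value is the upper chi-square tail for counts 58/23
against 1:1. The cross table shows the GSI rejection rule: every progeny
carries the paternal `Sy`. In the synthetic screen, the three planted
S-RNases (shared `S1`, maternal `Sx`, paternal `Sy`) are designated and
the decoys (an unlinked class III gene, an LPSC trio, classes I/II) are
excluded; the role table mirrors the reciprocal-cross reasoning — e.g.
the maternal unique S-RNase (`cIII_2`) is present in *every* progeny
when its carrier is the pollen donor and segregates 1:1 otherwise.

A command-line wrapper over the same functions is provided at
`inst/scripts/srnase-cli.R` (subcommands `segregate`, `simulate-cross`,
`simulate-data`, `structure`, `screen`, `express`, `report`).

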