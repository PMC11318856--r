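# prophager

Curation, typing and release quantification of prophages in poly-lysogenic
bacterial genomes.

Temperate phages integrate into bacterial chromosomes and ride along as
prophages. Automated finders (PHASTER-style tools) over-call: their hit lists
mix real prophages, fragments of the same prophage reported twice, and gene
clusters that are not phage at all. `prophager` implements the downstream
curation a phage biologist performs on such hit lists, for annotated
chromosomes of heavily lysogenized strains — the motivating case is a gut
*Clostridium* isolate carrying 15 prophages across >9.6% of its 7.78 Mb
chromosome. It is aimed at microbial genomicists characterizing lysogens from
annotation tables rather than raw sequence.

## What it computes

- **Hit curation.** Candidate hits are merged by interval union
  (`merge_hits`), then confirmed only if they contain a gene cluster
  conforming to at least one of the five classical phage functional modules
  — lysogeny control, DNA replication, packaging/capsid, tail, lysis
  (`assign_modules`, `confirm_phage`). A cluster is ≥2 co-oriented ORFs of
  the module's category family with ≤2 interspersed other genes; tail and
  lysis admit single-gene evidence.
- **Completeness categorization with defect overrides** (`categorize`,
  `detect_defects`). With an upstream completeness score *c* (0–100,
  AAI-based, consumed as input): *c* = 100 and no defects → `functional`;
  60 < *c* < 100 → `unknown`; *c* ≤ 60 → `defective`; *c* = 100 with any
  detected defect → demoted to `unknown`. The defect taxonomy covers split
  and truncated integrases (<200 aa fragments), missing large
  terminase/portal, group II intron-split genes, misoriented late-operon
  ORFs, and mosaic regions (≥2 disjoint lysogeny or replication clusters),
  which `delineate_mosaic` splits into sub-regions at
  transposase/replication openers and tail/recombinase closers.
- **Typing.** Virion morphology from tail-gene content with precedence
  sheath > tape measure > baseplate (myovirus / siphovirus / podovirus);
  lysogeny-switch architecture from gene synteny plus promoter orientation:
  ImmR/ImmA-like (ICE*Bs*1-type anti-repressor protease systems), Mu-like
  C/Ner (small divergent Ner plus nearby transposase), and λ-like CI/Cro
  (adjacent divergent regulator pair) as the fallback, in that precedence.
  Promoter calls are used only at score ≥ 0.87 and refine the call with
  divergent/convergent geometry; absent promoter data never blocks a call.
- **Accessory screen** (`screen_accessory`): a vocabulary-driven map from
  ORF traits to restriction–modification systems, toxin–antitoxin systems,
  diversity-generating retroelements, anti-phage defence factors,
  host-adaptation genes and large polyvalent-like ORFs.
- **Release quantification** (`analyze_qpcr`): DNase-protection qPCR by the
  2^−ΔΔCq method. DNase degrades free DNA but not encapsidated phage DNA;
  with ΔCq = mean treated Cq − mean untreated Cq per target, fold change =
  2^−(ΔCq_target − ΔCq_housekeeper), detection is called against each
  target's no-template control, and a housekeeper at/above its NTC is
  reported fully degraded.
- **Synthetic data** (`generate_chromosome`): plants these architectures
  (and decoys) with full ground truth for pipeline validation, and
  `build_lm41_fixture()` encodes the 15-prophage study genome as a packaged
  in-code fixture.

## Worked example

```r
library(prophager)
fx  <- build_lm41_fixture()                      # 29 candidate hits, 15 real
cur <- curate(fx$chromosome, fx$hits, fx$completeness, max_gap = 0)
table(cur$report$category[cur$report$confirmed])
#>  defective functional    unknown
#>          2          4          9
```

The 29 hits collapse to 23 distinct intervals; 15 contain phage modules and
are confirmed, and the completeness/defect rules split them 4 functional /
2 defective / 9 unknown. The largest region is a phage-recombination
hotspot:

```r
cur$regions$phi13
#> <prophage_region> phi13  LM41:6,632,999-6,769,447 (136,449 bp, forward strand)
#>   75 ORFs; completeness 100; category unknown; 1 defect flag(s)
sapply(delineate_mosaic(cur$regions$phi13), `[[`, "name")
#> [1] "phi13a" "phi13b" "phi13c" "phi13d" "phi13e"
```

Typing and the qPCR release panel:

```r
head(type_regions(cur$regions, fx$promoters)[, c(1, 2, 4, 7)], 5)
#>   region morphology lysogeny_system promoter_geometry
#> 1   phi1  podovirus          ci_cro         divergent
#> 2   phi2 siphovirus       immr_imma         divergent
#> 3   phi3   myovirus          ci_cro         divergent
#> 4   phi4  podovirus          ci_cro         divergent
#> 5   phi5 siphovirus       immr_imma        convergent

head(as.data.frame(analyze_qpcr(fx$qpcr))[, c(1, 5, 6, 7, 8)], 5)
#>   target delta_cq   ddcq fold_change detected
#> 1   phi1     5.11 -16.39       85878     TRUE
#> 2   phi4     8.06 -13.44       11113     TRUE
#> 3   phi2     8.37 -13.13        8964     TRUE
#> 4  phi10     8.69 -12.81        7181     TRUE
#> 5   phi3    10.20 -11.30        2521     TRUE
```

Smaller ΔCq after DNase treatment means more protected (encapsidated) DNA:
the four spontaneously released phages lead the ranking, and the
housekeeper is degraded below its NTC. The fixture's raw Cq replicates are
synthetic, constrained to the published ΔCq values and NTC relationships —
absolute fold-change magnitudes are therefore not comparable to published
means, while orderings and detection calls are.

A shell front end with `curate`, `type`, `screen`, `qpcr`, `run`,
`simulate` and `fixture` subcommands is installed at
`system.file("cli", "prophager.R", package = "prophager")`.

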