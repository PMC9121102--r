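# mircascade

`mircascade` is an R package for miRNA-centered regulatory-network
analysis in plants, built for methodologists and students who want every
stage of such a study runnable, inspectable and testable on a laptop: from
small-RNA reads to annotated miRNA hairpin loci, predicted and
degradome-confirmed targets, expression patterns and correlations,
weighted co-expression modules, and a TF→miRNA→target feed-forward-loop
(FFL) network. A fully specified synthetic-data generator emulates the
underlying study design — seven tissues (root/stem/leaf at the shooting
stage; root/stem/flag-leaf/panicle at grain filling) with 2 sRNA, 3 mRNA
and 1 PARE library each — and writes machine-checkable truth tables, so
the whole pipeline runs without any external download.

## The computations at the core

* **Locus annotation** follows the plant miRNA annotation checklist: the
  mature arm is the most abundant 19–25-nt read in a stack window, the
  miRNA\* is the duplex partner implied by the predicted secondary
  structure with 2-nt 3′ overhangs, and a locus passes only with ≤ 5
  duplex mismatches, ≤ 3-nt asymmetric bulge, precursor ≤ 300 nt, star
  reads at the expected coordinates (± 1 nt) and read precision ≥ 0.75.
  Folding is a maximum-base-pairing dynamic program (pairs {G:C, A:U,
  G:U}, loop ≥ 3), pluggable for external structures.
* **Target prediction** combines an expectation-penalty score
  (mismatch 1, G:U 0.5, bulge 2, doubled at miRNA positions 2–13;
  E < 3.0) and a duplex-energy ratio (MFE/MDE ≥ 0.75 with pair energies
  G:C −3, A:U −2, G:U −1); degradome 5′-tag profiles classify predicted
  cleavage sites into categories 0–4 (0/1 = transcript maximum) and
  categories {0,1} confirm. The *overall* dataset is the union of all
  evidence; the *overlap* dataset needs degradome support or ≥ 2
  computational methods.
* **Expression**: RPM with 2-nt-anchored mature counting and FPKM;
  tissue-averaged Pearson correlation of miRNA–target pairs with
  Student's t significance; pattern classes cut at RPM ≥ 100 / < 10.
* **Co-expression**: unsigned weighted network (|cor|^8), topological
  overlap, average-linkage modules, eigengenes, module–trait
  correlations (|r| ≥ 0.75, p < 0.01 retained) and kME hub ranking.
* **Network**: 2,000-nt promoters scanned with PWMs using exact
  score-distribution p-values (p ≤ 1e-4), typed edges (TMI/MTI/TTI) and
  exhaustive cascade/FFL enumeration.

## Worked example

```r
library(mircascade)
res <- run_pipeline("run42", pipeline_config(seed = 42))

truth <- res$sim$truth$loci
tmap  <- match_loci_to_truth(res$annot$loci, truth)
c(loci = nrow(res$annot$loci),
  true_recovered = sum(grepl("^mir", tmap), na.rm = TRUE),
  decoys_passing = sum(grepl("^dec", tmap), na.rm = TRUE))
#>           loci true_recovered decoys_passing
#>             28             28              0

res$stats$negative$fraction      # fraction of miRNA-target pairs, r < 0
#> [1] 0.6428571
res$network$motifs$counts
#>      n_tmi      n_mti      n_tti n_cascades     n_ffls
#>         65         30         40         66         28
subset(res$coexpress$module_trait, retained)
#>    module tissue         r            p retained
#> 14     M2      P 0.9980466 2.375704e-24     TRUE
```

Reading: of the 30 planted true hairpin loci, 28 pass the full annotation
checklist (the two planted low-abundance loci have expected RPM < 10 and
are not recoverable from reads); none of the 10 planted decoys pass, and
each decoy is rejected for exactly its planted defect. About 64% of
predicted miRNA–target pairs are negatively correlated across tissues
(repression strength 0.9 in the generator), the panicle-high
co-expression block is recovered as module M2 with an eigengene–panicle
correlation of 0.998, and the TF/miRNA/target edge sets combine into 66
cascades, 28 of which close into feed-forward loops.

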