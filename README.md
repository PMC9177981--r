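# synergyseq

Integrative analysis of two-hormone crosstalk in four-condition sequencing
experiments — untreated (`nt`), each single hormone (`gluc`, `cort`) and the
dual treatment (`dual`) — built around the biology of glucagon and
glucocorticoid cooperation in hepatocytes. The package classifies genes as
synergistically induced or antagonized, classifies transcription-factor
binding sites as *assisted* or *unassisted* (the assisted-loading model of
TF cooperativity), scans sequences for GRE/CRE motifs by PWM log-odds, and
analyzes enhancer clusters as whole regulatory units. A ground-truthed
synthetic-data generator plants all of this structure so every stage can be
verified against known truth at desk scale.

## Who this is for

Computational biologists analyzing combinatorial hormone/stimulus designs
(RNA-seq + ChIP-seq + accessibility in factorial conditions) who need the
full inference chain — normalization, negative-binomial differential tests,
crosstalk classification, binding-site classification, motif and
enhancer-cluster statistics — as plain, tested R functions.

## The statistics at the core

**Differential expression / binding.** Per-feature NB GLM with log link,
two-group design: counts `K_ij ~ NB(mu_ij, alpha_i)` with
`mu_ij = s_j q_ij` and `Var = mu + alpha mu^2`. Size factors are
median-of-ratios (with a second pass restricted to apparent null features,
which removes contamination when a large fraction of features responds);
TF-ChIP site counts use total-tag normalization instead. Gene-wise
method-of-moments dispersions are shrunk toward a parametric trend
`alpha(mu) = a0 + a1/mu`; the Wald statistic on the log2 fold change is
referred to a t distribution with moderated degrees of freedom. A feature is
*induced* when linear FC >= 1.5 and BH-adjusted p <= 0.05.

**Synergy.** A gene is synergistically induced when it is induced in `dual`
vs `nt`, vs `gluc`, and vs `cort`, **and** its expression increase in the
dual treatment exceeds the sum of the single-treatment increases on mean
RPKM (strict inequality; a `delta` and a `raw` form of the sum rule are both
available).

**Antagonism.** A gene is glucagon-induced but antagonized by
corticosterone when it is induced in `gluc` vs `nt` *and* in `gluc` vs
`dual` (and symmetrically for the reciprocal class).

**Assisted loading.** A GR binding site is *assisted* when GR binding is
significantly higher in `dual` than in `cort` alone; *unassisted* sites are
cort-increased sites not further increased by the dual treatment. Motif
strength is the best PWM hit's log-odds divided by the consensus log-odds
(1 = consensus); scanning relaxes the threshold by 3 log-odds units to catch
near-consensus motifs on both strands.

**Enhancer clusters.** For each focal site, member enhancer units are DNase
intervals whose centers lie within +/-12.5 kb; clusters need >= 2 units.
Motif co-occurrence and signal quantification are restricted to the
accessible units, and cluster-level analyses can exclude the focal unit to
test whether activation spans the cluster.

## Worked example

```r
library(synergyseq)

cfg <- sim_config(seed = 1,
                  n_per_class = c(null = 1000, gluc_only = 100,
                                  cort_only = 100, additive = 100,
                                  synergistic = 100, antag_by_cort = 100,
                                  antag_by_gluc = 100),
                  n_assisted = 20, n_unassisted = 20, n_inactive = 10)

## gene-level crosstalk
sim <- simulate_counts(cfg)
cm <- sim$counts
rmeans <- condition_means(rpkm(cm), cm$conditions)
syn <- classify_synergy(nb_wald_test(cm, "nt", "dual"),
                        nb_wald_test(cm, "gluc", "dual"),
                        nb_wald_test(cm, "cort", "dual"), rmeans)
length(syn$synergistic)
#> synergistic genes called: 95

## site-level assisted loading
g <- simulate_genome(cfg)
gr <- simulate_site_counts(g, assay = "GR")
cls <- classify_grbs(differential_binding(gr, "nt", "cort"),
                     differential_binding(gr, "cort", "dual"))
table(called = cls$table$class, planted = g$truth$site_class)
#>             planted
#> called       assisted inactive unassisted
#>   assisted         20        0          0
#>   other             0       10          0
#>   unassisted       0         0         20

## motif strength and enhancer clusters
site_cls <- g$truth$site_class[g$annotation$grbs$name]
mean_motif_score(g$annotation$grbs[site_cls == "assisted", ],
                 g$sequence, g$pwms$gre)$mean_score   # 0.62
mean_motif_score(g$annotation$grbs[site_cls == "unassisted", ],
                 g$sequence, g$pwms$gre)$mean_score   # 0.85
cl <- detect_clusters(g$annotation$grbs[site_cls == "assisted", ],
                      g$annotation$dhs)
cluster_co_occurrence(cl, g$sequence, g$pwms$gre, g$pwms$cre,
                      focal_only = TRUE)$percent      # 65
cluster_co_occurrence(cl, g$sequence, g$pwms$gre, g$pwms$cre)$percent # 100
```

Of 100 planted synergistic genes, 95 are called (the other gene classes
supply almost no false calls); all 20 planted assisted and 20 unassisted GR
sites are classified correctly with the 10 inactive sites left as `other`;
planted weak GREs score 0.62 vs 0.85 for strong GREs; and scanning whole
clusters instead of just the focal enhancer raises GRE+CRE co-occurrence
from 65% to 100% — the cluster-level gain the assisted-loading model
predicts.

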