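# cocaRank

Knowledge-guided gene ranking by **coordinative component analysis (COCA)**.

## What problem this solves

Biologists studying a pathway or process usually have a short curated list
of member genes and an expression matrix, and want to know *which other
genes participate in that process under these conditions*. Per-gene
statistics (fold-change, t/SAM) ignore co-regulation; unsupervised
decompositions (PCA/ICA) extract components with no guaranteed biological
relevance. COCA is the semi-supervised middle ground: the knowledge genes
guide the extraction of a single linear component, and every gene is then
ranked by its participation in it.

Under the linear latent model `X = A T` (genes × samples expression as a
mixture of a few process activities), COCA finds a unit *coordinative
direction* `w` in sample space maximizing the masked ratio

```
J(w) = Σ_{j ∈ knowledge} |x_j·w|  /  ( Σ_{j ∈ background} |x_j·w| + ε )
```

by simultaneous-perturbation stochastic approximation (SPSA; two objective
evaluations per gradient estimate regardless of dimension). Background
genes are bootstrap-resampled B times to avoid over-fitting the unbalanced
knowledge-vs-background comparison; replicate directions are
sign-corrected and the participation vectors `A = X w` bagged. Genes are
ranked by `|bagged participation|`. The package also ships the simulators
(one- and two-condition linear-model data with controlled SNR in dB),
baseline rankers (variance, fold-change, SAM-style moderated t, PCA-guided
correlation) and ROC/AUC utilities, so the comparative benchmark runs
entirely offline.

## Worked example

Simulate a one-condition dataset (2000 genes, 8 samples, 5 latent
processes, SNR 10 dB), guide COCA with 50 of the 200 ground-truth genes,
and compare with unguided variance ranking:

```r
library(cocaRank)

design <- simulationDesign("one_condition", nGenes = 2000)
sim <- simulateOneCondition(design, seed = 1)

res <- runCOCA(sim$x, knowledgeGenes(sim$truth),
               plan = bootstrapPlan(nBoot = 20), seed = 2)
res
#> ParticipationResult: 2000 genes, 20 bootstrap replicates
#>   top genes: g0014, g0232, g0206, g0274, g0277 ...

head(rankingTable(res), 3)
#>   rank  gene     score abs_score        sd method
#> 1    1 g0014 -6.165099  6.165099 1.2301485   coca
#> 2    2 g0232 -5.455530  5.455530 0.7807599   coca
#> 3    3 g0206  5.248146  5.248146 0.5805636   coca

detectionAccuracy(res, truthGenes(sim$truth))
#> [1] 0.735
detectionAccuracy(varianceRank(sim$x), truthGenes(sim$truth))
#> [1] 0.215
```

COCA recovers 73.5% of the ground-truth process members in the top 200,
versus 21.5% for variance ranking — guidance is worth more than a factor
of three here. `snrSweep()` repeats this comparison over an SNR grid with
replicates, and `evaluateRanking()` scores any ranking by ROC/AUC against
a positive gene list (optionally excluding the guidance genes, so only
genuinely discovered genes count).

A thin command-line front end is installed at
`system.file("scripts", "coca.R", package = "cocaRank")` with subcommands
`rank`, `baseline`, `simulate`, `evaluate`, `benchmark`.

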