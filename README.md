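# combiscreen

Simulation and analysis of **pooled combinatorial CRISPR-activator
screens** read out by FACS bin sorting and barcode/UMI sequencing.

Combinatorial activator libraries fuse 1–3 activation domains (ADs) and
inert protein folders (PFs) onto a programmable scaffold (e.g. MCP
recruited to dCas9), tag every part with an 8-nt barcode and every
transduction event with a 6-nt UMI, transduce at low MOI, sort cells into
four extreme fluorescence bins, and sequence each bin plus the unsorted
population and the plasmid pool. `combiscreen` is aimed at analysts of
such screens and at method developers who need a generative model with
known ground truth: it implements read extraction, UMI filtering,
activation and toxicity scoring, the construct-level combinatorial
analyses (order, position, copy number, additivity), and biochemical
featurization of AD sequences — plus a full synthetic screen simulator
to validate every stage end to end.

## The statistics at the core

For each construct, UMIs are pooled into prefix groups and, per sorted
condition, group counts are rescaled so their mean is 100. A
sufficiently covered UMI group with normalized bin profile
*r*<sub>1..4</sub> and per-sort bin mean fluorescence intensities
*MFI*<sub>1..4</sub> gets the **activation score**

> score = Σ<sub>bin=1..4</sub> *r*<sub>bin</sub> × *MFI*<sub>bin</sub>

and a construct's score is the mean over its UMI groups, then over
replicates. **Toxicity** is dropout of transduced cells relative to the
plasmid pool, with all UMIs pooled and one pseudoread guarding zeros:

> toxicity = −log₂ ((*reads*<sub>cells</sub> + 1) / (*reads*<sub>plasmid</sub> + 1))

(higher = more toxic), averaged over the endogenous-target populations
× replicates. AD sequence features include net charge per residue,
Kyte–Doolittle hydropathy (rescaled to [0, 9]), disorder-promoting
fraction, and the blob-patterning statistics **kappa** (K/R vs D/E
mixing) and **omega** (W/F/Y/L vs D/E mixing; lower = better mixed).

## Worked example

```r
library(combiscreen)

cfg <- simConfig(n_ads = 8, n_pfs = 2, arity = 2,
                 n_cells = 1e5, read_depth = 1e5, seed = 7)
sim <- simulateScreen(cfg)
sim
#> ScreenSim: 100 constructs (arity 2 ) | 42860 count rows | seed 7

scores <- scoreScreen(simCounts(sim), simMfi(sim),
                      filterConfig(umi_prefix_length = 2))
head(activationScores(scores), 3)
#>   construct_id  target activation_score n_groups
#> 1      A01-A01 targetA         5112.273        5
#> 2      A01-A02 targetA         4414.539        1
#> 3      A01-A03 targetA         5926.562        7
head(toxicityScores(scores), 3)
#>   construct_id toxicity_score n_populations
#> 1      A01-A01      0.4723300             4
#> 2      A01-A02      1.8734217             4
#> 3      A01-A03     -0.1014284             4
```

The activation score is in fluorescence-weighted read units: constructs
whose reads concentrate in the brightest bins score high (here, up to a
few thousand, the bin-4 MFI times the ~400 normalized reads a fully
shifted construct can carry). Toxicity is in log₂ depletion units: the
`A01-A02` clone above dropped ~3.7-fold relative to the plasmid pool
across the four populations, while `A01-A03` is neutral.

Because the simulation carries its own ground truth, recovery is a
one-liner:

```r
truth <- simLatent(sim)$construct_truth
act <- subset(activationScores(scores), target == "targetA")
m <- merge(act, truth, by = "construct_id")
cor(m$activation_score, m$strength, method = "spearman")
#> [1] 0.8686691

orderEffectCorrelation(act)$r   # forward vs reverse fusion order
#> [1] 0.898

kappaScore("EEEEEKKKKK")        # fully segregated charges
#> [1] 1
kappaScore("EKEKEKEKEK")        # perfectly mixed
#> [1] 0.0021
```

A shell interface to the same stages (simulate / extract / score /
toxicity / analyze / features / report) is installed at
`inst/exec/combiscreen`.

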