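# cellfuse

Survival prediction from whole-slide images (WSIs) at the cellular level.
`cellfuse` consumes the output of an upstream nuclei
segmentation/classification network (per-block JSON with nucleus centroids
and PanNuke-style class labels), reduces each gigapixel slide to a
3-channel **embedded WSI map** — per-64×64-pixel-window counts of
neoplastic, inflammatory and miscellaneous nuclei — and trains a
**dual-branch global fusion network** on those maps to predict a scalar
survival risk.

The two branches read the same map with complementary biases: an
MLP-Mixer-style branch (alternating token-mixing and channel-mixing
residual MLPs) captures the global composition of the cell population,
while a multi-head self-attention branch captures inter-patch context.
Each branch mean-pools its tokens to a 128-length feature; the features
are concatenated with the survival-event indicator μ into a 257-length
vector and mapped by one fully connected layer to the risk *r*. Training
minimizes the negative Cox log partial likelihood

    L = Σ_i μ_i · ( −r_i + log Σ_{j : t_j ≥ t_i} exp r_j ),

with Breslow handling of ties and mini-batch risk sets. Evaluation uses
the concordance index, Kaplan–Meier curves, two-sided log-rank tests and
low/high-risk stratification at an optimal quantile-scheme cutoff, under
stratified five-fold cross-validation.

The network, its hand-derived backpropagation and the Adam trainer are
implemented directly in R matrix algebra; the survival machinery delegates
Kaplan–Meier and log-rank computations to the `survival` package. A
synthetic-cohort generator with planted proportional-hazards ground truth
(known per-class nucleus totals, known log-hazard as a function of map
composition) makes every stage testable without external slides. Intended
users are computational-pathology researchers prototyping survival models
on nuclei-level WSI summaries.

## Worked example

Generate a small synthetic cohort, train the desk-scale model, and
evaluate a held-out set:

```r
library(cellfuse)

spec   <- synth_spec(n_patients = 260, seed = 101)
cohort <- generate_cohort(spec)
prof   <- model_profile("desk")

inputs <- prepare_model_inputs(cohort$maps, prof$train$input_resolution,
                               prof$train$normalize)
tr <- 1:200; te <- 201:260

model <- fusion_model(prof$mixer, prof$vit, seed = 1)
fit   <- train_fusion(model, inputs[tr], cohort$survival$time[tr],
                      cohort$survival$event[tr], prof$train)

ev <- evaluate_fusion(fit, inputs[te], cohort$survival$time[te],
                      cohort$survival$event[te])
ev$cindex
#> [1] 0.818
ev$stratification$p_value
#> [1] 3.7e-12
concordance_index(cohort$truth$eta[te], cohort$survival$time[te],
                  cohort$survival$event[te])
#> [1] 0.878
```

The trained model's held-out concordance (0.82 here) approaches the oracle
concordance of the planted log-hazard (0.88): the network has recovered
most of the compositional survival signal from the maps alone. The
log-rank p-value shows the induced low/high-risk split separates the
held-out survival curves. (Numbers are from the run shown; other seeds
vary by a few points.)

Block-level ingestion of real segmentation output follows the same path:

```r
man      <- read_block_manifest("slide01/manifest.csv", block_size = 8000)
tables   <- Map(read_block_nuclei, man$paths, man$blocks)
stitched <- stitch_blocks(unname(tables), man$blocks,
                          slide_width = 80000, slide_height = 60000)
mapped   <- map_classes(stitched)
emap     <- build_embedded_map(mapped, window_size = 64)
```

A thin command-line front end (`inst/cli/cellfuse`) exposes the same
operations as subcommands (`synth`, `ingest`, `embed`, `split`, `train`,
`eval`, `cv`, `project`).

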