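# fedlesion

Federated simulation of volumetric lesion segmentation in R, for
researchers studying how multi-site segmentation models behave when the
sites cannot pool their images.

Multi-site white-matter-lesion studies face two coupled problems:
**domain shift** (each scanner/protocol produces systematically different
intensity, contrast and noise) and **heterogeneous lesion burden** (the
lesion-to-brain volume ratio differs strongly across sites, and
small-lesion sites train more slowly on the class-imbalanced soft Dice
objective). `fedlesion` implements the **FedMSRW** strategy addressing
both, alongside FedAvg, FedBN and FedProx baselines, inside a
single-process federation simulator with a built-in 3-D phantom
generator — no GPU, no external data, fully deterministic under seeds.

## The method

Each client $i$ trains a 3-D U-Net $M_i$ with parameters
$\theta_i = \{\theta_i^{bn}, \theta_i^r\}$ (batch-norm state vs the
rest) on the smoothed soft Dice loss

$$L_{dice} = 1 - \frac{2\sum p\,y + \varepsilon}{\sum p^2 + \sum y^2 + \varepsilon}.$$

Building on the FedBN premise, $\theta_i^{bn}$ (including running
statistics) never leaves the client. FedMSRW adds two re-weightings:

* **Ability-weighted central aggregation.** Each lesion-bearing training
  patch yields the ability score
  $P_i = \frac{\sum p\,y}{\sum y}\,\bigl(1 - L_{dice}\bigr)$
  (in-lesion confidence × segmentation accuracy). The server aggregates
  the shared parameters as
  $\hat\theta^r = \sum_i \theta_i^r P_i \,/\, \sum_i P_i$,
  so stronger local models steer the global model.
* **Lesion-volume loss re-weighting.** Clients accumulate the running
  mean lesion-to-brain volume ratio $vr_i$ of their training patches;
  client $i$'s next round minimizes
  $\frac{\sum_j vr_j}{N\,vr_i}\,L_{dice}$, boosting small-lesion
  clients.

Ablations (`fedmsrw_ca_only`, `fedmsrw_lt_only`, `ours_ent`, `ours_vol`)
isolate each component or swap in whole-map entropy / raw lesion voxel
counts. Evaluation reports case-wise Dice (C-Dice), pooled voxel-wise
Dice (V-Dice), TPR and FPR in percent, with patch-tiled overlap-averaged
whole-volume inference. See the vignette
(`vignettes/federated-lesion-segmentation.Rmd`) for the full model
description and numerical conventions.

## Worked example

Two clients with strong appearance shift (intensity offsets 0 vs +50)
and a 4× difference in lesion burden; 6 training and 2 held-out cases
each:

```r
library(fedlesion)

profiles <- list(
  client_profile("siteA", n_cases = 8, volume_shape = 24, target_ratio = 0.01,
                 lesion_radius_range = c(2, 3), intensity_offset = 0,  noise_sigma = 5),
  client_profile("siteB", n_cases = 8, volume_shape = 24, target_ratio = 0.04,
                 lesion_radius_range = c(2, 3), intensity_offset = 50, noise_sigma = 5))
fed <- generate_federation(profiles, rng_seed = 1)
train <- lapply(fed, function(cs) cs[1:6])
test  <- lapply(fed, function(cs) cs[7:8])

fit <- fedlesion(train, mode = "fedmsrw",
                 network = network_config(depth = 2, base_channels = 4),
                 n_rounds = 5, iters_per_round = 50, batch_size = 4,
                 patch_size = c(16, 16, 16), lr = 0.05, lr_schedule = "poly",
                 master_seed = 1)
fit
#> Mode: fedmsrw | clients: siteA, siteB | 5 round(s) x 50 iteration(s), batch 4, patch 16x16x16
#> Final round mean Dice loss: siteA=3.364, siteB=0.091

h <- fit$history
h[h$round == 5, c("client", "ability", "agg_weight", "vr", "next_loss_weight")]
#>  client   ability agg_weight          vr next_loss_weight
#>   siteA 0.6005988  0.4693532 0.006554129        4.3858553
#>   siteB 0.6790321  0.5306468 0.050936797        0.5643359
```

The history shows the mechanism at work: siteA's accumulated
lesion-volume ratio (`vr` ≈ 0.007) is far below siteB's (≈ 0.051), so
siteA trains with a ≈ 4.4× loss weight (which is why its *weighted*
round-5 mean loss of 3.36 exceeds 1), and the server mixes the shared
parameters by the clients' abilities rather than uniformly. Held-out
evaluation with each client's assembled model (global shared weights +
private batch-norm state):

```r
masks <- c(predict(fit, test$siteA, client = "siteA"),
           predict(fit, test$siteB, client = "siteB"))
truth <- lapply(c(test$siteA, test$siteB), `[[`, "lesion_mask")
evaluate_cases(masks, truth)
#> <metrics_report over 4 case(s)>
#>   C-Dice  90.61  V-Dice  90.36  V-TPR  87.81  V-FPR   6.94  (percent)
```

The same data under `mode = "fedavg"` (everything averaged, batch-norm
included) reaches only V-Dice ≈ 45 on this federation — the gap the
method exists to close. A cross-validated experiment driver
(`run_experiment()`) and a command-line interface
(`inst/cli/fedlesion.R` with `simulate-data` / `train` / `evaluate` /
`experiment` subcommands) are included.

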