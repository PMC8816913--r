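# dpfedmil

Differentially private federated multiple-instance learning for
histopathology feature bags — a tested, desk-scale R implementation of the
full pipeline: mosaic bag preparation, a permutation-invariant memory-based
set classifier, DP-SGD local training, Rényi differential-privacy
accounting, and federated averaging over IID/non-IID hospital partitions,
exercised end to end on synthetic cohorts.

## Who this is for

Researchers who want to study *how* federated and differentially private
training behave on slide-level (bag) classification — partition effects,
client counts, privacy/utility budgets — with a fully reproducible,
download-free stand-in for the real thing. A whole-slide image is reduced to
a bag `X ∈ R^{n×f}` of patch feature vectors with one binary slide label
(multiple-instance learning); hospitals are clients holding bags.

## The model and method in brief

**Set classifier.** A memory unit embeds instances, `U_i = ρ(X A_i)`, forms
`S_i = column-softmax(U_i U_iᵀ)` and `p_i = row-average(S_i)` — an attention
distribution over instances. A memory block pools a per-instance encoder
sequence `C` under `m` such attentions, `x̂_i = Σ_j p_i[j] C_j`, giving a
permutation-invariant `m×h` representation fed to a softmax head. Gradients
are hand-derived and verified against finite differences.

**DP-SGD.** Per-microbatch gradients clipped to global L2 norm `C`, summed,
one Gaussian noise draw of sd `σ·C`, averaged, then SGD/Adam.

**Accounting.** Per-step Rényi DP of the subsampled Gaussian mechanism
(binomial moment sum at integer orders, numerical integration otherwise),
linear composition over `T = round(epochs·N/B)` steps, classical conversion
`ε = min_α T·RDP(α) + log(1/δ)/(α−1)` over the standard order grid.

**Federation.** FedAvg: local epochs per round, sample-size-weighted
parameter averaging, full participation, per-round central evaluation; IID
partitions deal classes round-robin, non-IID partitions sample clients from
normalized uniform weights per class.

## Worked example

```r
library(dpfedmil)

# price the reference DP-SGD run: pooled N = 705, batch 32, 180 epochs
epsilon_for_run(N = 705, B = 32, epochs = 180, sigma = 4.0, delta = 1e-4)
#> (epsilon = 3.406, delta = 0.0001)-DP  [q = 0.04539, sigma = 4, steps = 3966, best order = 7]

# a synthetic bag and its classification by an untrained model
bag <- make_bag(bag_spec(n_instances = 30, feature_dim = 16,
                         signal_fraction = 0.2, class_separation = 2,
                         noise_scale = 1, seed = 7), label = 1)
model <- mem_init(feature_dim = 16, n_units = 2, mem_dim = 4, hidden_dim = 8,
                  seed = 1)
classify(bag, model)
#>         0         1
#> 0.4763712 0.5236288
```

The `epsilon_for_run` line reads: with noise multiplier 4 the whole 3966-step
training run is (ε = 3.41, δ = 1e-4)-differentially private, the minimum
over the order grid being attained at Rényi order 7. The `classify` output
is the bag's class-probability pair (it sums to 1 and does not change if the
bag's instances are permuted).

The `analysis/` scripts run the full study in order — cohort simulation,
bag preparation, privacy budgets, the client-count/distribution sweep
(series 1), and the DP federation over the four-hospital cohort (series 2)
— writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_bag_preparation.R
Rscript analysis/03_privacy_budgets.R
Rscript analysis/04_series1_fedavg.R      # ~15 min
Rscript analysis/05_series2_dp_federation.R
```

The series-1 sweep prints the study's qualitative picture on the synthetic
cohort (five replicate seeds, shared pooled test set):

```
distribution    n  without FL      with FL         centralized
iid             4  0.856 +/- 0.025 0.873 +/- 0.024 0.902 +/- 0.041
iid             8  0.777 +/- 0.061 0.790 +/- 0.070 0.902 +/- 0.041
noniid          4  0.703 +/- 0.080 0.841 +/- 0.051 0.902 +/- 0.041
noniid          8  0.601 +/- 0.042 0.754 +/- 0.079 0.902 +/- 0.041
```

Federated training beats non-collaborative training in every cell (19 of 20
replicate comparisons), the gap widens under non-IID partitions and larger
client counts, and centralized pooling bounds both from above.

See `vignettes/methods.Rmd` for the model, the accounting assumptions, the
synthetic-data design and its limits.

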