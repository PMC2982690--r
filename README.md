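# phasenet

Directed gene regulatory network inference from **short expression time
series** (7–20 equally spaced samples), the regime of classical
synchronised-microarray experiments: a yeast cell-cycle elutriation
series of 24 genes × 14 half-hour samples, or a triplicate p53-pathway
series of 16 genes × 7 two-hour samples.

## Who this is for

Systems biologists with a small panel of genes measured over a short,
regular time grid who want (i) a ranked, thresholded set of putative
regulatory pairs and (ii) a *direction* for each pair, without fitting a
dynamical model to data that could never support one.

## The method

For each of the `n(n−1)/2` gene pairs, three association metrics are
computed from the log2 expression series `x`, `y`:

* **Pearson correlation** `r = cov(x,y)/(σ_x σ_y)` with the exact
  two-sided P-value from `t = r√((T−2)/(1−r²))` on `T−2` df;
* **mutual information** `I = Σ p(x,y) log₂[p(x,y)/(p₁(x)p₂(y))]` in
  bits, on an equal-width joint histogram (cube-root bin rule: 3 bins at
  T = 14);
* the **associativity measure** `AM = √((w₁·MI)² + (w₂·|r|)²)`, the norm
  of the pair projected onto orthogonal MI/correlation axes with
  weights `wᵢ = 1/centroid` so both axes have mean 1.

Pairs are partitioned by the **pairwise gene hierarchy criterion**:
authentic pairs (APGs) clear the MI threshold *and* the correlation
threshold at significance `p ≤ p_th`; questionable pairs (QPGs) clear
exactly one side; unauthentic pairs (UPGs) clear neither. Thresholds
start at the metric centroids and step by ±δ (default 0.005) until the
APG fraction lands in a target band (default 30–45 % of all pairs), a
supervised combinatorial-optimization loop that also accepts
prior-knowledge constraints (forced / forbidden edges).

Direction comes from signal processing: each pair is treated as an
input/output subsystem and its Welch cross-spectrum gives the
magnitude-squared coherence `C = |CPSD|²/(PSD_aa·PSD_bb)`, the transfer
gain `|CPSD|/PSD_aa`, and the transfer phase. At the pair's dominant
(max-coherence) frequency, a reliable call (coherence ≥ 0.9, both
transfer gains ≥ the gain threshold) is oriented by the phase sign —
the gene that leads in phase regulates the one that lags; phases within
5° are reported as undirected associations.

A ground-truthed simulator (`planted_network()` /
`simulate_expression()`) generates elutriation-like data — a few
regulator hubs driving lag-coupled targets at cell-cycle periods plus
noise-only genes — so the whole pipeline is testable without any
external dataset.

## Worked example

```r
library(phasenet)

sim <- simulate_expression(planted_network())   # 24 genes x 14 points,
                                                # 20 planted edges, seed 42
fit <- infer_network(sim$profile)
fit
#> Directed regulatory network inference
#>   24 genes, 14 time points, 276 pair candidates
#>   centroids: MI 0.4346 bits, |r| 0.4435; P threshold 0.05
#>   thresholds after 0 iterations (converged): MI 0.4346, |r| 0.4435
#>   partition: 88 authentic / 58 questionable / 130 unauthentic
#> Regulatory network: 24 nodes (0 isolated), 49 directed and 39 undirected edges

score_recovery(fit, sim$truth)
#> $recall                 0.75   # 15 of 20 planted edges in the APGs
#> $orientation_accuracy   1      # all 13 directed recovered edges point
#>                                # from the planted regulator to its target
```

Reading: the 276 pair candidates of 24 genes were scored, the
centroid-initialised thresholds already put 88 pairs (32 %) in the
authentic group, and the phase stage oriented 49 of those pairs. 15 of
the 20 planted couplings were recovered as authentic, and every
recovered pair with a detected phase shift was oriented correctly.

Export and inspect:

```r
export_network(fit$network, "network.sif", "sif")       # or graphml / edge-table
head(degree_summary(fit$network))
plot(fit)
```

## Command line

```sh
Rscript inst/cli/phasenet.R simulate --genes 24 --edges 20 --seed 42 --out sim/
Rscript inst/cli/phasenet.R infer --input sim/expression.tsv --out run/
Rscript inst/cli/phasenet.R phase-sweep --input sim/expression.tsv \
        --thresholds 0,0.3,1
```

`infer` also takes a YAML config (`--config run.yaml`) with keys
`input`, `out_dir`, `bins`, `band`, `gain_thresholds`, `knowledge`,
`seed`, …; every run writes pair statistics, the partition, per-pair
phase calls, network files per gain threshold, and a run log with the
full threshold iteration trace. Exit codes: 0 ok, 1 input error,
2 non-convergence.

## Documentation

The methods vignette (`vignettes/directed-network-inference.Rmd`)
describes the model, every tunable parameter with its default and
units, what the simulator does and does not emulate, and the known
limitations of MI estimation and spectral phase at 14 samples.
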