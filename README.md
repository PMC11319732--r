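# epibind

Sequence-binding models of monoclonal antibodies (mAbs) from near-random
peptide microarrays, and the question such models can answer: given
binding measurements of one antibody against ~10^5 random peptides, can a
model pick the antibody's cognate linear epitope out of a million random
sequences — and say which of its residues carry the binding?

The package is aimed at people analyzing peptide-array binding screens
(or designing methods for them): it implements the full analysis chain as
tested, reusable functions, plus a synthetic ground-truth generator so
the chain can be validated end-to-end without proprietary array data.

## The method in brief

Peptides (5–11 residues over the 16-letter alphabet `ADEFGHKLNPQRSVWY`)
are assayed at four concentrations (0.125/0.5/2/8 nM) in quadruplicate.
The pipeline:

1. **Averaging & saturation correction** — replicates are averaged as
   mean log10 counts; values at the 16-bit detector ceiling (65,536) are
   replaced by the next-lower concentration's value + log10(ratio),
   exploiting linearity of binding in concentration.
2. **Encoding** — each peptide is framed as `"(" + seq + ")"` padded with
   `X` to a fixed width and one-hot encoded over 19 tokens.
3. **Preprocessing ablations** — scarce high binders are up-weighted
   (bins of 0.2 log10 units on the 8 nM values grown to 300 members,
   max 100 copies per pair); each pair is expanded into 6 register-shifted
   frames; and the order-independent *composition* component (OLS of
   log10 binding on residue counts) is subtracted before training and
   added back at prediction.
4. **Model** — a fully connected network, 2 hidden layers × 250 ReLU
   units, predicting all four concentrations at once; trained with Adam
   on (weighted) MSE; ensembles of independently initialized networks are
   averaged.
5. **Evaluation** — the cognate's rank among n random same-length
   sequences (ranked per concentration, best rank kept, deterministically
   re-ranked; percent rank = 100·rank/(n+1)); single-residue substitution
   scans normalized to the cognate at 2 nM; antigen tiling by overlapping
   7-mers (I→V, T→S, M→L, C→S mapping for the four absent residues);
   robustness suites (similarity filtering at identity thresholds 6..2,
   training-set downsampling).

A `binding_landscape` generator plants a motif with known per-position
energies and composition coefficients, simulates the full assay
(background ≈ 850 counts, log-normal replicate noise, detector ceiling),
and serves as the oracle every stage is tested against. Two frozen
presets emulate the regimes real mAbs show: `abundant-signal` (thousands
of partial-motif probes above background) and `scarce-signal` (a few
dozen), the latter being where weighting and shifting are decisive.

## Worked example

Simulate the abundant-signal preset, train one full-pipeline model, and
ask where the planted cognate ranks among 100,000 random 7-mers:

```r
library(epibind)

sim <- simulate_preset("abundant-signal", n_peptides = 30000, seed = 5)
cfg <- model_config(weighting = TRUE, shifting = TRUE, composition = TRUE,
                    epochs = 10, seed = 42)
model <- train_binding_model(sim$binding_table, cfg)

randoms <- random_library(1e5, nchar(sim$cognate), seed = 9)
rank_cognate(model, sim$cognate, randoms)
#> Cognate PLEEVLN: rank 1 of 100001 (0.0010%)

scan  <- substitution_scan(model, sim$cognate)   # L x 16, wild type = 1
truth <- true_substitution_matrix(sim$landscape, sim$cognate)
cor(as.vector(unclass(scan)), as.vector(truth))
#> [1] 0.9283342
```

The planted epitope is the single best binder among 100,001 candidate
sequences (percent rank 0.001%), and the model's substitution scan —
which residues tolerate which replacements — correlates at r = 0.93 with
the generative truth. The `analysis/` directory contains numbered driver
scripts that run the full study (simulation + QC, the ablation ladder,
epitope maps, robustness suites) and write their tables under `results/`.

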