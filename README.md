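# gtloc

Multi-task graph learning for protein function and multi-label subcellular
localization, in pure R.

## The problem

Where a protein lives in the cell is a multi-label property (one protein
can occupy several compartments) and is tightly coupled to what the protein
does. Predictors that ignore function lose that signal; predictors that
look up curated GO annotations at test time cannot handle unannotated
proteins. `gtloc` implements a multi-task collaborative model that *learns*
function prediction (GO biological process, cellular component and
molecular function) as auxiliary tasks and feeds the learned functional
features into the localization head.

The model, per protein with `n` residues:

1. **Residue contact graph** — nodes are residues at their Cα positions;
   edges connect pairs with `‖x_i − x_j‖ ≤ 4.5 Å`. Edge features (42-d)
   encode the distance, sine/cosine of the displacement at geometric
   frequencies, displacements to the five nearest residues, and summed
   neighbour distances. Node features are per-residue embeddings from a
   pluggable provider (a protein language model in production; a synthetic
   Gaussian provider for offline work).
2. **Graph transformer (GT)** — `L` layers of multi-head attention
   restricted to contact edges, with edge features gating the attention
   channel-wise: `w_ij = softmax_{j∈N(i)} ((Q_i ⊙ K_j)/√d_k ⊙ E_ij)`.
   Both node and edge streams carry residual feed-forward blocks with
   batch norm and SiLU.
3. **Ontology branches** — per ontology, two affine layers, then a
   graph-autoencoder: one GCN layer
   `H = LeakyReLU(D̂^{-1/2}(A+I)D̂^{-1/2} H W)` whose inner-product decoder
   `Â = σ(HHᵀ)` is trained to reconstruct the adjacency (MSE over all n²
   entries). Self-attention pooling + MLP produce GO term scores.
4. **Functional cross-attention** — dense multi-head attention with queries
   from BP, keys from MF, values from CC features (three independent
   groups, averaged), fused into localization features.
5. **Localization head** — self-attention pooling + MLP → sigmoid scores
   over localization classes. The pooling scores, min–max normalized,
   are exported as per-residue importance.

Training minimizes the collaborative loss

```
L = α·(L_bp + L_cc + L_mf)  +  β·(L_bp_mse + L_cc_mse + L_mf_mse)  +  ω·L_sl
```

with Adam; ablation flags (`no_gt`, `no_funA`, `no_feaE`, `no_colT`)
reroute the forward pass or the loss weights exactly.

All tensor math runs on a small reverse-mode autodiff tape shipped in the
package (validated against finite differences), so there is no
deep-learning-framework dependency.

## Worked example

Generate a small synthetic dataset with planted motif→GO→localization
structure, train, and evaluate:

```r
library(gtloc)

sc   <- sim_config(n_proteins = 60, len_range = c(20L, 30L), d_h = 16L,
                   catalogue = default_motif_catalogue(k = 8L, mu = 4),
                   noise_rate = 0.05, seed = 7)
recs <- generate_records(sc)

cfg  <- model_config(d_h = 16L, d_p = 32L, h_d = 4L, n_layers = 2L,
                     d_fe = 16L, d_F = 16L, h_ki = 4L,
                     M_bp = 8L, M_cc = 5L, M_mf = 5L, C = 4L,
                     beta = 0.2, lr = 3e-3, batch_size = 4L, epochs = 10L,
                     seed = 7)
ds   <- prepare_dataset(recs, config = cfg)
sp   <- split_dataset(seq_along(recs), seed = 7)

model <- train_model(init_model(cfg), subset_dataset(ds, sp$train),
                     valid_data = subset_dataset(ds, sp$valid))
ev    <- evaluate_model(model, subset_dataset(ds, sp$test))
print(ev$sl)
```

```
#> metric_report: AP 0.7899 | AUROC 0.7014 | AUPR 0.7899 | Acc 0.4861 | Fmax 0.7358 (tau 0.63)
#>   Hloss 0.3750 | RL 0.2917 | Oerror 0.1667
```

The report fields: `AP`/`AUROC`/`AUPR` are macro averages over the
localization classes (higher is better); `Acc` is example-based Jaccard
accuracy and `Hloss` the Hamming loss at threshold 0.5; `Fmax` is the
protein-centric CAFA F-measure with its maximizing threshold; `RL` (ranking
loss) and `Oerror` (one-error, top-scored label not a true one) are
minimization metrics. Ten epochs on 48 training proteins is only a smoke
run — the shipped experiments below train 30 epochs on 240 and reach
test AUROC above 0.8 on both task families.

Per-residue importance for interpretability:

```r
pred <- predict_proteins(model, ds$graphs[1], ids = ds$ids[1])
round(pred$importance[[1]], 2)[1:10]
#>  [1] 0.30 0.81 0.49 0.87 0.60 0.70 0.70 0.70 0.70 0.59
```

A command-line interface wrapping the same functions ships in
`inst/scripts/gtloc` (subcommands `simulate`, `build-graphs`, `train`,
`predict`, `evaluate`, `ablate`).

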