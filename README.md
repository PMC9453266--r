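# resrepanet

Binary classification of structural brain MRI volumes (diseased vs. normal
cognition) with a 3D residual RepVGG-style attention network, built for the
regime that makes this problem hard: subtle interclass differences (mild
regional atrophy) and strong class imbalance (patients are several times
rarer than controls).

The package is a self-contained R implementation — data simulation, NIfTI
I/O, the network (forward *and* backward passes; the convolution core is
C++ im2col + GEMM over BLAS), losses, training, evaluation, saliency maps and
a command-line interface.

## The method

**ResRep blocks with exact deploy-time fusion.** Each block is a stride-2
3×3×3 conv + BN stem followed by two channel-preserving multi-branch stages:

    l1  = ReLU( f3×3×3(X') + f1×1×1(X') )
    l1' = ReLU( f3×3×3(l1) + f1×1×1(l1) + f_bn(l1) )

where every branch carries its own batch normalization. For inference each
stage is *structurally re-parameterized* into a single 3×3×3 convolution:
BN is folded into the kernel (`W' = W·γ/√(σ²+ε)`, `b' = β − γμ/√(σ²+ε)`),
the 1×1×1 kernel is embedded at the center of a 3×3×3 kernel, the identity
branch becomes a Dirac kernel, and kernels/biases are summed. Fusion is
algebraically exact (tested to 1e−10 per stage, 1e−8 end to end, in double
precision).

**NCSA (non-local context spatial attention).** Query/key/value 1×1×1
embeddings `F_φ, F_θ, F_δ`; the key embedding is pooled over space with
softmax weights `β(G_i) = e^{G_i}/Σ_m e^{G_m}`, passed through a
conv–LayerNorm–conv channel transform and average-pooled into a context
vector `G″`, which modulates the key branch channel-wise. The pairwise
affinity `F_φ (G″ ⊙ F_θ)ᵀ` is row-softmaxed into attention weights that
aggregate the value embedding; the result rejoins the trunk through a
zero-initialized residual projection.

**GDMM (gradient density multi-weighting) loss.** With per-sample gradient
norm `g_n = |σ(z_n) − y_n|`, a 10-bin histogram on [0,1] defines the gradient
density `GD(g_n)` (bin count / bin width, optionally EMA-smoothed across
batches), harmonizing weights `W_n = N / GD(g_n)`, and the loss

    F_soft = − Σ_n W_n [ y_n log σ(z_n) + (1−y_n) log(1−σ(z_n)) ]

which down-weights crowded histogram regions (the easy bulk and saturated
outliers) and up-weights sparse hard samples — the mechanism that lifts
minority-class sensitivity under imbalance. Baselines for ablation: plain
CE, CE with label smoothing, focal loss, and GHM.

Real AD/NC cohorts are access-restricted, so the package ships a seeded
**synthetic phantom generator**: ellipsoidal brain volumes with two interior
regions whose intensity/size carry the class effect (`delta`), Gaussian
noise, FWHM smoothing and global-mean intensity normalization, at a
configurable imbalance ratio (default 1:3). The phantom is schematic by
design — it validates the pipeline, not clinical claims.

## Worked example

Simulate an imbalanced cohort, train the reduced network with the GDMM loss,
and evaluate:

```r
library(resrepanet)

cohort <- generate_cohort(cohort_spec(n_total = 160, imbalance_ratio = c(1, 3),
                                      effect_size = 0.3, seed = 7))
cfg <- train_config(epochs = 15, lr = 0.02, loss = "gdmm", seed = 7,
                    reduced = TRUE, verbose = TRUE)
res <- train_network(cfg, cohort)
res$report
```

```
epoch   1 lr 4.00e-03 loss 0.6625 val AUC 0.5000
epoch   2 lr 8.00e-03 loss 0.6396 val AUC 0.9583
epoch   3 lr 1.20e-02 loss 0.6044 val AUC 0.9792
...
epoch  15 lr 2.00e-02 loss 0.4395 val AUC 1.0000
ACC 1.0000 | SEN 1.0000 | SPE 1.0000 | AUC 1.0000 (threshold 0.50)
confusion: tp=4 fn=0 tn=12 fp=0
```

The 160 phantoms split 9:1 (stratified, so both parts keep the 1:3 ratio);
the checkpoint with the best validation AUC (ties broken toward later, better
calibrated epochs) is retained and `res$report` is its held-out report: on
the 16 validation phantoms (4 diseased / 12 controls) this run classifies
every case correctly. Validation metrics on 16 subjects are coarse — the AUC
moves in steps of 1/48 — which is why the per-epoch trace jumps around before
settling.

Deploy-time fusion and saliency:

```r
dep <- deploy_network(res$best_net)          # single 3x3x3 conv per stage
x   <- array(cohort$volumes[[1]]$image, c(32, 40, 32, 1, 1))
max(abs(network_forward(res$best_net, x)$logits -
        network_forward(dep, x)$logits))     # 7.1e-14: exact fusion
cam <- gradcam3d(res$best_net, x, target_class = 2, tap_stage = "res4")
```

The command-line surface wraps the same functions:

```sh
Rscript inst/cli/resrepanet.R simulate --n 160 --ratio 1:3 --seed 7 -o cohort/
Rscript inst/cli/resrepanet.R train --reduced true --loss gdmm --epochs 15 \
        --lr 0.02 --data cohort/ -o run/
Rscript inst/cli/resrepanet.R fuse run/checkpoint.rds -o deploy.rds
Rscript inst/cli/resrepanet.R gradcam --checkpoint run/checkpoint.rds \
        --input cohort/sub-0001.nii.gz -o cam.png
```

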