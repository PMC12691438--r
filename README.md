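# zsrecon

Scan-specific self-supervised reconstruction of accelerated (undersampled)
multicoil MRI, with logarithmically scaled k-space training losses.

## The problem

Parallel MRI acquires the spatial-frequency transform (k-space) of a complex
image `x` through `C` receiver coils: `y_c = F S_c x + eps_c`.  Accelerated
scans measure only a subset `Omega` of k-space, which aliases the naive
reconstruction; classical SENSE inverts the forward operator
`A = P_Omega F S` by least squares but amplifies noise at high acceleration.
Supervised deep-learning reconstructions need fully sampled reference data,
which many protocols cannot provide.

`zsrecon` implements *scan-specific self-supervision*: the acquired set
`Omega` is partitioned into disjoint subsets — `Lambda` (network input),
`Theta` (training loss), `Psi` (validation) in ratio 0.48:0.32:0.20 — and an
unrolled model-based network is trained only on the undersampled
measurements of the scan being reconstructed.  The model alternates a
conjugate-gradient data-consistency solve with learned residual priors in
the image and k-space domains,

    x_{n+1} = (A^H A + l1 I + l2 I)^{-1} (A^H y + l1 eta_n + l2 zeta_n)
    eta_{n+1}  = V^H N_i(V x_{n+1})
    zeta_{n+1} = V^H F^H N_k(F V x_{n+1})

where `V x = [x, conj(x)]` is the virtual-coil augmentation injecting
k-space conjugate symmetry (which lets the network infer the region omitted
by partial-Fourier sampling), and `l1`, `l2` are trainable weights.  A
single-domain variant (`"zs_ssl"`) drops the k-space prior.

Training losses compare predicted and measured k-space on `Theta`.  Beyond
the conventional normalized l1/l2 residuals, the package provides their
log-scaled forms

    L_p = || log(1 + |y_hat - y|) ||_p^p / || log(1 + |y|) ||_p^p

which compress the dynamic range of k-space residuals and re-balance
training toward the high-frequency components that carry edges and fine
structure.  Quality metrics (NRMSE, PSNR, SSIM, HFEN, GMSD), 1D and 2D-CAIPI
mask generation with partial Fourier, CG-SENSE baselines and a synthetic
multicoil scan generator complete the pipeline; the CNN layers and their
gradients are implemented natively (R + a small compiled kernel), so
everything runs on a plain CPU.

## Worked example

```r
library(zsrecon)

cfg <- default_config(seed = 1)           # 64x64, 8 coils, 1D R=4, 6/8 partial Fourier
cfg$losses <- c("conventional", "log_scaled")
res <- run_experiment(cfg)
print(res$comparison, digits = 4)
```

Output (metrics against the known phantom, NRMSE in percent, PSNR in dB):

```
                   method nrmse  psnr   ssim   hfen   gmsd
1             zero_filled 52.15 17.78 0.5000 0.6430 0.3201
2                cg_sense 31.84 22.06 0.5485 0.2637 0.2746
3 zero_mirid_conventional 30.70 22.38 0.5726 0.2600 0.2675
4   zero_mirid_log_scaled 30.00 22.58 0.5753 0.2527 0.2609
```

The zero-filled adjoint `A^H y` shows heavy aliasing (52% NRMSE); converged
CG-SENSE removes most of it but amplifies noise (31.8%); the
scan-specifically trained dual-domain model improves on both without ever
seeing fully sampled data, and training with the log-scaled loss improves
every metric over the conventional loss — most visibly the high-frequency
error norm (HFEN) and SSIM.

Lower-level entry points: `make_1d_mask()` / `make_caipi_mask()`,
`partition_kspace()`, `synth_scan()`, `unrolled_model()`,
`train_scan_specific()`, `reconstruct_inference()`, `compute_metric()`.
A thin command-line wrapper with `run` / `simulate` / `mask` / `train` /
`reconstruct` subcommands is installed at `inst/cli/zsrecon.R`.

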