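# netprog

Network-based cancer prognosis from gene-expression data, with higher-order
module features.

## What it does

In prognosis studies, survival is predicted from microarray expression of
thousands of genes measured on ~100 patients. `netprog` handles this with a
weighted gene-coexpression network: similarity `S(k,j) = |cor(k,j)|`,
soft-thresholded adjacency `a = S^b` (default `b = 6`, or chosen by the
scale-free topology criterion), topological-overlap dissimilarity

    d(k,j) = 1 − (l(k,j) + a(k,j)) / (min(C_k, C_j) + 1 − a(k,j)),
    l(k,j) = Σ_u a(k,u) a(j,u),   C_k = Σ_u a(k,u)

and average-linkage clustering into gene modules. Each module is summarised
by principal components, and four nested *representative feature* sets are
built from them:

| set | contents | size |
|-----|----------|------|
| R1 | first component per module (the eigengenes) | M |
| R2 | R1 plus all pairwise products (quadratics and interactions) | M(M+3)/2 |
| R3 | per-module leading components explaining 80% of variance | P |
| R4 | R3 plus all pairwise products | P(P+3)/2 |

A Cox proportional-hazards model over these features is fitted by **threshold
gradient directed regularization** (TGDR): from `β = 0`, each of K iterations
updates only the coordinates whose gradient magnitude reaches `τ · max|g|` by
`Δν = 1e-3` times their gradient, with `(τ, K)` tuned by 5-fold
cross-validation. For R2/R4 a modified variant enforces strong heredity:
whenever a product term is updated, both of its parent components are updated
too. Prediction is evaluated by cross-validated risk scores — the
median-split logrank statistic and Harrell's concordance index — and any fit
can be rewritten at the gene level (linear + quadratic + gene-pair
interaction coefficients) with the top-20 terms ranked.

A block latent-factor simulator generates module-structured expression with
Cox-model survival (constant baseline hazard 0.5, 10 true features with
Unif[−0.5, 0.5] coefficients) and independent exponential censoring
calibrated to 40%, so the full stack runs and is tested without any external
dataset.

## Worked example

A simulated study at small scale (100 genes, 10 planted modules, 200
subjects), analysed end to end with the R2 feature set:

```r
library(netprog)

cfg <- sim_config(n_genes = 100, n_modules = 10, module_sizes = rep(8, 10),
                  factor_loading_range = c(0.5, 0.9), n_factors = 2,
                  min_module_size = 5, seed = 1, n_replicates = 1)
x    <- gen_expression(cfg, seed = 1)           # genes x samples, rescaled
net  <- build_network(x, power = 6)
mods <- detect_modules(net, min_module_size = 5)
mods
#> Module assignment: 100 genes, 10 modules, 13 unassigned
#> Module sizes: 10, 10, 9, 9, 9, 8, 8, 8, 8, 8

pcas  <- module_pca(x, mods)
feats <- build_features(pcas, kind = "R2")
feats
#> Feature set R2 : 200 samples x 65 features ( 10 first-order, 55 second-order )

truth <- draw_true_model(feats, cfg, seed = 2)   # 10 causal features
surv  <- gen_survival(feats, truth$beta_true, cfg, seed = 3)
mean(surv$status == 0)                           # calibrated censoring
#> [1] 0.44

fit <- tgdr_tune(feats, surv$time, surv$status, v = 5,
                 tau_grid = c(1, 0.8, 0.6, 0.4, 0.2, 0), k_max = 300, seed = 4)
fit
#> TGDR Cox fit (modified): 65 features, 65 selected; tau = 0.00, K = 300

ev <- cv_predict(x, surv$time, surv$status, kind = "R2", v = 5, seed = 5,
                 min_module_size = 5, tau_grid = c(1, 0.8, 0.6, 0.4, 0.2, 0),
                 k_max = 300, inner_v = 3)
glance(ev)
#> # A tibble: 1 × 4
#>   kind  logrank_statistic logrank_p concordance
#> 1 R2                 67.2  2.50e-16       0.790

gm <- gene_level_coefficients(fit, feats, pcas)
head(tidy(gm), 5)
#> # A tibble: 5 × 3
#>   term        type        coefficient
#> 1 g0051       gene            0.0120
#> 2 g0050       gene            0.0115
#> 3 g0054       gene            0.00993
#> 4 g0020:g0022 interaction     0.00862
#> 5 g0053       gene            0.00818
```

Reading the output: module detection recovered the 10 planted blocks (13
weakly loading genes left unassigned); censoring landed at 44% against the
40% target on these 200 subjects; cross-validated out-of-fold scores split
the cohort into risk groups whose survival differs with a logrank chi-square
of 67.2 (p ≈ 2.5e-16) and rank 79% of usable patient pairs correctly
(concordance 0.79 — 0.5 would be chance). Here the inner cross-validation
chose τ = 0 (no thresholding), so all 65 features carry small coefficients;
the gene-level expansion then ranks individual genes and one gene-pair
interaction among the strongest terms.

`run_pipeline()` drives the same analysis from expression/survival files and
a YAML config, `run_study()` repeats the train/test simulation across feature
sets and replicates, and `inst/cli/netprog.R` wraps both for the shell.

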