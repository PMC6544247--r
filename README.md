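# edgescreen

Model-free screening of continuous features against a categorical outcome,
built for high-dimensional genomic data where effects are often nonlinear
and features are correlated. For each feature `X_i` the package tests
equality of the `J` conditional distributions

    H_0i : F_{X_i | Y=1} = ... = F_{X_i | Y=J}

with a **k-MST edge-count test**: a similarity graph `G` (union of `k`
edge-disjoint Euclidean minimum spanning trees on the pooled samples) is
built, the within-group edge counts `R_j = #{(a,b) in G : y_a = y_b = j}`
are compared with their exact permutation-null moments, and the quadratic
form

    S = (R - E R)' V(R)^{-1} (R - E R),   E(R_j) = |G| n_j (n_j - 1) / (N (N - 1))

is referred to its asymptotic chi-squared distribution with `J` degrees of
freedom (or to a label-permutation null when any group has <= 10 samples).
Because the test targets the whole conditional distribution, it detects
variance changes, bimodal splits and other symmetric effects that t/F-type
screens cannot see.

Selection across the `p` features is then done on the quantile-normalized
z-values `z_i = qnorm(pchisq(S_i, J))` by **Efron's dependence-adjusted
procedure**: the dispersion of the central z-mass,
`A = (P0 - #{|z_i|<=1}/p) / Q0` with `P0 = 2*pnorm(1)-1`,
`Q0 = 1/sqrt(pi*e)`, feeds a correction factor

    A(z) = 1 / (1 + |A| |z| phi(z) / (sqrt(2) (1 - Phi(z))))

and the cutoff `z0 = inf{ z : 1 - Phi(z) <= alpha A(z) max(1, #{z_i >= z}) / p }`;
features with `z_i > z0` are reported. With `A = 0` this is exactly
Benjamini–Hochberg on the one-sided p-values, which is also available as a
comparator, as are Welch's unequal-variance t test and a mutual-information
z test (equal-frequency discretization into `ceiling(N^(1/3))` bins,
Fisher-z transform of normalized MI).

A simulation module regenerates the benchmark designs the method was
validated on (p = 500, ten signal features with linear / cubic / quadratic /
sinusoidal transformations, logistic or latent-variable response,
independent-uniform or correlated-Gaussian features) and measures power and
false-discovery proportion for every test x procedure combination.

## Worked example

Two hundred features on 200 samples, two groups; feature 1 carries a mean
shift (+1), feature 2 a pure scale change (x 2.5) with identical means.

```r
library(edgescreen)
set.seed(11)
X <- matrix(rnorm(200 * 200), nrow = 200)   # features x samples
X[1, 101:200] <- X[1, 101:200] + 1
X[2, 101:200] <- X[2, 101:200] * 2.5
y <- rep(c("normal", "tumour"), each = 100)

res <- screen_features(X, y, method = "edgecount", procedure = "efron",
                       alpha = 0.10, k = 3, seed = 1)
res
#> screening: edgecount + efron, alpha = 0.1 -> 1 of 200 features selected
head(res$table[order(-res$table$z), ], 4)
#>      feature_id statistic    z  p_value selected
#> 2     feature_2     39.48 5.84 2.67e-09     TRUE
#> 72   feature_72      8.19 2.13 1.66e-02    FALSE
#> 139 feature_139      8.15 2.12 1.70e-02    FALSE
#> 45   feature_45      7.67 2.02 2.16e-02    FALSE
c(z0 = res$threshold, A = res$A)
#>      z0       A
#>  3.3942  0.0517
```

The edge-count screen finds the scale-only feature 2 (`S = 39.5`, one of 200
features selected at targeted FDR 0.10; the cutoff `z0 = 3.39` reflects the
estimated dispersion `A = 0.05`, close to the independence value 0). Welch's
t with BH sees the mean shift instead and is blind to feature 2:

```r
w <- screen_features(X, y, method = "welch", procedure = "bh", alpha = 0.10)
w$table[w$table$selected, ]
#>   feature_id statistic    z  p_value selected
#> 1  feature_1      5.56 5.35 4.45e-08     TRUE
```

The two screens are complementary: the edge-count test pays for its
generality with lower power against pure location shifts, and repays it on
distributional effects the t test cannot represent.

A shell interface wraps the same pipeline
(`inst/cli/edgescreen run --matrix M.tsv --labels L.tsv --method edgecount
--mt efron --alpha 0.10 --kmst 3 --seed 7 --out results.tsv`, plus an
`edgescreen simulate` subcommand for the benchmark grid), writing a ranked
TSV with header comments recording method, alpha, k, seed and threshold.

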