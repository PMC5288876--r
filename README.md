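# cmtkin

Center-manifold stability analysis of nonlinear protein-assembly kinetics.

## The problem

Cytoskeletal polymers (microtubules, actin filaments) switch intermittently
between growth and shrinkage — *dynamic instability*. A minimal kinetic
picture tracks three monomer pools: the ATP/GTP-bound, assembly-active
monomer **X**, the ADP/GDP-bound monomer **Y** sitting at the oligomer tip
**W** (held constant), and the released ADP/GDP-bound monomer **Z** that
re-activates by exchanging its spent cofactor for a fresh one at supply
rate `p`:

    dX/dt = -D1·W·X + p·Z - k·X
    dY/dt =  D1·W·X - D2·Y            with  X + Y + Z = M  conserved
    dZ/dt =  D2·Y  - p·Z + k·X

Because assembly is diffusion-limited and the diffusion coefficient of a
protein falls with its concentration, fluctuations `x = X - Xe`,
`z = Z - Ze` about the steady state feed back on their own rates, giving a
quadratic (nonlinear) fluctuation system:

    dx/dt = (-D1·W + a·Xe - k)·x + a·x² + (p - b·Xe)·z - b·x·z
    dz/dt = k·x + c·x² + d·x·z - p·z            ("fig2_code" variant)
    dz/dt = (k - c·Ye)·x + c·x² + c·x·z - p·z   ("paper_eq" variant)

At a critical cofactor supply `p_c` the determinant of the fluctuation
Jacobian `L(p)` vanishes and the dynamics change character: below `p_c`
fluctuations attenuate, above it they diverge — the model's image of
dynamic instability. The package computes:

* exact steady states and regime classification (`steady_state()`,
  `classify()`, `stability_sweep()`);
* the critical supply `p_c` by bisection of `det L(p) = 0`, with the
  steady state recomputed at each trial `p` (`find_critical_p()`);
* deterministic trajectories of the attenuated/oscillatory/divergent
  regimes and the nine-panel sweep over the published supply levels
  (`integrate_fluctuations()`, `diagnose_regime()`, `reproduce_fig2()`);
* a fully symbolic center-manifold reduction at `p = p_c`
  (`center_manifold()`): the supply deviation `ε = p - p_c` is suspended
  (`dε/dt = 0`), the system is transformed to the eigenbasis of the
  critical Jacobian (eigenvalues `τ` and 0), and the invariance equation
  for the slaved coordinate `u = h(v, ε) = a1·v² + a2·vε + … + a7·ε³` is
  solved order by order, yielding the reduced center dynamics
  `dv/dt = n1·v² + n2·vε + … + n7·ε³` and its fixed-point branches — the
  bifurcation that underlies the oscillation.

The symbolic work runs on a small exact computer-algebra layer included in
the package (rationals, multivariate polynomials over ℚ, rational functions
with factored denominators), so statements like `a3 = a7 = 0` are certified
as exact zeros for *arbitrary* parameter values, not just numerically small
at one parameter set.

## Worked example

```r
library(cmtkin)

pr <- preset_params("fig2_code", p = 0.01)   # published simulation set
steady_state(pr)
#> Steady state (sums to M = 0.1 )
#>               Xe               Ye               Ze
#> 0.00189704094041 0.04403729225780 0.05406566680178

classify(pr, variant = "paper_eq")
#> Stability at p = 0.01 (paper_eq variant): stable_spiral
#>   trace = -1.044386e-02  det = 1.749353e-04  disc = -5.906670e-04
#>   eigenvalues: -0.0052219+0.0121518i -0.0052219-0.0121518i

cp <- find_critical_p(preset_params("fig2_code"))
cp
#> Critical cofactor concentration p_c = 0.0107969420684
#>   |det L(p_c)| = 1.425e-13 after 30 bisections on [1e-06, 0.1] (paper_eq)
#>   eigenvalues at p_c:  5.86949e-04+0i -2.42701e-10+0i
```

At `p = 0.01` the steady state is a stable spiral (complex eigenvalues with
negative real part): a small perturbation oscillates with decaying envelope.
The critical supply rounds to `p_c ≈ 0.011`; just above it one eigenvalue is
positive and the fluctuation diverges. The center-manifold reduction at
`p_c`, in the published approximate eigenbasis:

```r
center_manifold(preset_params("fig2_code"), p_c = cp$p_c, mode = "paper_approx")
#> Center-manifold reduction (paper_approx eigenbasis, order 3)
#>   p_c = 0.0107969420684 (paper_eq)
#>   identically zero: a3, a7, n2, n3, n6, n7
#>   manifold coefficients a1..a7:
#>      -35.2901    11.3839     0.0000 18539.0092 -5988.0074    38.4093     0.0000
#>   reduced dynamics n1..n7:
#>      -2.900    0.000    0.000 1569.957 -506.438    0.000    0.000
#>   invariance residual: lowest surviving total degree = 4
```

The pure-ε coefficients vanish identically (symbolically, for arbitrary
parameters), the manifold is tangent to the center direction, and the
invariance equation is satisfied through cubic order. `fixed_point_branches()`
and `back_transform()` then give the two fluctuation amplitudes of the
bifurcation in the physical `x` coordinate. `mode = "exact"` uses the true
eigenvectors instead; see the methods vignette
(`vignettes/center-manifold-kinetics.Rmd`) for what changes and why.

A nine-panel regime sweep mirroring the published figure:

```r
fig <- reproduce_fig2()
fig$summary   # p, regime, envelope_ratio, n_peaks, eigenvalue classification
```

A thin command-line tool wraps the same functions:

```sh
Rscript inst/exec/cmtkin critical-point --preset fig2_code
Rscript inst/exec/cmtkin run-all --preset fig2_code --out out/
```

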