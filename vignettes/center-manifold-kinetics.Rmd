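---
title: "Center-manifold kinetics of cofactor-driven protein assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-manifold kinetics of cofactor-driven protein assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmtkin)
```

## The model

Three monomer pools cycle through a cofactor-driven assembly loop: the
ATP/GTP-bound, assembly-competent monomer $X$ attaches to a constant pool of
oligomer ends $W$ (becoming the tip-bound, hydrolysed monomer $Y$), $Y$ is
released as the inactive monomer $Z$, and $Z$ is re-activated by cofactor
exchange at a rate proportional to the external cofactor supply.  With the
lumped rate constants $D_1$ (attachment, proportional to the diffusion
coefficient of $X$), $D_2$ (release), $k$ (direct inactivation of $X$) and
$p$ (cofactor exchange), the mass-action system is

$$\frac{dX}{dt} = -D_1 W X + pZ - kX,\qquad
  \frac{dY}{dt} = D_1 W X - D_2 Y,\qquad
  \frac{dZ}{dt} = D_2 Y - pZ + kX,$$

with $X+Y+Z = M$ conserved.  One detail is worth stating because the
literature forms are ambiguous: the attachment rate here carries the
oligomer concentration $W$ explicitly.  That is the only reading under
which the closed-form steady state

$$X_e = \frac{D_2 M p}{q},\quad Y_e = \frac{D_1 M p W}{q},\quad
  Z_e = \frac{D_2 M (k + D_1 W)}{q},\qquad
  q = D_2 k + D_2 p + D_1 D_2 W + D_1 p W,$$

is the exact equilibrium of the rate field for *every* $W$; the two
conventions coincide at $W = 1$, the value used by every published
parameter set.  The package asserts this identity for thousands of random
parameter sets in its test suite.  The per-species published forms of the
steady state carry mutually inconsistent denominators (transcription
noise); the common-denominator form above, which also makes
$X_e+Y_e+Z_e = M$ an algebraic identity, is canonical here.

## Fluctuations with diffusion feedback

Diffusion coefficients of proteins decrease roughly linearly with
concentration at low concentration.  Writing $X = X_e + x$, $Z = Z_e + z$
(and $y = -x-z$ by conservation) and letting the diffusion coefficients
respond linearly to the fluctuations turns the linear relaxation into a
quadratic system:

$$\frac{dx}{dt} = (-D_1 W + aX_e - k)\,x + a x^2 + (p - bX_e)\,z - b x z$$

with feedback strengths $a$, $b$ (and $c$, $d$ in the $z$ equation).  Two
published variants of the $z$ equation circulate and both are implemented:
the equation-set form `paper_eq`, $\dot z = (k - cY_e)x - pz + cx^2 + cxz$,
and the simulation-code form `fig2_code`, $\dot z = kx - pz + cx^2 + dxz$,
which carries an independent cross-term coefficient $d$ (zero in the
canonical sets) and no $-cY_e$ correction in the linear part.  The printed
linear $x$-coefficient with $+k$ inside the bracket contradicts both the
published Jacobian and the published code; the $-k$ form is used.  Both
parameter lists in circulation ship as presets: `fig2_code`
($b=156$, $c=0.1$, $D_2 = 117/9700$) — the only set whose critical point
and trajectories are actually printed — and `text_2017` ($b=150$, $c=0$).

## Stability and the critical cofactor supply

The Jacobian at the origin of the fluctuation system is

$$L(p) = \begin{pmatrix} -D_1 W + aX_e(p) - k & -bX_e(p) + p\\
   k - cY_e(p) & -p\end{pmatrix},$$

where the steady state itself moves with $p$.  `classify()` labels the
regime from trace, determinant and discriminant; `find_critical_p()`
bisects $\det L(p) = 0$, recomputing $X_e(p)$, $Y_e(p)$ at every trial
$p$ — freezing them yields no root anywhere near the reported critical
value.  Bisection (not a secant/Brent hybrid) is used deliberately: under
the sign-change precondition it is guaranteed and fully deterministic, and
the default tolerance $10^{-10}$ on $p$ leaves a determinant residual of
order $10^{-13}$–$10^{-11}$.  For the `fig2_code` preset,
$p_c = 0.0107969\ldots \approx 0.011$ at two significant figures.

Two things about the critical neighbourhood are easy to miss. First, the
trace of $L$ crosses zero slightly *below* $p_c$ (at $p \approx 0.01075$
for the canonical preset), so between that point and $p_c$ the origin is
already unstable while the determinant is still positive; the
determinant root is the parameter the analysis tracks, and the nine
published supply levels straddle it cleanly (the largest stable level,
$0.010705$, sits just below the trace crossing).  Second, at $p_c$ the
nonzero eigenvalue is $\tau = \operatorname{tr} L(p_c) \approx
5.87\times10^{-4} > 0$: the fast direction is (weakly) unstable at
criticality, so the center manifold is repelling in $u$ — which does not
affect its computation, only the interpretation of "slaved" as formal
rather than attracting.  A published statement that the eigenvalues at
criticality are $0$ and $2.9\times10^{-4}$ is not reproducible from
either printed parameter set; it is left as an open discrepancy and
asserted nowhere.

## Trajectories and regime diagnosis

`integrate_fluctuations()` uses `deSolve::lsodar` (adaptive, stiff-capable)
with relative tolerance $10^{-9}$, absolute tolerance $10^{-12}$ and up to
50\,000 internal steps, the settings of the published simulation; physical
concentrations are reconstructed as $X = X_e+x$, $Y = Y_e-x-z$,
$Z = Z_e+z$, so conservation is exact by construction.  Two root
conditions terminate a run early: a divergence ceiling $|x|,|z| >
10M$ (beyond which the fluctuation expansion has no physical meaning; the
run is flagged *divergent*) and a convergence floor (vector field below
$10^{-140}$), needed because at $p=0$ the $x$ coordinate decays at rate
$0.285$ and would underflow to a NaN inside the integrator long before the
standard horizon $t = 3300$.

`diagnose_regime()` operationalises the visual classification of the
published nine-panel figure with an *envelope ratio* $r$: the largest
$|x|$ over the last third of the integrated window divided by the largest
$|x|$ over the first third, with thresholds $r < 0.5$ (*attenuated*) and
$r > 2$ or a divergence flag (*divergent*), otherwise *sustained*.  The
ratio is taken over the full integration span $[0, 3300]$, not the
plotting window $[0, 1000]$: the near-critical panel decays at rate
$3.2\times10^{-4}$, which is only visible as attenuation over the longer
span ($r \approx 0.49$ versus $\approx 0.8$ over the plot window).
Monotone decays (real eigenvalues, no oscillation) are classified by the
same ratio rather than rejected for lacking peaks, otherwise the small-$p$
panels could not be diagnosed at all.  The thresholds are package choices;
the published classification is visual.

## The center-manifold reduction

At $p = p_c$ the system has eigenvalues $\{\tau, 0\}$ and linearization
alone cannot decide stability.  The package suspends the supply deviation
$\varepsilon = p - p_c$ as a state with $\dot\varepsilon = 0$, freezing
the steady state at its critical value, so $\varepsilon$ enters the
$(x,z)$ field only through the explicit $p$ occurrences — as
$+\varepsilon z$ in $\dot x$ and $-\varepsilon z$ in $\dot z$.  Two
consequences are structural: the origin is a fixed point for every
$\varepsilon$, and the suspended field contains no pure powers of
$\varepsilon$.  (Freezing the steady state is a modelling choice: the
reduced dynamics then reproduce the slow eigenvalue of the *suspended*
linear part, not the full $p$-derivative of the eigenvalue, which would
also include the drift of $X_e(p)$; the test suite checks exactly the
former.)

Writing the critical Jacobian entries as $A, B, C, D$ with the constraint
$\det L_c = 0$ imposed exactly ($D = BC/A$), the eigenvector matrix
$T = [\,l_1\ l_2\,] = \bigl(\begin{smallmatrix} B & B\\ D & -A
\end{smallmatrix}\bigr)$ (fast column first) diagonalises the linear part,
and in coordinates $(u,v) = T^{-1}(x,z)$ the invariance equation for the
ansatz

$$u = h(v,\varepsilon) = a_1 v^2 + a_2 v\varepsilon + a_3\varepsilon^2 +
  a_4 v^3 + a_5 v^2\varepsilon + a_6 v\varepsilon^2 + a_7 \varepsilon^3$$

is solved by collecting monomials $v^i\varepsilon^j$ of total degree
$\le 3$ and solving the resulting linear system over the field of rational
functions in $(A, B, C, q_a, q_b, q_c, q_d)$ — the Jacobian entries and
the quadratic coefficients kept fully symbolic.  Substituting $h$ into the
center equation gives the reduced dynamics coefficients $n_1,\ldots,n_7$.
Because the solve is symbolic and exact (rational arithmetic throughout),
"coefficient equals zero" means *identically zero for arbitrary
parameters*, which is the strongest sense available.

Everything is computed once per eigenbasis mode and cached; numeric values
are evaluations of the symbolic solution at a parameter set.  The
truncation order is fixed at 3, matching the cubic ansatz; the invariance
residual is re-expanded one order higher and verified to contain no
monomial of total degree $\le 3$ (its lowest surviving degree, 4, is
reported).

### What vanishes, and in which basis

In the **exact eigenbasis**, the absence of pure-$\varepsilon$ forcing
makes

$$a_3 = a_7 = 0 \qquad\text{and}\qquad n_3 = n_7 = 0$$

identities for arbitrary symbolic parameters.  The $v\varepsilon^2$
coefficient, however, survives:

$$n_6 = \frac{A^2 C\,(A+C)(A-B)}{(A^2+BC)^3} \neq 0$$

in general (about $6.5\times10^5$ at the canonical preset, where
$A^2+BC \approx 10^{-4}$ is small).  The published claim that
$n_3, n_6, n_7$ all vanish independently of parameter values is a theorem
only in the **approximate eigenbasis**
$T \approx \bigl(\begin{smallmatrix} -aX_e & 1\\ aX_e & 1
\end{smallmatrix}\bigr)$ (valid when $D_1, k, Y_e, p_c$ are all small,
where the fast eigenvalue tends to $aX_e$): there the center row of
$T^{-1}$ is $(\tfrac12, \tfrac12)$, which annihilates the
$(+\varepsilon z, -\varepsilon z)$ cofactor coupling, so
$n_2 = n_3 = n_6 = n_7 = 0$ for arbitrary symbols.  Both modes are
first-class (`mode = "exact"` and `mode = "paper_approx"`); every report
records which produced it.  Note the flip side: in the approximate basis
$n_2 = 0$ as well, which degenerates the published branch expressions that
divide by combinations involving $n_2$ — the two halves of the published
analysis are not mutually consistent, and the package simply computes
whichever basis is requested honestly.  In `paper_approx` mode the linear
part is taken as its limiting diagonal $\mathrm{diag}(aX_e, 0)$; keeping
the untransformed linear part would leave a linear $v$ term in the fast
equation and make the tangency ansatz inconsistent at first order.

A related caveat: even with all quadratic feedback switched off, the
suspension retains the bilinear $\varepsilon z$ coupling, so the manifold
is *not* flat ($a_2 \neq 0$) for a feedback-free system — flatness holds
only for a genuinely linear suspended field, which is how the property is
tested.

### Branches and back-transform

Setting $\dot v = 0$ in the reduced dynamics and dividing out the trivial
root leaves $n_4 v^2 + (n_1 + n_5\varepsilon)v + n_2\varepsilon = 0$, with
roots

$$v_\pm = \frac{-(n_1+n_5\varepsilon) \pm
  \sqrt{(n_1+n_5\varepsilon)^2 - 4 n_2 n_4 \varepsilon}}{2n_4},$$

which collide where the discriminant vanishes — the bifurcation
signature.  The first-order series reported alongside are
$v \approx -n_1/n_4 - (n_5/n_4 - n_2/n_1)\varepsilon$ (continuation of the
nontrivial root) and $v \approx -n_2\varepsilon/n_1$ (the branch through
the origin); the series printed in the source analysis (constant term
$-2n_1$, etc.) do not reduce to the exact roots at $\varepsilon = 0$ and
are treated as corrupted typography.  `back_transform()` maps branches to
the physical fluctuation via $x = T_{11}u + T_{12}v$ and reports the
discrepancy of the published shortcut $x \approx v$ (exact on the trivial
branch in the approximate basis).  The proportionality constant in the
published order-of-magnitude statement $u \approx c'(n_1/n_4)^2$ is never
defined; the package reports the exact branch values instead.

### Numerical choices in the symbolic layer

The engine stores rationals as reduced integer pairs in doubles (exact
below $2^{53}$, with a hard overflow error rather than silent rounding),
recognises decimal inputs as small exact rationals by continued fractions
(e.g. $0.012061855670103093 = 117/9700$, $0.28 = 7/25$), and keeps
rational-function denominators in *factored* form so cancellation is exact
trial division per factor — this, plus truncated polynomial products that
never form terms above the working degree, keeps the full symbolic
reduction near two seconds without a general multivariate gcd.

## What the tests do and do not show

The deterministic fluctuation variable here is a perturbation, not
sampled noise: no stochastic (Langevin/Gillespie) channel exists, no
spatial transport is modelled (the diffusion coefficients enter as lumped
rate factors, not as a PDE), and nucleation kinetics are out of scope.
Passing the trajectory and regime tests therefore shows that the
deterministic two-variable reduction behaves as published — not that real
tubulin/actin systems, with spatial structure, stochastic attachment and
explicit nucleation, would.  The problem sizes used by the test-suite
oracles (1000 random parameter sets for the Jacobian and steady-state
identities, nine trajectories to $t = 3300$, ten launch points on the
manifold) were chosen so the full suite exercises every module in under a
minute; all are trivially enlargeable.

Known limitations: the microscopic-to-lumped map follows the published
lumping ($a = k_1 D_X W \alpha$) even though a direct expansion of the
microscopic fluctuation equations would attach $k_1 W \alpha$ to the
quadratic term — the lumped interface is authoritative and the micro
route is a documented convenience; the $\delta$ feedback on the diffusion
of $Z$ is accepted in the microscopic schema but dropped from the lumped
dynamics (treated as negligible, as in the source analysis); and the
reduction is truncated at cubic order with no normal-form/Lyapunov
coefficient computation beyond it.
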