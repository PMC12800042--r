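---
title: "A Caputo fractional-order model of colon cancer under combination therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Caputo fractional-order model of colon cancer under combination therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracCRC)
```

## The model

`fracCRC` implements a five-compartment dynamical model of colorectal
cancer under combined chemotherapy, immunotherapy and probiotic dosing.
The state is $(T, M, G, C, P)$: tumor cells, macrophages, dendritic
cells, CD4+ T helper cells, and the probiotic drug concentration.  The
base model is

$$
\begin{aligned}
D^\alpha T &= g_1 T\Big(1-\frac{T}{s_1}\Big)
  - \beta_1 \frac{TM}{s_2+T} - \omega \frac{TC}{s_4+T} - u_3 T,\\
D^\alpha M &= g_2 \frac{T}{s_2+T} - (\beta_2+d_1) M,\\
D^\alpha G &= r_1 + g_3 \frac{T}{s_3+T} - (\beta_3+d_2) G,\\
D^\alpha C &= r_2 + g_4 G - (\beta_4+d_3) C
  + \frac{\delta P C}{b+P} + u_2 C,\\
D^\alpha P &= u_1 - \vartheta P,
\end{aligned}
$$

where $D^\alpha$ is the Caputo derivative of order $\alpha \in (0,1]$.
Tumor growth is logistic with carrying capacity $s_1$; macrophages and
CD4+ cells kill tumor cells through saturating (Michaelis–Menten-type)
interactions with half-saturation constants $s_2$ and $s_4$; tumor
antigens recruit macrophages and dendritic cells; dendritic cells
activate CD4+ cells at rate $g_4$; the probiotic recruits CD4+ cells
through the saturating term $\delta P C/(b+P)$; and the three constant
dose rates $u_1, u_2, u_3$ represent probiotic, immunotherapeutic and
chemotherapy administration.  Although dosing could in principle vary in
time, every experiment implemented here uses constant doses, so the
package stores them as parameters and treats the system as autonomous.

An extended variant (`variant = "extended"`) adds three cross-recruitment
terms — macrophage recruitment by CD4+ cells ($g_5$), and dendritic-cell
recruitment by macrophages ($g_6$) and by CD4+ cells ($g_7$) — and
reduces exactly to the base model when $g_5=g_6=g_7=0$, which is the
default.

Parameter defaults in `model_parameters()` reproduce the tabulated
literature values (e.g. $s_1 = 1000$ cells, $\vartheta = 1$ per unit
time, $b = 0.25$).  Five parameters are tabulated as ranges rather than
points ($g_1, g_2, g_3, g_4 \in$ roughly $[0.1, 0.9]$ and
$\delta \in [0.15, 0.60]$); values outside these ranges warn rather than
error, because the sweep scenarios deliberately step across them.

## Fractional order, memory and the $\sigma$ scaling

The Caputo kernel $(t-\tau)^{\alpha-1}$ weights the entire history of the
state, so smaller $\alpha$ means stronger memory and slower, algebraically
tailed transients; at $\alpha = 1$ the model is an ordinary ODE system.
Because a fractional derivative carries units of time$^{-\alpha}$, the
dimensionally consistent formulation multiplies the right-hand side by
$\sigma^{1-\alpha}$ for a rescaling constant $\sigma > 0$
(`scaled_rhs()`).  No specific value of $\sigma$ accompanies the model in
the literature, so the package defaults to $\sigma = 1$ — which makes the
scaled and unscaled systems coincide — and exposes the constant for
sensitivity exploration only.

## Numerical integration

`solve_pece()` implements the fractional Adams–Bashforth–Moulton
predictor–corrector of Diethelm, Ford and Freed: writing the system in
its Volterra integral form, the predictor applies a product-rectangle
rule and the corrector a product-trapezoid rule, with one corrector pass
by default (configurable).  Design choices that matter:

* **Full memory.** No short-memory truncation is applied: truncation
  biases exactly the $\alpha$-dependent transients that the scenarios
  study.  The $O(n^2)$ history convolution runs in compiled code with
  precomputed weight tables, which keeps 80&nbsp;000-step runs in the
  seconds range.
* **Uniform grids.** Steps are $h = t_{\text{end}}/n$.  Scenario defaults
  use $h \le 0.05$ for short transient runs and $h \in [0.1, 0.2]$ for
  the two long-horizon runs, where all local rates are far below $1/h$.
  At $h = 0.25$ one of the multi-initial runs exhibits a transient
  numerical instability (a large negative excursion that later recovers);
  the registry therefore keeps those runs at $h = 0.1$.
* **No clamping.** States are validated as nonnegative at construction
  only.  The integrator never projects; instead, any component dipping
  below $-10^{-6}$ raises a warning that the run should be repeated with
  a smaller step.  Small fractional undershoots above that tolerance are
  expected and harmless.
* **Blow-up reporting.** A non-finite state aborts with the first bad
  step index rather than returning garbage.

Two independent oracles validate the stepper.  `mittag_leffler()`
evaluates $E_\alpha(z) = \sum_k z^k/\Gamma(\alpha k + 1)$, the exact
solution kernel of linear Caputo decay: the defining series is used where
its alternation is harmless ($z > 0$ or $|z|^{1/\alpha} \le 5$) and a
completely monotone spectral integral elsewhere, after a substitution
that removes the endpoint singularity and a split at the Lorentzian peak
of the spectral density; accuracy is at or below $10^{-8}$ across
$z \in [-50, 5]$, checked against the $E_{1/2}$ closed form
$e^{x^2}\mathrm{erfc}(x)$ and frozen high-precision references.
`solve_integer_reference()` wraps a tight-tolerance classical solver
(`deSolve::ode`, lsoda) for the $\alpha = 1$ case.  The empirical
convergence order of the scheme on linear decay is close to $1+\alpha$
(`empirical_convergence_order()`).

A useful structural fact: the probiotic equation is linear and decoupled,
so $P(t) = \frac{u_1}{\vartheta}\big(1 - E_\alpha(-\vartheta t^\alpha)\big)
+ P_0 E_\alpha(-\vartheta t^\alpha)$ exactly.  The test suite holds every
scenario's $P$-component to this closed form, and the steady level
$u_1/\vartheta$ is the package's primary worked-example quantity.

## Equilibria

Setting the right-hand side to zero, the tumor-free equilibrium
$E_1^* = (0, 0, G^*, C^*, P^*)$ has the closed form

$$
P^* = \frac{u_1}{\vartheta},\qquad
G^* = \frac{r_1}{\beta_3+d_2},\qquad
C^* = \frac{r_2 + g_4 G^*}{D_C},\qquad
D_C = \beta_4 + d_3 - u_2 - \frac{\delta P^*}{b+P^*}.
$$

$D_C > 0$ is the existence condition: when immunotherapy plus
probiotic-driven recruitment outpace CD4+ turnover, no finite tumor-free
steady state exists and `tumor_free_equilibrium()` says so rather than
returning a negative cell count.  Some published statements of these
closed forms contain typographical slips (an undefined rate symbol in the
$C^*$ numerator, and swapped labels between the dendritic and CD4
branches of the coexistence equilibrium).  The package derives everything
directly from the steady-state system, keeps the printed variants
available (`mode = "paper_verbatim"`) for comparison, and lets an
objective criterion arbitrate: every reported equilibrium must drive the
max-norm of the full right-hand side below $10^{-9}$, which only the
derived forms do when the two disagree.

Coexistence equilibria ($T^* > 0$) reduce, by back-substituting
$M^*(T), G^*(T), C^*(T)$, to one scalar equation in $T$.
`find_coexistence()` scans it on a uniform grid over $(0, s_1]$
(10&nbsp;000 points by default), brackets every sign change, polishes
each root with `uniroot()` to $|f| < 10^{-12}$, merges roots closer than
$10^{-6} s_1$, and discards any root whose back-substituted state is
negative or fails the residual check — an empty list is the documented
"no coexistence" answer, not an error.

## Stability

`jacobian_matrix()` linearizes the model; `assess_equilibrium()` then
computes eigenvalues, the quartic characteristic coefficients
$R_1, \dots, R_4$ of the coupled $(T, M, G, C)$ block (the probiotic row
decouples, contributing the eigenvalue $-\vartheta$), the Hurwitz
determinants $H_1, \dots, H_4$, and a classification.

Two linearization modes exist for the base model.  The default,
`"correct"`, is the exact derivative — e.g. a saturating term
$a\,x/(s+x)$ differentiates to $a\,s/(s+x)^2$, and the probiotic
recruitment has $P$-derivative $\delta b C/(b+P)^2$.  The
`"paper_verbatim"` mode reproduces a published variant of the matrix that
differs from the exact derivative in four entries (stray $(1-T^*)$ and
$(1-P^*)$ factors and a squared saturation constant).  A central
finite-difference oracle arbitrates in the test suite; the verbatim mode
exists so the discrepancy is reproducible, and it is never used for
classification.

Classification uses the Matignon criterion: a fractional linear system of
order $\alpha$ is asymptotically stable iff every eigenvalue satisfies
$|\arg\lambda| > \alpha\pi/2$.  At $\alpha = 1$ this is the classical
left-half-plane condition, and the Routh–Hurwitz signs ($H_i > 0$ for
all $i$) are its algebraic equivalent for the quartic block — an
equivalence the suite checks on 200 seeded random parameter draws.  One
consequence worth noting: a spectrum that is stable at $\alpha = 1$ is
stable for every $\alpha \in (0,1]$, because the stability cone only
widens as $\alpha$ decreases.  Eigenvalues within $10^{-8}$ of the
critical cone (including eigenvalues at the origin) classify as
`"marginal"`, never `"stable"`.

## Well-posedness diagnostics

On a box $\|T\| < b_1, \dots, \|P\| < b_5$ the five kernels are Lipschitz
with explicit constants, e.g. $L_1 = g_1 + u_3 + 2 b_1 g_1/s_1 +
\beta_1 b_2/s_2 + \omega b_4/s_4$ and $L_5 = \vartheta$
(`lipschitz_constants()`).  The uniqueness condition checked is the
literal contraction test $1 - \sigma^{1-\alpha} L_i/\Gamma(\alpha) \ge 0$.
As printed, this condition carries no horizon factor; the standard
fixed-point argument would instead produce
$1 - \sigma^{1-\alpha} t^\alpha L_i/\Gamma(\alpha+1) \ge 0$ on a horizon
$t$.  Rather than silently repairing the condition, the report carries
both (`flags` and `flags_horizon`), and the Picard demonstrator works on
a unit horizon, where the two essentially coincide.  The comparison
constant `bound_a` only needs to dominate every $L_i$; it defaults to
$1 + \max_i L_i$.  Default bounds $(s_1, 2, 2, 10, 2u_1/\vartheta + 1)$
are generous envelopes of the scenario trajectories and can be replaced
by realized bounds via `bounds_from_trajectory()`.

`picard_iterate()` demonstrates the fixed-point construction itself:
successive substitution into the fractional-integral form, discretized by
a product-rectangle rule that is exact for constant integrands — so the
first iterate from rest reproduces $u_1 t^\alpha/\Gamma(\alpha+1)$ on the
probiotic line to machine precision.  When every contraction flag holds,
the sup-norms of successive differences shrink geometrically and the
iterates converge to the PECE solution.

## Scenarios and the fixture generator

`run_scenario()` reproduces five published experiment families with their
constants stored verbatim in a registry (checked byte-for-byte by a unit
test): tumor clearance under full triple dosing across five fractional
orders; tumor–immune coexistence under low chemotherapy across five
orders; five initial states converging to a common attractor at
$\alpha = 0.96$; five dose triples at $\alpha = 0.9$; and extended-model
sweeps over $g_1, g_2, g_3, g_4, \delta$ (the $\delta$ sweep starting
from the distinct printed initial state $(10, 0, 10, 40, 40)$).

Horizons and step counts are not stated alongside the published figures,
so the registry chooses them from the linearized relaxation rates so that
every component settles on the horizon: e.g. the multi-initial scenario
relaxes through a slow CD4 mode with rate $D_C \approx 0.057$, whose
fractional tail decays only algebraically, hence its long horizon
($t_{\text{end}} = 8000$); the clearance scenario needs
$t_{\text{end}} = 800$ for the same reason at rate $\approx 0.23$.
Settling speed is operationalized by `time_to_threshold()` — the first
grid time after which a component stays within a band around its
reference — with "never" (`NA`) ordered after every finite time.

`draw_parameters()` generates seed-reproducible random admissible
parameter sets for the property suites: ranged parameters uniform on
their tabulated intervals, point-valued parameters jittered ±20% (doses
around the baseline triple 0.2/0.4/0.5), which keeps every saturation and
decay constant strictly positive and covers both stable and unstable
equilibrium classes.  The draws emulate plausible parameter uncertainty
around the tabulated values — nothing more.  There is no empirical
dataset behind this model, so passing property suites demonstrates
internal mathematical consistency (solver vs. closed forms, algebra vs.
spectra, theory vs. simulation), not agreement with clinical data.

## Problem sizes and limitations

The test and acceptance workloads run at desk scale by design: linear
decay problems use up to 2000 steps; full-model runs use 2000–16&nbsp;000
steps for short horizons and up to 80&nbsp;000 steps for the one
slow-mode scenario; random-draw suites use 100–200 draws.

Known limitations: dosing is constant (no schedules or optimal control);
the memory kernel is the Caputo power law only; grids are uniform with no
adaptivity; extended-model equilibria are probed only by long-time
simulation (no closed forms exist); spatial structure, CD8+ T cells and
parameter estimation from data are out of scope; and the model's units
are the literature's dimensionless cell/concentration scales, not
calibrated counts.
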