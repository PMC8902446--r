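---
title: "Auditing the free energy principle in weakly coupled linear systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the free energy principle in weakly coupled linear systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepaudit)
library(dplyr)
```

## The model

The free energy principle (FEP) claims that a system at non-equilibrium
steady state whose internal and external states are separated by a Markov
blanket can be read as performing variational Bayesian inference about its
environment. `fepaudit` makes that claim quantitatively checkable in the
simplest setting that supports it: linear Langevin dynamics

$$\frac{dz_t}{dt} = J\,(z_t - \rho) + \omega_t,
  \qquad \mathrm{cov}(\omega_t) = 2\Gamma,$$

with the state partitioned as $z = (y, s, a, x)$ — external, sensory,
active and internal blocks — and the blanket $b = (s, a)$. The drift is
written $J = -I + C$: unit self-decay plus a coupling matrix $C$ whose
entries are the interactions under audit. $\Gamma$ is diagonal; the
homogeneous case $\Gamma = \varsigma^2 I$ is the default and the only mode
the series expansions assume. Whenever $J$ is Hurwitz the process has a
Gaussian stationary density $N(\rho, \Sigma^*)$ with

$$J\Sigma^* + \Sigma^* J^\top + 2\Gamma = 0,$$

and the drift decomposes into a dissipative and a circulating part,
$J = (Q - \Gamma) H$ with $H = (\Sigma^*)^{-1}$ and the antisymmetric
solenoidal matrix $Q$. We fix the convention $Q = J\Sigma^* + \Gamma$,
which is antisymmetric by the Lyapunov identity, reconstructs the drift
exactly, and agrees with the weak-coupling series
$Q = \tfrac12(C\Gamma - \Gamma C^\top) + \tfrac14(C^2\Gamma - \Gamma (C^2)^\top) + O(C^3)$
through second order. (The opposite global sign is a self-consistent
alternative; `q_sign = "negative"` exposes it.)

Three statistical requirements are audited:

1. **Markov blanket** (`markov_blanket_residual()`): for Gaussians the
   conditional independence of $y$ and $x$ given $b$ is exactly
   $H_{yx} = 0$, so the scale-free residual is
   $\lVert H_{yx}\rVert_F / \lVert H\rVert_F$.
2. **Solenoidal decoupling** (`solenoidal_block_residuals()`): the FEP
   needs the off-diagonal blocks of $Q$ to vanish — either all six
   (`full_block_diagonal`) or only those coupling the autonomous $(a,x)$
   and non-autonomous $(y,s)$ sides (`autonomous_split`). Both modes are
   first-class because the literature uses both; the connection of the
   split mode to free energy minimisation is itself unsettled.
3. **Gradient–flow identity** (`gradient_flow_identity_residual()`): when
   1–2 hold exactly, the conditional average flow of the external block is
   a preconditioned free-energy gradient with rate matrix
   $-(Q_{yy} - \Gamma_{yy})$. The residual quantifies how badly that
   identity fails away from the idealised regime.

## Synthetic systems are the study conditions

No external data exists for this problem; the generator **is** the
experimental design. `generate_random_system()` draws the mask-allowed
entries of $C$ as independent Rademacher signs times $\varepsilon$ —
exactly $\pm\varepsilon$, not uniform — with defaults
$\varepsilon = 0.1$, $\varsigma = 0.1$ and partition sizes
$n_y = n_x = 2$, $n_s = n_a = 1$ for the reference trajectory studies.
These are the coupling magnitudes, noise scale and sizes at which the
weak-coupling regime is unambiguous, and they are deliberately not tuned:
every scaling claim below is stated as an exponent or ratio precisely so
that it is invariant to reasonable changes of these numbers. The full sign
pattern is drawn in a single pass from the seed, so the same seed gives
the same pattern at every $\varepsilon$; sweeps therefore isolate
$\varepsilon$-scaling from sign-pattern noise. At these scales the
Hurwitz check never needs a resample (verified over $10^3$ seeds).

Three sensorimotor structures are built in beside the unconstrained case:

* **canonical** — the perception-action interface: $C_{yx}$, $C_{sx}$,
  $C_{ay}$, $C_{xy}$ forced to zero;
* **circular** — a unidirectional loop, fixed here as
  $y \to s \to x \to a \to y$ (the opposite orientation is a
  configuration option, `loop_direction = "reverse"`, since the verbal
  description the structure comes from does not pin the arrows down);
* **symmetric_chain** — canonical zeros plus $C_{ya} = C_{xs} = 0$ and all
  remaining between-block couplings symmetric, confining asymmetry (hence
  circulation) to within blocks.

What the generator does **not** emulate: nonlinear drifts,
state-dependent or correlated noise, strong coupling, heavy-tailed
fluctuations. A passing audit here shows the package's claims hold for
weakly coupled linear systems; it says nothing about systems outside that
class, which is exactly the scope within which the negative results below
are meaningful (if a requirement already fails in the simplest linear
case, nonlinearity is unlikely to rescue it).

## What the audit finds

```{r audit}
p <- partition(2, 1, 1, 2)
sys <- generate_random_system("canonical", p, epsilon = 0.1,
                              sigma = 0.1, seed = 1)
audit_system(sys, tol = 1e-6)
```

Across matched-seed sweeps (`epsilon_sweep()` + `sweep_exponents()`) the
residuals obey clean scaling laws: the Markov-blanket residual is
$O(\varepsilon^2)$ for canonical systems — matching the closed form
$H_{yx} = -\tfrac{\varsigma^{-2}}{4}(C_{ys}C_{xs}^\top + C_{ya}C_{xa}^\top) + O(C^3)$
— and $O(\varepsilon^3)$ for the circular loop, whose cycles only induce
$y$–$x$ precision couplings at higher order. For the symmetric chain we
find the residual is $O(\varepsilon^4)$: the between-block symmetry
cancels the odd orders as well, so the exponent is 4, not 3 — a sharper
statement than the qualitative "higher than second order" expectation,
and one of the package's own empirical findings. The off-diagonal $Q$
blocks are $O(\varepsilon)$ for generic canonical systems (leading term
$\tfrac{\varsigma^2}{2} C_{ya}$ for the environment–action block) and
$O(\varepsilon^2)$ for the symmetric chain. Only the symmetric chain,
which forbids asymmetric agent–environment interaction, comes close to
the FEP's required statistical structure.

## Inference geometry

Conditional moments use the Schur complement
$\Sigma_{y|b} = \Sigma_{yy} - \Sigma_{yb}\Sigma_{bb}^{-1}\Sigma_{by}$
rather than $(H_{yy})^{-1}$: the two agree only under an exact blanket,
and their gap is reported as an extra diagnostic
(`schur_precision_gap`). The variational free energy for a Gaussian model
$q(y\,|\,\theta) = N(\theta, \Sigma_\theta)$ is surprise plus KL
divergence; for linear systems the quadratic (Laplace) form of the
surprise is exact, so the gradient
$\nabla_\theta F = \Sigma_{y|b}^{-1}(\theta - m_y(b))$ is exact too — the
package exploits this rather than approximating, which is why the
finite-difference check holds to $10^{-6}$.

```{r geometry}
d <- stationary_density(sys)
m <- conditional_moments(d)
b <- c(0.05, -0.03)
free_energy(conditional_mode(m, b), m$cond_cov_y, b, d)
```

The synchronisation map $\sigma$ with $m_y(b) = \sigma(m_x(b))$ and the
flow map $\varphi$ connecting the conditional average flows are
implemented for the square-block case $n_y = n_x = n_b$ only; other
shapes raise a mapping-undefined error naming the violated rank
condition, rather than silently pseudo-inverting. $\varphi$ is composed
as $(J_{yy}G_y + J_{yb})(J_{xx}G_x + J_{xb})^{-1}$ with
$G_i = \Sigma^*_{ib}(\Sigma^*_{bb})^{-1}$ — the unique linear map between
the two flows, both of which are linear images of $b - \rho_b$. It
generically differs from $\nabla\sigma$ by order one
(`flow_map_mismatch()`), so reading the FEP "on average" requires
replacing the synchronisation gradient by a different map. One caveat
found while testing: in the symmetric chain with a single active state,
$\Sigma^*_{xb}$ is near rank-1 (internal states reach the sensor only
through the active state at leading order), so $\sigma$ is
ill-conditioned there; the maps are reliable on canonical structures,
where occasional degenerate sign-pattern draws are refused by the rank
check rather than inverted.

## Trajectories: the average of the dynamics is not the dynamics of the average

The central negative result is dynamical. Along a simulated path the true
conditional mode $m_y(b_t)$ is a fixed linear image of the blanket state —
stationary whenever the system is. The surrogate $\tilde m_y(t)$ obtained
by *integrating* the conditional average flow,
$d\tilde m_y/dt = (J_{yy}G_y + J_{yb})(b_t - \rho_b)$, accumulates the
integral of a stationary process and therefore random-walks. To first
order the two dynamics differ by a sign flip of $C_{yb}$:
$A_{\mathrm{true}} = -\tfrac12(C_{yb} + C_{by}^\top)$ versus
$A_{\mathrm{surr}} = -\tfrac12(-C_{yb} + C_{by}^\top)$, so for the
symmetric chain ($C_{yb} = C_{by}^\top$) the surrogate's drive vanishes
identically while the true one does not.

```{r divergence}
chain <- generate_random_system("symmetric_chain", p, epsilon = 0.1,
                                sigma = 0.1, seed = 42)
cmp <- flow_divergence_ensemble(chain, members = 16, dt = 1e-2,
                                t_end = 50, seed = 1)
glance(cmp)
```

The comparisons are always made between *integrated* paths, never by
finite-differencing noisy trajectories — the formal time derivative of
$m_y(b_t)$ contains white noise, so pointwise derivative comparisons are
ill-posed while path comparisons are exact. The ensemble variance of the
surrogate grows linearly (its value at $T$ is about four times its value
at $T/4$), while the true path's variance plateaus at its stationary
value, and the per-coordinate correlation between the two is small. Even
with tiny noise ($\varsigma = 10^{-3}$) and an agent that only observes
($C_{yb} = 0$) the gap keeps growing; the only clean validity case is the
noiseless observation-only limit, where the residual gap is
$O(\varepsilon^2)$. The two-variable spiral demo (`bivariate_demo()`)
makes the mechanism visible: with $J = [[-1, c], [-c, -1]]$ every
trajectory spirals into the origin, yet the conditional average flow of
$y$ at fixed $b$ is $c\,b$ — read as a velocity it points away from the
conditional mode, a "gradient ascent" that no trajectory performs.

## Numerical choices

* **Lyapunov solves.** No installed solver exists in this environment's R
  stack, so the package carries a spectral solver: diagonalise $J$,
  divide by eigenvalue sums, transform back; a dense Kronecker
  vectorization ($O(n^6)$, exact) is the fallback for ill-conditioned
  eigenbases and the independent test oracle. Residual tolerances:
  Lyapunov $10^{-10}\max(1, \lVert\Gamma\rVert_F)$, antisymmetry
  $10^{-10}$, reconstruction $10^{-8}$.
* **Series.** Truncations are exact recursions collecting terms by total
  power of $C$ (never numeric subtraction of exact solutions), so e.g.
  every truncation of the $Q$ series is exactly antisymmetric.
* **Positive definiteness.** $\Sigma^*$ is symmetrised before inversion
  and checked via its eigenvalue ratio ($>10^{-12}$); degenerate
  densities (e.g. $\varsigma = 0$) raise errors instead of
  pseudo-inverting. The conditioning gains do fall back to the
  Moore–Penrose pseudoinverse when $\Sigma^*_{bb}$ is singular, and the
  result is flagged.
* **Probe points.** The gradient–flow identity is probed at 16 Halton
  quasi-random $(\theta, b)$ pairs within $\pm 3$ conditional standard
  deviations: deterministic, scale-aware coverage.
* **Integration.** Euler–Maruyama with noise scaling
  $\sqrt{2\,dt}\,\Gamma^{1/2}$; defaults $dt = 10^{-2}$, $T = 100$,
  32 ensemble members resolve the divergence phenomenology in seconds.
  A step-size warning fires when $dt\,\max|\lambda(J)| \ge 0.1$. Exact
  matrix-exponential sampling was deliberately left out: Euler's $O(dt)$
  weak error is well below every effect measured here (checked against
  the closed-form deterministic solution by grid halving).
* **Problem sizes.** Sweeps use 20 matched seeds on
  $\varepsilon \in \{0.025, 0.05, 0.1\}$ at $n = 6$; residual identities
  are verified over 100 random stable systems up to $n = 12$; stationary
  moments of the integrator are checked with $10^3$ ensemble members.
  Medians over seeds are the headline statistics because individual sign
  patterns can accidentally cancel a leading-order coefficient, making
  per-seed ratios heavy-tailed around the theoretical value.

## Known limitations

* Heterogeneous diagonal noise is supported by the exact solvers but not
  by the series machinery, which assumes $\Gamma = \varsigma^2 I$.
* The $\sigma$ and $\varphi$ maps handle square blocks only; rectangular
  generalisations via pseudoinverses are refused because several
  inequivalent choices exist.
* Blanket *discovery* is out of scope: the partition is always given.
* Strong coupling is only probed numerically (the generator resamples
  non-Hurwitz draws and eventually refuses); the series are meaningless
  there.
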