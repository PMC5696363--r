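---
title: "Structured sparse Bayesian learning for EEG source imaging: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured sparse Bayesian learning for EEG source imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inverse problem

EEG source imaging estimates a primary current density matrix $J \in
\mathbb{R}^{S\times T}$ ($S$ generators, $T$ samples) from scalp potentials
$V \in \mathbb{R}^{N\times T}$ through the linear forward model $V = KJ +
\varepsilon$, where $K$ is the $N\times S$ lead field. With $N \ll S$ the
system is severely underdetermined and the lead-field columns are strongly
correlated, so all information beyond the data must come from the prior.

`ssbleeg` implements two structured-sparsity priors fitted by empirical
Bayes, plus a LORETA baseline:

* **Elastic Net (ENET-SSBL).** Per column, each amplitude carries the
  Laplace/Normal density $p(J_{it}) \propto e^{-\alpha_{1,t} J_{it}^2 -
  \alpha_{2,t}|J_{it}|}$, which mixes ridge smoothness and lasso selection.
  The density is represented exactly as a Gaussian scale mixture: $J_{it}
  \mid \gamma_{it} \sim N(0, \Lambda_{it})$ with $\Lambda_{it} =
  \bar\Lambda_{it}/(2\alpha_{1,t})$, $\bar\Lambda_{it} = 1 -
  k_t/\gamma_{it}$, and $\gamma_{it}$ following a Gamma$(1/2, 1)$ law
  truncated below at $k_t = \alpha_{2,t}^2/(4\alpha_{1,t})$. The package
  verifies this identity numerically (`enet_mixture_marginal()` against
  direct quadrature of the normalized density). The working
  hyperparameters are $(\alpha_{1,t}, k_t, \beta_t)$: scale, truncation
  (sparsity) and noise variance, each per time point, with a near-flat
  Gamma$(\tau+1, \upsilon)$ prior on $k_t$ ($\tau = \upsilon = 10^{-3}$,
  shape/rate convention) and flat priors elsewhere.

* **Elitist Lasso (ELASSO-SSBL).** The prior $p(J) \propto e^{-\alpha
  \sum_t \|J_{\cdot t}\|_1^2}$ penalizes the squared column L1 norm: mass
  within a column competes, which promotes within-column exclusivity while
  one global $\alpha$ sets the same sparsity level at every time point.
  Expanding $\|J_{\cdot t}\|_1^2$ as a pairwise Markov random field gives
  per-coordinate conditionals $p(J_{it}\mid\delta_{it}) \propto e^{-\alpha
  J_{it}^2 - 2\alpha\delta_{it}|J_{it}|}$ with couplings $\delta_{it} =
  \sum_{j\ne i}|J_{jt}|$, i.e. the ENET machinery with per-coordinate
  truncation $k_{it} = \alpha\delta_{it}^2$. The couplings relate to the
  amplitudes through $\delta = W|J|$ with $W = \mathbf{1} - I$, whose
  closed-form inverse `winv_apply()` is $(\sum_j \delta_j)/(S-1) -
  \delta_i$. The tower-property identity between the hierarchical marginal
  and the original prior is checked by quadrature for $S = 2$ in the test
  suite.

* **LORETA.** Per time point, $\hat J = \arg\min \|v - KJ\|^2 + \lambda
  \|LJ\|^2$ with $L$ the combinatorial graph Laplacian of the generator
  mesh, $\lambda$ selected on a 100-point log grid by generalized
  cross-validation. The Laplacian nullspace is stabilized by a $10^{-8}$
  ridge.

## The Type-II objective and the descent strategy

Hyperparameters are estimated by minimizing the negative log posterior
$L(\Theta)$ of the hyperparameters with the sources integrated out
(`type2_objective()`), equal per time point to

$$\tfrac12\left\{ N\log\beta_t + \tfrac{1}{\beta_t}\|v_t - K\mu_t\|^2 +
\textstyle\sum_i \log\Lambda_{it} + \mu_t^\top \mathrm{diag}(\Lambda_t)^{-1}
\mu_t + \log|\Sigma_t^{-1}| \right\} - \log p(\Theta_t),$$

where $\mu_t, \Sigma_t$ are the instantaneous Gaussian posterior moments
(computed through the $N\times N$ system, cost $O(N^2S)$; coordinates with
zero prior variance are carried as exact zeros and log terms restrict to
the positive support). The $\log|\Sigma^{-1}|$ term uses the source
posterior covariance itself; with that convention the expression equals the
standard negative log evidence plus the hyperprior terms, which is what
makes the descent argument below available.

Minimization alternates the posterior computation with one coordinate
sweep: for ENET $\gamma \to \alpha_1 \to k \to \beta$ per time point; for
ELASSO $\delta \to \gamma \to \alpha \to \beta$ with $\delta$ set directly
from the current posterior mean (its objective is non-differentiable, so it
is updated through its defining identity rather than minimized). Every
minimized coordinate update is the exact argmin of the *EM surrogate*: the
expected complete-data objective with $\mu, \Sigma$ frozen, i.e. $\mu_i^2
\mapsto \mu_i^2 + \Sigma_{ii}$ and $\|v-K\mu\|^2 \mapsto \|v-K\mu\|^2 +
\mathrm{tr}(K\Sigma K^\top)$. Closed forms exist for $\gamma$
($u^2 + u/2 = \alpha_1 m k$ with $u = \gamma - k$, solved in a rationalized
form that is stable when $\alpha_1 m k$ underflows), $\alpha_1$
($S_+/(2\sum m_i/\bar\Lambda_i)$) and $\beta$ (expected residual power);
$k$ and $\alpha$ use a safeguarded log-grid line search. By the usual EM
inequality each sweep cannot increase $L$, and the package enforces this
numerically: any relative increase beyond $10^{-9}$ reverts the sweep and
redoes it in a safe mode (no pruning, $\delta$ frozen) that is plain EM.

Two non-obvious algorithmic devices deserve a record:

* **Profiled block moves.** With $\gamma$ held fixed, the $k$ and $\alpha$
  objectives decrease monotonically all the way to the feasibility barrier
  $\min_i \gamma_i$ (the truncated-Gamma normalizer rewards a larger
  truncation, and the cancelling $+\gamma_i$ density terms only react after
  $\gamma$ is re-solved), so the plain coordinate update creeps forever.
  After the barrier-limited update the solver therefore makes one upward
  block move minimizing over the truncation limit with every support
  $\gamma_i$ profiled at its closed-form conditional argmin — an exact
  joint argmin of the surrogate, so descent is preserved. The move is
  restricted upward because the profiled objective is improper as the
  truncation limit approaches zero (the Gamma$(1/2)$ density diverges at
  the origin — a genuine degeneracy of the hierarchical MAP, not an
  implementation artifact).

* **Stopping rule.** With flat hyperpriors the objective has a second
  improper direction: at desk scale ($S \gg N$) it keeps creeping while
  $\beta$ and $\alpha_1$ slide toward noise interpolation, and estimate
  quality *degrades* past roughly thirty sweeps. The defaults therefore cap
  the fit at 30 sweeps (the operating point at which trajectories have
  stabilized) with `tol = 1e-3` on the relative objective change, and a fit
  whose relative per-sweep improvement has fallen below `10*tol` at the cap
  is reported as converged. Exact-zero pruning is available behind
  `prune_threshold` (with a closed-form test that only prunes when the
  objective cannot increase) but is off by default: the continuous
  shrinkage path is what the quality metrics see.

* **ELASSO normalizer.** The coupling prior $p(\delta\mid\alpha) \propto
  e^{-\alpha\|W^{-1}\delta\|_1^2}$ has normalizer $\bar Z \propto
  \alpha^{-S/2}$. Including $-\tfrac{ST}{2}\log\alpha$ in the objective
  makes the hyperparameter posterior unbounded along $(\mu \to 0, \delta
  \to 0, \alpha \to \infty)$ — the classic scale-family MAP collapse — and
  the fit then ratchets into the trivial all-zero solution. The normalizer
  is therefore treated as constant in the $\alpha$ update (the
  $\alpha\|W^{-1}\delta\|_1^2$ data-coupling term is kept), which anchors
  $\alpha$ to the data. Similarly, the ELASSO noise variance is pooled
  across time points by default (`shared_beta = TRUE`): with per-time
  $\beta_t$ the quiet columns re-absorb their own noise as sources and the
  estimated per-time activation anti-tracks the simulated one, while the
  pooled update restores the expected tracking with no cost in detection
  accuracy. Both choices resolve questions the source model description
  leaves open, and both are recorded as deviations in the project notes.

## Synthetic world

`sim_config()` defaults state the simulated world once:

* **Geometry.** $S = 300$ generators quasi-uniform on a spherical cap
  (radius 80 mm, cap $z > -0.4R$) with 6-nearest-neighbor adjacency — a
  cortical-shell stand-in; the full sphere would put a third of the
  generators in a sensor-free zone with no anatomical counterpart. $N = 32$
  sensors quasi-uniform on the upper three quarters of a 100 mm scalp
  shell.
* **Lead field.** Analytic single-homogeneous-sphere potential of a radial
  dipole per generator, average-referenced (columns sum to zero);
  alternatively a graph-diffused random gain (`smooth_random`) with unit
  columns. Both induce the high neighbor-column correlation real gain
  matrices show. No BEM head model is attempted: that requires subject
  MRIs, and what the solvers are sensitive to — ill-conditioning and
  spatially correlated columns — is preserved.
* **Sources.** Three patches at fixed scalp directions, geodesic radii
  30/10/20 mm (occipital / motor / temporal): 1 Hz cosine, six narrow
  Gaussian pulses (10 ms width, thresholded so samples below 0.1% of the
  maximum are exact zeros), 3 Hz cosine; amplitudes 1.0 / 1.5 / 0.7.
  Four hemispheric configurations mirror the occipital and/or temporal
  patch. 1 s at 100 Hz (101 samples).
* **Noise.** Alpha-band biological noise — AR(2), poles at radius 0.97 and
  10 Hz, giving a spectral peak inside 8–12 Hz — on a random 10% of
  generators, projected through the true lead field, plus white sensor
  noise; powers split 50/50 and jointly rescaled so the realized SNR is
  exactly 6 dB.
* **Inverse-crime avoidance.** The solvers never see the generating lead
  field: inversion uses a lead field recomputed after 5 mm Gaussian jitter
  of every generator and sensor position, and LORETA's Laplacian comes from
  the jittered geometry too.

What a green benchmark test does establish: on this stated world the
structured-sparsity posteriors localize patch sources more accurately than
a smoothness prior under model mismatch and realistic noise. What it does
not establish: performance on real heads (BEM lead fields, cortical
folding, non-radial orientations), at real scale (thousands of
generators), or for evoked dynamics beyond the three stylized time
courses.

## Quality metrics

`emd()` is the exact optimal-transport distance between the normalized
absolute maps with Euclidean ground metric, solved by an in-package
transportation simplex (no LP library is available in the target
environment); optimality of every solve is certifiable through the dual
potentials the solver returns, and the tests also check a 1-D closed form
and a from-scratch tableau simplex. `dle()` measures the mean distance
from each true patch center to the nearest graph-local maximum of the
estimate (direction chosen because the description of the measure does not
formalize the asymmetry; a symmetric average is available). `roc_auc()` is
the mid-rank Mann-Whitney statistic in percent; `f1_optimal()` picks the
ROC operating point maximizing Youden's J and reports the harmonic-mean F1
(the geometric mean, which the source text names, is available via
`mean = "geometric"`). `sparsity_level()` and `activation_level()` are the
per-time 1 − normalized-L1 and raw-L1 curves. `rank_summaries()` selects
the median-summed-rank typical trial and builds pairwise win-count tables
from two-sided Wilcoxon rank-sum tests at $p < 0.05$ (the significance
level is an assumption; none is stated in the source).

All metrics consume non-thresholded estimates.

## Known limitations

* The hyperparameter posterior is improper in several directions (noted
  above); fits are therefore operating-point estimators — iteration budget
  and stopping tolerance are part of the method, as they were in the
  original algorithm's reported ~15–30 iterations.
* The per-time truncation limit $k_t$ equilibrates near the point where
  the truncated-Gamma hazard matches the support ratio, so its *absolute*
  level is only weakly data-driven without pruning; the per-time scale
  $\alpha_{1,t}$ (equivalently the L1 rate $\alpha_{2,t} =
  2\sqrt{\alpha_{1,t}k_t}$) is what tracks the simulated sparsity level in
  practice.
* The ELASSO $\alpha$ is weakly identified (wide flat basin); the reported
  value depends on the minimum-norm-matched initialization scale.
* Patch supports at $S = 300$ contain only 1–11 generators, so
  configuration-to-configuration variation is dominated by discretization;
  conclusions about patch-extent effects need larger $S$.
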