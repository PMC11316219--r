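---
title: "Directional selection with linkage: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional selection with linkage: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkinf)
```

## The model

`linkinf` studies recurrent directional selection in the infinitesimal model
of quantitative genetics when the infinitely many loci are completely linked:
they lie on one continuous chromosome, taken circular so that the two
obligate crossovers of each meiosis are diametrically opposed and the
recombination rate is flat. A gamete is described by its allelic-effect
profile $x(\theta)$, $\theta \in [0, 2\pi)$, or equivalently by Fourier
coefficients $X_k$ with $X_{-k} = \overline{X_k}$. The genetic value is the
mode-0 coefficient, $G = X_0$. The initial population is at linkage
equilibrium: $x(\theta)$ is Gaussian white noise, so the $X_k$ are
independent complex normals with unit complex variance ($X_0$ real with
variance 1).

Each generation is one cycle:

1. **Selection.** Gametes are selected at the exact genetic value
   $\mu + \beta\sigma$ ($\beta$ = selection intensity). In Fourier terms this
   collapses $X_0$ to a point mass and leaves all other modes untouched.
2. **Recombination.** Panmictic mating with two diametrically opposed
   crossovers at angle $\psi \sim U[0, 2\pi)$. The child profile is
   $x(\theta)H(\theta - \psi) + x'(\theta)H(\theta - \psi - \pi)$, where $H$
   is the periodic step function. Since $H$ has harmonics $h_0 = 1/2$ and
   $h_j = -i/(\pi j)$ at odd $j$, the child's coefficients are
   $$Y_k = \tfrac{1}{2}(X_k + X'_k) + \sum_{j\ \mathrm{odd}}
     \frac{-i}{\pi j}\, e^{-ij\psi}\,(X_{k-j} - X'_{k-j}).$$

Under the rotation-invariant complex-normal projection the population state
reduces to the mean $\mu_g$ of $X_0$ and the per-mode variances
$\sigma^2_{k,g}$, with the recursion
$$\sigma^2_{k,g+1} = \frac{\hat\sigma^2_{k,g}}{2}
  + \frac{2}{\pi^2}\sum_{j\ \mathrm{odd}} \frac{\hat\sigma^2_{k+j,g}}{j^2},
  \qquad \mu_{g+1} = \mu_g + \beta\,\sigma_{0,g},$$
where $\hat\sigma^2$ is the post-selection spectrum ($\hat\sigma^2_0 = 0$).
Interpreting $\sigma^2_{k}$ as matter, each cycle removes the matter at the
origin and then applies a lazy heavy-tailed random walk: retention $1/2$,
weight $4/(\pi^2 j^2)$ at each odd distance $j$ split over the two signs.
These weights sum to one exactly. The walk's one-step characteristic
function is $1 - |q|/\pi$ on $|q| \le \pi$ — the boundary case
$\alpha = 1$ of the stable family — so its $g$-fold iterate approaches a
Cauchy profile whose scale grows linearly in $g$ (`iterated_kernel()`,
`cauchy_comparator()`). The consequence is *aging*: no steady state exists,
$\sigma^2_{0,g}$ decays like $A/\log_2 g$, and the per-generation gain
vanishes while the cumulative gain diverges.

The package computes in the deficit variables $c_k = 1 - \sigma^2_k$, which
vanish at large $|k|$; because the kernel has exactly unit mass, the
recursion is identical in $c$ and the boundary condition becomes
$c_k \to 0$, far better conditioned numerically.

## The no-linkage control

`loci_model()` and friends implement the classical exactly solvable case at
finite $M$: i.i.d. allelic effects of variance $1/M$, exact Gaussian
conditioning on $G$ (the Bulmer covariances $-1/M^2$, variances
$1/M - 1/M^2$), half-sum variance exactly $1/4$ for every even $M$, and a
released offspring variance of exactly $1/2$. One cycle reaches the steady
state: the first released variance is $1/2$ for every $M$. Iterating the
cycle at *finite* $M$ depletes the transmitted trace by $\mathrm{Var}(G)/M$
per cycle, so the fixed point at $1/2$ is exact only as $M \to \infty$; the
tests assert the first-cycle identity at $10^{-12}$ and the $O(1/M)$
shrinkage of later deviations, which is the finite-$M$ content of the
infinite-$M$ statement.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `beta` | 1 | selection intensity (threshold $\mu + \beta\sigma$); affects only the mean trajectory |
| `cutoff` (N) | 1024 | largest stored mode of the deterministic recursion |
| `generations` | 256 | number of cycles; trustworthy while $g \lesssim N/4$ |
| `gain_rule` | `std_dev` | mean update $\beta\sigma_{0,g}$ (literal) vs `variance` ($\beta\sigma^2_{0,g}$) |
| `tail_extent` | N | modes beyond the cutoff closed by the power-law tail model |
| `kernel_half_width` (J) | N + tail_extent | largest odd kernel offset carried explicitly |
| `population_size` (P) | — | simulator gametes per replicate |
| `mode_cutoff` (K) | 128 | simulator modes stored per gamete |
| `recomb_truncation` (J_r) | 1023 | largest odd step harmonic in the recombination operator |
| `selection_window` (epsilon) | 0 | 0 = hard conditioning of $X_0$; else a $\pm\epsilon\sigma$ window |

The `gain_rule` choice is deliberately exposed: the no-linkage literature
prints a steady-state gain consistent with $\beta \times 1/2$ (the
variance reading) while the literal mean recursion gives
$\beta\sqrt{1/2}$; the source material is typographically ambiguous, so the
default follows the literal recursion and `steady_state_summary()` reports
both readings rather than silently reconciling them.

## Numerical treatment of the recursion

**Tail closure.** Every mode couples to arbitrarily distant modes, so
deficits beyond the cutoff are replaced by an analytic expression matched to
the retained values. We use a power law $c_k = a k^{-p}$, fit by log–log
least squares on the top 20% of retained modes ($k \in [0.8N, N]$, points
below $10^{-14}$ excluded, at least 8 points required, $p$ clamped to
$[1, 4]$, $a$ re-estimated after clamping). The Cauchy Green function makes
a $k^{-2}$ deficit tail the expected asymptote; fitting $p$ rather than
fixing it absorbs pre-asymptotic curvature. The adequacy of this closure is
tested by cutoff doubling, not by fidelity to any particular reference: the
extension at cutoff $N$ agrees with an honest $2N$ run within 10%, and a
control run with the closure disabled changes $\sigma^2_{0,g}$ by less than
$5\times10^{-6}$ for $g \le N/4$ — at these sizes the closure is a
safeguard, not a driver.

**Kernel truncation and residual.** The kernel is carried explicitly to
half-width $J = N + E$ (E = tail extent, default $N$); its residual mass
beyond $\pm J$, $(4/\pi^2)\sum_{\mathrm{odd}\, j > J} j^{-2}$, is evaluated
in closed form via the trigamma function and *carried*, never renormalized
away (renormalizing would silently violate matter conservation). With
$E \ge N$, every source reached through a beyond-kernel offset lies in the
tail-model region, and its contribution is approximated by the residual mass
times the tail model at the outermost extension point (bounded by
$\sim 10^{-7}$ per step at $N = 8192$).

**Convolution.** The diffusion is a linear convolution of the mirrored,
tail-closed deficit (length $2(N{+}J){+}1$) with the kernel (length
$2J{+}1$), computed by FFT in a zero-padded buffer of length
$\ge 2(N{+}J) + 2J + 1$ so circular wrap-around cannot touch any retained
index. A literal $O(NJ)$ direct sum (`convolve_direct()`) defines the
contract bit-for-bit and serves as the oracle; the two paths agree to
$10^{-12}$ elementwise in the tests. Deficits outside
$[-10^{-10},\, 1 + 10^{-10}]$ abort the run (a blow-up check, not clipping).

**Validity guard.** Finite-cutoff errors become visible once $g$ is
comparable to $N$; `iterate_recursion()` warns when the budget exceeds
$N/4$, and `validity_window(N)` returns $[64, N/4]$ as the default
trustworthy fit window.

## The Monte-Carlo simulator

`run_simulation()` is a validation instrument, not a production breeding
simulator: it checks the complex-normal projection by brute force. Finite
$P$ and the truncations $K$ and $J_r$ are explicit approximations, so
replicate counts and standard errors are first-class outputs. Selection at
an exact value with finite $P$ is implemented by default as hard
conditioning (overwrite $X_0$), exploiting the independence of mode 0 under
the projection; the $\epsilon$-window mode exists to probe whether hard
conditioning distorts the true (mixture, non-Gaussian) population.

The batched recombination uses the factorization
$Y = \tfrac{1}{2}(X + X') + \mathrm{diag}(e^{-ik\psi})\, H_0\,
\mathrm{diag}(e^{im\psi})\, D$ with the fixed Toeplitz matrix
$H_0[k,m] = h_{k-m}$, evaluated in compiled code as one complex
matrix product per chunk of children. This is *exact* for continuous
crossover angles — no grid, no angular discretization — and coincides with
the per-pair reference `recombine()` to $10^{-12}$ in the tests, and with an
independent grid-masking oracle to better than $10^{-6}$.

What the simulator does *not* emulate: mutation, drift beyond the chosen
$P$, diploidy and dominance, multiple or linear chromosomes, and variation
in crossover number. A passing cross-validation therefore supports the
projection recursion as a description of this idealized system, not of any
particular breeding population.

**Truncation bias.** A simulated child can only draw variance from parent
modes $|m| \le K$, so its mode-0 variance falls short of the untruncated
recursion by $(4/\pi^2)\sum_{\mathrm{odd}\, j > K} j^{-2} \approx
2/(\pi^2 K)$ per cycle ($\approx 1.6\times10^{-3}$ at $K = 128$). This
deterministic offset is *not* statistical error: at large $P$ and many
replicates the Monte-Carlo band shrinks below it. The apples-to-apples
deterministic reference is the mode-truncated projection recursion (modes
beyond $K$ carrying no variance), against which the simulator is unbiased;
the test suite asserts exactly that, and reports the offset from the full
recursion rather than asserting it away.

## Scaling analysis

`fit_scaling()` performs ordinary least squares of
$y = \log_2(g)\,\sigma^2_{0,g}$ on $\{1,\ \log_2(\log_2 g)/\log_2 g\}$ —
the aging law linear in its two constants. Unweighted least squares is used
because no error model is available for a deterministic trajectory. The
default window is `validity_window(N)`; both endpoints are overridable and
recorded in the `scaling_fit` object.

Two cautions, both visible in the package's own output. First, the
two-parameter law is an asymptotic form: over accessible windows the
residual curvature is systematic, so the fitted constants drift as the
window moves (the fit object records the window and residual RMS for this
reason). Second, a self-consistency argument fixes the asymptote: the
iterated kernel's central density is $\approx 1/g$, so the deficit
re-injected at the origin must satisfy
$1 - s_g \approx s_g \ln g$, giving
$s_g \to 1/\ln g$, i.e. $A \to 1/\ln 2 \approx 1.44$ on the $\log_2$ scale.
Windowed estimates at reachable $N$ sit above this limit and approach it
slowly from above. The acceptance script reports the constants for the
fixed window $g \in [64, 2048]$ at $N = 8192$ (about a minute of compute);
these are reproducible to the last bit, but they are window-dependent
quantities, not universal constants.

For the Green-function comparison, the Cauchy scale is deliberately treated
as *fitted* (matched to the central density): the per-step characteristic
function $1 - |q|/\pi$ implies a scale $\simeq g/\pi$, half the
continuum-limit value printed in parts of the literature where the lazy
half-retention factor is ambiguous; `cauchy_comparator()` reports the
fitted, $g/\pi$ and $2g/\pi$ candidates side by side so no contested
constant is baked into a passing test.

## Problem sizes used by the tests

The test suite exercises the recursion at $N$ up to 8192 for 2048
generations and the simulator at $P = 10^5$, $K = 128$ with 8 replicate
seeds — the sizes at which the package's headline numbers are quoted — and
smaller sizes everywhere else, chosen so that closed-form values are exact
and Monte-Carlo bands are a few times $10^{-3}$. All fixtures are generated
in code; nothing is read from disk.

## Known limitations

* The recursion describes the complex-normal projection; the simulator's
  hard-conditioning selection implements the projection's assumption rather
  than testing it, and the $\epsilon$-window mode only probes it at
  Monte-Carlo resolution.
* Quantities at $g \gtrsim N/4$ are contaminated by the cutoff; the package
  warns but does not refuse.
* The scaling constants are window-dependent (see above); comparisons
  across studies require matching windows and cutoffs.
* Single circular chromosome, haploid selection, exactly two opposed
  crossovers, no mutation, no drift in the deterministic component.
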