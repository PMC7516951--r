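---
title: "dgpop: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dgpop: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the mathematics implemented by `dgpop`, the
numerical conventions, and the design decisions a user should know before
trusting the output.

## 1. The model

The homogeneous dichotomized-Gaussian (DG) population consists of `n`
exchangeable binary neurons. Neuron `i` spikes in a time bin iff its latent
Gaussian input exceeds zero:

$$u_i = h + \sqrt{1-\alpha}\, v_i + \sqrt{\alpha}\, \varepsilon, \qquad
  x_i = \mathbf{1}[u_i > 0],$$

with private $v_i \sim N(0,1)$ and a single shared drive
$\varepsilon \sim N(0,1)$. Every latent pair has correlation $\alpha$, and
the marginal firing probability is $\mu = \Phi(h)$. The threshold converts
purely pairwise Gaussian input statistics into output correlations of *all*
orders; quantifying those is the point of the package.

**Parameters.** `h` is the latent mean in units of the latent standard
deviation (the threshold is fixed at 0 without loss of generality);
`alpha` $\in [0, 1)$ is the shared-variability fraction. The inverse
parametrisation `dg_model(n, mu = , rho = )` solves the moment map
numerically (bisection; $\Phi_2$ is strictly increasing in its correlation
argument, so the root is unique).

## 2. Output moments from orthant probabilities

Raw output moments are Gaussian orthant probabilities,
$E[x_{i_1}\cdots x_{i_d}] = \Phi_d(h; \Lambda)$, computed by `mvn_orthant`
for $d \le 4$ — exactly the orders needed up to the fourth cross-moment.
Deterministic algorithms are used so results are bitwise reproducible:
closed forms for independent/comonotone/antithetic cases, TVPACK for
$d = 2, 3$, and a Miwa lattice rule with 2048 steps for $d = 4$ (absolute
accuracy around $10^{-12}$, verified in the tests against a conditional-
independence quadrature oracle to $6 \times 10^{-13}$).

Central cross-moments follow by the inclusion–exclusion expansions

$$\Sigma_{ijk} = E[x_ix_jx_k] - \sum \mu\, E[\cdot\cdot] + 2\mu_i\mu_j\mu_k,$$
$$\Sigma_{ijkl} = E[x_ix_jx_kx_l] - \sum \mu\, E[\cdot\cdot\cdot]
  + \sum \mu\mu\, E[\cdot\cdot] - 3\mu_i\mu_j\mu_k\mu_l.$$

For the exchangeable pool these are the skewness coefficient $\zeta$ and
kurtosis coefficient $\chi$ reported by `homogeneous_cumulants` (raw
central cross-moments; standardized ratios are available with
`standardized = TRUE`).

**Feature structure versus firing rate** (`sweep_cumulants`,
`sweep_features`): on the default 99-point $\mu$-grid, $\rho(\mu)$ has its
maximum at $\mu = 0.5$ and rises monotonically below it; $\zeta(\mu)$ has
exactly one sign change, at $\mu = 0.5$ (an exact symmetry: flipping
$x \to 1-x$ maps $h \to -h$ and negates odd central moments); $\chi(\mu)$
is unimodal for weak coupling and develops a local minimum at $\mu = 0.5$
flanked by two maxima for strong coupling.

**Where does the kurtosis turn bimodal?** The exact onset lies between
$\alpha = 0.55$ and $\alpha = 0.6$ on the standard grid
$\{0.4, 0.45, 0.5, 0.55, 0.6, 0.7, 0.8, 0.9, 0.95\}$. The central dip at
$\alpha = 0.6$ has depth $6.5 \times 10^{-5}$ against a curve scale of
$\approx 0.017$ (relative depth $0.4\%$), and $7 \times 10^{-4}$
($\approx 3\%$) at $\alpha = 0.7$. Three independent computations agree:
the Miwa $\Phi_4$ route, a one-dimensional conditional-independence
quadrature $E[x_1 \cdots x_4] = \int \phi(t)\,
\Phi\!\big((\sqrt{\alpha}\,t + h)/\sqrt{1-\alpha}\big)^4 dt$ (agreement
$\le 6\times 10^{-13}$, three orders of magnitude below the dip), and the
fourth central moment of the exact spike-count distribution at $n = 50$,
which has the identical onset. Dips this shallow are invisible when the
curves are plotted, which is why the bimodality is commonly only reported
for $\alpha \ge 0.8$; `sweep_features` deliberately counts strict interior
maxima without any minimum-depth threshold, so it reports the exact onset.
Two expectations in the test suite document this boundary and fail by
design.

## 3. Exact spike-count distribution

Conditioning on the shared drive makes neurons independent with
$L(\varepsilon) = \Phi((\varepsilon + h)/\sqrt{1-\alpha})$, so

$$P(k) = \binom{n}{k} \int \phi_\alpha(\varepsilon)\,
  L^k (1-L)^{n-k}\, d\varepsilon.$$

`spike_count_pmf` evaluates this by adaptive quadrature on the standardized
shared drive over $[-8, 8]$ SDs (truncation error below $10^{-15}$), with
the integrand assembled in the log domain so large `n` cannot overflow.
`alpha = 0` short-circuits to the binomial. Identities checked in the
tests: $\sum_k P(k) = 1$ to $10^{-12}$, $E[k] = n\mu$,
$\mathrm{Var}[k] = n\mu(1-\mu) + n(n-1)\sigma$, and the flip symmetry
$P_k(h) = P_{n-k}(-h)$.

## 4. Information geometry

With $Q(m) = P(m)/\binom{n}{m}$ the per-pattern probability, the
exchangeable log-linear expansion is
$\log Q(m) = \sum_{i \le m} \binom{m}{i}\theta_i - \psi$, inverted by the
alternating finite difference
$\theta_k = \sum_{j=0}^k (-1)^{k-j}\binom{k}{j}\log Q(j)$.

**Precision.** The alternating sum cancels catastrophically at high
orders. No extended-precision arithmetic is available in the target
environment, so `theta_from_pmf` works in double precision and attaches an
explicit first-order error bound per order
($\varepsilon_{\text{mach}} \sum_j \binom{k}{j}\lvert\log Q(j)\rvert$) plus
a `reliable` flag. Because $\log Q$ itself carries only $\sim 10^{-16}$
absolute error, orders up to $k \approx 20$ at $n = 50$ are
well-determined; round-trips at $n \le 10$ reproduce $\theta$ to
$10^{-8}$, which the tests verify together with a brute-force $2^n$
subset-enumeration oracle.

**Entropy** is computed through exchangeability,
$H = -\sum_k P(k)[\log P(k) - \log\binom{n}{k}]$, and decreases with
$\alpha$ at fixed $\mu$.

**Fisher information — two readings.** `fisher_information` defaults to
the information the count carries about its own firing rate at fixed
$\alpha$ (central finite difference in $h$ with chain rule through
$\mu = \Phi(h)$). Shared variability makes the count *less* informative
about the rate, so this quantity decreases with $\alpha$. The
complementary decoding view — information about the *shared input*
$\varepsilon$, $E_\varepsilon[n L'^2 / (L(1-L))]$ — instead grows with
$\alpha$ and is available as `about = "common_input"`. Both monotonicities
are asserted in the tests; be explicit about which reading you need.

## 5. Criticality

**Asymptotic density.** As $n \to \infty$ the active fraction
$r = \Phi((\varepsilon + h)/\sqrt{1-\alpha})$ has, in the Gaussian
coordinate $u = \Phi^{-1}(r)$,

$$\log f(r) = \tfrac12\log\tfrac{1-\alpha}{\alpha}
  + \frac{-(1-2\alpha)u^2 + 2\sqrt{1-\alpha}\,h\,u - h^2}{2\alpha},$$

i.e. $u \sim N\!\big(h/\sqrt{1-\alpha},\ \alpha/(1-\alpha)\big)$. This
exact change-of-variables form contains no $1/(1-2\alpha)$, so
$\alpha = 1/2$ needs no special branch: at $h = 0, \alpha = 1/2$ the
density is exactly uniform, with moments $\mu = 1/2$, $\rho = 1/3$,
$\zeta = 0$, $\chi = 1/80$ (all verified to $10^{-10}$ or better). Below
$\alpha = 1/2$ the density is unimodal; above, it diverges at both
boundaries — the bimodal UP/DOWN regime.

**Modality detection.** `modality` counts strict local maxima of
$\log f$ on a grid in $u$ (monotone in $r$; resolves the boundary
singularities). For $h \neq 0$ and $\alpha$ slightly above $1/2$ the
U-shape upturn can begin beyond any finite grid, so positive tail
curvature of $\log f$ at *both* ends — the exact signature of the convex
(bimodal) regime, since $\log f$ is quadratic in $u$ — also marks both
boundaries as modes. With this rule `modality_threshold` locates the
transition at $\alpha = 0.5000 \pm 10^{-3}$ for every tested $h$,
confirming its $h$-independence.

**Integration domains.** Integrals against $f$ (e.g.
`asymptotic_cumulants`) use the standardized grid
$u = \mu_u \pm 8 s_u$: a fixed window would cover only $\pm 1.8$ SD at
$\alpha = 0.95$ and break normalization. The *tempered* integrals instead
keep the fixed window $u \in [-8, 8]$, which doubles as the regularizer
the tempered family needs (below).

**Temperature extension.** $P_\beta \propto P^\beta$ with $\beta = 1/T$
acts on the asymptotic density as
$f_\beta(r) \propto f(r)^\beta \exp\{n(1-\beta)\eta(r)\}$, where
$\eta(r) = -r\log r - (1-r)\log(1-r)$ is the Stirling form of the pattern
multiplicity. For $\alpha > 1/2$ and small $T$, $f^\beta$ alone is not
normalizable on $(0,1)$; the fixed $u$-window plays the role of finite
$n$. From $f_\beta$: entropy rate $h_{DG} = \int f_\beta\, \eta$, specific
heat $c = n \int f_\beta (\eta - h_{DG})^2$, log-probability cumulants
$\nu_2, \nu_4$, and the Binder cumulant $B = 1 - \nu_4/(3\nu_2^2)$. An
exact finite-$n$ tempering of the spike-count distribution,
$P_\beta(k) \propto \binom{n}{k}^{1-\beta} P(k)^\beta$, is available as a
cross-check (`exact = TRUE`).

**Binder crossing.** At $\beta = 1$ the multiplicity term drops out, so
$f_\beta = f$ for *every* $n$ and $B(T{=}1)$ is size-independent — the
curves for different sizes meet at $T = 1$ exactly. They meet
*tangentially* (the difference does not change sign), so
`crossing_temperature` does not rely on sign flips alone: it collects all
pairwise intersections (grid points where $B_i - B_j$ vanishes to
$10^{-9}$, plus interpolated sign changes) and reports the consensus
combination minimizing the cross-pair spread. At $(h = 0, \alpha = 0.8)$,
sizes $\{10, 20, 50\}$, the detected crossing is $T = 1.00$ with spread 0;
incidental low-$T$ intersections (truncation artifacts) scatter by
$\sim 0.1$ and are rejected. This mirrors the Binder-method logic itself:
only at criticality do all size pairs agree.

## 6. Simulation and empirical estimation

`simulate.dg_model` draws rasters vectorised over trials with a mandatory
seed (the caller's RNG state is saved and restored). `empirical_cumulants`
computes the exchangeability-averaged $\hat\mu, \hat\rho, \hat\zeta,
\hat\chi$ *exactly* — the averages over all distinct index
pairs/triples/quadruples — via elementary symmetric polynomials of the
centered rows in $O(\text{trials} \times n)$, avoiding both tuple
enumeration and subsampling; the tests verify exact equality with
brute-force enumeration. Trial-to-trial standard errors are attached, and
the Monte-Carlo checks assert agreement with the analytic moments within
three standard errors at $10^5$ trials.

## 7. Sizes, runtime, limitations

- A full 9-value $\alpha$ sweep on the 99-point $\mu$-grid costs ~10 s
  (dominated by Miwa $\Phi_4$); a 151-point thermodynamic curve for three
  sizes costs ~5 s; the exact PMF at $n = 50$ costs ~50 ms.
- Supported regimes: equicorrelated nonnegative latent coupling
  $\alpha \in [0, 1)$ for the homogeneous pool; general $h$ and
  correlation matrices only up to $d = 4$ in `mvn_orthant`.
- `theta` orders beyond the `reliable` flag are numerically meaningless in
  double precision; consult `err_bound`.
- The tempered quantities inherit the fixed-window regularization; at very
  low $T$ they describe the truncated family, not a normalizable continuum
  limit.
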