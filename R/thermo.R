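#' Temperature-extended spike-count density
#'
#' The temperature extension of the model distribution,
#' \eqn{P_\beta(x) = P(x)^\beta / Z_\beta} with \eqn{\beta = 1/T}, acts on
#' the asymptotic active-fraction density as
#' \deqn{f_\beta(r) \propto f(r)^\beta \exp\{n (1-\beta)\, \eta(r)\},}
#' where \eqn{\eta(r) = -r\log r - (1-r)\log(1-r)} is the Stirling form of
#' the per-neuron pattern multiplicity. At \eqn{\beta = 1} this is `f`
#' itself, for every `n` -- the basis of the Binder-cumulant crossing at
#' the critical temperature T = 1.
#'
#' The density is represented on a fixed Gauss-Legendre grid in
#' \eqn{u = \Phi^{-1}(r)} over \eqn{[-8, 8]} and normalized there (computed
#' in the log domain). The fixed window also regularizes the low-T regime
#' for \eqn{\alpha > 1/2}, where \eqn{f^\beta} alone would not be
#' normalizable on (0, 1); see the package vignette.
#'
#' @param fr a `"dg_fr"` asymptotic density.
#' @param n population size entering the multiplicity term.
#' @param beta inverse temperature, `> 0`.
#' @param n_nodes Gauss-Legendre node count.
#' @return object of class `"dg_tempered"`: list with grid `u`, `r`,
#'   probability masses `mass` (summing to 1), `log_fbeta` (normalized
#'   log-density values in `r`), and the generating `n`, `beta`, `h`,
#'   `alpha`.
#' @export
tempered_density <- function(fr, n, beta, n_nodes = 801) {
  stopifnot(inherits(fr, "dg_fr"))
  n <- check_count(n, "n")
  check_scalar(beta, "beta")
  if (beta <= 0) stop("'beta' must be positive", call. = FALSE)
  gl <- gauss_legendre(n_nodes, -8, 8)
  u <- gl$x
  r <- stats::pnorm(u)
  # log of w_i * fbeta(r_i) * dr/du, normalized by logsumexp
  log_kernel <- beta * fr$log_f_u(u) + n * (1 - beta) * eta_binary(r) +
    stats::dnorm(u, log = TRUE)
  lw <- log(gl$w) + log_kernel
  lZ <- logsumexp(lw)
  structure(list(u = u, r = r, mass = exp(lw - lZ),
                 log_fbeta = log_kernel - lZ,
                 n = n, beta = beta, h = fr$h, alpha = fr$alpha),
            class = "dg_tempered")
}

# integral of g(r) against a tempered density (or any object carrying
# probability masses on an r grid)
tempered_integral <- function(fbeta, g) sum(fbeta$mass * g(fbeta$r))

#' Entropy rate of a tempered DG population
#'
#' \eqn{h_{DG} = \int_0^1 f_\beta(r)\, \eta(r)\, dr}, the large-`n` entropy
#' per neuron (nats), bounded by \eqn{\log 2}.
#'
#' @param fbeta a `"dg_tempered"` density (or any list with fields `r` and
#'   `mass`).
#' @return entropy rate in nats per neuron.
#' @export
entropy_rate <- function(fbeta) {
  tempered_integral(fbeta, eta_binary)
}

#' Specific heat of a tempered DG population
#'
#' Dominant large-`n` term of the variance of the per-neuron log
#' probability: \eqn{c = n \int f_\beta(r) (\eta(r) - h_{DG})^2 dr}.
#'
#' @param fbeta a `"dg_tempered"` density.
#' @param n population size (defaults to the one stored in `fbeta`).
#' @param hdg entropy rate; recomputed if missing.
#' @return the specific heat, `>= 0`.
#' @export
specific_heat <- function(fbeta, n = fbeta$n, hdg = entropy_rate(fbeta)) {
  n * tempered_integral(fbeta, function(r) (eta_binary(r) - hdg)^2)
}

#' Binder cumulant of a tempered DG population
#'
#' Second and fourth cumulants of the log-probability fluctuations,
#' \eqn{\nu_2 = n^2 \int f_\beta (\eta - h_{DG})^2 dr} and
#' \eqn{\nu_4 = n^4 \int f_\beta (\eta - h_{DG})^4 dr}, and the Binder
#' ratio \eqn{B = 1 - \nu_4 / (3 \nu_2^2)}. The powers of `n` cancel in
#' `B`, which therefore depends on `n` only through \eqn{f_\beta} -- so at
#' \eqn{\beta = 1}, where \eqn{f_\beta = f}, `B` is size-independent and
#' curves for different `n` cross at T = 1.
#'
#' @param fbeta a `"dg_tempered"` density.
#' @param n population size (defaults to the one stored in `fbeta`).
#' @param hdg entropy rate; recomputed if missing.
#' @return list with `nu2`, `nu4`, `B`.
#' @export
binder_cumulant <- function(fbeta, n = fbeta$n, hdg = entropy_rate(fbeta)) {
  m2 <- tempered_integral(fbeta, function(r) (eta_binary(r) - hdg)^2)
  m4 <- tempered_integral(fbeta, function(r) (eta_binary(r) - hdg)^4)
  if (m2 <= 0)
    stop("degenerate (point-mass) tempered density: Binder cumulant ",
         "undefined", call. = FALSE)
  list(nu2 = n^2 * m2, nu4 = n^4 * m4, B = 1 - m4 / (3 * m2^2))
}

#' Thermodynamic curve of the DG model over a temperature grid
#'
#' For each temperature `T` (\eqn{\beta = 1/T}) computes the tempered
#' density and its entropy rate, specific heat, second and fourth
#' log-probability cumulants and Binder cumulant.
#'
#' `exact = TRUE` uses the exact finite-`n` tempering of the spike-count
#' distribution, \eqn{P_\beta(k) \propto \binom{n}{k}^{1-\beta} P(k)^\beta},
#' instead of the asymptotic (Stirling) form -- useful as a cross-check at
#' small `n`; its `B` is only asymptotically size-independent at T = 1.
#'
#' @param n population size.
#' @param h latent mean.
#' @param alpha latent correlation in (0, 1).
#' @param T_grid temperatures, all `> 0`.
#' @param exact use exact finite-`n` tempering (flagged cross-check).
#' @param n_nodes quadrature nodes for the asymptotic route.
#' @return data frame of class `"dg_thermo"` with columns
#'   `n, T, beta, hdg, c, nu2, nu4, B`.
#' @export
thermo_curve <- function(n, h, alpha, T_grid = seq(0.5, 2, by = 0.01),
                         exact = FALSE, n_nodes = 801) {
  n <- check_count(n, "n")
  if (any(T_grid <= 0)) stop("temperatures must be positive", call. = FALSE)
  if (!exact) fr <- asymptotic_density(h, alpha)
  else pmf <- spike_count_pmf(n, h = h, alpha = alpha)
  rows <- lapply(T_grid, function(Tt) {
    beta <- 1 / Tt
    fb <- if (!exact) tempered_density(fr, n, beta, n_nodes = n_nodes)
          else tempered_pmf(pmf, beta)
    hdg <- entropy_rate(fb)
    bc <- binder_cumulant(fb, n = n, hdg = hdg)
    data.frame(n = n, T = Tt, beta = beta, hdg = hdg,
               c = specific_heat(fb, n = n, hdg = hdg),
               nu2 = bc$nu2, nu4 = bc$nu4, B = bc$B)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dg_thermo", class(out))
  out
}

# exact finite-n tempering: P_beta(k) = C(n,k)^(1-beta) P(k)^beta / Z,
# represented as atoms at r = k/n so the same integral helpers apply
tempered_pmf <- function(pmf, beta) {
  n <- pmf$n
  k <- 0:n
  lw <- (1 - beta) * lchoose(n, k) + beta * pmf$log_p
  lZ <- logsumexp(lw)
  list(u = stats::qnorm(clip_prob(k / n)), r = k / n,
       mass = exp(lw - lZ), n = n, beta = beta, h = pmf$h,
       alpha = pmf$alpha)
}

#' Binder-cumulant crossing temperature across population sizes
#'
#' Locates the critical temperature as the common intersection of
#' Binder-cumulant curves computed for different population sizes on a
#' shared temperature grid. For each pair of sizes, every intersection of
#' \eqn{B_i(T)} and \eqn{B_j(T)} is collected: grid points where the
#' difference vanishes to numerical precision (at T = 1 the curves
#' coincide exactly, since \eqn{f_\beta = f} there for every `n`) and
#' linearly interpolated sign changes. The reported crossing is the
#' consensus: one intersection per pair, chosen jointly to minimize the
#' spread across pairs -- at the critical temperature the intersections of
#' all pairs coincide, whereas incidental intersections scatter.
#'
#' @param curves a list of `"dg_thermo"` data frames with distinct `n`,
#'   sharing the same `T` grid.
#' @param zero_tol treat `|B_i - B_j|` below this as an exact intersection.
#' @return mean crossing temperature over pairs, with attributes
#'   `crossings` (the per-pair consensus intersections) and `spread`
#'   (their max - min).
#' @export
crossing_temperature <- function(curves, zero_tol = 1e-9) {
  if (length(curves) < 2L) stop("need at least two curves", call. = FALSE)
  Tg <- curves[[1]]$T
  for (cu in curves)
    if (length(cu$T) != length(Tg) || max(abs(cu$T - Tg)) > 1e-12)
      stop("curves must share a common temperature grid", call. = FALSE)
  pairs <- utils::combn(length(curves), 2)
  cand_list <- apply(pairs, 2, function(ij) {
    D <- curves[[ij[1]]]$B - curves[[ij[2]]]$B
    if (max(abs(D)) < zero_tol)
      stop("curves are identical everywhere; crossing undefined",
           call. = FALSE)
    cand <- Tg[abs(D) < zero_tol]
    flips <- which(D[-length(D)] * D[-1] < 0)
    for (i in flips) {
      tc <- Tg[i] + (Tg[i + 1] - Tg[i]) * D[i] / (D[i] - D[i + 1])
      # skip flips adjacent to an exact zero (the same intersection)
      if (length(cand) == 0L || min(abs(cand - tc)) > 2 * (Tg[2] - Tg[1]))
        cand <- c(cand, tc)
    }
    if (length(cand) == 0L)
      stop("no crossing of the Binder curves inside the temperature grid",
           call. = FALSE)
    sort(unique(cand))
  }, simplify = FALSE)
  combos <- as.matrix(expand.grid(cand_list))
  spreads <- apply(combos, 1, function(x) max(x) - min(x))
  best <- combos[which.min(spreads), ]
  crossings <- as.numeric(best)
  structure(mean(crossings), crossings = crossings,
            spread = max(crossings) - min(crossings))
}
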