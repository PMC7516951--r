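# Internal numerical helpers.

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Cached Gauss-Legendre rules (pracma::gaussLegendre is deterministic)
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n, a, b) {
  key <- sprintf("%d_%.17g_%.17g", n, a, b)
  rule <- .gl_cache[[key]]
  if (is.null(rule)) {
    gl <- pracma::gaussLegendre(n, a, b)
    rule <- list(x = gl$x, w = gl$w)
    .gl_cache[[key]] <- rule
  }
  rule
}

# binary Shannon surprise eta(r) = -r log r - (1-r) log(1-r), nats;
# eta(0) = eta(1) = 0 by continuity
eta_binary <- function(r) {
  out <- numeric(length(r))
  ok <- r > 0 & r < 1
  rr <- r[ok]
  out[ok] <- -rr * log(rr) - (1 - rr) * log1p(-rr)
  out
}

# clip a firing probability away from {0,1} before qnorm
clip_prob <- function(mu, eps = 1e-12) pmin(pmax(mu, eps), 1 - eps)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%g, %g], got %g", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower)
    stop(sprintf("'%s' must be an integer >= %d", name, lower), call. = FALSE)
  as.integer(x)
}

# run a stochastic expression under a seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", lower = 0L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
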