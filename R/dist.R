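#' Distribution specifications for probabilistic inputs
#'
#' A `dist_spec` describes how one uncertain quantity (an exposure parameter
#' or a soil concentration) is drawn in the Monte Carlo engine. Supported
#' kinds are `point`, `normal`, `lognormal`, `uniform` and `triangular`;
#' every kind except `point` and `uniform` accepts optional truncation
#' bounds. Truncation is applied exactly, by rescaling the CDF before
#' inverting it, so no draw ever falls outside `[lower, upper]`.
#'
#' `normal` and `lognormal` are parameterised by the *arithmetic* mean and
#' standard deviation of the untruncated law, which is how survey tables
#' report them; the lognormal parameters on the log scale are derived
#' internally.
#'
#' @param kind Distribution kind.
#' @param mean,sd Arithmetic mean and standard deviation (`normal`,
#'   `lognormal`).
#' @param min,max Support bounds (`uniform`, `triangular`).
#' @param mode Mode of a triangular distribution.
#' @param value Point value (`point`).
#' @param lower,upper Optional truncation bounds.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_lognormal(100, 60)
#' dist_normal(64.3, 10.5, lower = 40, upper = 100)
#' @name dist_spec
NULL

new_dist_spec <- function(kind, args, lower = -Inf, upper = Inf) {
  if (!is.finite(lower) && !is.finite(upper)) {
    lower <- -Inf
    upper <- Inf
  }
  if (lower >= upper) stopf("truncation bounds must satisfy lower < upper")
  structure(list(kind = kind, args = args, lower = lower, upper = upper),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stopf("point value must be a single finite number")
  }
  new_dist_spec("point", list(value = value))
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, lower = -Inf, upper = Inf) {
  check_positive(sd, "sd")
  new_dist_spec("normal", list(mean = mean, sd = sd), lower, upper)
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(mean, sd, lower = 0, upper = Inf) {
  check_positive(mean, "mean")
  check_positive(sd, "sd")
  pars <- lnorm_params(mean, sd)
  new_dist_spec("lognormal", pars, max(lower, 0), upper)
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min, max) {
  if (min >= max) stopf("uniform requires min < max")
  new_dist_spec("uniform", list(min = min, max = max))
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max, lower = -Inf, upper = Inf) {
  if (!(min <= mode && mode <= max && min < max)) {
    stopf("triangular requires min <= mode <= max and min < max")
  }
  new_dist_spec("triangular", list(min = min, mode = mode, max = max),
                lower, upper)
}

#' @export
print.dist_spec <- function(x, ...) {
  args <- paste(names(x$args), signif(unlist(x$args), 5),
                sep = " = ", collapse = ", ")
  trunc <- if (is.finite(x$lower) || is.finite(x$upper)) {
    sprintf(" truncated to [%s, %s]", signif(x$lower, 5), signif(x$upper, 5))
  } else ""
  cat(sprintf("<dist_spec %s(%s)%s>\n", x$kind, args, trunc))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

# log-scale parameters of the lognormal with given arithmetic mean / sd
lnorm_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

dist_cdf <- function(spec, q) {
  switch(spec$kind,
    normal = pnorm(q, spec$args$mean, spec$args$sd),
    lognormal = plnorm(pmax(q, 0), spec$args$meanlog, spec$args$sdlog),
    uniform = punif(q, spec$args$min, spec$args$max),
    triangular = ptri(q, spec$args$min, spec$args$mode, spec$args$max),
    stopf("no CDF for kind '%s'", spec$kind)
  )
}

dist_quantile <- function(spec, p) {
  switch(spec$kind,
    normal = qnorm(p, spec$args$mean, spec$args$sd),
    lognormal = qlnorm(p, spec$args$meanlog, spec$args$sdlog),
    uniform = qunif(p, spec$args$min, spec$args$max),
    triangular = qtri(p, spec$args$min, spec$args$mode, spec$args$max),
    stopf("no quantile function for kind '%s'", spec$kind)
  )
}

ptri <- function(q, a, c, b) {
  p <- numeric(length(q))
  p[q >= b] <- 1
  i <- q > a & q <= c
  p[i] <- (q[i] - a)^2 / ((b - a) * (c - a))
  i <- q > c & q < b
  p[i] <- 1 - (b - q[i])^2 / ((b - a) * (b - c))
  p
}

qtri <- function(p, a, c, b) {
  pc <- (c - a) / (b - a)
  ifelse(p <= pc,
         a + sqrt(p * (b - a) * (c - a)),
         b - sqrt((1 - p) * (b - a) * (b - c)))
}

#' Draw from a distribution specification
#'
#' Inverse-CDF sampling: uniforms are mapped through the (truncation-rescaled)
#' quantile function, so truncation bounds are honoured exactly and a fixed
#' seed yields identical draws.
#'
#' @param spec A [dist_spec].
#' @param n Number of draws.
#' @param u Optional vector of uniforms in (0, 1), e.g. copula-correlated
#'   ones; defaults to `runif(n)`.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n, u = NULL) {
  if (!is_dist_spec(spec)) stopf("`spec` must be a dist_spec")
  if (n < 1) stopf("`n` must be >= 1")
  if (spec$kind == "point") return(rep(spec$args$value, n))
  u <- u %||% runif(n)
  pl <- dist_cdf(spec, spec$lower)
  pu <- dist_cdf(spec, spec$upper)
  if (pu - pl <= 0) stopf("truncation interval has zero probability mass")
  dist_quantile(spec, pl + u * (pu - pl))
}

#' Sample a set of named parameters
#'
#' @param specs Named list of [dist_spec] objects.
#' @param n Number of draws per parameter.
#' @param seed Integer seed; draws are deterministic given `(specs, n, seed)`.
#' @return Named list of numeric vectors of length `n`.
#' @export
sample_parameters <- function(specs, n, seed = NULL) {
  if (!length(specs) || is.null(names(specs)) || any(!nzchar(names(specs)))) {
    stopf("`specs` must be a non-empty named list")
  }
  bad <- names(specs)[!vapply(specs, is_dist_spec, logical(1))]
  if (length(bad)) stopf("invalid distribution spec for parameter '%s'", bad[1])
  draw <- function() lapply(specs, sample_dist, n = n)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# --- truncated moments and moment matching ---------------------------------

# mean and sd of a normal / lognormal restricted to [lower, upper]
tmom_norm <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

tmom_lnorm <- function(meanlog, sdlog, lower, upper) {
  a <- (log(pmax(lower, .Machine$double.xmin)) - meanlog) / sdlog
  b <- (log(upper) - meanlog) / sdlog
  Z <- pnorm(b) - pnorm(a)
  m1 <- exp(meanlog + sdlog^2 / 2) * (pnorm(b - sdlog) - pnorm(a - sdlog)) / Z
  m2 <- exp(2 * meanlog + 2 * sdlog^2) *
    (pnorm(b - 2 * sdlog) - pnorm(a - 2 * sdlog)) / Z
  c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

#' Match a truncated distribution to target moments
#'
#' Finds parameters of a normal or lognormal law such that, *after*
#' truncation to `[lower, upper]`, its mean and standard deviation equal the
#' targets. Matching the truncated rather than the parent moments is what
#' makes generated surveys reproduce tabulated survey moments. The
#' untruncated closed-form parameters are the starting point of a
#' Nelder-Mead search on (location, log scale).
#'
#' @param mean,sd Target moments of the truncated law.
#' @param lower,upper Truncation bounds.
#' @param law `"lognormal"` or `"normal"`.
#' @param tol Relative tolerance on the achieved moments.
#' @return A [dist_spec] with the fitted parameters and the given bounds.
#' @export
match_truncated <- function(mean, sd, lower, upper,
                            law = c("lognormal", "normal"), tol = 1e-5) {
  law <- match.arg(law)
  check_positive(sd, "sd")
  if (lower >= upper) stopf("truncation bounds must satisfy lower < upper")
  if (mean <= lower || mean >= upper) {
    stopf("target mean %.4g lies outside truncation bounds [%.4g, %.4g]",
          mean, lower, upper)
  }
  tmom <- if (law == "lognormal") {
    function(p) tmom_lnorm(p[1], exp(p[2]), lower, upper)
  } else {
    function(p) tmom_norm(p[1], exp(p[2]), lower, upper)
  }
  start <- if (law == "lognormal") {
    p <- lnorm_params(mean, sd)
    c(p$meanlog, log(p$sdlog))
  } else {
    c(mean, log(sd))
  }
  obj <- function(p) {
    m <- tmom(p)
    if (any(!is.finite(m))) return(1e10)
    ((m[1] - mean) / mean)^2 + ((m[2] - sd) / sd)^2
  }
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  got <- tmom(fit$par)
  if (abs(got[1] - mean) / mean > tol || abs(got[2] - sd) / sd > tol) {
    stopf(paste0("cannot match mean %.4g, sd %.4g on [%.4g, %.4g] with a ",
                 "truncated %s (achieved mean %.4g, sd %.4g)"),
          mean, sd, lower, upper, law, got[1], got[2])
  }
  if (law == "lognormal") {
    new_dist_spec("lognormal",
                  list(meanlog = fit$par[1], sdlog = exp(fit$par[2])),
                  max(lower, 0), upper)
  } else {
    new_dist_spec("normal",
                  list(mean = fit$par[1], sd = exp(fit$par[2])),
                  lower, upper)
  }
}
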