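#' Arrival / service time distribution specification
#'
#' A `dist_spec` describes the stochastic process behind an interarrival or
#' service time stream: a family plus its `mean` and `sd` in minutes, and a
#' hard lower bound that every sampled value respects.
#'
#' Families:
#' \describe{
#'   \item{`truncated_normal`}{A normal distribution with the given
#'     (pre-truncation) `mean` and `sd`, truncated at `lower` (draws are
#'     conditioned on exceeding the bound). Note the realized mean of draws
#'     exceeds `mean` when the truncation bites; [dist_mean()] returns the
#'     realized (post-truncation) mean.}
#'   \item{`clipped_normal`}{A normal distribution with draws below `lower`
#'     set *equal to* `lower` (censoring), leaving a point mass at the
#'     bound. For an interarrival process a zero gap means simultaneous
#'     arrivals, i.e. patients arriving in small bursts — the behavior of
#'     simulation languages that replace negative normal interarrival draws
#'     by zero.}
#'   \item{`lognormal`}{Moment-matched lognormal: `mean` and `sd` are the
#'     mean and standard deviation of the sampled variate itself.}
#'   \item{`exponential`}{Exponential with mean `mean` (requires `lower == 0`).}
#'   \item{`constant`}{Degenerate at `mean` (requires `sd == 0`).}
#' }
#'
#' @param family One of `"truncated_normal"`, `"exponential"`, `"lognormal"`,
#'   `"constant"`.
#' @param mean Mean in minutes (pre-truncation for `truncated_normal`).
#' @param sd Standard deviation in minutes; 0 for `constant`.
#' @param lower Hard lower bound of the support (minutes, default 0).
#' @return An object of class `dist_spec`.
#' @examples
#' inter <- dist_spec("truncated_normal", mean = 4.2, sd = 5.8)
#' dist_mean(inter)        # realized mean after truncation at 0 (~6.52)
#' set.seed(1); x <- dist_sample(inter, 5)
#' all(x >= 0)
#' @export
dist_spec <- function(family = c("truncated_normal", "clipped_normal",
                                 "exponential", "lognormal", "constant"),
                      mean, sd = 0, lower = 0) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("dist_spec: `mean` must be a finite number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("dist_spec: `sd` must be a finite non-negative number", call. = FALSE)
  if (family != "constant" && mean <= 0)
    stop("dist_spec: `mean` must be > 0 for family '", family, "'",
         call. = FALSE)
  if (family == "constant" && sd != 0)
    stop("dist_spec: `sd` must be 0 for family 'constant'", call. = FALSE)
  if (family %in% c("exponential", "lognormal") && lower != 0)
    stop("dist_spec: `lower` must be 0 for family '", family, "'",
         call. = FALSE)
  structure(list(family = family, mean = mean, sd = sd, lower = lower),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s mean=%g sd=%g lower=%g>\n",
              x$family, x$mean, x$sd, x$lower))
  invisible(x)
}

#' Sample from a distribution specification
#'
#' Draws use the current R RNG state; callers manage seeding (the engine
#' assigns one substream per stochastic source so that scenario comparisons
#' share common random numbers).
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`, every value `>= spec$lower`.
#' @export
dist_sample <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  if (n == 0L) return(numeric(0))
  x <- switch(spec$family,
    truncated_normal = {
      if (spec$sd == 0) rep(max(spec$mean, spec$lower), n)
      else {
        p0 <- stats::pnorm(spec$lower, spec$mean, spec$sd)
        # inverse-CDF sampling of the conditional (truncated) distribution
        stats::qnorm(p0 + stats::runif(n) * (1 - p0), spec$mean, spec$sd)
      }
    },
    clipped_normal = stats::rnorm(n, spec$mean, spec$sd),  # pmax below
    exponential = stats::rexp(n, rate = 1 / spec$mean),
    lognormal = {
      p <- lnorm_params(spec$mean, spec$sd)
      stats::rlnorm(n, meanlog = p[1L], sdlog = p[2L])
    },
    constant = rep(spec$mean, n)
  )
  x <- pmax(x, spec$lower)
  if (any(!is.finite(x)))
    stop("dist_sample: non-finite value sampled from ", spec$family,
         " distribution (mean=", spec$mean, ", sd=", spec$sd, ")",
         call. = FALSE)
  x
}

#' Realized mean of a distribution specification
#'
#' For `truncated_normal` this is the post-truncation mean
#' \eqn{\mu + \sigma \phi(\alpha)/(1 - \Phi(\alpha))} with
#' \eqn{\alpha = (l - \mu)/\sigma}; for the other families it equals `mean`.
#'
#' @param spec A [dist_spec()].
#' @return Expected value of a sampled variate, in minutes.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$sd == 0) return(max(spec$mean, spec$lower))
  a <- (spec$lower - spec$mean) / spec$sd
  switch(spec$family,
    truncated_normal = spec$mean +
      spec$sd * stats::dnorm(a) / (1 - stats::pnorm(a)),
    clipped_normal = spec$lower * stats::pnorm(a) +
      spec$mean * (1 - stats::pnorm(a)) + spec$sd * stats::dnorm(a),
    spec$mean)
}

#' Realized standard deviation of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @return Standard deviation of a sampled variate, in minutes.
#' @export
dist_sd <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$sd == 0) return(0)
  a <- (spec$lower - spec$mean) / spec$sd
  switch(spec$family,
    truncated_normal = {
      lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
      spec$sd * sqrt(1 + a * lam - lam^2)
    },
    clipped_normal = {
      ex2 <- spec$lower^2 * stats::pnorm(a) +
        (spec$mean^2 + spec$sd^2) * (1 - stats::pnorm(a)) +
        spec$sd * (spec$lower + spec$mean) * stats::dnorm(a)
      sqrt(ex2 - dist_mean(spec)^2)
    },
    spec$sd)
}

# meanlog/sdlog of the lognormal with the given arithmetic mean and sd
lnorm_params <- function(mean, sd) {
  if (sd == 0) return(c(log(mean), 0))
  s2 <- log(1 + (sd / mean)^2)
  c(log(mean) - s2 / 2, sqrt(s2))
}
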