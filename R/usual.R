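# Habitual (usual) intake estimation from repeated 24-h recalls:
# a one-part measurement-error model. Daily values are transformed towards
# normality, the variance is decomposed into between- and within-person
# components with survey-weighted moments, person means are shrunk towards
# the stratum mean so the usual-intake distribution carries the
# between-person variance only, and results are back-transformed.

#' Survey-weighted quantiles
#'
#' Frequency-weight generalisation of R's default (type 7) quantile: for
#' integer weights the result is identical to `quantile(rep(x, w), type = 7)`,
#' so doubling a person's weight is exactly equivalent to duplicating that
#' person.
#'
#' @param x Numeric values.
#' @param w Positive weights (default: equal).
#' @param probs Probabilities in \[0, 1\].
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs) {
  stopifnot(length(x) == length(w), all(w > 0),
            all(probs >= 0 & probs <= 1))
  if (length(x) == 0) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  W <- cw[length(cw)]
  value_at <- function(pos) {
    # value of the pos-th observation of the weight-expanded sample
    x[min(which(cw >= pos - 1e-12))]
  }
  vapply(probs, function(p) {
    h <- p * (W - 1) + 1
    j <- floor(h)
    lo <- value_at(max(j, 1))
    hi <- value_at(min(j + 1, W))
    lo + (h - j) * (hi - lo)
  }, numeric(1))
}

weighted_mean_ <- function(x, w) sum(w * x) / sum(w)

# unbiased-style weighted variance (frequency-weight convention)
weighted_var_ <- function(x, w) {
  m <- weighted_mean_(x, w)
  sum(w * (x - m)^2) / (sum(w) - 1)
}

boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

boxcox_inverse <- function(y, lambda) {
  if (abs(lambda) < 1e-8) exp(y) else (lambda * y + 1)^(1 / lambda)
}

# profile log-likelihood estimate of the Box-Cox exponent on pooled values
boxcox_lambda <- function(x, interval = c(-2, 2)) {
  n <- length(x)
  slx <- sum(log(x))
  nll <- function(lambda) {
    y <- boxcox_transform(x, lambda)
    n / 2 * log(stats::var(y) * (n - 1) / n) - (lambda - 1) * slx
  }
  optimize(nll, interval)$minimum
}

#' Estimate the habitual intake distribution from repeated recall days
#'
#' One-part usual-intake model for a daily-consumed nutrient: daily values
#' are transformed (`log` by default; `identity`, or `boxcox` with the
#' exponent chosen by maximum likelihood), the transformed values are
#' decomposed into between-person and within-person variance components by
#' survey-weighted one-way random-effects moments, each person's mean is
#' shrunk towards the weighted stratum mean by
#' `sqrt(s2_between / (s2_between + s2_within / n_days))` — so that the
#' population of shrunken values carries the between-person variance, free
#' of day-to-day noise — and the shrunken values are back-transformed into
#' a weighted population of person-level usual intakes.
#'
#' @param data Tibble of person-day records with columns `pid`, `value`
#'   (positive daily intake), and optionally `weight` (survey weight,
#'   default 1) and `day`.
#' @param transform `"log"` (default), `"identity"`, or `"boxcox"`.
#' @param metric Free-text label of the quantity (used to guard against
#'   querying a distribution on the wrong scale).
#' @return A `usual_intake` object; query it with [percentile()],
#'   [prevalence_below()], [tidy()] and [glance()].
#' @export
estimate_usual_intake <- function(data, transform = c("log", "identity", "boxcox"),
                                  metric = "value") {
  transform <- match.arg(transform)
  stopifnot(all(c("pid", "value") %in% names(data)))
  if (!"weight" %in% names(data)) data$weight <- 1
  if (n_distinct(data$pid) < 2) {
    abort("at least two persons are required", class = "dietshift_data_error")
  }
  if (transform != "identity" && any(data$value <= 0)) {
    abort("non-positive values cannot be transformed; use a one-part model ",
          class = "dietshift_transform_error")
  }
  lambda <- switch(transform,
                   identity = 1,
                   log = 0,
                   boxcox = boxcox_lambda(data$value))
  per_person <- data %>%
    mutate(t = boxcox_transform(.data$value, lambda)) %>%
    group_by(.data$pid) %>%
    summarise(weight = .data$weight[1],
              n_days = n(),
              person_mean_t = mean(.data$t),
              s2_i = if (n() > 1) stats::var(.data$t) else NA_real_,
              .groups = "drop")
  multi <- filter(per_person, .data$n_days > 1)
  if (nrow(multi) == 0) {
    abort("within-person variance is inestimable: no person has 2+ days",
          class = "dietshift_data_error")
  }
  s2_within <- weighted_mean_(multi$s2_i, multi$weight)
  mu <- weighted_mean_(per_person$person_mean_t, per_person$weight)
  var_means <- weighted_var_(per_person$person_mean_t, per_person$weight)
  s2_between <- max(0, var_means -
                      s2_within * weighted_mean_(1 / per_person$n_days,
                                                 per_person$weight))
  shrink <- sqrt(s2_between / (s2_between + s2_within / per_person$n_days))
  shrink[!is.finite(shrink)] <- 0
  per_person <- per_person %>%
    mutate(usual_t = mu + shrink * (.data$person_mean_t - mu),
           usual = boxcox_inverse(.data$usual_t, lambda))
  structure(
    list(transform = transform, lambda = lambda, metric = metric,
         mu = mu, s2_between = s2_between, s2_within = s2_within,
         people = per_person,
         n_persons = nrow(per_person), n_days = nrow(data)),
    class = "usual_intake"
  )
}

#' @export
print.usual_intake <- function(x, ...) {
  cat(sprintf(
    "<usual_intake> metric=%s, %d persons / %d days, transform=%s\n",
    x$metric, x$n_persons, x$n_days, x$transform))
  cat(sprintf("  variance components (transformed scale): between=%.4g, within=%.4g\n",
              x$s2_between, x$s2_within))
  q <- percentile(x, c(0.25, 0.5, 0.75))
  cat(sprintf("  p50 (p25-p75): %.3g (%.3g-%.3g)\n", q[2], q[1], q[3]))
  invisible(x)
}

#' Percentile of a usual intake distribution
#'
#' Survey-weighted quantile of the shrunken person-level usual intakes;
#' monotone in `q`.
#'
#' @param dist A `usual_intake` object.
#' @param q Probabilities, each strictly inside (0, 1).
#' @return Numeric vector of intake values.
#' @export
percentile <- function(dist, q) {
  stopifnot(inherits(dist, "usual_intake"))
  if (any(q <= 0 | q >= 1)) {
    abort("percentile probabilities must lie strictly inside (0, 1)",
          class = "dietshift_domain_error")
  }
  weighted_quantile(dist$people$usual, dist$people$weight, q)
}

#' Prevalence of usual intake below a cutoff (EAR cut-point method)
#'
#' Survey-weighted percentage of person-level usual intakes strictly below
#' the cutoff. Applied to a distribution estimated on the g/kg bw/day
#' metric with the quality-adjusted EAR as cutoff, this is the EAR
#' cut-point estimate of the prevalence of inadequate intake.
#'
#' @param dist A `usual_intake` object.
#' @param cutoff Intake cutoff, on the same scale as the distribution.
#' @param require_metric If non-`NULL`, abort unless the distribution was
#'   estimated on this metric (guards against unit mismatches).
#' @return Percentage in \[0, 100\].
#' @export
prevalence_below <- function(dist, cutoff, require_metric = NULL) {
  stopifnot(inherits(dist, "usual_intake"))
  if (!is.null(require_metric) && !identical(dist$metric, require_metric)) {
    abort(sprintf("distribution was estimated on metric '%s', not '%s'",
                  dist$metric, require_metric),
          class = "dietshift_usage_error")
  }
  100 * weighted_mean_(as.numeric(dist$people$usual < cutoff),
                       dist$people$weight)
}

#' @rdname estimate_usual_intake
#' @param x A `usual_intake` object.
#' @param ... Unused.
#' @method tidy usual_intake
#' @export
tidy.usual_intake <- function(x, ...) {
  select(x$people, "pid", "weight", "n_days", "person_mean_t", "usual")
}

#' @rdname estimate_usual_intake
#' @method glance usual_intake
#' @export
glance.usual_intake <- function(x, ...) {
  q <- percentile(x, c(0.25, 0.5, 0.75))
  tibble(metric = x$metric, transform = x$transform, lambda = x$lambda,
         n_persons = x$n_persons, n_days = x$n_days,
         s2_between = x$s2_between, s2_within = x$s2_within,
         p25 = q[1], p50 = q[2], p75 = q[3])
}
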