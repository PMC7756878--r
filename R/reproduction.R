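#' Binomial log-likelihood of breeding success
#'
#' The number of successful sites among monitored sites with known
#' outcome in a habitat-year is binomial:
#' `B ~ Binomial(R, b)`.
#'
#' @param successes number of successful sites B (integer, 0 <= B <= R).
#' @param trials number of monitored sites R with known outcome.
#' @param b breeding success probability.
#' @return log pmf value (vectorised over habitat-years).
#' @export
breeding_success_loglik <- function(successes, trials, b) {
  if (any(successes < 0) || any(trials < 0) || any(successes > trials)) {
    stop("need 0 <= successes <= trials")
  }
  if (any(b < 0 | b > 1)) stop("'b' must be in [0, 1]")
  dbinom(successes, trials, b, log = TRUE)
}

#' Shifted-Poisson log-likelihood of fledgling counts
#'
#' Total fledglings F across S successful sites with known brood size
#' must satisfy F >= S (every successful site fledges at least one
#' young), so the excess is modelled as
#' `F - S ~ Poisson(2 f S - S)`,
#' where `2 f` is the expected total number of fledglings per successful
#' site and `f` the expected number of the modelled sex (even sex ratio).
#' The rate is non-negative only for `f >= 0.5`; smaller values are
#' rejected (when S > 0).  At `f = 0.5` the distribution degenerates to a
#' point mass at F = S.
#'
#' @param fledglings total fledglings F.
#' @param sites successful sites with known brood size S.
#' @param f expected fledglings of the modelled sex per successful site.
#' @return log pmf value (vectorised); 0 where S = 0 (no data).
#' @export
fledgling_loglik <- function(fledglings, sites, f) {
  if (any(sites < 0)) stop("'sites' must be >= 0")
  if (any(fledglings < sites)) {
    stop("fledglings must be at least as large as the number of successful sites")
  }
  n <- max(length(fledglings), length(sites), length(f))
  fledglings <- rep_len(fledglings, n); sites <- rep_len(sites, n)
  f <- rep_len(f, n)
  if (any(f < 0.5 & sites > 0)) {
    stop("'f' < 0.5 implies a negative Poisson rate; f must be >= 0.5 where S > 0")
  }
  out <- numeric(n)
  pos <- sites > 0
  out[pos] <- dpois(fledglings[pos] - sites[pos],
                    2 * f[pos] * sites[pos] - sites[pos], log = TRUE)
  out
}

#' Expand intercept + year effects to natural-scale rates
#'
#' Year-varying rates are modelled on a link scale as intercept plus a
#' random year deviation: `logit` for probabilities (breeding success,
#' survival), `log` for positive rates (fledglings per successful site).
#'
#' @param intercept link-scale intercept.
#' @param effects numeric vector of per-year deviations.
#' @param link `"logit"` or `"log"`.
#' @return per-year rates on the natural scale.
#' @export
expand_year_effects <- function(intercept, effects, link = c("logit", "log")) {
  link <- match.arg(link)
  eta <- intercept + effects
  switch(link, logit = plogis(eta), log = exp(eta))
}
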