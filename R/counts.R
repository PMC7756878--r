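#' Poisson log-likelihood of a territory count
#'
#' Annual counts of occupied breeding territories are linked to the
#' latent number of breeders by a Poisson observation model:
#' `count ~ Poisson(NB)`.
#'
#' @param count observed territory count (non-negative integer,
#'   vectorised).
#' @param nb latent breeder number (>= 0; the `nb -> 0` limit gives log
#'   pmf 0 at count 0 and `-Inf` otherwise).
#' @return log pmf value.
#' @export
count_loglik <- function(count, nb) {
  if (any(count < 0)) stop("'count' must be non-negative")
  if (any(nb < 0)) stop("'nb' must be non-negative")
  dpois(count, nb, log = TRUE)
}
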