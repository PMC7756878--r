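#' Vital rates for the two-habitat projection
#'
#' Bundles the demographic rates that drive the habitat-structured Leslie
#' projection for one year: breeding success `b`, fledglings of the
#' modelled sex per successful site `f`, first-year survival `phi_fl`,
#' breeder survival `phi_br`, and the habitat-switch probabilities
#' `psi_fl` (natal dispersal between habitat classes) and `psi_br`
#' (breeding dispersal).  All per-habitat arguments are length-2 vectors
#' in (Short, Tall) order; scalars are recycled.
#'
#' @param b breeding success probability per habitat, in \[0, 1\].
#' @param f fledglings of the modelled sex per successful site, >= 0.
#' @param phi_fl first-year (fledgling) survival probability per habitat.
#' @param phi_br breeder survival probability per habitat.
#' @param psi_fl probability that a surviving recruit settles in the
#'   habitat it was not born in.
#' @param psi_br probability that a surviving breeder switches habitat.
#' @param year optional integer year index carried along for bookkeeping.
#' @return an object of class `vital_rates`.
#' @examples
#' v <- vital_rates(b = c(0.8, 0.6), f = c(2.5, 2), phi_fl = c(0.2, 0.15),
#'                  phi_br = 0.5, psi_fl = c(0.1, 0.2), psi_br = c(0.05, 0.1))
#' build_projection_matrix(v)
#' per_capita_contribution(v)
#' @export
vital_rates <- function(b, f, phi_fl, phi_br, psi_fl = 0, psi_br = 0,
                        year = NA_integer_) {
  out <- list(
    b      = check_habitat_vector(b, "b", 0, 1),
    f      = check_habitat_vector(f, "f", 0, Inf),
    phi_fl = check_habitat_vector(phi_fl, "phi_fl", 0, 1),
    phi_br = check_habitat_vector(phi_br, "phi_br", 0, 1),
    psi_fl = check_habitat_vector(psi_fl, "psi_fl", 0, 1),
    psi_br = check_habitat_vector(psi_br, "psi_br", 0, 1),
    year   = as.integer(year)
  )
  structure(out, class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("Vital rates (Short, Tall)",
      if (!is.na(x$year)) sprintf("for year %d", x$year) else "", "\n")
  m <- rbind(b = x$b, f = x$f, phi_fl = x$phi_fl, phi_br = x$phi_br,
             psi_fl = x$psi_fl, psi_br = x$psi_br)
  print(round(m, 4))
  invisible(x)
}

#' Build the 2x2 habitat-structured Leslie matrix
#'
#' Entry (j, h) is the expected number of breeders in habitat j next year
#' per breeder in habitat h this year:
#' `b_h * f_h * phi_fl_h * rho(h -> j) + phi_br_h * kappa(h -> j)`,
#' where `rho`/`kappa` equal `1 - psi` on the diagonal and `psi`
#' off-diagonal.  Column sums equal the per-capita contributions
#' [per_capita_contribution()] for any admissible rates.
#'
#' @param v a [vital_rates] object.
#' @return 2x2 non-negative matrix with dimnames (to, from).
#' @export
build_projection_matrix <- function(v) {
  stopifnot(inherits(v, "vital_rates"))
  rec <- v$b * v$f * v$phi_fl          # recruitment per origin habitat
  a <- matrix(0, 2, 2, dimnames = list(to = HABITATS, from = HABITATS))
  for (h in 1:2) {
    stay <- h
    switch_to <- 3L - h
    a[stay, h] <- rec[h] * (1 - v$psi_fl[h]) + v$phi_br[h] * (1 - v$psi_br[h])
    a[switch_to, h] <- rec[h] * v$psi_fl[h] + v$phi_br[h] * v$psi_br[h]
  }
  a
}

#' Deterministic one-year projection
#'
#' `NB_{t+1} = A_t NB_t + Im_{t+1}`: projects the per-habitat breeder
#' vector one year forward and adds net immigration.  The result is not
#' clipped at zero; a negative entry (possible when `im` is strongly
#' negative) is returned as-is so that the net-immigration residual
#' identity holds exactly.
#'
#' @param nb breeder numbers per habitat (length 2, >= 0).
#' @param a 2x2 projection matrix from [build_projection_matrix()].
#' @param im net immigrants per habitat added after projection (may be
#'   negative).
#' @return named numeric of length 2.
#' @export
project_deterministic <- function(nb, a, im = c(0, 0)) {
  nb <- check_habitat_vector(nb, "nb", 0, Inf)
  im <- check_habitat_vector(im, "im")
  if (!is.matrix(a) || any(dim(a) != 2L)) stop("'a' must be a 2x2 matrix")
  setNames(drop(a %*% nb) + im, HABITATS)
}

#' Stochastic one-year projection with demographic stochasticity
#'
#' Projects integer breeder numbers one year forward: recruits destined
#' for habitat j from origin h are Poisson with mean
#' `b_h f_h phi_fl_h rho(h -> j) NB_h`, and each current breeder follows
#' a three-outcome categorical (stay in its habitat with probability
#' `phi_br (1 - psi_br)`, switch with `phi_br psi_br`, or die), realised
#' as a multinomial draw.  The expectation equals
#' [project_deterministic()] applied to the same rates.
#'
#' @param nb integer breeder numbers per habitat.
#' @param v a [vital_rates] object.
#' @param im net immigrants per habitat added to the realised numbers
#'   (integer-valued; the sum must leave every habitat non-negative).
#' @return named integer vector of length 2.
#' @export
project_stochastic <- function(nb, v, im = c(0, 0)) {
  stopifnot(inherits(v, "vital_rates"))
  nb <- check_habitat_vector(nb, "nb", 0, Inf)
  im <- check_habitat_vector(im, "im")
  if (any(nb != round(nb))) stop("'nb' must be integer-valued for stochastic projection")
  rec_mean <- v$b * v$f * v$phi_fl * nb  # per origin habitat
  new <- c(0, 0)
  for (h in 1:2) {
    rho <- c(0, 0)
    rho[h] <- 1 - v$psi_fl[h]
    rho[3L - h] <- v$psi_fl[h]
    new <- new + rpois(2L, rec_mean[h] * rho)
    fate <- rmultinom(1L, size = nb[h],
                      prob = c(v$phi_br[h] * (1 - v$psi_br[h]),
                               v$phi_br[h] * v$psi_br[h],
                               1 - v$phi_br[h]))[, 1L]
    new[h] <- new[h] + fate[1L]
    new[3L - h] <- new[3L - h] + fate[2L]
  }
  out <- new + im
  if (any(out < 0)) {
    stop("stochastic projection produced a negative breeder number; ",
         "net immigration cannot remove more breeders than are present")
  }
  setNames(as.integer(round(out)), HABITATS)
}

#' Per-capita habitat contribution
#'
#' The expected number of individuals alive in the total population next
#' year stemming from one breeder in habitat h this year (the breeder's
#' own survival plus its surviving recruits):
#' `C_h = b_h * f_h * phi_fl_h + phi_br_h`.  The contribution counts
#' emigrants to the other habitat, so it does not depend on the switch
#' probabilities psi; algebraically it equals the column sums of the
#' projection matrix.  A habitat is a source in a year if C > 1 and a
#' sink if C < 1.
#'
#' @param v a [vital_rates] object.
#' @return named numeric of length 2.
#' @export
per_capita_contribution <- function(v) {
  stopifnot(inherits(v, "vital_rates"))
  setNames(v$b * v$f * v$phi_fl + v$phi_br, HABITATS)
}

#' Net immigration as a projection residual
#'
#' `Im_{t+1} = NB_{t+1} - A_t NB_t`: the per-year, per-habitat difference
#' between the breeders present and those projected from local vital
#' rates.  Positive values indicate a surplus relative to local
#' demography (net inflow); negative values suggest a net outflow.
#'
#' @param nb_series numeric matrix with one row per year and two columns
#'   (Short, Tall).
#' @param a_series list of 2x2 projection matrices, one per transition,
#'   of length `nrow(nb_series) - 1`.
#' @return matrix with `nrow(nb_series) - 1` rows (transitions into years
#'   2..T) and columns (Short, Tall).
#' @export
net_immigration <- function(nb_series, a_series) {
  nb_series <- as.matrix(nb_series)
  if (ncol(nb_series) != 2L) stop("'nb_series' must have two columns (Short, Tall)")
  n <- nrow(nb_series)
  if (n < 2L) stop("'nb_series' needs at least two years")
  if (length(a_series) != n - 1L) {
    stop("'a_series' must have length nrow(nb_series) - 1")
  }
  out <- matrix(NA_real_, n - 1L, 2L, dimnames = list(NULL, HABITATS))
  for (t in seq_len(n - 1L)) {
    out[t, ] <- nb_series[t + 1L, ] - drop(a_series[[t]] %*% nb_series[t, ])
  }
  out
}

#' Classify source-sink status from posterior contribution draws
#'
#' Computes the posterior mean and equal-tailed credible interval of the
#' per-capita contribution and classifies the habitat-year as a source
#' (lower bound > 1), a sink (upper bound < 1) or uncertain (interval
#' spans 1).
#'
#' @param c_samples numeric vector of posterior draws of one
#'   contribution, or a matrix with draws in rows and one column per
#'   habitat/year.
#' @param level credible level (default 0.95, equal-tailed).
#' @return data.frame with columns mean, lower, upper, status.
#' @export
classify_status <- function(c_samples, level = 0.95) {
  m <- if (is.matrix(c_samples)) c_samples else matrix(c_samples, ncol = 1L)
  if (nrow(m) < 1L || any(!is.finite(m))) stop("empty or non-finite contribution sample")
  alpha <- (1 - level) / 2
  lo <- apply(m, 2L, quantile, probs = alpha, names = FALSE)
  hi <- apply(m, 2L, quantile, probs = 1 - alpha, names = FALSE)
  status <- ifelse(lo > 1, "source", ifelse(hi < 1, "sink", "uncertain"))
  data.frame(mean = colMeans(m), lower = lo, upper = hi, status = status,
             row.names = colnames(m), stringsAsFactors = FALSE)
}
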