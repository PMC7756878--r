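#' Posterior predictive checks
#'
#' Draws replicated datasets from a thinned set of posterior draws and
#' compares a discrepancy statistic between observed and replicated data
#' (Bayesian p-value = fraction of replicates whose discrepancy is at
#' least as large as the observed one).  Discrepancies are Freeman-Tukey,
#' `sum((sqrt(obs) - sqrt(expected))^2)`, applied to four streams:
#' population counts, yearly successful-site counts, yearly fledgling
#' excesses (F - S), and per-occasion totals of "seen" events in the
#' capture-mark-resighting data.  For the CMR stream the replicate is a
#' forward simulation of the state process from each individual's
#' marking; under the spatial variant the detection probability of an
#' individual is taken at the zone of its marking location (a spatially
#' collapsed omnibus check).
#'
#' Extreme p-values (near 0 or 1) indicate systematic misfit of the
#' corresponding stream.
#'
#' @param fit an `ipm_fit`.
#' @param bundle the dataset the model was fitted to.
#' @param n_draws number of posterior draws used (thinned evenly).
#' @param seed RNG seed for the replicates.
#' @return data.frame with one row per stream: Bayesian p-value and the
#'   mean observed/replicated discrepancies.
#' @export
posterior_predictive_check <- function(fit, bundle, n_draws = 100, seed = 1L) {
  set.seed(seed)
  m <- as.matrix(fit$samples)
  idx <- unique(round(seq(1, nrow(m), length.out = min(n_draws, nrow(m)))))
  ny <- length(fit$years)
  ft <- function(obs, expected) sum((sqrt(obs) - sqrt(pmax(expected, 0)))^2)
  get2 <- function(base, t) m[idx, sprintf("%s[%d,%d]", base, rep(1:2, ny), rep(seq_len(t), each = 2)), drop = FALSE]

  counts <- stream_matrix(bundle$counts, "count", ny, fit$years)
  R <- stream_matrix(bundle$breeding_success, "R", ny, fit$years)
  B <- stream_matrix(bundle$breeding_success, "B", ny, fit$years)
  S <- stream_matrix(bundle$fledglings, "S", ny, fit$years)
  Fm <- stream_matrix(bundle$fledglings, "F", ny, fit$years) - S

  NBd <- get2("NB", ny); bd <- get2("b", ny); fd <- get2("f", ny)
  res <- list()
  one_stream <- function(obs_vec, exp_mat, rgen) {
    To <- Tr <- numeric(length(idx))
    for (j in seq_along(idx)) {
      e <- exp_mat[j, ]
      To[j] <- ft(obs_vec, e)
      Tr[j] <- ft(rgen(e), e)
    }
    c(p = mean(Tr >= To), T_obs = mean(To), T_rep = mean(Tr))
  }
  res$counts <- one_stream(as.vector(counts), NBd, function(e) rpois(length(e), e))
  res$breeding_success <- one_stream(
    as.vector(B), sweep(bd, 2, as.vector(R), `*`),
    function(e) rbinom(length(e), as.vector(R), pmin(e / pmax(as.vector(R), 1), 1)))
  res$fledglings <- one_stream(
    as.vector(Fm), sweep(2 * fd - 1, 2, as.vector(S), `*`),
    function(e) rpois(length(e), e))
  res$cmr <- ppc_cmr(fit, m, idx, ny, ft)

  out <- do.call(rbind, res)
  data.frame(stream = rownames(out), p_value = out[, "p"],
             T_obs = out[, "T_obs"], T_rep = out[, "T_rep"], row.names = NULL)
}

# CMR omnibus check on per-occasion totals of seen events
ppc_cmr <- function(fit, m, idx, ny, ft) {
  dat <- fit$jags_data
  n <- dat$nind
  first <- dat$first
  y <- dat$y
  obs_seen <- vapply(seq_len(ny), function(t) {
    sum(y[, t] %in% 1:3 & first < t)
  }, numeric(1))
  ## per-individual detection probability (zone of marking location)
  if (fit$variant == "spatial") {
    zone <- detection_zone(fit$marks$x, fit$marks$y, fit$area)
    p_i_of <- function(j) {
      p <- setNames(c(m[j, "p_det[1]"], m[j, "p_det[2]"], 0),
                    c("core", "peripheral", "outside"))
      unname(p[zone])
    }
  } else {
    p_i_of <- function(j) rep(m[j, "p_det0"], n)
  }
  h0 <- match(fit$marks$habitat, HABITATS)
  agem <- dat$age
  To <- Tr <- numeric(length(idx))
  for (k in seq_along(idx)) {
    j <- idx[k]
    p_i <- p_i_of(j)
    psi <- matrix(c(m[j, "psi_fl[1]"], m[j, "psi_fl[2]"],
                    m[j, "psi_br[1]"], m[j, "psi_br[2]"]), 2, 2, byrow = TRUE)
    ## marginal alive probabilities and a forward-simulated replicate
    alpha <- matrix(0, n, 2)  # P(alive in Short / Tall), unconditional
    alpha[cbind(seq_len(n), h0)] <- 1
    zs <- matrix(0L, n, 2)    # simulated state indicator
    zs[cbind(seq_len(n), h0)] <- 1L
    exp_seen <- rep_seen <- numeric(ny)
    for (t in 2:ny) {
      phi_t <- matrix(c(m[j, sprintf("phi[1,1,%d]", t - 1)],
                        m[j, sprintf("phi[1,2,%d]", t - 1)],
                        m[j, sprintf("phi[2,1,%d]", t - 1)],
                        m[j, sprintf("phi[2,2,%d]", t - 1)]), 2, 2, byrow = TRUE)
      act <- first < t            # individuals already marked before t
      a_t <- agem[cbind(seq_len(n), pmax(t - 1L, 1L))]
      for (a in 1:2) {
        rows <- act & a_t == a
        if (!any(rows)) next
        M <- rbind(c(phi_t[a, 1] * (1 - psi[a, 1]), phi_t[a, 1] * psi[a, 1]),
                   c(phi_t[a, 2] * psi[a, 2], phi_t[a, 2] * (1 - psi[a, 2])))
        alpha[rows, ] <- alpha[rows, , drop = FALSE] %*% M
        ## replicate: survive then switch
        zr <- zs[rows, , drop = FALSE]
        cur <- zr[, 1] + 2L * zr[, 2]          # 1, 2 or 0 (dead)
        alive <- cur > 0L
        surv <- alive & runif(length(cur)) < ifelse(alive, phi_t[a, pmax(cur, 1)], 0)
        sw <- surv & runif(length(cur)) < ifelse(surv, psi[a, pmax(cur, 1)], 0)
        newh <- ifelse(sw, 3L - cur, cur)
        zr[] <- 0L
        zr[cbind(seq_along(cur), pmax(newh, 1))] <- ifelse(surv, 1L, 0L)
        zs[rows, ] <- zr
      }
      exp_seen[t] <- sum(rowSums(alpha[act, , drop = FALSE]) * p_i[act])
      alive_now <- rowSums(zs) > 0L
      rep_seen[t] <- sum(runif(n) < p_i * alive_now * act)
    }
    To[k] <- ft(obs_seen[-1], exp_seen[-1])
    Tr[k] <- ft(rep_seen[-1], exp_seen[-1])
  }
  c(p = mean(Tr >= To), T_obs = mean(To), T_rep = mean(Tr))
}
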