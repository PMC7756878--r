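# JAGS model code for the integrated population model.
#
# Shared blocks: reproduction (binomial breeding success, shifted-Poisson
# broods, intercept + year random effects on logit/log scales), survival
# year random effects, the state transition array Omega, the count
# state-space process with demographic stochasticity (Poisson recruits,
# sequential-binomial breeder fates) and a vague normal prior on the
# yearly net-immigration residuals, plus derived contributions and
# net-immigration rates.
#
# The spatial variant adds latent locations G with Student-t random-walk
# steps (site-fidelity mixture realised as a very high precision on the
# stay branch), and zone-dependent detection computed from G with step()
# (zero outside the total area).  The non-spatial comparator uses
# spatially constant detection and ignores locations.

jags_common_top <- "
model {
  ## reproduction: intercept + year random effects
  for (h in 1:2) {
    mu_b[h] ~ dnorm(0, 0.01)
    sd_b[h] ~ dnorm(0, 0.25) T(0,)
    tau_b[h] <- pow(sd_b[h] + 0.0001, -2)
    mu_f[h] ~ dnorm(0, 0.01)
    sd_f[h] ~ dnorm(0, 0.25) T(0,)
    tau_f[h] <- pow(sd_f[h] + 0.0001, -2)
    for (t in 1:nyears) {
      eps_b[h,t] ~ dnorm(0, tau_b[h])
      logit(b[h,t]) <- mu_b[h] + eps_b[h,t]
      eps_f[h,t] ~ dnorm(0, tau_f[h])
      f[h,t] <- 0.5 + exp(mu_f[h] + eps_f[h,t])
      B[h,t] ~ dbin(b[h,t], R[h,t])
      Fm[h,t] ~ dpois(2 * f[h,t] * S[h,t] - S[h,t] + 0.000001)
    }
    psi_fl[h] ~ dunif(0, 1)
    psi_br[h] ~ dunif(0, 1)
  }
  psi[1,1] <- psi_fl[1]
  psi[1,2] <- psi_fl[2]
  psi[2,1] <- psi_br[1]
  psi[2,2] <- psi_br[2]

  ## survival: intercept + year random effects per age x habitat
  for (a in 1:2) {
    for (h in 1:2) {
      mu_phi[a,h] ~ dnorm(0, 0.01)
      sd_phi[a,h] ~ dnorm(0, 0.25) T(0,)
      tau_phi[a,h] <- pow(sd_phi[a,h] + 0.0001, -2)
      for (t in 1:(nyears-1)) {
        eps_phi[a,h,t] ~ dnorm(0, tau_phi[a,h])
        logit(phi[a,h,t]) <- mu_phi[a,h] + eps_phi[a,h,t]
      }
    }
  }

  ## state transition array (rows: aliveShort, aliveTall, dead)
  for (t in 1:(nyears-1)) {
    for (a in 1:2) {
      omega[1,1,a,t] <- phi[a,1,t] * (1 - psi[a,1])
      omega[1,2,a,t] <- phi[a,1,t] * psi[a,1]
      omega[1,3,a,t] <- 1 - phi[a,1,t]
      omega[2,1,a,t] <- phi[a,2,t] * psi[a,2]
      omega[2,2,a,t] <- phi[a,2,t] * (1 - psi[a,2])
      omega[2,3,a,t] <- 1 - phi[a,2,t]
      omega[3,1,a,t] <- 0
      omega[3,2,a,t] <- 0
      omega[3,3,a,t] <- 1
    }
  }

  ## count state-space process with demographic stochasticity
  for (h in 1:2) {
    lam0[h] ~ dunif(0, 500)
    NB[h,1] ~ dpois(lam0[h])
    for (t in 1:nyears) {
      Cc[h,t] ~ dpois(NB[h,t] + 0.000001)
    }
    for (t in 1:(nyears-1)) {
      survb[h,t] ~ dbin(phi[2,h,t], NB[h,t])
      swb[h,t] ~ dbin(psi[2,h], survb[h,t])
      rec_own[h,t] ~ dpois(NB[h,t] * b[h,t] * f[h,t] * phi[1,h,t] * (1 - psi[1,h]) + 0.000001)
      rec_oth[h,t] ~ dpois(NB[h,t] * b[h,t] * f[h,t] * phi[1,h,t] * psi[1,h] + 0.000001)
      Im[h,t+1] ~ dnorm(0, 0.0001)
    }
  }
  for (t in 1:(nyears-1)) {
    Lloc[1,t+1] <- survb[1,t] - swb[1,t] + swb[2,t] + rec_own[1,t] + rec_oth[2,t]
    Lloc[2,t+1] <- survb[2,t] - swb[2,t] + swb[1,t] + rec_own[2,t] + rec_oth[1,t]
    NB[1,t+1] <- round(max(Lloc[1,t+1] + Im[1,t+1], 0))
    NB[2,t+1] <- round(max(Lloc[2,t+1] + Im[2,t+1], 0))
  }

  ## derived quantities
  for (h in 1:2) {
    b_mean[h] <- mean(b[h,1:nyears])
    f_mean[h] <- mean(f[h,1:nyears])
    phi_fl_mean[h] <- mean(phi[1,h,1:(nyears-1)])
    phi_br_mean[h] <- mean(phi[2,h,1:(nyears-1)])
    Nmean[h] <- mean(NB[h,1:nyears])
    for (t in 1:(nyears-1)) {
      Ctr[h,t] <- b[h,t] * f[h,t] * phi[1,h,t] + phi[2,h,t]
      imrate[h,t] <- Im[h,t+1] / max(NB[h,t+1], 1)
    }
    C_mean[h] <- mean(Ctr[h,1:(nyears-1)])
    imrate_mean[h] <- mean(imrate[h,1:(nyears-1)])
  }
"

jags_cmr_spatial <- "
  ## movement and detection priors
  for (h in 1:2) {
    Pstay[h] ~ dunif(0, 1)
    for (a in 1:2) {
      sigma_move[a,h] ~ dunif(0, 20)
    }
  }
  for (k in 1:2) {
    p_det[k] ~ dunif(0, 1)
    c_det[k] ~ dunif(0, 1)
  }

  ## spatial multi-event capture-mark-resighting
  ## site fidelity as a deterministic mixture: the latent location G is
  ## exactly the previous one when stay = 1, else a fresh Student-t step;
  ## recorded sighting coordinates attach to G with a 1-m measurement
  ## error so that exact repeats identify stays.
  for (i in 1:nind) {
    G[i,first[i],1] <- Gobs[i,first[i],1]
    G[i,first[i],2] <- Gobs[i,first[i],2]
    for (t in (first[i]+1):nyears) {
      z[i,t] ~ dcat(omega[z[i,t-1], 1:3, age[i,t-1], t-1])
      pstay_eff[i,t] <- equals(age[i,t-1], 2) *
        (equals(z[i,t-1], 1) * Pstay[1] + equals(z[i,t-1], 2) * Pstay[2])
      stay[i,t] ~ dbern(pstay_eff[i,t])
      sig[i,t] <- equals(z[i,t-1], 1) * sigma_move[age[i,t-1], 1] +
                  equals(z[i,t-1], 2) * sigma_move[age[i,t-1], 2] +
                  equals(z[i,t-1], 3)
      tau_mv[i,t] <- 1 / pow(sig[i,t], 2)
      Gmove[i,t,1] ~ dt(G[i,t-1,1], tau_mv[i,t], tdf)
      Gmove[i,t,2] ~ dt(G[i,t-1,2], tau_mv[i,t], tdf)
      G[i,t,1] <- stay[i,t] * G[i,t-1,1] + (1 - stay[i,t]) * Gmove[i,t,1]
      G[i,t,2] <- stay[i,t] * G[i,t-1,2] + (1 - stay[i,t]) * Gmove[i,t,2]
      Gobs[i,t,1] ~ dnorm(G[i,t,1], 1.0E6)
      Gobs[i,t,2] ~ dnorm(G[i,t,2], 1.0E6)
      in_core[i,t] <- step(G[i,t,1] - core[1]) * step(core[2] - G[i,t,1]) *
                      step(G[i,t,2] - core[3]) * step(core[4] - G[i,t,2])
      in_tot[i,t] <- step(G[i,t,1] - tot[1]) * step(tot[2] - G[i,t,1]) *
                     step(G[i,t,2] - tot[3]) * step(tot[4] - G[i,t,2])
      p_it[i,t] <- in_tot[i,t] * (in_core[i,t] * p_det[1] + (1 - in_core[i,t]) * p_det[2])
      c_it[i,t] <- in_core[i,t] * c_det[1] + (1 - in_core[i,t]) * c_det[2]
      alive1[i,t] <- equals(z[i,t], 1)
      alive2[i,t] <- equals(z[i,t], 2)
      po[i,t,1] <- alive1[i,t] * p_it[i,t] * c_it[i,t]
      po[i,t,2] <- alive2[i,t] * p_it[i,t] * c_it[i,t]
      po[i,t,3] <- (alive1[i,t] + alive2[i,t]) * p_it[i,t] * (1 - c_it[i,t])
      po[i,t,4] <- 1 - (alive1[i,t] + alive2[i,t]) * p_it[i,t]
      y[i,t] ~ dcat(po[i,t,1:4])
    }
  }
}
"

jags_cmr_nonspatial <- "
  ## spatially constant detection
  p_det0 ~ dunif(0, 1)
  c_det0 ~ dunif(0, 1)

  ## non-spatial multi-event capture-mark-resighting
  for (i in 1:nind) {
    for (t in (first[i]+1):nyears) {
      z[i,t] ~ dcat(omega[z[i,t-1], 1:3, age[i,t-1], t-1])
      alive1[i,t] <- equals(z[i,t], 1)
      alive2[i,t] <- equals(z[i,t], 2)
      po[i,t,1] <- alive1[i,t] * p_det0 * c_det0
      po[i,t,2] <- alive2[i,t] * p_det0 * c_det0
      po[i,t,3] <- (alive1[i,t] + alive2[i,t]) * p_det0 * (1 - c_det0)
      po[i,t,4] <- 1 - (alive1[i,t] + alive2[i,t]) * p_det0
      y[i,t] ~ dcat(po[i,t,1:4])
    }
  }
}
"

jags_model_code <- function(variant = c("spatial", "nonspatial")) {
  variant <- match.arg(variant)
  paste0(jags_common_top,
         if (variant == "spatial") jags_cmr_spatial else jags_cmr_nonspatial)
}
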