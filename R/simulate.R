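#' Generate a territory-site landscape
#'
#' Scatters territory sites uniformly over the study area with habitat
#' labels ("Short"/"Tall") mixed at fine scale, mimicking a fine-grained
#' mosaic of short and tall field-layer patches.  Core sites fall inside
#' the intensively monitored core region; peripheral sites in the
#' remainder of the total area.
#'
#' @param n_core number of sites inside the core (default 124, the
#'   counted subsample scale).
#' @param n_peripheral number of sites in the total area outside the
#'   core.
#' @param prop_short expected proportion of Short-habitat sites.
#' @param area a [study_area] object.
#' @return object of class `landscape`: the area plus a `sites`
#'   data.frame (site, x, y, habitat, zone).
#' @export
generate_landscape <- function(n_core = 124, n_peripheral = 55,
                               prop_short = 0.6, area = study_area()) {
  stopifnot(n_core >= 4, n_peripheral >= 0)
  draw_in <- function(n, region, exclude = NULL) {
    # rejection sampling from the bounding box
    bb <- if (region$kind == "rect") region$rect else {
      p <- region$poly; c(range(p[, 1]), range(p[, 2]))
    }
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < n) {
      m <- 4L * (n - nrow(out)) + 16L
      x <- runif(m, bb[1], bb[2]); y <- runif(m, bb[3], bb[4])
      keep <- point_in_region(x, y, region)
      if (!is.null(exclude)) keep <- keep & !point_in_region(x, y, exclude)
      out <- rbind(out, cbind(x, y)[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
  core_xy <- draw_in(n_core, area$core)
  per_xy <- if (n_peripheral > 0) draw_in(n_peripheral, area$total, exclude = area$core)
            else matrix(NA_real_, 0, 2)
  xy <- rbind(core_xy, per_xy)
  n <- nrow(xy)
  hab <- HABITATS[1L + rbinom(n, 1L, 1 - prop_short)]
  # guarantee >= 2 sites per habitat inside the core
  for (h in 1:2) {
    idx_core <- seq_len(n_core)
    if (sum(hab[idx_core] == HABITATS[h]) < 2L) {
      hab[idx_core[seq_len(2L) + 2L * (h - 1L)]] <- HABITATS[h]
    }
  }
  sites <- data.frame(site = seq_len(n), x = xy[, 1], y = xy[, 2],
                      habitat = hab,
                      zone = detection_zone(xy[, 1], xy[, 2], area),
                      stringsAsFactors = FALSE)
  structure(list(area = area, sites = sites), class = "landscape")
}

#' Simulation scenario
#'
#' Collects the generating parameter values for the individual-based
#' simulator.  Defaults emulate the study system: 15 years, breeding
#' success ~0.79/0.65 and ~2.83/2.45 fledglings of the modelled sex per
#' successful site in Short/Tall, first-year survival ~0.21/0.16, breeder
#' survival ~0.52/0.53, year random effects on the link scales, natal
#' dispersal longer-tailed than breeding dispersal, and ~100 fledglings
#' plus ~27 breeders newly marked per year.
#'
#' Rates are specified as natural-scale means; year variation is applied
#' on the logit scale for probabilities and on `log(f - 0.5)` for
#' fledgling rates (keeping f >= 0.5, the support of the shifted-Poisson
#' brood model).
#'
#' @param years number of study years.
#' @param b_mean,phi_fl_mean,phi_br_mean per-habitat mean probabilities.
#' @param f_mean per-habitat mean fledglings of the modelled sex per
#'   successful site.
#' @param sd_b,sd_f,sd_phi_fl,sd_phi_br year-effect standard deviations
#'   on the respective link scales.
#' @param psi_fl,psi_br habitat-switch probabilities (time-constant).
#' @param movement a [movement_params] object.
#' @param detection a [detection_params] object.
#' @param nb_init initial breeders per habitat in the counted population.
#' @param immigration optional integer matrix (years x 2) of external net
#'   immigrants added in years 2..T; default none (closed population).
#' @param n_mark_fl,n_mark_br individuals newly marked per year.
#' @param monitored_frac fraction of breeding sites with known outcome.
#' @param brood_known_frac fraction of successful sites with known brood
#'   size.
#' @param sex label written to the encounter table ("M" or "F"; one
#'   dataset is one sex's model).
#' @param snap_to_site if `TRUE`, recorded sighting coordinates are
#'   snapped to the nearest territory-site centre; default records the
#'   exact latent location.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(years = 15,
                         b_mean = c(0.79, 0.65), sd_b = 0.25,
                         f_mean = c(2.83, 2.45), sd_f = 0.15,
                         phi_fl_mean = c(0.21, 0.16), sd_phi_fl = 0.3,
                         phi_br_mean = c(0.52, 0.53), sd_phi_br = 0.2,
                         psi_fl = c(0.20, 0.35), psi_br = c(0.05, 0.15),
                         movement = movement_params(),
                         detection = detection_params(),
                         nb_init = c(48, 28),
                         immigration = NULL,
                         n_mark_fl = 100, n_mark_br = 27,
                         monitored_frac = 0.95, brood_known_frac = 0.85,
                         sex = "M", snap_to_site = FALSE) {
  stopifnot(years >= 3, all(f_mean > 0.5))
  structure(list(
    years = as.integer(years),
    b_mean = check_habitat_vector(b_mean, "b_mean", 0, 1), sd_b = sd_b,
    f_mean = check_habitat_vector(f_mean, "f_mean", 0.5, Inf), sd_f = sd_f,
    phi_fl_mean = check_habitat_vector(phi_fl_mean, "phi_fl_mean", 0, 1),
    sd_phi_fl = sd_phi_fl,
    phi_br_mean = check_habitat_vector(phi_br_mean, "phi_br_mean", 0, 1),
    sd_phi_br = sd_phi_br,
    psi_fl = check_habitat_vector(psi_fl, "psi_fl", 0, 1),
    psi_br = check_habitat_vector(psi_br, "psi_br", 0, 1),
    movement = movement, detection = detection,
    nb_init = check_habitat_vector(nb_init, "nb_init", 0, Inf),
    immigration = immigration,
    n_mark_fl = n_mark_fl, n_mark_br = n_mark_br,
    monitored_frac = monitored_frac, brood_known_frac = brood_known_frac,
    sex = sex, snap_to_site = snap_to_site
  ), class = "sim_scenario")
}

draw_year_rates <- function(scn) {
  T_ <- scn$years
  logitn <- function(mu, sdv, n) plogis(qlogis(mu) + rnorm(n, 0, sdv))
  b <- rbind(logitn(scn$b_mean[1], scn$sd_b, T_), logitn(scn$b_mean[2], scn$sd_b, T_))
  f <- rbind(0.5 + exp(log(scn$f_mean[1] - 0.5) + rnorm(T_, 0, scn$sd_f)),
             0.5 + exp(log(scn$f_mean[2] - 0.5) + rnorm(T_, 0, scn$sd_f)))
  phi <- array(NA_real_, c(2, 2, T_ - 1),
               dimnames = list(age = c("fledgling", "breeder"),
                               habitat = HABITATS, NULL))
  for (h in 1:2) {
    phi[1, h, ] <- logitn(scn$phi_fl_mean[h], scn$sd_phi_fl, T_ - 1)
    phi[2, h, ] <- logitn(scn$phi_br_mean[h], scn$sd_phi_br, T_ - 1)
  }
  rownames(b) <- rownames(f) <- HABITATS
  list(b = b, f = f, phi = phi,
       psi = rbind(fledgling = scn$psi_fl, breeder = scn$psi_br))
}

#' Simulate all four data streams with known ground truth
#'
#' Forward-simulates the full generative model: year-varying rates from
#' intercept + year effects, the latent breeder numbers with demographic
#' stochasticity (Poisson recruits, categorical breeder fates) plus any
#' external immigration, Poisson-observed counts, binomial breeding
#' success and shifted-Poisson broods, and an individual-based spatial
#' capture-mark-resighting stream (state categorical, site-fidelity
#' Bernoulli, Student-t steps, zone-structured detection with zero
#' detection outside the total area).
#'
#' @param landscape a [generate_landscape()] result.
#' @param scenario a [sim_scenario] object.
#' @return object of class `sim_dataset` with elements `counts`,
#'   `breeding_success`, `fledglings`, `encounters` (data.frames in the
#'   packaged CSV schemas), `area`, and `truth` (all generating values,
#'   the latent NB trajectory, yearly projection matrices and
#'   contributions, and realized emigration by stratum).  If the counted
#'   population goes extinct before the final year the dataset is
#'   returned with `truth$extinct = TRUE` and a warning.
#' @export
simulate_dataset <- function(landscape, scenario) {
  stopifnot(inherits(landscape, "landscape"), inherits(scenario, "sim_scenario"))
  area <- landscape$area
  T_ <- scenario$years
  rates <- draw_year_rates(scenario)
  ## latent population and aggregate streams ------------------------------
  NB <- matrix(NA_real_, 2, T_, dimnames = list(HABITATS, NULL))
  NB[, 1] <- round(scenario$nb_init)
  A_list <- vector("list", T_ - 1)
  C_true <- matrix(NA_real_, 2, T_ - 1, dimnames = list(HABITATS, NULL))
  im_ext <- matrix(0, T_, 2, dimnames = list(NULL, HABITATS))
  if (!is.null(scenario$immigration)) {
    im_ext[] <- as.matrix(scenario$immigration)
  }
  extinct <- FALSE
  for (t in seq_len(T_ - 1)) {
    v <- vital_rates(b = rates$b[, t], f = rates$f[, t],
                     phi_fl = rates$phi[1, , t], phi_br = rates$phi[2, , t],
                     psi_fl = rates$psi[1, ], psi_br = rates$psi[2, ], year = t)
    A_list[[t]] <- build_projection_matrix(v)
    C_true[, t] <- per_capita_contribution(v)
    NB[, t + 1] <- project_stochastic(NB[, t], v, im = im_ext[t + 1, ])
  }
  if (any(colSums(NB) == 0)) {
    extinct <- TRUE
    warning("counted population went extinct before the final year")
  }
  counts <- data.frame(year = rep(seq_len(T_), each = 2),
                       habitat = rep(HABITATS, T_),
                       count = rpois(2 * T_, as.vector(NB)))
  R <- matrix(rbinom(2 * T_, size = round(as.vector(NB)),
                     prob = scenario$monitored_frac), 2, T_)
  B <- matrix(rbinom(2 * T_, size = as.vector(R), prob = as.vector(rates$b)), 2, T_)
  S <- matrix(rbinom(2 * T_, size = as.vector(B), prob = scenario$brood_known_frac), 2, T_)
  Fl <- S + matrix(rpois(2 * T_, (2 * as.vector(rates$f) - 1) * as.vector(S)), 2, T_)
  breeding_success <- data.frame(year = rep(seq_len(T_), each = 2),
                                 habitat = rep(HABITATS, T_),
                                 R = as.vector(R), B = as.vector(B))
  fledglings <- data.frame(year = rep(seq_len(T_), each = 2),
                           habitat = rep(HABITATS, T_),
                           S = as.vector(S), F = as.vector(Fl))
  ## individual-based CMR stream ------------------------------------------
  sites <- landscape$sites
  mv <- scenario$movement; det <- scenario$detection
  n_new <- function(t, age) if (age == "fledgling") scenario$n_mark_fl else scenario$n_mark_br
  inds <- list(); emig <- list(); k <- 0L
  for (t0 in seq_len(T_ - 1)) {
    w_fl <- rates$b[, t0] * rates$f[, t0] * NB[, t0]
    w_br <- NB[, t0]
    for (age0 in c("fledgling", "breeder")) {
      n0 <- n_new(t0, age0)
      if (n0 <= 0) next
      w <- if (age0 == "fledgling") w_fl else w_br
      if (sum(w) <= 0) next
      habs <- HABITATS[1L + rbinom(n0, 1L, w[2] / sum(w))]
      for (i in seq_len(n0)) {
        k <- k + 1L
        h0 <- habs[i]
        cand <- sites[sites$habitat == h0, , drop = FALSE]
        s0 <- cand[sample.int(nrow(cand), 1L), ]
        z <- rep(NA_integer_, T_); G <- matrix(NA_real_, T_, 2)
        stay <- rep(NA_integer_, T_); ev <- rep(NA_integer_, T_)
        obs <- matrix(NA_real_, T_, 2)
        z[t0] <- match(h0, HABITATS)
        G[t0, ] <- c(s0$x, s0$y)
        ev[t0] <- z[t0]
        obs[t0, ] <- G[t0, ]
        for (t in seq(t0 + 1L, T_)) {
          a_prev <- if (t - 1L == t0 && age0 == "fledgling") 1L else 2L
          zp <- z[t - 1L]
          if (zp == 3L) { z[t] <- 3L; ev[t] <- 4L; next }
          hab_prev <- HABITATS[zp]
          if (runif(1) > rates$phi[a_prev, zp, t - 1L]) {
            z[t] <- 3L; ev[t] <- 4L; next
          }
          sw <- runif(1) < rates$psi[a_prev, zp]
          z[t] <- if (sw) 3L - zp else zp
          ps <- if (a_prev == 2L) mv$p_stay[[hab_prev]] else 0
          st <- rbinom(1L, 1L, ps)
          stay[t] <- st
          origin_inside <- point_in_region(G[t - 1L, 1], G[t - 1L, 2], area$total)
          if (st == 1L) {
            G[t, ] <- G[t - 1L, ]
          } else {
            sig <- if (a_prev == 1L) mv$sigma_fl[[hab_prev]] else mv$sigma_br[[hab_prev]]
            G[t, ] <- G[t - 1L, ] + sig * rt(2L, mv$df)
          }
          if (origin_inside) {
            emig[[length(emig) + 1L]] <- data.frame(
              age = c("fledgling", "breeder")[a_prev], habitat = hab_prev,
              out = !point_in_region(G[t, 1], G[t, 2], area$total))
          }
          zone <- detection_zone(G[t, 1], G[t, 2], area)
          if (zone == "outside") { ev[t] <- 4L; next }
          if (runif(1) < det$p[[zone]]) {
            ev[t] <- if (runif(1) < det$c[[zone]]) z[t] else 3L
            obs[t, ] <- if (scenario$snap_to_site) {
              j <- which.min((sites$x - G[t, 1])^2 + (sites$y - G[t, 2])^2)
              c(sites$x[j], sites$y[j])
            } else G[t, ]
          } else ev[t] <- 4L
        }
        inds[[k]] <- list(id = k, mark_year = t0, mark_age = age0,
                          mark_habitat = h0, events = ev, obs = obs,
                          z = z, G = G, stay = stay)
      }
    }
  }
  encounters <- encounters_to_wide(inds, T_, scenario$sex)
  emig <- if (length(emig)) do.call(rbind, emig) else NULL
  emig_rate <- if (!is.null(emig)) {
    ag <- aggregate(out ~ age + habitat, data = emig,
                    FUN = function(z) c(rate = mean(z), n = length(z)))
    data.frame(ag[1:2], rate = ag$out[, "rate"], n = ag$out[, "n"])
  } else NULL
  truth <- list(rates = rates, psi = rates$psi, movement = mv, detection = det,
                NB = NB, A = A_list, C = C_true, im_external = im_ext,
                realized_emigration = emig_rate, extinct = extinct,
                tracks = inds,
                mean_b = rowMeans(rates$b), mean_f = rowMeans(rates$f),
                mean_phi_fl = rowMeans(rates$phi[1, , , drop = FALSE], dims = 2)[, 1],
                mean_phi_br = rowMeans(rates$phi[2, , , drop = FALSE], dims = 2)[, 1])
  structure(list(counts = counts, breeding_success = breeding_success,
                 fledglings = fledglings, encounters = encounters,
                 area = area, landscape = landscape, truth = truth),
            class = "sim_dataset")
}

encounters_to_wide <- function(inds, T_, sex) {
  n <- length(inds)
  out <- data.frame(id = integer(n), sex = character(n), mark_year = integer(n),
                    mark_age = character(n), mark_habitat = character(n),
                    stringsAsFactors = FALSE)
  evm <- matrix(4L, n, T_); xm <- matrix(NA_real_, n, T_); ym <- matrix(NA_real_, n, T_)
  for (i in seq_len(n)) {
    d <- inds[[i]]
    out$id[i] <- d$id; out$sex[i] <- sex
    out$mark_year[i] <- d$mark_year; out$mark_age[i] <- d$mark_age
    out$mark_habitat[i] <- d$mark_habitat
    known <- !is.na(d$events)
    evm[i, known] <- d$events[known]
    xm[i, ] <- d$obs[, 1]; ym[i, ] <- d$obs[, 2]
  }
  for (t in seq_len(T_)) {
    out[[paste0("event_", t)]] <- evm[, t]
    out[[paste0("x_", t)]] <- xm[, t]
    out[[paste0("y_", t)]] <- ym[, t]
  }
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  T_ <- max(x$counts$year)
  cat(sprintf("Simulated dataset: %d years, %d marked individuals, counts %s\n",
              T_, nrow(x$encounters),
              paste(range(x$counts$count), collapse = "-")))
  invisible(x)
}
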