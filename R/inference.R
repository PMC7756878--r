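#' MCMC configuration for the integrated model
#'
#' The `"paper"` preset holds full-scale settings suitable for a real
#' multi-decade dataset (3 chains, 29,000 adaptation iterations, 1,000
#' burn-in, 30,000 sampling iterations thinned by 30); the `"desk"`
#' preset is a reduced
#' configuration for desk-scale experiments and tests (2 chains, 500
#' adaptation, 400 burn-in, 1,100 kept iterations).
#'
#' @param variant `"spatial"` (locations inform survival via the
#'   dispersal kernel and zone-structured detection) or `"nonspatial"`
#'   (the comparator in which detection does not vary in space and
#'   locations are ignored).
#' @param preset `"desk"` or `"paper"`; individual settings can be
#'   overridden.
#' @param n_chains,n_adapt,n_burn,n_iter,thin MCMC settings (overrides).
#' @param seed integer seed controlling all chains' generators.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(variant = c("spatial", "nonspatial"),
                       preset = c("desk", "paper"),
                       n_chains = NULL, n_adapt = NULL, n_burn = NULL,
                       n_iter = NULL, thin = NULL, seed = 1L) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  def <- if (preset == "paper") {
    list(n_chains = 3L, n_adapt = 29000L, n_burn = 1000L, n_iter = 30000L, thin = 30L)
  } else {
    list(n_chains = 2L, n_adapt = 500L, n_burn = 400L, n_iter = 1100L, thin = 1L)
  }
  cfg <- list(variant = variant, preset = preset,
              n_chains = as.integer(n_chains %||% def$n_chains),
              n_adapt = as.integer(n_adapt %||% def$n_adapt),
              n_burn = as.integer(n_burn %||% def$n_burn),
              n_iter = as.integer(n_iter %||% def$n_iter),
              thin = as.integer(thin %||% def$thin),
              seed = as.integer(seed))
  stopifnot(cfg$n_chains >= 1, cfg$n_iter >= 1, cfg$thin >= 1)
  structure(cfg, class = "fit_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## -- data preparation ------------------------------------------------------

rect_of <- function(region, what) {
  if (region$kind != "rect") {
    stop("the ", what, " region must be rectangular for JAGS fitting ",
         "(polygon geometries are supported for simulation and emigration only)")
  }
  region$rect
}

encounters_to_arrays <- function(enc, nyears) {
  ev_cols <- paste0("event_", seq_len(nyears))
  x_cols <- paste0("x_", seq_len(nyears))
  y_cols <- paste0("y_", seq_len(nyears))
  stopifnot(all(ev_cols %in% names(enc)))
  keep <- enc$mark_year < nyears  # final-year markings carry no information
  if (any(!keep)) {
    message(sum(!keep), " individuals marked in the final year dropped (no post-marking occasions)")
  }
  enc <- enc[keep, , drop = FALSE]
  n <- nrow(enc)
  if (n == 0L) stop("empty encounter data after dropping final-year markings")
  y <- as.matrix(enc[, ev_cols]); dimnames(y) <- NULL
  storage.mode(y) <- "integer"
  gx <- as.matrix(enc[, x_cols]); gy <- as.matrix(enc[, y_cols])
  dimnames(gx) <- dimnames(gy) <- NULL
  first <- as.integer(enc$mark_year)
  z <- matrix(NA_integer_, n, nyears)
  age <- matrix(2L, n, nyears)
  G <- array(NA_real_, c(n, nyears, 2))
  for (i in seq_len(n)) {
    f0 <- first[i]
    z[i, f0] <- match(enc$mark_habitat[i], HABITATS)
    if (enc$mark_age[i] == "fledgling") age[i, f0] <- 1L
    seen12 <- which(y[i, ] %in% 1:2)
    z[i, seen12[seen12 > f0]] <- y[i, seen12[seen12 > f0]]
    G[i, , 1] <- gx[i, ]
    G[i, , 2] <- gy[i, ]
    G[i, seq_len(f0 - 1L), ] <- NA  # pre-marking cells are not graph nodes
  }
  list(n = n, y = y, z = z, age = age, G = G, first = first,
       mark_age = enc$mark_age, mark_habitat = enc$mark_habitat)
}

stream_matrix <- function(df, value, nyears, years) {
  m <- matrix(NA_real_, 2, nyears)
  idx <- match(df$year, years)
  m[cbind(match(df$habitat, HABITATS), idx)] <- df[[value]]
  if (any(is.na(m))) stop("stream '", value, "' does not cover every year x habitat")
  m
}

prepare_jags_data <- function(bundle, area, variant) {
  years <- sort(unique(bundle$counts$year))
  if (!all(diff(years) == 1L)) stop("count years must be contiguous")
  nyears <- length(years)
  Cc <- stream_matrix(bundle$counts, "count", nyears, years)
  R <- stream_matrix(bundle$breeding_success, "R", nyears, years)
  B <- stream_matrix(bundle$breeding_success, "B", nyears, years)
  S <- stream_matrix(bundle$fledglings, "S", nyears, years)
  Fl <- stream_matrix(bundle$fledglings, "F", nyears, years)
  enc <- bundle$encounters
  enc$mark_year <- match(enc$mark_year, years)
  if (any(is.na(enc$mark_year))) stop("encounter mark years outside the count year range")
  arr <- encounters_to_arrays(enc, nyears)
  dat <- list(nyears = nyears, Cc = Cc, R = R, B = B, S = S, Fm = Fl - S,
              nind = arr$n, y = arr$y, z = arr$z, age = arr$age,
              first = arr$first)
  if (variant == "spatial") {
    dat$Gobs <- arr$G
    dat$tot <- rect_of(area$total, "total")
    dat$core <- rect_of(area$core, "core")
    dat$tdf <- 5
  }
  list(data = dat, arr = arr, years = years)
}

make_inits <- function(dat, arr, variant, seed, chain) {
  nyears <- dat$nyears
  n <- dat$nind
  z_init <- matrix(NA_integer_, n, nyears)
  stay_init <- matrix(NA_integer_, n, nyears)
  Gmove_init <- array(NA_real_, c(n, nyears, 2))
  for (i in seq_len(n)) {
    f0 <- dat$first[i]
    if (f0 >= nyears) next
    seen <- which(dat$y[i, ] %in% 1:3)
    last_seen <- max(c(f0, seen[seen > f0]))
    last_hab <- dat$z[i, f0]
    last_loc <- if (variant == "spatial") dat$Gobs[i, f0, ] else c(0, 0)
    for (t in seq(f0 + 1L, nyears)) {
      if (!is.na(dat$z[i, t])) {
        last_hab <- dat$z[i, t]
      } else if (t <= last_seen) {
        z_init[i, t] <- last_hab  # alive between sightings
      } else {
        z_init[i, t] <- 3L        # start from apparent mortality after the
      }                           # last sighting; the sampler revives as needed
      if (variant == "spatial") {
        stay_init[i, t] <- 0L
        if (!is.na(dat$Gobs[i, t, 1])) last_loc <- dat$Gobs[i, t, ]
        # latent step initialised at the current best location guess so
        # that the measurement term is finite under stay = 0
        Gmove_init[i, t, ] <- last_loc
      }
    }
  }
  Im_init <- matrix(0, 2, nyears)
  Im_init[, 1] <- NA
  inits <- list(
    mu_b = c(1, 0.5), sd_b = c(0.2, 0.2),
    mu_f = c(0.7, 0.7), sd_f = c(0.2, 0.2),
    mu_phi = matrix(c(-1.5, -1.5, 0, 0), 2, 2, byrow = TRUE),
    sd_phi = matrix(0.2, 2, 2),
    psi_fl = c(0.2, 0.2), psi_br = c(0.1, 0.1),
    lam0 = pmax(dat$Cc[, 1], 1),
    Im = Im_init,
    z = z_init,
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = as.integer((seed * 1000L + chain) %% 2147483587L)
  )
  if (variant == "spatial") {
    inits$Pstay <- c(0.5, 0.5)
    inits$sigma_move <- matrix(c(1.5, 1.5, 0.5, 0.5), 2, 2, byrow = TRUE)
    inits$p_det <- c(0.8, 0.5)
    inits$c_det <- c(0.9, 0.8)
    inits$stay <- stay_init
    inits$Gmove <- Gmove_init
  } else {
    inits$p_det0 <- 0.5
    inits$c_det0 <- 0.8
  }
  inits
}

## -- fitting ---------------------------------------------------------------

#' Fit the integrated population model
#'
#' Jointly fits the count state-space model, the reproduction models and
#' the (spatial or non-spatial) multi-event survival model by MCMC in
#' JAGS, sharing vital rates across data streams.  Derived quantities
#' (per-capita contributions, net-immigration rates, across-year means)
#' are tracked inside the sampler.
#'
#' @param bundle a dataset bundle: either a [simulate_dataset()] result
#'   or a [read_bundle()] result (elements `counts`, `breeding_success`,
#'   `fledglings`, `encounters`).
#' @param area a [study_area] object (defaults to the bundle's own, if
#'   present); must use rectangular regions for the spatial variant.
#' @param cfg a [fit_config] object.
#' @param quiet suppress JAGS progress output.
#' @return object of class `ipm_fit`: `samples` (a [coda::mcmc.list]),
#'   `cfg`, `variant`, `years`, and the marked individuals' strata for
#'   derived emigration rates.  A warning is issued when movement
#'   parameters mix poorly (R-hat > 1.1), which is expected for this
#'   model class.
#' @export
fit_ipm <- function(bundle, area = NULL, cfg = fit_config(), quiet = TRUE) {
  stopifnot(inherits(cfg, "fit_config"))
  area <- area %||% bundle$area
  if (is.null(area)) stop("an 'area' is required (none found in the bundle)")
  prep <- prepare_jags_data(bundle, area, cfg$variant)
  dat <- prep$data
  if (all(dat$y[cbind(seq_len(dat$nind), dat$first)] %in% 1:2) &&
      !any(dat$y[col(dat$y) > dat$first[row(dat$y)]] %in% 1:3)) {
    warning("no resightings after marking: survival posteriors will collapse toward the prior")
  }
  monitors <- c("b", "f", "phi", "psi_fl", "psi_br", "mu_phi", "sd_phi",
                "NB", "Im", "Ctr", "imrate", "b_mean", "f_mean",
                "phi_fl_mean", "phi_br_mean", "C_mean", "imrate_mean", "Nmean")
  monitors <- c(monitors,
                if (cfg$variant == "spatial") c("Pstay", "sigma_move", "p_det", "c_det")
                else c("p_det0", "c_det0"))
  inits <- lapply(seq_len(cfg$n_chains), function(ch)
    make_inits(dat, prep$arr, cfg$variant, cfg$seed, ch))
  jdat <- dat[setdiff(names(dat), "mark_age")]
  model <- rjags::jags.model(textConnection(jags_model_code(cfg$variant)),
                             data = jdat, inits = inits,
                             n.chains = cfg$n_chains, n.adapt = cfg$n_adapt,
                             quiet = quiet)
  if (cfg$n_burn > 0) update(model, cfg$n_burn,
                             progress.bar = if (quiet) "none" else "text")
  samples <- rjags::coda.samples(model, monitors, n.iter = cfg$n_iter,
                                 thin = cfg$thin,
                                 progress.bar = if (quiet) "none" else "text")
  marks <- data.frame(
    x = if (cfg$variant == "spatial") dat$Gobs[cbind(seq_len(dat$nind), dat$first, 1)] else NA_real_,
    y = if (cfg$variant == "spatial") dat$Gobs[cbind(seq_len(dat$nind), dat$first, 2)] else NA_real_,
    age = prep$arr$mark_age, habitat = prep$arr$mark_habitat,
    stringsAsFactors = FALSE)
  fit <- structure(list(samples = samples, cfg = cfg, variant = cfg$variant,
                        years = prep$years, area = area, marks = marks,
                        jags_data = jdat),
                   class = "ipm_fit")
  if (cfg$variant == "spatial" && cfg$n_chains >= 2) {
    mv <- grep("^(Pstay|sigma_move)", coda::varnames(samples), value = TRUE)
    rh <- vapply(mv, function(p) rhat(draws_matrix_by_chain(fit, p)), numeric(1))
    if (any(rh > 1.1, na.rm = TRUE)) {
      warning("low mixing of movement parameters (max R-hat ",
              sprintf("%.2f", max(rh, na.rm = TRUE)),
              "); demographic parameters are usually unaffected")
    }
  }
  fit
}

#' @export
print.ipm_fit <- function(x, ...) {
  cat(sprintf("IPM fit (%s variant): %d chains x %d kept iterations, %d years\n",
              x$variant, length(x$samples),
              nrow(x$samples[[1]]), length(x$years)))
  invisible(x)
}

#' Extract pooled posterior draws of one or more parameters
#'
#' @param fit an `ipm_fit`.
#' @param pars character vector of parameter names as monitored in JAGS,
#'   e.g. `"phi_fl_mean[1]"`.
#' @return numeric matrix, pooled draws (chains stacked) x parameters.
#' @export
posterior_draws <- function(fit, pars) {
  m <- as.matrix(fit$samples)
  miss <- setdiff(pars, colnames(m))
  if (length(miss)) stop("parameters not monitored: ", paste(miss, collapse = ", "))
  m[, pars, drop = FALSE]
}

draws_matrix_by_chain <- function(fit, par) {
  sapply(fit$samples, function(ch) as.matrix(ch)[, par])
}

## -- diagnostics and summaries --------------------------------------------

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-rank-normalised) R-hat: with m chains of length n,
#' within-chain variance W and between-chain variance B,
#' `Rhat = sqrt(((n-1)/n W + (1 + 1/m) B/n) / W)`.  The
#' degrees-of-freedom correction of the original estimator is omitted, as
#' in most modern implementations; values near 1 indicate convergence.
#'
#' @param x iterations x chains matrix, a list of equal-length numeric
#'   vectors, or a [coda::mcmc.list].
#' @return scalar R-hat (>= 1 up to sampling noise).
#' @export
rhat <- function(x) {
  if (inherits(x, "mcmc.list")) x <- sapply(x, as.numeric)
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("R-hat requires at least 2 chains")
  if (n < 10L) stop("R-hat requires at least 10 draws per chain")
  W <- mean(apply(x, 2L, var))
  Bn <- var(colMeans(x))           # B/n
  if (W == 0) return(if (Bn == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + (1 + 1 / m) * Bn) / W)
}

#' Posterior probability that a - b > 0
#'
#' Computes the proportion of positive paired differences between two
#' sets of posterior samples (paired by chain and iteration).
#'
#' @param a,b equal-length numeric vectors of posterior draws.
#' @return probability in \[0, 1\].
#' @export
prob_difference_positive <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  mean(a - b > 0)
}

#' Summarise a fitted model
#'
#' One row per monitored scalar with posterior mean, SD, equal-tailed 95%
#' credible interval, R-hat and effective sample size.  The across-year
#' means of latent breeder numbers (`Nmean`), demographic rates and
#' net-immigration rates (net immigrants divided by the same-year breeder
#' number) are included among the monitored quantities.
#'
#' @param fit an `ipm_fit`.
#' @param pars optional regular expression selecting parameters.
#' @param level credible level (default 0.95).
#' @return data.frame with columns parameter, mean, sd, lower, upper,
#'   rhat, n_eff.
#' @export
summarize_posterior <- function(fit, pars = NULL, level = 0.95) {
  m <- as.matrix(fit$samples)
  keep <- colnames(m)
  if (!is.null(pars)) keep <- grep(pars, keep, value = TRUE)
  alpha <- (1 - level) / 2
  rh <- if (length(fit$samples) >= 2) {
    vapply(keep, function(p) {
      x <- draws_matrix_by_chain(fit, p)
      if (all(apply(x, 2, var) == 0)) 1 else rhat(x)
    }, numeric(1))
  } else rep(NA_real_, length(keep))
  ne <- vapply(keep, function(p) {
    unname(coda::effectiveSize(fit$samples[, p]))
  }, numeric(1))
  data.frame(parameter = keep,
             mean = colMeans(m[, keep, drop = FALSE]),
             sd = apply(m[, keep, drop = FALSE], 2, sd),
             lower = apply(m[, keep, drop = FALSE], 2, quantile, alpha),
             upper = apply(m[, keep, drop = FALSE], 2, quantile, 1 - alpha),
             rhat = rh, n_eff = ne, row.names = NULL)
}

#' Posterior emigration rates by age and habitat
#'
#' Derived estimate of the probability that an individual's next-year
#' location falls outside the total study area: for a thinned set of
#' posterior draws of the movement parameters, [emigration_probability()]
#' is averaged over the marked individuals' marking locations in each
#' age x habitat stratum.
#'
#' @param fit a spatial-variant `ipm_fit`.
#' @param n_draws number of posterior draws to evaluate.
#' @param n_mc kernel Monte-Carlo sample size per origin-draw.
#' @param max_origins cap on origins per stratum (subsampled for speed).
#' @return data.frame with stratum, posterior mean and 95% interval of
#'   the emigration rate.
#' @export
emigration_rates <- function(fit, n_draws = 50, n_mc = 2000, max_origins = 50) {
  if (fit$variant != "spatial") stop("emigration rates require the spatial variant")
  pars <- c("sigma_move[1,1]", "sigma_move[1,2]", "sigma_move[2,1]",
            "sigma_move[2,2]", "Pstay[1]", "Pstay[2]")
  dr <- posterior_draws(fit, pars)
  idx <- round(seq(1, nrow(dr), length.out = min(n_draws, nrow(dr))))
  marks <- fit$marks[!is.na(fit$marks$x), , drop = FALSE]
  grid <- expand.grid(age = c("fledgling", "breeder"), habitat = HABITATS,
                      stringsAsFactors = FALSE)
  out <- grid; out$mean <- NA_real_; out$lower <- NA_real_; out$upper <- NA_real_
  for (k in seq_len(nrow(grid))) {
    sel <- marks$age == grid$age[k] & marks$habitat == grid$habitat[k]
    if (!any(sel)) next
    org <- marks[sel, c("x", "y"), drop = FALSE]
    if (nrow(org) > max_origins) org <- org[sample.int(nrow(org), max_origins), ]
    a <- if (grid$age[k] == "fledgling") 1L else 2L
    h <- match(grid$habitat[k], HABITATS)
    vals <- vapply(idx, function(j) {
      mp <- movement_params(
        sigma_fl = dr[j, c("sigma_move[1,1]", "sigma_move[1,2]")],
        sigma_br = dr[j, c("sigma_move[2,1]", "sigma_move[2,2]")],
        p_stay = dr[j, c("Pstay[1]", "Pstay[2]")])
      mean(vapply(seq_len(nrow(org)), function(i) {
        emigration_probability(c(org$x[i], org$y[i]), grid$age[k],
                               grid$habitat[k], mp, fit$area, n_mc = n_mc)
      }, numeric(1)))
    }, numeric(1))
    out$mean[k] <- mean(vals)
    out$lower[k] <- quantile(vals, 0.025, names = FALSE)
    out$upper[k] <- quantile(vals, 0.975, names = FALSE)
  }
  out
}
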