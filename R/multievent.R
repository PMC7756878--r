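#' State transition matrix of the multi-event survival model
#'
#' Latent states are 1 = alive in Short, 2 = alive in Tall, 3 = dead.
#' A breeder (or recruit) in Short survives with probability `phi_s` and,
#' given survival, switches to Tall with probability `psi_s` (and
#' symmetrically from Tall); death is absorbing.
#'
#' @param phi_s,phi_t survival probability from Short / Tall.
#' @param psi_s,psi_t habitat-switch probability given survival.
#' @return 3x3 row-stochastic matrix.
#' @export
build_state_transition <- function(phi_s, phi_t, psi_s, psi_t) {
  p <- c(phi_s, phi_t, psi_s, psi_t)
  if (any(p < 0 | p > 1)) stop("all transition inputs must be probabilities in [0, 1]")
  matrix(c(phi_s * (1 - psi_s), phi_s * psi_s,       1 - phi_s,
           phi_t * psi_t,       phi_t * (1 - psi_t), 1 - phi_t,
           0,                   0,                   1),
         nrow = 3, byrow = TRUE,
         dimnames = list(from = c("aliveShort", "aliveTall", "dead"),
                         to = c("aliveShort", "aliveTall", "dead")))
}

#' Observation (event) matrix of the multi-event model
#'
#' Events are 1 = seen in Short, 2 = seen in Tall, 3 = seen but habitat
#' undetermined, 4 = not seen.  An alive individual is detected with
#' probability `p`; given detection its breeding habitat is determined
#' with probability `c`.  Dead individuals are never seen.
#'
#' @param p detection probability.
#' @param c probability the habitat is determined given detection.
#' @return 3x4 row-stochastic matrix (rows: aliveShort, aliveTall, dead).
#' @export
build_observation_matrix <- function(p, c) {
  if (any(c(p, c) < 0 | c(p, c) > 1)) stop("'p' and 'c' must be probabilities in [0, 1]")
  matrix(c(p * c, 0,     p * (1 - c), 1 - p,
           0,     p * c, p * (1 - c), 1 - p,
           0,     0,     0,           1),
         nrow = 3, byrow = TRUE,
         dimnames = list(state = c("aliveShort", "aliveTall", "dead"),
                         event = c("seenShort", "seenTall", "seenUndet", "notSeen")))
}

#' Detection zone of a location
#'
#' Monitoring effort is spatially structured: the core area is visited
#' intensively, the rest of the total area peripherally, and detection is
#' impossible outside the total area.
#'
#' @param x,y coordinates in km (vectorised).
#' @param area a [study_area] object.
#' @return character vector in `c("core", "peripheral", "outside")`.
#' @export
detection_zone <- function(x, y, area) {
  out <- rep("outside", length(x))
  in_tot <- point_in_region(x, y, area$total)
  in_core <- point_in_region(x, y, area$core)
  out[in_tot] <- "peripheral"
  out[in_tot & in_core] <- "core"
  out
}

#' Detection parameters
#'
#' @param p detection probability `c(core, peripheral)`; zero outside the
#'   total area by construction.
#' @param c probability the habitat is determined given detection,
#'   `c(core, peripheral)`.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(p = base::c(core = 0.9, peripheral = 0.6),
                             c = base::c(core = 0.95, peripheral = 0.85)) {
  if (any(p < 0 | p > 1) || any(c < 0 | c > 1)) stop("'p' and 'c' must be in [0, 1]")
  structure(list(p = setNames(as.numeric(p), c("core", "peripheral")),
                 c = setNames(as.numeric(c), c("core", "peripheral"))),
            class = "detection_params")
}

# age index of individual at occasion t: 1 = fledgling, 2 = breeder
age_at <- function(t, first, mark_age) {
  ifelse(t == first & mark_age == "fledgling", 1L, 2L)
}

#' Joint log density of an augmented (state, location, event) track
#'
#' Evaluates the complete-data log density of one individual's encounter
#' history together with a proposed latent track: the product of state
#' transition terms (survival / habitat-switch), movement terms (site
#' fidelity Bernoulli plus the Student-t kernel for movers; the first
#' transition of an individual marked as a nestling uses the natal
#' dispersal scale), and observation terms with detection probability set
#' by the [detection_zone()] of the latent location.  Inconsistent tracks
#' (seen while latent-dead, location jump while staying, latent location
#' disagreeing with an observed one) return `-Inf`.
#'
#' @param history list with elements `first` (occasion of marking),
#'   `mark_age` ("fledgling"/"breeder"), `events` (integer codes 1-4 per
#'   occasion) and `obs_loc` (occasions x 2 matrix, `NA` where no
#'   location was recorded).
#' @param track list with `z` (latent states 1-3 per occasion), `G`
#'   (occasions x 2 latent locations, defined while alive) and `stay`
#'   (0/1 per transition into occasion t, breeders only).
#' @param vitals list with `phi` (array `[age, habitat, transition]`) and
#'   `psi` (matrix `[age, habitat]`).
#' @param movement a [movement_params] object.
#' @param det a [detection_params] object.
#' @param area a [study_area] object.
#' @return scalar log density (possibly `-Inf`).
#' @export
augmented_joint_logdensity <- function(history, track, vitals, movement, det,
                                       area) {
  T_ <- length(history$events)
  first <- history$first
  z <- track$z
  G <- track$G
  ll <- 0
  obs_tol <- 1e-9
  for (t in seq(first + 1L, length.out = max(0L, T_ - first))) {
    a_prev <- age_at(t - 1L, first, history$mark_age)
    zp <- z[t - 1L]; zt <- z[t]
    ## state transition
    om <- build_state_transition(
      vitals$phi[a_prev, 1L, t - 1L], vitals$phi[a_prev, 2L, t - 1L],
      vitals$psi[a_prev, 1L], vitals$psi[a_prev, 2L])
    if (om[zp, zt] <= 0) return(-Inf)
    ll <- ll + log(om[zp, zt])
    ## movement (only along alive -> alive transitions)
    if (zp < 3L && zt < 3L) {
      hab_prev <- HABITATS[zp]
      ps <- if (a_prev == 2L) movement$p_stay[[hab_prev]] else 0
      sig <- if (a_prev == 1L) movement$sigma_fl[[hab_prev]] else movement$sigma_br[[hab_prev]]
      st <- track$stay[t]
      if (isTRUE(st == 1L)) {
        if (ps <= 0 || any(abs(G[t, ] - G[t - 1L, ]) > obs_tol)) return(-Inf)
        ll <- ll + log(ps)
      } else {
        if (ps >= 1) return(-Inf)
        ll <- ll + log(1 - ps) +
          kernel_logdensity(G[t, ], G[t - 1L, ], sig, movement$df)
      }
    }
    ## observation
    y <- history$events[t]
    if (zt == 3L) {
      if (y != 4L) return(-Inf)  # seen while latent-dead
      next
    }
    if (!any(is.na(history$obs_loc[t, ])) &&
        any(abs(G[t, ] - history$obs_loc[t, ]) > obs_tol)) {
      return(-Inf)  # latent location contradicts an observed one
    }
    zone <- detection_zone(G[t, 1L], G[t, 2L], area)
    p <- if (zone == "outside") 0 else det$p[[zone]]
    cc <- if (zone == "outside") 0 else det$c[[zone]]
    th <- build_observation_matrix(p, cc)
    if (th[zt, y] <= 0) return(-Inf)
    ll <- ll + log(th[zt, y])
  }
  ll
}

#' Exact marginal log-likelihood of a history, non-spatial model
#'
#' Forward algorithm over the three latent states for the comparator
#' model in which detection probability and state certainty do not vary
#' in space (locations are ignored).  The likelihood conditions on the
#' first release: the state at marking is known from the marking event.
#'
#' @param events integer event codes 1-4 per occasion; `events[first]`
#'   must be a seen code (1 or 2).
#' @param first occasion of marking.
#' @param mark_age `"fledgling"` or `"breeder"`.
#' @param vitals list with `phi` (array `[age, habitat, transition]`) and
#'   `psi` (matrix `[age, habitat]`).
#' @param p,c spatially constant detection and habitat-determination
#'   probabilities.
#' @return scalar log marginal likelihood (0 for an empty post-marking
#'   history).
#' @export
nonspatial_history_loglik <- function(events, first, mark_age, vitals, p, c) {
  T_ <- length(events)
  if (first >= T_) return(0)
  if (!events[first] %in% 1:2) stop("marking event must be seen-Short (1) or seen-Tall (2)")
  th <- build_observation_matrix(p, c)
  alpha <- c(0, 0, 0)
  alpha[events[first]] <- 1
  ll <- 0
  for (t in seq(first + 1L, T_)) {
    a_prev <- age_at(t - 1L, first, mark_age)
    om <- build_state_transition(
      vitals$phi[a_prev, 1L, t - 1L], vitals$phi[a_prev, 2L, t - 1L],
      vitals$psi[a_prev, 1L], vitals$psi[a_prev, 2L])
    alpha <- drop(alpha %*% om) * th[, events[t]]
    s <- sum(alpha)
    if (s <= 0) return(-Inf)
    ll <- ll + log(s)
    alpha <- alpha / s
  }
  ll
}
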