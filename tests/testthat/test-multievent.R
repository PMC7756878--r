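test_that("state transition matrix matches the printed form and is stochastic", {
  om <- build_state_transition(0.5, 0.7, 0.1, 0.3)
  expect_equal(unname(om[1, ]), c(0.45, 0.05, 0.50), tolerance = 1e-15)
  expect_equal(unname(om[2, ]), c(0.21, 0.49, 0.30), tolerance = 1e-15)
  expect_equal(unname(om[3, ]), c(0, 0, 1))
  expect_equal(unname(build_state_transition(1, 1, 0, 0)[1:2, 1:2]), diag(2))
  expect_equal(unname(build_state_transition(0, 0, 0.5, 0.5)[, 3]), c(1, 1, 1))
  expect_error(build_state_transition(1.2, 0.5, 0.1, 0.1), "probabilities")
  set.seed(12)
  for (k in 1:200) {
    om <- build_state_transition(runif(1), runif(1), runif(1), runif(1))
    expect_true(all(abs(rowSums(om) - 1) < 1e-12))
  }
})

test_that("observation matrix matches the printed form and is stochastic", {
  th <- build_observation_matrix(0.6, 0.9)
  expect_equal(unname(th[1, ]), c(0.54, 0, 0.06, 0.40), tolerance = 1e-15)
  expect_equal(unname(th[2, ]), c(0, 0.54, 0.06, 0.40), tolerance = 1e-15)
  expect_equal(unname(th[3, ]), c(0, 0, 0, 1))
  expect_equal(unname(build_observation_matrix(0, 0.5)[, 4]), c(1, 1, 1))
  expect_equal(unname(build_observation_matrix(1, 1)[1, ]), c(1, 0, 0, 0))
  set.seed(13)
  for (k in 1:200) {
    th <- build_observation_matrix(runif(1), runif(1))
    expect_true(all(abs(rowSums(th) - 1) < 1e-12))
  }
})

test_that("detection zones partition the plane", {
  area <- study_area()  # total [0,10]x[0,6], core [1,9]x[0.5,5.5]
  expect_equal(detection_zone(5, 3, area), "core")
  expect_equal(detection_zone(0.5, 3, area), "peripheral")
  expect_equal(detection_zone(100, 3, area), "outside")
  expect_equal(detection_zone(c(5, 0.5, 100), c(3, 3, 3), area),
               c("core", "peripheral", "outside"))
})

test_that("augmented joint density matches single-term hand computation", {
  area <- study_area()
  vit <- make_cmr_vitals(phi_br = c(0.8, 0.8), psi_br = c(0.1, 0.1), n_trans = 1)
  mv <- movement_params(p_stay = c(1, 1))
  det <- detection_params(p = c(core = 1, peripheral = 1),
                          c = c(core = 1, peripheral = 1))
  loc <- c(5, 3)  # in the core
  hist <- list(first = 1L, mark_age = "breeder", events = c(1L, 1L),
               obs_loc = rbind(loc, loc))
  track <- list(z = c(1L, 1L), G = rbind(loc, loc), stay = c(NA, 1L))
  ll <- augmented_joint_logdensity(hist, track, vit, mv, det, area)
  # survive and stay in Short, certain fidelity, certain detection
  expect_equal(ll, log(0.8 * (1 - 0.1)) + log(1) + log(1))
})

test_that("inconsistent tracks are rejected with -Inf", {
  area <- study_area()
  vit <- make_cmr_vitals(n_trans = 1)
  mv <- movement_params()
  det <- detection_params()
  loc <- c(5, 3)
  hist <- list(first = 1L, mark_age = "breeder", events = c(1L, 1L),
               obs_loc = rbind(loc, loc))
  # latent-dead but seen
  dead <- list(z = c(1L, 3L), G = rbind(loc, c(NA, NA)), stay = c(NA, NA))
  expect_identical(augmented_joint_logdensity(hist, dead, vit, mv, det, area),
                   -Inf)
  # staying while the location jumped
  jump <- list(z = c(1L, 1L), G = rbind(loc, loc + 1), stay = c(NA, 1L))
  expect_identical(augmented_joint_logdensity(hist, jump, vit, mv, det, area),
                   -Inf)
  # latent location contradicting the observed one
  off <- list(z = c(1L, 1L), G = rbind(loc, loc + 0.5), stay = c(NA, 0L))
  expect_identical(augmented_joint_logdensity(hist, off, vit, mv, det, area),
                   -Inf)
})

test_that("path enumeration over (state, stay) matches the fixed-location marginal", {
  area <- study_area()
  phi <- c(0.6, 0.7); psi <- c(0.15, 0.25)
  vit <- make_cmr_vitals(phi_br = phi, psi_br = psi, n_trans = 1)
  ps <- c(0.5, 0.3); sig_br <- c(0.3, 0.5)
  mv <- movement_params(sigma_br = sig_br, p_stay = ps)
  pd <- 0.7; cd <- 0.8
  det <- detection_params(p = c(core = pd, peripheral = pd),
                          c = c(core = cd, peripheral = cd))
  g1 <- c(5, 3)
  for (case in list(list(g2 = g1, y2 = 1L),       # exact repeat, seen in Short
                    list(g2 = c(5.4, 2.6), y2 = 3L),  # moved, habitat undetermined
                    list(g2 = c(5.4, 2.6), y2 = 4L))) {  # moved, not seen
    g2 <- case$g2; y2 <- case$y2
    obs2 <- if (y2 == 4L) c(NA, NA) else g2
    hist <- list(first = 1L, mark_age = "breeder", events = c(1L, y2),
                 obs_loc = rbind(g1, obs2))
    total <- 0
    for (z2 in 1:3) for (st in 0:1) {
      G <- rbind(g1, if (z2 == 3L) c(NA, NA) else g2)
      tr <- list(z = c(1L, z2), G = G, stay = c(NA, if (z2 == 3L) NA else st))
      ll <- augmented_joint_logdensity(hist, tr, vit, mv, det, area)
      if (is.finite(ll)) total <- total + exp(ll)
      if (z2 == 3L) break  # stay undefined for the dead branch
    }
    ## independent oracle: explicit forward sum with the kernel written out
    kern <- function(d, s) prod(dt(d / s, 5) / s)
    move_dens <- function(stayed) {
      if (stayed) (if (all(g2 == g1)) ps[1] else 0)
      else (1 - ps[1]) * kern(g2 - g1, sig_br[1])
    }
    th <- rbind(c(pd * cd, 0, pd * (1 - cd), 1 - pd),
                c(0, pd * cd, pd * (1 - cd), 1 - pd),
                c(0, 0, 0, 1))
    oracle <- phi[1] * (1 - psi[1]) * (move_dens(TRUE) + move_dens(FALSE)) * th[1, y2] +
              phi[1] * psi[1] * (move_dens(TRUE) + move_dens(FALSE)) * th[2, y2] +
              (1 - phi[1]) * th[3, y2]
    expect_equal(total, oracle, tolerance = 1e-12)
  }
})

test_that("non-spatial forward algorithm matches brute-force enumeration", {
  ## 3-occasion history, all parameters 0.5
  phi <- c(0.5, 0.5); psi <- c(0.5, 0.5); p <- 0.5; cc <- 0.5
  vit <- make_cmr_vitals(phi_fl = phi, phi_br = phi, psi_fl = psi,
                         psi_br = psi, n_trans = 2)
  om <- rbind(c(phi[1] * (1 - psi[1]), phi[1] * psi[1], 1 - phi[1]),
              c(phi[2] * psi[2], phi[2] * (1 - psi[2]), 1 - phi[2]),
              c(0, 0, 1))
  th <- rbind(c(p * cc, 0, p * (1 - cc), 1 - p),
              c(0, p * cc, p * (1 - cc), 1 - p),
              c(0, 0, 0, 1))
  for (events in list(c(1L, 4L, 2L), c(1L, 3L, 4L), c(2L, 4L, 4L))) {
    brute <- 0
    for (z2 in 1:3) for (z3 in 1:3) {
      brute <- brute + om[events[1], z2] * th[z2, events[2]] *
                       om[z2, z3] * th[z3, events[3]]
    }
    expect_equal(nonspatial_history_loglik(events, 1L, "breeder", vit, p, cc),
                 log(brute), tolerance = 1e-10)
  }
  ## certain detection and determination: product of Omega terms only
  vit2 <- make_cmr_vitals(phi_br = c(0.8, 0.6), psi_br = c(0.2, 0.3),
                          n_trans = 2)
  ll <- nonspatial_history_loglik(c(1L, 2L, 2L), 1L, "breeder", vit2, 1, 1)
  expect_equal(ll, log(0.8 * 0.2) + log(0.6 * (1 - 0.3)), tolerance = 1e-12)
  ## empty post-marking history
  expect_equal(nonspatial_history_loglik(c(1L), 1L, "breeder", vit2, 0.5, 0.5), 0)
})

test_that("the marking-year age selects fledgling rates for first transitions", {
  vit <- make_cmr_vitals(phi_fl = c(0.2, 0.2), phi_br = c(0.9, 0.9),
                         psi_fl = c(0, 0), psi_br = c(0, 0), n_trans = 1)
  # marked as nestling, resighted next year: first transition is a
  # fledgling transition, so survival 0.2 applies
  ll_fl <- nonspatial_history_loglik(c(1L, 1L), 1L, "fledgling", vit, 1, 1)
  ll_br <- nonspatial_history_loglik(c(1L, 1L), 1L, "breeder", vit, 1, 1)
  expect_equal(ll_fl, log(0.2), tolerance = 1e-12)
  expect_equal(ll_br, log(0.9), tolerance = 1e-12)
})
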