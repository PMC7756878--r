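test_that("landscape generation is deterministic given the seed", {
  set.seed(77); l1 <- generate_landscape(n_core = 40, n_peripheral = 15)
  set.seed(77); l2 <- generate_landscape(n_core = 40, n_peripheral = 15)
  expect_identical(l1$sites, l2$sites)
  expect_equal(sum(l1$sites$zone == "core"), 40)
  expect_equal(sum(l1$sites$zone == "peripheral"), 15)
  expect_true(all(l1$sites$zone != "outside"))
})

test_that("landscape habitat mix is binomially plausible", {
  set.seed(78)
  l <- generate_landscape(n_core = 300, n_peripheral = 100, prop_short = 0.6)
  p_hat <- mean(l$sites$habitat == "Short")
  se <- sqrt(0.6 * 0.4 / 400)
  expect_lt(abs(p_hat - 0.6), 4 * se)
  # at least two sites of each habitat inside the core
  core <- l$sites[l$sites$zone == "core", ]
  expect_gte(sum(core$habitat == "Short"), 2)
  expect_gte(sum(core$habitat == "Tall"), 2)
})

test_that("simulated datasets are reproducible and schema-valid", {
  d1 <- tiny_sim(seed = 5)
  d2 <- tiny_sim(seed = 5)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$encounters, d2$encounters)
  with(d1$breeding_success, expect_true(all(B >= 0 & B <= R)))
  with(d1$fledglings, expect_true(all(F >= S & S >= 0)))
  expect_true(all(d1$counts$count >= 0))
  ev <- as.matrix(d1$encounters[, paste0("event_", 1:6)])
  expect_true(all(ev %in% 1:4))
})

test_that("sightings never occur while the true location is outside the area", {
  d <- tiny_sim(seed = 9, years = 8,
                movement = movement_params(sigma_fl = c(3, 4),
                                           sigma_br = c(1, 1.5),
                                           p_stay = c(0.3, 0.2)))
  for (tr in d$truth$tracks) {
    for (t in seq_len(8)) {
      if (!is.na(tr$events[t]) && tr$events[t] %in% 1:3 && t > tr$mark_year) {
        expect_equal(detection_zone(tr$G[t, 1], tr$G[t, 2], d$area) != "outside",
                     TRUE)
      }
    }
  }
})

test_that("realized emigration matches the kernel-mass prediction", {
  mv <- movement_params(sigma_fl = c(1.0, 1.5), sigma_br = c(0.3, 0.5),
                        p_stay = c(0.55, 0.35))
  d <- tiny_sim(seed = 23, years = 10, n_core = 40, n_peripheral = 16,
                n_mark_fl = 60, n_mark_br = 25, movement = mv)
  re <- d$truth$realized_emigration
  # predicted per-stratum rates from the marked individuals' start sites
  set.seed(1)
  for (k in seq_len(nrow(re))) {
    if (re$n[k] < 30) next
    sel <- d$landscape$sites
    # predictions averaged over all sites of the stratum's habitat
    orgs <- sel[sel$habitat == re$habitat[k], c("x", "y")]
    orgs <- orgs[sample.int(nrow(orgs), min(20, nrow(orgs))), ]
    pred <- mean(vapply(seq_len(nrow(orgs)), function(i) {
      emigration_probability(c(orgs$x[i], orgs$y[i]), re$age[k], re$habitat[k],
                             mv, d$area, n_mc = 5000)
    }, numeric(1)))
    se <- sqrt(pred * (1 - pred) / re$n[k])
    expect_lt(abs(re$rate[k] - pred), 3 * se + 0.03)
  }
})

test_that("empirical breeding success tracks the generating year rates", {
  d <- tiny_sim(seed = 31, years = 12, n_core = 60, n_peripheral = 20,
                nb_init = c(120, 80))
  bs <- d$breeding_success
  btrue <- d$truth$rates$b
  for (h in 1:2) {
    rows <- bs$habitat == c("Short", "Tall")[h]
    R <- bs$R[rows]; B <- bs$B[rows]
    ok <- R >= 10
    p_hat <- B[ok] / R[ok]
    se <- sqrt(btrue[h, ok] * (1 - btrue[h, ok]) / R[ok])
    expect_true(mean(abs(p_hat - btrue[h, ok]) < 3 * se) > 0.8)
  }
})

test_that("a closed simulated population has near-zero projection residuals", {
  # with no external immigration the truth NB series is generated exactly by
  # the stochastic projection, so deterministic residuals average out to ~0
  set.seed(55)
  res_all <- c()
  for (r in 1:6) {
    d <- tiny_sim(seed = 100 + r, years = 10, nb_init = c(150, 100),
                  phi_br_mean = c(0.55, 0.55), phi_fl_mean = c(0.25, 0.2))
    im <- net_immigration(t(d$truth$NB), d$truth$A)
    res_all <- c(res_all, as.vector(im) / mean(d$truth$NB))
  }
  expect_lt(abs(mean(res_all)), 3 * sd(res_all) / sqrt(length(res_all)) + 0.02)
})

test_that("degenerate detection and fidelity yield certain resightings", {
  d <- tiny_sim(seed = 61, years = 5, n_mark_fl = 0, n_mark_br = 10,
                phi_br_mean = c(1, 1) - 1e-9, psi_br = c(0, 0),
                movement = movement_params(p_stay = c(1, 1)),
                detection = detection_params(p = c(core = 1, peripheral = 1),
                                             c = c(core = 1, peripheral = 1)))
  ev <- as.matrix(d$encounters[, paste0("event_", 1:5)])
  for (i in seq_len(nrow(ev))) {
    t0 <- d$encounters$mark_year[i]
    expect_true(all(ev[i, t0:5] %in% 1:2))
    # always at the same site
    xs <- as.numeric(d$encounters[i, paste0("x_", t0:5)])
    expect_equal(length(unique(xs)), 1L)
  }
})

test_that("huge dispersal makes apparent survival collapse while truth stays", {
  d <- tiny_sim(seed = 71, years = 8, n_mark_fl = 80, n_mark_br = 0,
                movement = movement_params(sigma_fl = c(60, 60),
                                           sigma_br = c(60, 60),
                                           p_stay = c(0, 0)))
  re <- d$truth$realized_emigration
  fl <- re[re$age == "fledgling", ]
  expect_gt(sum(fl$rate * fl$n) / sum(fl$n), 0.9)
  # virtually no resightings after marking despite nonzero true survival
  ev <- as.matrix(d$encounters[, paste0("event_", 1:8)])
  post <- mapply(function(i, t0) any(ev[i, -seq_len(t0)] %in% 1:3),
                 seq_len(nrow(ev)), d$encounters$mark_year)
  expect_lt(mean(post), 0.05)
})
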