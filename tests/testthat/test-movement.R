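test_that("study area validates geometry and areas", {
  area <- study_area()
  expect_equal(unname(area_km2(area)), c(60, 40))
  expect_error(study_area(total = c(0, 4, 0, 4), core = c(0, 5, 0, 4)),
               "contained")
  expect_error(study_area(total = c(5, 1, 0, 4)), "positive extent")
  skip_if_not_installed("mgcv")
  poly <- study_area(total = "POLYGON((0 0, 10 0, 10 6, 0 6, 0 0))",
                     core = c(1, 9, 1, 5))
  expect_equal(unname(area_km2(poly)), c(60, 32))
  expect_equal(detection_zone(c(5, 50), c(3, 3), poly), c("core", "outside"))
})

test_that("kernel log density matches the closed-form Student-t", {
  # at zero displacement: twice the log standard-t density, minus scale terms
  expect_equal(kernel_logdensity(c(0, 0), c(0, 0), sigma = 1, df = 5),
               2 * dt(0, 5, log = TRUE))
  s <- 0.7
  expect_equal(kernel_logdensity(c(1, 2), c(0.5, 1), sigma = s, df = 5),
               dt(0.5 / s, 5, log = TRUE) + dt(1 / s, 5, log = TRUE) - 2 * log(s))
  # symmetry around the origin
  d <- c(0.8, -1.7)
  expect_equal(kernel_logdensity(c(3, 4) + d, c(3, 4), 0.5),
               kernel_logdensity(c(3, 4) - d, c(3, 4), 0.5))
  expect_error(kernel_logdensity(c(0, 0), c(0, 0), sigma = 0), "sigma")
})

test_that("kernel integrates to one (quadrature oracle)", {
  # product structure: the 2-d integral is the square of the 1-d integral
  for (s in c(0.3, 1.5)) {
    one_axis <- integrate(function(x) dt(x / s, 5) / s, -Inf, Inf,
                          rel.tol = 1e-9)$value
    expect_lt(abs(one_axis^2 - 1), 1e-4)
  }
})

test_that("next-location sampling honours fidelity and t-tail variance", {
  mp <- movement_params(sigma_fl = c(1, 1.5), sigma_br = c(0.3, 0.5),
                        p_stay = c(1, 0.4))
  set.seed(21)
  # full fidelity: destination identical to origin
  s <- sample_next_location(c(2, 3), "breeder", "Short", mp, n = 50)
  expect_true(all(s$stay == 1L))
  expect_true(all(s$loc[, 1] == 2 & s$loc[, 2] == 3))
  # fledglings never use the stay mechanism
  s <- sample_next_location(c(2, 3), "fledgling", "Short", mp, n = 200)
  expect_true(all(s$stay == 0L))
  # axis variance of movers approaches sigma^2 * df / (df - 2)
  s <- sample_next_location(c(0, 0), "fledgling", "Tall", mp, n = 40000)
  v_theory <- 1.5^2 * 5 / 3
  expect_equal(var(s$loc[, 1]), v_theory, tolerance = 0.1)
  expect_equal(var(s$loc[, 2]), v_theory, tolerance = 0.1)
})

test_that("emigration probability behaves at the limits", {
  area <- study_area()
  mp0 <- movement_params(sigma_fl = c(1e-6, 1e-6), sigma_br = c(1e-6, 1e-6),
                         p_stay = c(0, 0))
  set.seed(3)
  # vanishing scale from the centre: nobody leaves
  expect_lt(emigration_probability(c(5, 3), "breeder", "Short", mp0, area), 1e-6)
  # full fidelity: exactly zero
  mp1 <- movement_params(p_stay = c(1, 1))
  expect_identical(emigration_probability(c(5, 3), "breeder", "Tall", mp1, area), 0)
  expect_error(emigration_probability(c(50, 50), "breeder", "Short", mp1, area),
               "inside")
})

test_that("boundary origins emigrate with probability at least one half", {
  # supporting-halfplane bound for a convex region
  area <- study_area()
  mp <- movement_params(p_stay = c(0, 0))
  set.seed(4)
  for (orig in list(c(0, 3), c(10, 3), c(5, 0), c(0, 0))) {
    p <- emigration_probability(orig, "fledgling", "Short", mp, area,
                                n_mc = 2e4)
    expect_gte(p, 0.5 - 3 * sqrt(0.25 / 2e4))
  }
})

test_that("emigration probability is monotone in the kernel scale", {
  area <- study_area()
  set.seed(6)
  sigmas <- c(0.1, 0.3, 0.8, 1.5, 3, 6)
  p <- vapply(sigmas, function(s) {
    mp <- movement_params(sigma_fl = c(s, s), sigma_br = c(s, s),
                          p_stay = c(0, 0))
    emigration_probability(c(4, 3), "fledgling", "Short", mp, area, n_mc = 4e4)
  }, numeric(1))
  expect_true(all(diff(p) > -3 * sqrt(0.25 / 4e4)))
  # kernel mass inside + outside = 1: estimate both directly
  mp <- movement_params(sigma_fl = c(1, 1), p_stay = c(0, 0))
  x <- 4 + 1 * rt(4e4, 5); y <- 3 + 1 * rt(4e4, 5)
  inside <- mean(x >= 0 & x <= 10 & y >= 0 & y <= 6)
  p_out <- emigration_probability(c(4, 3), "fledgling", "Short", mp, area,
                                  n_mc = 4e4)
  expect_equal(inside + p_out, 1, tolerance = 3 * sqrt(0.25 / 4e4) * 2)
})

test_that("population emigration rate averages over strata correctly", {
  area <- study_area()
  mp <- movement_params()
  set.seed(8)
  # duplicated origins give the same rate as a single origin (up to MC noise)
  one <- data.frame(x = 5, y = 3, age = "fledgling", habitat = "Short")
  dup <- one[rep(1, 4), ]
  r1 <- suppressWarnings(population_emigration_rate(one, mp, area, n_mc = 2e4))
  r4 <- suppressWarnings(population_emigration_rate(dup, mp, area, n_mc = 2e4))
  f1 <- r1$rate[r1$age == "fledgling" & r1$habitat == "Short"]
  f4 <- r4$rate[r4$age == "fledgling" & r4$habitat == "Short"]
  expect_lt(abs(f1 - f4), 0.01)
  # empty strata are NA-flagged, not zero
  expect_warning(out <- population_emigration_rate(one, mp, area, n_mc = 1e4),
                 "empty strata")
  expect_true(is.na(out$rate[out$age == "breeder" & out$habitat == "Tall"]))
  # each stratum matches its own direct Monte-Carlo oracle within 2 SE
  origins <- data.frame(x = c(5, 1.2), y = c(3, 0.7),
                        age = c("fledgling", "breeder"),
                        habitat = c("Short", "Tall"))
  suppressWarnings(est <- population_emigration_rate(origins, mp, area, n_mc = 4e4))
  oracle <- function(orig, sig, ps, n = 4e4) {
    x <- orig[1] + sig * rt(n, 5); y <- orig[2] + sig * rt(n, 5)
    (1 - ps) * mean(!(x >= 0 & x <= 10 & y >= 0 & y <= 6))
  }
  o_fl <- oracle(c(5, 3), 1.0, 0)
  o_br <- oracle(c(1.2, 0.7), 0.5, 0.35)
  se <- 2 * sqrt(0.25 / 4e4)
  expect_lt(abs(est$rate[est$age == "fledgling" & est$habitat == "Short"] - o_fl),
            4 * se + 0.01)
  expect_lt(abs(est$rate[est$age == "breeder" & est$habitat == "Tall"] - o_br),
            4 * se + 0.01)
})
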