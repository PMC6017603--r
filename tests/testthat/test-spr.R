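test_that("blank subtraction: zero reference is the identity, self is zero", {
  tt <- seq(0, 100, by = 0.5)
  act <- sensorgram(tt, 30 * (1 - exp(-0.1 * tt)), 5, 95)
  zero <- sensorgram(tt, rep(0, length(tt)), 5, 95)
  expect_equal(blank_subtract(act, zero)$response_RU, act$response_RU)
  expect_true(all(blank_subtract(act, act)$response_RU == 0))
})

test_that("blank subtraction interpolates shifted reference grids", {
  tt <- seq(0, 100, by = 0.5)
  ref_t <- seq(-5, 105, by = 0.7)
  # piecewise-linear reference: linear interpolation is exact on it
  ref <- sensorgram(ref_t, 2 + 0.3 * ref_t, 0, 100)
  act <- sensorgram(tt, 10 + 0.3 * tt, 5, 95)
  out <- blank_subtract(act, ref)
  expect_lt(max(abs(out$response_RU - 8)), 1e-9)
  short <- sensorgram(seq(10, 50, 1), rep(0, 41), 12, 48)
  expect_error(blank_subtract(act, short), "cover")
})

test_that("equilibrium extraction averages the plateau and flags drift", {
  tt <- seq(0, 120, by = 0.5)
  const <- sensorgram(tt, rep(42, length(tt)), 10, 100)
  est <- extract_equilibrium(const)
  expect_equal(est$Req_RU, 42)
  expect_true(est$plateau)
  rising <- sensorgram(tt, tt, 10, 100)
  expect_false(extract_equilibrium(rising)$plateau)
})

test_that("equilibrium extraction recovers the Langmuir plateau", {
  sp <- sensorgram_spec(Kd_M = 40e-6, Rmax_RU = 100, kon_M_s = 1e4,
                        concentrations_M = 40e-6)
  ss <- make_sensorgram_set(sp)
  est <- extract_equilibrium(ss$sensorgrams[[1]])
  expect_equal(est$Req_RU, 50, tolerance = 0.005)  # Req(C = Kd) = Rmax/2
  expect_true(est$plateau)
})

test_that("noise-free isotherms are fitted essentially exactly", {
  kd <- 40.3e-6; bmax <- 100
  conc <- kd * c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  iso <- isotherm(conc, bmax * conc / (kd + conc), ligand = "cpd5")
  fit <- fit_steady_state(iso)
  expect_equal(fit$Kd_M, kd, tolerance = 1e-6)
  expect_equal(fit$Bmax_RU, bmax, tolerance = 1e-6)
  expect_true(fit$saturable)
  expect_false(fit$presumed)
  # fitted curve identities
  expect_equal(predict(fit, fit$Kd_M), fit$Bmax_RU / 2)
  expect_true(all(diff(predict(fit, conc)) > 0))
})

test_that("non-saturating designs are flagged presumed", {
  kd <- 200e-6; bmax <- 50
  conc <- kd * c(0.0125, 0.025, 0.05, 0.1, 0.2)  # max C = Kd/5
  iso <- isotherm(conc, bmax * conc / (kd + conc))
  fit <- fit_steady_state(iso)
  expect_true(fit$presumed)
  expect_false(fit$saturable)
  expect_equal(fit$presumed, !fit$saturable)
})

test_that("Scatchard and naive initialisation reach the same optimum", {
  set.seed(42)
  kd <- 60e-6; bmax <- 80
  conc <- kd * c(0.25, 0.5, 1, 2, 4, 8)
  req <- bmax * conc / (kd + conc) + rnorm(6, sd = 0.8)
  iso <- isotherm(conc, req)
  fit <- fit_steady_state(iso)
  naive <- minpack.lm::nlsLM(
    req ~ Bmax * conc / (Kd + conc),
    start = list(Bmax = max(req) * 2, Kd = median(conc)),
    lower = c(0, 0))
  expect_equal(fit$rss, sum(resid(naive)^2), tolerance = 1e-9)
  expect_equal(fit$Kd_M, coef(naive)[["Kd"]], tolerance = 1e-6)
})

test_that("too few concentrations are rejected", {
  iso <- isotherm(c(1e-6, 2e-6), c(10, 18))
  expect_error(fit_steady_state(iso), ">= 3")
})

test_that("RU to surface density conversion is exact and linear", {
  expect_equal(ru_to_density(0, 5e4), 0)
  expect_equal(ru_to_density(1000, 5e4), 20)
  expect_equal(ru_to_density(7800, 53500), 145.794, tolerance = 1e-3)
  ru <- c(100, 500, 2000)
  expect_equal(ru_to_density(ru, 5e4), ru * ru_to_density(1, 5e4))
  expect_equal(ru_to_density(1000, 1e5), ru_to_density(1000, 5e4) / 2)
  expect_error(ru_to_density(100, 0), "positive")
})

test_that("competition metrics carry inhibition/enhancement signs", {
  expect_equal(competition_metrics(35, 35)$percent_change, 0)
  expect_equal(competition_metrics(35, 68)$percent_change, 94.2857,
               tolerance = 1e-4)
  expect_equal(competition_metrics(40, 20)$percent_change, -50)
  expect_error(competition_metrics(0, 10), "positive")
})
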