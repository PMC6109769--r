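test_that("noise-free single-site data round-trips within 0.1%", {
  pro <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3))
  s2 <- binding_scheme("S2")
  iso <- simulate_isotherm(s2, c(K1 = 3.6e5), c(K1 = -3260), pro)
  fit <- itc_fit(itc_dataset(iso, s2, pro),
                 start = c(ka_K1 = 1e5, dh_K1 = -2000),
                 fixed = c(r_m_d1 = 1, q_dil_d1 = 0))
  expect_true(fit$converged)
  expect_equal(coef(fit)[["ka_K1"]], 3.6e5, tolerance = 1e-3)
  expect_equal(coef(fit)[["dh_K1"]], -3260, tolerance = 1e-3)
  expect_gt(fit$gof, 99.9)
  expect_true(all(is.finite(fit$se[fit$free])))
})

test_that("all-zero heats yield a near-zero dh and a degenerate flag", {
  pro <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3))
  s2 <- binding_scheme("S2")
  iso <- simulate_isotherm(s2, c(K1 = 3.6e5), c(K1 = 0), pro)
  fit <- suppressWarnings(
    itc_fit(itc_dataset(iso, s2, pro),
            start = c(ka_K1 = 1e5, dh_K1 = -500),
            fixed = c(r_m_d1 = 1, q_dil_d1 = 0)))
  expect_lt(abs(coef(fit)[["dh_K1"]]), 1)
  expect_true(fit$degenerate)
})

test_that("nuisance parameters r_m and q_dil are recovered", {
  pro <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3))
  s2 <- binding_scheme("S2")
  iso <- simulate_isotherm(s2, c(K1 = 3.6e5), c(K1 = -3260), pro,
                           r_m = 0.85, q_dil = -120)
  fit <- itc_fit(itc_dataset(iso, s2, pro),
                 start = c(ka_K1 = 1e5, dh_K1 = -2000))
  expect_equal(coef(fit)[["r_m_d1"]], 0.85, tolerance = 1e-3)
  expect_equal(coef(fit)[["q_dil_d1"]], -120, tolerance = 1e-2)
  expect_equal(coef(fit)[["ka_K1"]], 3.6e5, tolerance = 1e-3)
})

test_that("under-determined specs are rejected before optimization", {
  pro <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3),
                            injections = rep(10e-6, 3))
  s1 <- binding_scheme("S1")
  iso <- simulate_isotherm(s1, c(K1 = 1.71e7, K2 = 2.31e4),
                           c(K1 = -3730, K2 = -4600), pro)
  expect_error(
    itc_fit(itc_dataset(iso, s1, pro),
            start = c(ka_K1 = 1e6, ka_K2 = 1e4, dh_K1 = -2000,
                      dh_K2 = -2000)),
    "under-determined")
})

test_that("ternary-complex model outfits the no-ternary model on
           ternary-generated competition data", {
  sc5 <- reference_scenario("compete_dcry_into_caminad")
  g <- gen_itc(sc5, seed = 42)
  fit5 <- itc_fit(g$dataset,
                  start = c(ka_K3 = 1e5, dh_K2 = -5000, dh_K3 = 0),
                  fixed = c(ka_K1 = 1.04e7, ka_K2 = 1.02e4,
                            ka_KB = 9.95e3, dh_K1 = -3963,
                            dh_KB = -4132, r_m_S5 = 1, q_dil_S5 = 0))
  ds4 <- itc_dataset(g$isotherm, binding_scheme("S4"), sc5$protocol,
                     name = "S4c")
  fit4 <- itc_fit(ds4,
                  start = c(ka_K2 = 1.02e4, dh_K2 = -5000),
                  fixed = c(ka_K1 = 1.04e7, ka_KB = 9.95e3,
                            dh_K1 = -3963, dh_KB = -4132,
                            r_m_S4c = 1, q_dil_S4c = 0))
  expect_lt(fit5$ssr, fit4$ssr)
  # the ternary constant is recovered to well within an order of magnitude
  expect_lt(abs(log10(coef(fit5)[["ka_K3"]]) - log10(5.6e6)), 0.5)
})

test_that("global fit with shared parameters matches the single fit on
           noise-free data", {
  s2 <- binding_scheme("S2")
  pro_a <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3))
  pro_b <- titration_protocol(cell = c(M = 20e-6), syringe = c(A = 0.4e-3))
  iso_a <- simulate_isotherm(s2, c(K1 = 3.6e5), c(K1 = -3260), pro_a)
  iso_b <- simulate_isotherm(s2, c(K1 = 3.6e5), c(K1 = -3260), pro_b)
  single <- itc_fit(itc_dataset(iso_a, s2, pro_a, name = "a"),
                    start = c(ka_K1 = 1e5, dh_K1 = -2000),
                    fixed = c(r_m_a = 1, q_dil_a = 0))
  global <- itc_fit(list(itc_dataset(iso_a, s2, pro_a, name = "a"),
                         itc_dataset(iso_b, s2, pro_b, name = "b")),
                    start = c(ka_K1 = 1e5, dh_K1 = -2000),
                    fixed = c(r_m_a = 1, q_dil_a = 0,
                              r_m_b = 1, q_dil_b = 0))
  expect_equal(coef(global)[["ka_K1"]], coef(single)[["ka_K1"]],
               tolerance = 1e-6)
  expect_equal(coef(global)[["dh_K1"]], coef(single)[["dh_K1"]],
               tolerance = 1e-6)
  expect_length(global$gof_by_dataset, 2)
})

test_that("goodness of fit follows the normalized-SSR definition", {
  expect_equal(goodness_of_fit(c(0, 0, 0), c(3, 1, 2)), 100)
  # model = mean of data: SSR = SST
  obs <- c(3, 1)
  expect_equal(goodness_of_fit(obs - mean(obs), obs), 0)
  expect_equal(goodness_of_fit(c(1, -1), c(3, 1)), 0)
  expect_warning(g0 <- goodness_of_fit(c(0, 0), c(2, 2)), "undefined")
  expect_true(is.na(g0))
  expect_error(goodness_of_fit(0, 1), "two points")
})

test_that("excluded injections do not enter the fit", {
  pro <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3),
                            discard_first = TRUE)
  s2 <- binding_scheme("S2")
  iso <- simulate_isotherm(s2, c(K1 = 3.6e5), c(K1 = -3260), pro)
  iso$q_molar[1] <- 1e6  # corrupt the discarded injection only
  fit <- itc_fit(itc_dataset(iso, s2, pro),
                 start = c(ka_K1 = 1e5, dh_K1 = -2000),
                 fixed = c(r_m_d1 = 1, q_dil_d1 = 0))
  expect_equal(coef(fit)[["ka_K1"]], 3.6e5, tolerance = 1e-3)
  expect_length(fit$residuals$d1, 24)
})

test_that("fit methods behave: print, summary, predict, residuals,
           simulate", {
  pro <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3))
  s2 <- binding_scheme("S2")
  iso <- simulate_isotherm(s2, c(K1 = 3.6e5), c(K1 = -3260), pro)
  fit <- itc_fit(itc_dataset(iso, s2, pro),
                 start = c(ka_K1 = 1e5, dh_K1 = -2000),
                 fixed = c(r_m_d1 = 1, q_dil_d1 = 0))
  expect_output(print(fit), "GoF")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.itc_fit")
  expect_equal(sm$thermo$kd[sm$thermo$step == "K1"],
               1 / coef(fit)[["ka_K1"]])
  pred <- predict(fit)
  expect_s3_class(pred, "itc_isotherm")
  expect_equal(pred$q_molar, iso$q_molar, tolerance = 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]][[1]]$q_molar, sims[[2]][[1]]$q_molar))
})
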