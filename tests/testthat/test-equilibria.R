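test_that("bundled schemes encode the expected networks", {
  s2 <- binding_scheme("S2")
  expect_equal(names(s2$complexes), "MA")
  expect_equal(unname(cumulative_beta(s2, c(K1 = 3.6e5))[["MA"]]), 3.6e5)

  s1 <- binding_scheme("S1")
  expect_length(s1$complexes, 2)
  b <- cumulative_beta(s1, c(K1 = 1.71e7, K2 = 2.31e4))
  expect_equal(b[["MA2"]], 1.71e7 * 2.31e4)

  s5 <- binding_scheme("S5")
  expect_setequal(names(s5$complexes), c("MA", "MA2", "MB", "MAB"))
  b5 <- cumulative_beta(s5, c(K1 = 1, K2 = 1, KB = 9.95e3, K3 = 5.6e6))
  expect_equal(b5[["MAB"]], 9.95e3 * 5.6e6)

  s3 <- binding_scheme("S3")
  expect_equal(s3$species, c("M", "B"))

  expect_error(binding_scheme("S9"), "valid ids.*S1")
  dhc <- cumulative_dh(s1, c(K1 = -3730, K2 = -4600))
  expect_equal(unname(dhc), c(-3730, -8330))
})

test_that("custom schemes validate stoichiometry and paths", {
  expect_error(
    make_scheme("bad", species = c("M", "A"), steps = "K1",
                complexes = list(MX = list(stoich = c(M = 1, X = 1),
                                           path = "K1"))),
    "unknown species")
  expect_error(
    make_scheme("bad", species = c("M", "A"), steps = "K1",
                complexes = list(MA = list(stoich = c(M = 1, A = 1),
                                           path = "K9"))),
    "path step")
})

test_that("speciation matches the 1:1 closed-form quadratic", {
  s2 <- binding_scheme("S2")
  st <- solve_speciation(s2, c(K1 = 1e6), c(M = 1e-6, A = 1e-6))
  # x = (-1 + sqrt(5)) / (2e6): golden-ratio root of the quadratic
  expect_equal(st$free[["M"]], (-1 + sqrt(5)) / 2e6, tolerance = 1e-9)
  expect_equal(st$free[["A"]], st$free[["M"]], tolerance = 1e-12)
  expect_equal(st$complexes[["MA"]], 1e-6 - (-1 + sqrt(5)) / 2e6,
               tolerance = 1e-9)
})

test_that("no ligand means no complexes; vast excess saturates", {
  for (id in c("S1", "S4", "S5")) {
    sch <- binding_scheme(id)
    tot <- setNames(rep(0, length(sch$species)), sch$species)
    tot["M"] <- 1e-5
    st <- solve_speciation(sch, setNames(rep(1e5, length(sch$steps)),
                                         sch$steps), tot)
    expect_true(all(st$complexes == 0))
    expect_equal(st$free[["M"]], 1e-5)
  }
  st <- solve_speciation(binding_scheme("S1"),
                         c(K1 = 1.71e7, K2 = 2.31e4),
                         c(M = 1e-5, A = 1e-2))
  expect_gt(st$complexes[["MA2"]] / 1e-5, 0.99)
})

test_that("mass balances close for random schemes/parameters/totals", {
  set.seed(11)
  for (i in 1:60) {
    cs <- draw_random_case()
    st <- solve_speciation(cs$scheme, cs$ka, cs$totals)
    expect_lt(st$residual, 1e-9)
    expect_true(all(st$free >= 0) && all(st$complexes >= 0))
  }
})

test_that("solver agrees with quadratic (S2/S3) and bisection (S1) oracles", {
  set.seed(21)
  for (i in 1:100) {
    ka <- 10^runif(1, 3, 7)
    mt <- 10^runif(1, -6, -3)
    lt <- 10^runif(1, -6, -3)
    st2 <- solve_speciation(binding_scheme("S2"), c(K1 = ka),
                            c(M = mt, A = lt))
    expect_equal(st2$complexes[["MA"]], oracle_quad_complex(ka, mt, lt),
                 tolerance = 1e-9)
    st3 <- solve_speciation(binding_scheme("S3"), c(KB = ka),
                            c(M = mt, B = lt))
    expect_equal(st3$complexes[["MB"]], oracle_quad_complex(ka, mt, lt),
                 tolerance = 1e-9)
  }
  for (i in 1:60) {
    ka1 <- 10^runif(1, 4, 7.5)
    ka2 <- 10^runif(1, 3, 6)
    mt <- 10^runif(1, -5.5, -4)
    at <- 10^runif(1, -5.5, -3)
    st <- solve_speciation(binding_scheme("S1"), c(K1 = ka1, K2 = ka2),
                           c(M = mt, A = at))
    orc <- oracle_s1_bisect(ka1, ka2, mt, at)
    expect_equal(st$free[["A"]], orc$free_a, tolerance = 1e-6)
    expect_equal(st$complexes[["MA2"]], orc$ma2, tolerance = 1e-6)
  }
})

test_that("schemes reduce when step constants vanish", {
  tot <- c(M = 4e-5, A = 3e-5, B = 1.6e-4)
  ka <- c(K1 = 1.71e7, K2 = 2.31e4, KB = 6.08e3)
  s4 <- solve_speciation(binding_scheme("S4"), ka, tot)
  s5 <- solve_speciation(binding_scheme("S5"), c(ka, K3 = 0), tot)
  for (cx in names(s4$complexes))
    expect_equal(s5$complexes[[cx]], s4$complexes[[cx]],
                 tolerance = 1e-10)
  expect_equal(s5$complexes[["MAB"]], 0)

  s2 <- solve_speciation(binding_scheme("S2"), c(K1 = 1.71e7),
                         c(M = 4e-5, A = 3e-5))
  s4r <- solve_speciation(binding_scheme("S4"),
                          c(K1 = 1.71e7, K2 = 0, KB = 0), tot)
  expect_equal(s4r$complexes[["MA"]], s2$complexes[["MA"]],
               tolerance = 1e-10)
  expect_equal(s4r$free[["M"]], s2$free[["M"]], tolerance = 1e-10)
})

test_that("bound receptor fraction is monotone in ligand total", {
  sch <- binding_scheme("S5")
  ka <- c(K1 = 1.04e7, K2 = 1.02e4, KB = 9.95e3, K3 = 5.6e6)
  at <- seq(0, 2e-4, length.out = 15)
  bound <- vapply(at, function(a) {
    st <- solve_speciation(sch, ka, c(M = 4e-5, A = a, B = 1.6e-4))
    1 - st$free[["M"]] / 4e-5
  }, numeric(1))
  expect_true(all(diff(bound) >= -1e-12))
})

test_that("species distribution tabulates complexes along a trajectory", {
  sch <- binding_scheme("S5")
  ka <- c(K1 = 1.04e7, K2 = 1.02e4, KB = 9.95e3, K3 = 5.6e6)
  at <- seq(0, 1.5e-4, length.out = 12)
  traj <- data.frame(M = rep(4e-5, 12), A = at, B = rep(1.6e-4, 12))
  dist <- species_distribution(sch, ka, traj)
  expect_true(all(c("MA", "MA2", "MB", "MAB") %in% names(dist)))
  expect_equal(dist$MAB[1], 0)
  expect_equal(dist$MA[1], 0)
  expect_true(all(dist$MAB[-1] > 0))

  dist4 <- species_distribution(binding_scheme("S4"),
                                ka[c("K1", "K2", "KB")], traj)
  expect_false("MAB" %in% names(dist4))
  expect_error(species_distribution(sch, ka, traj[0, ]), "empty")
})

test_that("invalid totals are rejected", {
  s2 <- binding_scheme("S2")
  expect_error(solve_speciation(s2, c(K1 = 1e5), c(M = -1e-6, A = 1e-6)),
               ">= 0")
  expect_error(solve_speciation(s2, c(K1 = 1e5), c(M = 1e-6)),
               "missing totals")
})
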