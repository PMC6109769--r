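# Independent oracles for the speciation solver, kept deliberately simple
# and separate from the package's Newton/bisection machinery.

# 1:1 binding, closed-form quadratic root for the complex concentration
oracle_quad_complex <- function(ka, m_t, l_t) {
  kdis <- 1 / ka
  s <- m_t + l_t + kdis
  (s - sqrt(s^2 - 4 * m_t * l_t)) / 2
}

# sequential two-site binding: bisection on the free-ligand balance
# a + M(a) * (b1 a + 2 b2 a^2) = A_t  with  M(a) = M_t/(1 + b1 a + b2 a^2)
oracle_s1_bisect <- function(ka1, ka2, m_t, a_t, iters = 200L) {
  b1 <- ka1
  b2 <- ka1 * ka2
  f <- function(a) {
    m <- m_t / (1 + b1 * a + b2 * a^2)
    a + m * (b1 * a + 2 * b2 * a^2) - a_t
  }
  lo <- 0
  hi <- a_t
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  a <- (lo + hi) / 2
  m <- m_t / (1 + b1 * a + b2 * a^2)
  list(free_a = a, free_m = m, ma = b1 * m * a, ma2 = b2 * m * a^2)
}

# random scheme/parameter/total draws for property tests
draw_random_case <- function() {
  id <- sample(c("S1", "S2", "S3", "S4", "S5"), 1)
  sch <- binding_scheme(id)
  ka <- setNames(10^stats::runif(length(sch$steps), 3, 7), sch$steps)
  totals <- setNames(10^stats::runif(length(sch$species), -6, -3),
                     sch$species)
  list(scheme = sch, ka = ka, totals = totals)
}

# shared reference constants (single-titration estimates)
KA1_DCRY <- 1.71e7
KA2_DCRY <- 2.31e4
KA_DCRY_APO <- 3.6e5
KA_INAD <- 6.08e3
DH1_DCRY <- -3730
DH2_DCRY <- -4600
DH_DCRY_APO <- -3260
DH_INAD <- -8520
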