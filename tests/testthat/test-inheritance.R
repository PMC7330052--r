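test_that("genotype_probs matches the enumeration oracle at its anchors", {
  expect_equal(genotype_probs(PP = 1, beta = 0),
               c(pAA = 0, pAM = 1, pMM = 0))
  expect_equal(genotype_probs(PP = 0, beta = 0),
               c(pAA = 1 / 6, pAM = 2 / 3, pMM = 1 / 6))
  expect_equal(unname(genotype_probs(PP = 0, beta = 1 / 6)),
               c(2 / 9, 5 / 9, 2 / 9))
  for (PP in c(0, .3, .77, 1)) for (b in c(0, .05, 1 / 6))
    expect_equal(unname(genotype_probs(PP, b)),
                 unname(enum_genotype_probs(PP, b)),
                 tolerance = 1e-12)
  expect_error(genotype_probs(1.1, 0), "PP")
  expect_error(genotype_probs(0.5, 0.2), "beta")
})

test_that("genotype_probs sums to 1 with pAA = pMM on a parameter grid", {
  for (PP in seq(0, 1, length.out = 101))
    for (b in seq(0, 1 / 6, length.out = 18)) {
      p <- genotype_probs(PP, b)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_identical(p[["pAA"]], p[["pMM"]])
    }
})

test_that("loglik_counts is the multinomial log-likelihood", {
  expect_equal(loglik_counts(genotype_counts(0, 10, 0), PP = 1), 0)
  expect_equal(loglik_counts(genotype_counts(1, 9, 0), PP = 1), -Inf)
  ct <- genotype_counts(1, 4, 1)
  expect_equal(loglik_counts(ct, PP = 0),
               stats::dmultinom(c(1, 4, 1), prob = c(1, 4, 1) / 6,
                                log = TRUE))
  set.seed(11)
  for (i in 1:20) {
    x <- as.vector(stats::rmultinom(1, 50, c(.2, .6, .2)))
    PP <- stats::runif(1); b <- stats::runif(1, 0, 1 / 6)
    expect_equal(loglik_counts(genotype_counts(x[1], x[2], x[3]), PP, b),
                 stats::dmultinom(x, prob = genotype_probs(PP, b),
                                  log = TRUE))
  }
})

test_that("estimate_tau closed form matches examples and grid ML", {
  expect_equal(estimate_tau(genotype_counts(0, 300, 0))$tau_hat, 0)
  expect_equal(estimate_tau(genotype_counts(50, 200, 50))$tau_hat, 1)
  est <- estimate_tau(genotype_counts(10, 280, 10))
  expect_equal(est$tau_hat, 0.2)
  expect_equal(est$se, 3 * sqrt((20 / 300) * (280 / 300) / 300))
  expect_error(estimate_tau(genotype_counts(0, 0, 0)), "no observed")

  set.seed(5)
  for (i in 1:50) {
    tau <- stats::runif(1)
    x <- as.vector(stats::rmultinom(1, 300, genotype_probs(1 - tau)))
    cf <- estimate_tau(genotype_counts(x[1], x[2], x[3]))$tau_hat
    gr <- estimate_tau(genotype_counts(x[1], x[2], x[3]),
                       method = "grid")$tau_hat
    expect_lt(abs(cf - grid_ml_tau(x[1], x[2], x[3])), 1e-3)
    expect_lt(abs(cf - gr), 1e-3)
  }
})

test_that("estimate_dr closed form matches examples and grid ML", {
  # f_hom = tau/3 means no excess homozygosity
  expect_equal(estimate_dr(genotype_counts(50, 200, 50), tau = 1)$beta_hat, 0)
  est <- estimate_dr(genotype_counts(528, 8944, 528), tau = 0.249)
  expect_equal(est$beta_hat, (3 * 0.1056 / 0.249 - 1) / 2, tolerance = 1e-9)
  expect_equal(est$beta_hat, 0.136, tolerance = 0.005)
  # f_hom above tau*(4/9): clipped to the admissible maximum 1/6
  over <- estimate_dr(genotype_counts(500, 1000, 500), tau = 1)
  expect_equal(over$beta_hat, 1 / 6)
  expect_true(over$clipped)
  expect_error(estimate_dr(genotype_counts(1, 4, 1), tau = 0),
               "unidentifiable")

  set.seed(6)
  for (i in 1:50) {
    tau <- stats::runif(1, 0.2, 1)
    b <- stats::runif(1, 0, 1 / 6)
    x <- as.vector(stats::rmultinom(1, 500, genotype_probs(1 - tau, b)))
    cf <- estimate_dr(genotype_counts(x[1], x[2], x[3]), tau)$beta_hat
    gr <- estimate_dr(genotype_counts(x[1], x[2], x[3]), tau,
                      method = "grid")$beta_hat
    expect_lt(abs(cf - grid_ml_beta(x[1], x[2], x[3], tau)), 1e-3)
    expect_lt(abs(cf - gr), 1e-3)
  }
})

test_that("estimate_chromosome averages marker-level estimates", {
  gt <- matrix("AM", 50, 4)
  g <- tiny_gametes(gt, role = "centromeric")
  est <- estimate_chromosome(g)
  expect_equal(est$PP, 1)
  expect_equal(est$tau_sd, 0)

  # two centromeric markers engineered to tau-hat 0.2 and 0.3
  mk1 <- c(rep("AA", 10), rep("AM", 280), rep("MM", 10))   # tau 0.2
  mk2 <- c(rep("AA", 15), rep("AM", 270), rep("MM", 15))   # tau 0.3
  g2 <- tiny_gametes(cbind(mk1, mk2), role = "centromeric")
  est2 <- estimate_chromosome(g2)
  expect_equal(est2$tau, 0.25)
  expect_equal(est2$tau_sd, sd(c(0.2, 0.3)), tolerance = 1e-9)
  expect_equal(est2$PP, 0.75)

  g3 <- tiny_gametes(matrix("AM", 5, 2), role = "other")
  expect_error(estimate_chromosome(g3), "no centromeric")
})

test_that("tau recovery from locus-wise simulation is consistent", {
  cfg <- sim_config(list(sim_chromosome("2", n_markers = 4, PP = 0.82,
                                        beta_telomeric = 0)),
                    n_gametes = 50000, seed = 82L)
  g <- simulate_locus_wise(cfg)
  est <- estimate_chromosome(g)
  expect_lt(abs(est$PP - 0.82), 0.01)
})

test_that("beta recovery at n = 50000 is within 0.02", {
  set.seed(99)
  p <- genotype_probs(1 - 0.3, 0.1)
  x <- as.vector(stats::rmultinom(1, 50000, p))
  est <- estimate_dr(genotype_counts(x[1], x[2], x[3]), tau = 0.3)
  expect_lt(abs(est$beta_hat - 0.1), 0.02)
})

test_that("PHR identity 1 - tau/3 holds at centromeric loci", {
  for (tau in c(0.25, 0.6, 1)) {
    cfg <- sim_config(list(sim_chromosome("1", n_markers = 1, PP = 1 - tau,
                                          beta_telomeric = 0)),
                      n_gametes = 20000, seed = round(1000 * tau))
    g <- simulate_locus_wise(cfg)
    phr <- mean(g$genotype == "AM")
    p <- 1 - tau / 3
    expect_lt(abs(phr - p), 3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("phr_summary computes marker, gamete and chromosome statistics", {
  gt <- rbind(g1 = c("AM", "AM", "AA", "AM"),
              g2 = c("AM", NA, "AA", "AM"),
              g3 = c("AA", "AM", "AM", "AM"),
              g4 = c("AM", "AM", "AM", "AM"))
  g <- tiny_gametes(gt)
  s <- phr_summary(g)
  expect_equal(s$per_marker$phr[1], 0.75)
  expect_equal(s$per_gamete$phr[s$per_gamete$gamete_id == "g2"], 2 / 3)
  expect_equal(s$per_chromosome$phr_mean,
               mean(s$per_marker$phr))
  expect_equal(s$per_chromosome$pct_full_het, 25)  # only g4

  all_het <- tiny_gametes(matrix("AM", 6, 3))
  s2 <- phr_summary(all_het)
  expect_equal(s2$per_chromosome$pct_full_het, 100)
  expect_equal(s2$genome$phr_mean, 1)
})
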