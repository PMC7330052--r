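test_that("simulation is deterministic given the seed", {
  cfg <- giant_key_config(n_gametes = 40, seed = 123L, missing_rate = 0.05)
  g1 <- simulate_locus_wise(cfg)
  g2 <- simulate_locus_wise(cfg)
  expect_identical(g1$genotype, g2$genotype)

  cfgc <- giant_key_config(n_gametes = 40, seed = 123L,
                           mode = "chromosome_wise")
  expect_identical(simulate_chromosome_wise(cfgc)$genotype,
                   simulate_chromosome_wise(cfgc)$genotype)

  cfg3 <- giant_key_config(n_gametes = 40, seed = 124L)
  expect_false(identical(simulate_locus_wise(cfg3)$genotype, g1$genotype))
})

test_that("the giant_key preset mirrors the study design", {
  cfg <- giant_key_config()
  expect_equal(length(cfg$chromosomes), 9)
  expect_equal(sum(vapply(cfg$chromosomes,
                          function(ch) length(ch$marker_cM), integer(1))),
               158)
  expect_equal(cfg$n_gametes, 269)
  expect_equal(cfg$chromosomes[[2]]$PP, 0.82)
  expect_equal(cfg$chromosomes[[8]]$PP, 0.995)
  g <- simulate_locus_wise(giant_key_config(n_gametes = 5))
  expect_equal(dim(g$genotype), c(5, 158))
  expect_equal(length(unique(g$markers$chromosome)), 9)
  # four centromeric markers per chromosome
  tab <- table(g$markers$chromosome[g$markers$role == "centromeric"])
  expect_true(all(tab == 4))
})

test_that("both modes hit the disomic limit and the tetrasomic 1:4:1", {
  cfg1 <- sim_config(list(sim_chromosome("1", n_markers = 5, PP = 1)),
                     n_gametes = 100, seed = 1L)
  expect_true(all(simulate_locus_wise(cfg1)$genotype == "AM"))
  cfg1c <- sim_config(list(sim_chromosome("1", n_markers = 5, PP = 1)),
                      n_gametes = 100, seed = 1L, mode = "chromosome_wise")
  expect_true(all(simulate_chromosome_wise(cfg1c)$genotype == "AM"))

  n <- 60000
  cfg0 <- sim_config(list(sim_chromosome("1", n_markers = 1, PP = 0,
                                         beta_telomeric = 0)),
                     n_gametes = n, seed = 2L)
  g0 <- simulate_locus_wise(cfg0)
  freq <- table(factor(g0$genotype, c("AA", "AM", "MM"))) / n
  p <- c(1 / 6, 2 / 3, 1 / 6)
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / n)))

  # chromosome-wise marginal at the centromere matches locus-wise
  cfgc <- sim_config(list(sim_chromosome("1", marker_cM = 40,
                                         length_cM = 100,
                                         centromere_cM = 40, PP = 0,
                                         beta_telomeric = 0)),
                     n_gametes = n, seed = 3L, mode = "chromosome_wise")
  gc <- simulate_chromosome_wise(cfgc)
  freqc <- table(factor(gc$genotype, c("AA", "AM", "MM"))) / n
  expect_true(all(abs(freqc - p) <= 3 * sqrt(p * (1 - p) / n)))
})

test_that("chromosome-wise marginals with beta = 0 match genotype_probs", {
  n <- 60000
  for (PP in c(0.3, 0.82)) {
    cfg <- sim_config(list(sim_chromosome("1", n_markers = 3, PP = PP,
                                          beta_telomeric = 0)),
                      n_gametes = n, seed = round(100 * PP),
                      mode = "chromosome_wise")
    g <- simulate_chromosome_wise(cfg)
    p <- genotype_probs(PP, 0)
    for (k in 1:3) {
      freq <- table(factor(g$genotype[, k], c("AA", "AM", "MM"))) / n
      expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / n) + 1e-9),
                  label = sprintf("PP = %.2f marker %d", PP, k))
    }
  }
})

test_that("mean crossovers per gamete follow the chromatid expectation", {
  # heterologous meioses (fraction tau * 2/3) carry two chromatids with
  # Poisson(L) crossovers each: expected observable switches
  # = tau * (2/3) * 2 * L at dense marker spacing
  n <- 5000
  for (tau in c(0.5, 1)) {
    cfg <- sim_config(list(sim_chromosome("1", length_cM = 100,
                                          n_markers = 51, PP = 1 - tau,
                                          beta_telomeric = 0)),
                      n_gametes = n, seed = round(10 * tau),
                      mode = "chromosome_wise")
    g <- simulate_chromosome_wise(cfg)
    expected <- tau * (2 / 3) * 2 * 1
    observed <- mean(attr(g, "true_crossovers"))
    expect_lt(abs(observed - expected) / expected, 0.05)
  }
})

test_that("locus-wise beta ramp is zero at the centromere, maximal at ends", {
  ch <- sim_chromosome("1", length_cM = 100, marker_cM = c(0, 40, 100),
                       centromere_cM = 40, PP = 0.5, beta_telomeric = 0.15)
  # internal profile: inspect via simulated homozygosity
  n <- 60000
  cfg <- sim_config(list(ch), n_gametes = n, seed = 10L)
  g <- simulate_locus_wise(cfg)
  f_hom <- colMeans(g$genotype != "AM")
  p_end <- sum(genotype_probs(0.5, 0.15)[c(1, 3)])
  p_cen <- sum(genotype_probs(0.5, 0)[c(1, 3)])
  expect_lt(abs(f_hom[[2]] - p_cen), 3 * sqrt(p_cen * (1 - p_cen) / n))
  for (k in c(1, 3))
    expect_lt(abs(f_hom[[k]] - p_end), 3 * sqrt(p_end * (1 - p_end) / n))
})

test_that("make_triploid_doses round-trips with doses_to_gametes", {
  cfg <- giant_key_config(n_gametes = 30, seed = 5L, missing_rate = 0.1)
  g <- simulate_locus_wise(cfg)
  d <- make_triploid_doses(g)
  expect_identical(doses_to_gametes(d)$genotype, g$genotype)
  expect_equal(unname(d$dose[which(g$genotype == "AM")[1]]), 1)
  expect_equal(unname(d$dose[which(g$genotype == "MM")[1]]), 2)
})

test_that("locus-wise recovery of the published PP anchors at n = 50000", {
  for (pp in c(0.633, 0.82, 0.995)) {
    cfg <- sim_config(list(sim_chromosome("1", n_markers = 4, PP = pp,
                                          beta_telomeric = 0)),
                      n_gametes = 50000, seed = round(1000 * pp))
    est <- estimate_chromosome(simulate_locus_wise(cfg))
    expect_lt(abs(est$PP - pp), 0.01)
  }
})
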