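test_that("two_locus_probs matches enumeration and analytic anchors", {
  t0 <- two_locus_probs(0)
  expect_equal(diag(t0), c(AA = 1 / 6, AM = 2 / 3, MM = 1 / 6))
  expect_equal(sum(t0) - sum(diag(t0)), 0)

  t5 <- two_locus_probs(0.5)
  expect_equal(t5["AA", "AA"], 1 / 24)
  expect_equal(t5["AM", "AM"], 1 / 2)

  for (r in c(0, 0.07, 0.2, 0.33, 0.5)) {
    tab <- two_locus_probs(r)
    expect_equal(unname(tab), unname(enum_two_locus_probs(r)),
                 tolerance = 1e-12)
    expect_equal(sum(tab), 1, tolerance = 1e-12)
    # marginals equal the single-locus tetrasomic distribution
    expect_equal(rowSums(tab), genotype_probs(0, 0),
                 ignore_attr = TRUE)
    expect_equal(colSums(tab), genotype_probs(0, 0),
                 ignore_attr = TRUE)
    # A/M symmetry: table invariant under reversing both axes
    expect_equal(unname(tab), unname(tab[3:1, 3:1]))
  }
  expect_error(two_locus_probs(0.6), "r must")
})

test_that("two_locus_probs agrees with chromosome-wise simulation", {
  n <- 200000
  for (r in c(0.1, 0.25)) {
    d_cM <- -50 * log(1 - 2 * r)   # Haldane inverse
    cfg <- sim_config(list(sim_chromosome("1", length_cM = d_cM,
                                          marker_cM = c(0, d_cM), PP = 0,
                                          beta_telomeric = 0)),
                      n_gametes = n, seed = round(1e4 * r),
                      mode = "chromosome_wise")
    g <- simulate_chromosome_wise(cfg)
    obs <- joint_counts(g, colnames(g$genotype)[1],
                        colnames(g$genotype)[2]) / n
    exp_tab <- two_locus_probs(r)
    se <- sqrt(exp_tab * (1 - exp_tab) / n)
    expect_true(all(abs(obs - exp_tab) <= 3 * se + 1e-9),
                label = sprintf("r = %.2f", r))
  }
})

test_that("estimate_rf recovers the generating recombination fraction", {
  n <- 6000
  tab <- round(n * two_locus_probs(0.2))
  est <- estimate_rf(tab)
  expect_lt(abs(est$r_hat - 0.2), 0.01)
  expect_gt(est$lod, 3)

  ind <- round(6000 * two_locus_probs(0.5))
  est5 <- estimate_rf(ind)
  expect_equal(est5$r_hat, 0.5)
  expect_equal(est5$lod, 0)

  diag_tab <- round(200 * two_locus_probs(0))
  est0 <- estimate_rf(diag_tab)
  expect_equal(est0$r_hat, 0)
  expect_gt(est0$lod, 3)

  degenerate <- matrix(0, 3, 3, dimnames = list(c("AA", "AM", "MM"),
                                                c("AA", "AM", "MM")))
  degenerate["AM", "AM"] <- 50
  expect_equal(estimate_rf(degenerate)$flag, "degenerate table")
})

test_that("kosambi map function: closed form, monotone, convex", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.1), 25 * log(1.2 / 0.8))
  expect_equal(kosambi(0.1), 10.14, tolerance = 1e-3)
  expect_equal(kosambi(0.25), 27.47, tolerance = 1e-3)
  expect_error(kosambi(0.5), "Kosambi")
  expect_equal(kosambi(0.5, inf_ok = TRUE), Inf)
  r <- seq(0, 0.49, by = 0.01)
  d <- kosambi(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
})

fake_pairwise <- function(edges) {
  data.frame(marker_i = edges[[1]], marker_j = edges[[2]],
             r_hat = if (length(edges) > 3) edges[[4]] else 0.1,
             lod = edges[[3]], n_informative = 100, flag = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("group_markers forms connected components above the LOD threshold", {
  pw <- fake_pairwise(list(
    c("a", "a", "b", "c", "c", "d"),
    c("b", "c", "c", "d", "e", "e"),
    c(20, 20, 20, 0, 0, 20)))
  grp <- group_markers(pw, 14)
  expect_equal(length(grp$groups), 2)
  expect_setequal(grp$groups$LG1, c("a", "b", "c"))
  expect_setequal(grp$groups$LG2, c("d", "e"))

  chain <- fake_pairwise(list(c("A", "B", "A"), c("B", "C", "C"),
                              c(15, 15, 2)))
  grp2 <- group_markers(chain, 14)
  expect_equal(length(grp2$groups), 1)
  expect_setequal(grp2$groups$LG1, c("A", "B", "C"))

  lone <- fake_pairwise(list(c("A", "A", "B"), c("B", "X", "X"),
                             c(15, 1, 1)))
  grp3 <- group_markers(lone, 14)
  expect_equal(grp3$unassigned, "X")
})

test_that("order_markers recovers collinear orders and rescales positions", {
  # three markers with additive Kosambi distances 5, 5 (ends 10)
  r_of <- function(d) (1 - exp(-4 * d / 100)) / (2 * (1 + exp(-4 * d / 100)))
  pw <- data.frame(marker_i = c("m1", "m1", "m2"),
                   marker_j = c("m2", "m3", "m3"),
                   r_hat = r_of(c(5, 10, 5)),
                   lod = 20, n_informative = 200, flag = NA,
                   stringsAsFactors = FALSE)
  panel <- tiny_panel(c("m1", "m2", "m3"))
  om <- order_markers(c("m1", "m2", "m3"), pw, panel)
  expect_equal(om$marker_id, c("m1", "m2", "m3"))
  expect_equal(om$position_cM, c(0, 5, 10), tolerance = 1e-6)

  om2 <- order_markers(c("m2", "m1"), pw, panel)
  expect_equal(om2$marker_id, c("m1", "m2"))
  expect_equal(om2$position_cM[2], 5, tolerance = 1e-6)
})

test_that("MDS ordering recovers a simulated 15-marker chromosome", {
  cfg <- sim_config(list(sim_chromosome("1", length_cM = 100,
                                        n_markers = 15, PP = 0.7,
                                        beta_telomeric = 0)),
                    n_gametes = 250, seed = 303L,
                    mode = "chromosome_wise")
  g <- simulate_chromosome_wise(cfg)
  pw <- pairwise_linkage(g)
  om <- order_markers(colnames(g$genotype), pw, g$markers)
  truth <- match(om$marker_id, g$markers$marker_id)
  rho <- suppressWarnings(cor(truth, seq_along(truth), method = "spearman"))
  expect_gte(abs(rho), 0.95)
})

test_that("map length is invariant to marker label permutation", {
  cfg <- sim_config(list(sim_chromosome("1", length_cM = 80, n_markers = 8,
                                        PP = 0.5, beta_telomeric = 0)),
                    n_gametes = 300, seed = 17L, mode = "chromosome_wise")
  g <- simulate_chromosome_wise(cfg)
  pw <- pairwise_linkage(g)
  om1 <- order_markers(colnames(g$genotype), pw, g$markers)
  set.seed(1)
  perm <- sample(colnames(g$genotype))
  om2 <- order_markers(perm, pw, g$markers)
  expect_equal(max(om2$position_cM), max(om1$position_cM), tolerance = 1e-6)
  expect_true(identical(om2$marker_id, om1$marker_id) ||
              identical(om2$marker_id, rev(om1$marker_id)))
})

test_that("build_map and marey_diagnostics report synteny and rates", {
  cfg <- sim_config(list(
    sim_chromosome("1", length_cM = 60, n_markers = 6, PP = 0.6,
                   beta_telomeric = 0, length_Mb = 20),
    sim_chromosome("2", length_cM = 60, n_markers = 6, PP = 0.6,
                   beta_telomeric = 0, length_Mb = 25)),
    n_gametes = 400, seed = 55L, mode = "chromosome_wise")
  g <- simulate_chromosome_wise(cfg)
  gm <- build_map(g, lod_threshold = 3)
  expect_s3_class(gm, "genetic_map")
  expect_equal(nrow(gm$lengths), 2)
  md <- marey_diagnostics(gm)
  expect_equal(md$synteny_pct, 100)
  expect_true(all(abs(md$per_lg$spearman_rho) == 1))
  # rate column is length over physical span
  expect_equal(gm$lengths$rate_cM_per_Mb,
               gm$lengths$length_cM / gm$lengths$span_Mb)
  # arithmetic of the published-rate form: 24.9 cM over 26.32 Mb
  expect_equal(round(24.9 / 26.32, 2), 0.95)
})

test_that("synteny drops when a marker sits on another chromosome", {
  panel <- marker_panel(paste0("m", 1:10), c(rep("1", 9), "2"),
                        position_bp = 1:10 * 1e6)
  map <- data.frame(lg_id = "LG1", marker_id = paste0("m", 1:10),
                    position_cM = seq(0, 45, by = 5),
                    chromosome = panel$chromosome,
                    position_bp = panel$position_bp,
                    stringsAsFactors = FALSE)
  gm <- structure(list(map = map,
                       lengths = data.frame(lg_id = "LG1", n_markers = 10,
                                            length_cM = 45, span_Mb = 9,
                                            rate_cM_per_Mb = 5)),
                  class = "genetic_map")
  md <- marey_diagnostics(gm)
  expect_equal(md$per_lg$synteny_pct, 90)
})
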