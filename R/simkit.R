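#' Define a chromosome for the meiosis simulator
#'
#' @param id chromosome label.
#' @param length_cM genetic length of the bivalent in centiMorgans.
#' @param n_markers number of (evenly spaced) markers; ignored when
#'   \code{marker_cM} is given.
#' @param marker_cM optional explicit marker positions in cM.
#' @param centromere_cM centromere position (default 40\% of the length).
#' @param PP preferential pairing rate.
#' @param beta_telomeric double reduction rate reached at the chromosome
#'   ends (ramps linearly from 0 at the centromere).
#' @param length_Mb physical size used to assign bp positions
#'   (cM mapped linearly to bp).
#' @param n_centromeric,n_telomeric_per_arm how many markers get the
#'   \code{"centromeric"} role (nearest the centromere) and the
#'   \code{"telomeric"} role (outermost per arm).
#' @return object of class \code{sim_chromosome}.
#' @export
sim_chromosome <- function(id, length_cM = 100, n_markers = 18,
                           marker_cM = NULL, centromere_cM = NULL,
                           PP = 0.75, beta_telomeric = 0.1,
                           length_Mb = 30, n_centromeric = 4,
                           n_telomeric_per_arm = 3) {
  if (is.null(marker_cM))
    marker_cM <- seq(0, length_cM, length.out = n_markers)
  if (any(marker_cM < 0 | marker_cM > length_cM))
    stop("marker positions must lie within [0, length_cM]")
  if (is.null(centromere_cM)) centromere_cM <- 0.4 * length_cM
  if (PP < 0 || PP > 1) stop("PP must lie in [0, 1]")
  if (beta_telomeric < 0 || beta_telomeric > 1 / 6 + 1e-12)
    stop("beta_telomeric must lie in [0, 1/6]")
  m <- length(marker_cM)
  role <- rep("other", m)
  ord_cen <- order(abs(marker_cM - centromere_cM))
  role[ord_cen[seq_len(min(n_centromeric, m))]] <- "centromeric"
  k <- n_telomeric_per_arm
  left <- order(marker_cM)[seq_len(min(k, m))]
  right <- order(marker_cM, decreasing = TRUE)[seq_len(min(k, m))]
  tel <- setdiff(union(left, right), ord_cen[seq_len(min(n_centromeric, m))])
  role[tel] <- "telomeric"
  structure(list(id = as.character(id), length_cM = length_cM,
                 marker_cM = sort(marker_cM),
                 centromere_cM = centromere_cM, PP = PP,
                 beta_telomeric = beta_telomeric, length_Mb = length_Mb,
                 role = role[order(marker_cM)]),
            class = "sim_chromosome")
}

#' Simulator configuration
#'
#' @param chromosomes list of \code{\link{sim_chromosome}}.
#' @param n_gametes number of diploid gametes to simulate.
#' @param seed RNG seed; fully determines the output.
#' @param mode \code{"locus_wise"} (independent draws from the single-locus
#'   genotype model; exact beta profiles) or \code{"chromosome_wise"}
#'   (whole-chromosome crossover process; linked markers).
#' @param missing_rate fraction of cells masked missing.
#' @param signal_noise_sd angular noise (degrees) for simulated
#'   fluorescence signals.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(chromosomes, n_gametes = 269, seed = 1L,
                       mode = c("locus_wise", "chromosome_wise"),
                       missing_rate = 0, signal_noise_sd = 2) {
  mode <- match.arg(mode)
  stopifnot(n_gametes >= 1, missing_rate >= 0, missing_rate < 1)
  if (!all(vapply(chromosomes, inherits, logical(1), "sim_chromosome")))
    stop("chromosomes must be sim_chromosome objects")
  structure(list(chromosomes = chromosomes, n_gametes = n_gametes,
                 seed = as.integer(seed), mode = mode,
                 missing_rate = missing_rate,
                 signal_noise_sd = signal_noise_sd),
            class = "sim_config")
}

#' Default preset emulating the 'Giant Key' lime study design
#'
#' Nine chromosomes with the published per-chromosome preferential-pairing
#' and double-reduction estimates, 158 markers distributed as in the SNP
#' panel, 269 gametes.
#'
#' @param n_gametes cohort size (default 269).
#' @param seed RNG seed (default 20200625).
#' @param mode simulation mode (default \code{"locus_wise"}).
#' @param missing_rate missing-cell fraction (default 0.02).
#' @return a \code{sim_config}.
#' @export
giant_key_config <- function(n_gametes = 269, seed = 20200625L,
                             mode = "locus_wise", missing_rate = 0.02) {
  pp <- c(0.751, 0.82, 0.749, 0.781, 0.633, 0.669, 0.733, 0.995, 0.945)
  # published 0.167 values are the rounded admissible maximum 1/6
  dr <- pmin(c(0.136, 0.118, 0.167, 0.084, 0.109, 0.007, 0.132, 0.167,
               0.167), 1 / 6)
  n_mk <- c(19, 19, 25, 19, 14, 13, 14, 15, 20)
  mb <- c(26.32, 33.11, 50.8, 25.35, 43.06, 24.97, 18.87, 23.79, 30.03)
  chroms <- lapply(1:9, function(i)
    sim_chromosome(id = as.character(i), length_cM = 100,
                   n_markers = n_mk[i], PP = pp[i],
                   beta_telomeric = dr[i], length_Mb = mb[i]))
  sim_config(chroms, n_gametes = n_gametes, seed = seed, mode = mode,
             missing_rate = missing_rate)
}

sim_marker_panel <- function(cfg) {
  rows <- lapply(cfg$chromosomes, function(ch) {
    bp <- round(1 + ch$marker_cM / max(ch$length_cM, 1e-9) *
                  (ch$length_Mb * 1e6 - 1))
    bp <- cummax(bp + seq_along(bp) - 1)  # enforce distinct, increasing
    data.frame(
      marker_id = sprintf("S%02d_%d", as.integer(ch$id), bp),
      chromosome = ch$id, position_bp = bp, role = ch$role,
      cM = ch$marker_cM, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# beta profile: 0 at the centromere, beta_telomeric at each chromosome end,
# linear in the distance fraction along the arm.
beta_profile <- function(ch) {
  arm <- ifelse(ch$marker_cM <= ch$centromere_cM,
                ch$centromere_cM,
                ch$length_cM - ch$centromere_cM)
  frac <- abs(ch$marker_cM - ch$centromere_cM) / pmax(arm, 1e-9)
  ch$beta_telomeric * pmin(frac, 1)
}

mask_missing <- function(mat, rate) {
  if (rate <= 0) return(mat)
  mat[stats::runif(length(mat)) < rate] <- NA
  mat
}

#' Locus-wise gamete simulation
#'
#' Each marker x gamete genotype is drawn independently from
#' \code{\link{genotype_probs}} at the chromosome's PP and the marker's
#' double reduction rate (linear ramp from 0 at the centromere to the
#' chromosome's telomeric beta).  This mode realises the single-locus
#' model exactly and is the default for estimator validation.
#'
#' @param cfg a \code{sim_config} with \code{mode = "locus_wise"}.
#' @return a \code{gamete_matrix}; gamete ids \code{g1..gn}.
#' @export
simulate_locus_wise <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$mode == "locus_wise")
  set.seed(cfg$seed)
  panel <- sim_marker_panel(cfg)
  n <- cfg$n_gametes
  cols <- list()
  for (ch in cfg$chromosomes) {
    betas <- beta_profile(ch)
    for (k in seq_along(ch$marker_cM)) {
      p <- genotype_probs(ch$PP, betas[k])
      cols[[length(cols) + 1]] <-
        sample(GENOTYPE_LEVELS, n, replace = TRUE, prob = p)
    }
  }
  gt <- do.call(cbind, cols)
  dimnames(gt) <- list(paste0("g", seq_len(n)), panel$marker_id)
  gt <- mask_missing(gt, cfg$missing_rate)
  gamete_matrix(gt, marker_panel(panel$marker_id, panel$chromosome,
                                 panel$position_bp, panel$role))
}

# Chromatid origins for nH gametes from one heterologous M/A bivalent:
# matrix (nH x m) of 1 = M origin, 0 = A origin.  Haldane model: origin
# starts uniform at position 0 and switches with Poisson(interval length
# in Morgans) crossovers; only switch-count parity matters per interval.
chromatid_origins <- function(nH, marker_cM) {
  m <- length(marker_cM)
  gaps <- diff(c(0, marker_cM)) / 100  # Morgans
  switches <- matrix(stats::rpois(nH * m, rep(gaps, each = nH)), nH, m)
  cum <- if (m == 1) switches else t(apply(switches, 1, cumsum))
  (matrix(stats::rbinom(nH, 1, 0.5), nH, m) + cum) %% 2
}

#' Chromosome-wise gamete simulation
#'
#' Whole-meiosis model: with probability PP the chromosome pairs
#' homologously and the gamete is AM at every marker.  Otherwise the
#' pairing configuration is uniform over the three possibilities; the
#' homologous one again yields AM throughout, while either heterologous
#' configuration builds one chromatid per M/A bivalent with crossovers
#' from a Poisson process at 1 event/Morgan (Haldane, no interference).
#' Double reduction is approximated within random-pairing meioses: with
#' probability \eqn{6\beta} the gamete's two chromatid origins are forced
#' equal distal to the first crossover of one bivalent and opposite
#' proximal to it (no effect when that chromatid has no crossover), a
#' mechanism calibrated to reach roughly the target beta at the telomeres.
#'
#' @param cfg a \code{sim_config} with \code{mode = "chromosome_wise"}.
#' @return a \code{gamete_matrix}; per-chromosome simulated crossover
#'   counts are attached as attribute \code{"true_crossovers"}.
#' @export
simulate_chromosome_wise <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$mode == "chromosome_wise")
  set.seed(cfg$seed)
  panel <- sim_marker_panel(cfg)
  n <- cfg$n_gametes
  blocks <- list()
  xo <- list()
  for (ch in cfg$chromosomes) {
    m <- length(ch$marker_cM)
    gt <- matrix("AM", n, m)
    n_xo <- integer(n)
    tetra <- stats::runif(n) >= ch$PP
    config <- integer(n)
    config[tetra] <- sample.int(3, sum(tetra), replace = TRUE)
    het <- which(config >= 2)  # heterologous configurations
    nH <- length(het)
    if (nH > 0) {
      o1 <- chromatid_origins(nH, ch$marker_cM)
      o2 <- chromatid_origins(nH, ch$marker_cM)
      if (ch$beta_telomeric > 0) {
        dr <- stats::runif(nH) < 6 * ch$beta_telomeric
        for (i in which(dr)) {
          j <- which(o1[i, ] != o1[i, 1])[1]  # first observed switch
          if (is.na(j)) next
          if (j > 1) o2[i, seq_len(j - 1)] <- 1 - o1[i, seq_len(j - 1)]
          o2[i, j:m] <- o1[i, j:m]
        }
      }
      alle <- o1 + o2
      gt[het, ] <- GENOTYPE_LEVELS[alle + 1]
      if (m > 1)
        n_xo[het] <- rowSums(abs(o1[, -1, drop = FALSE] -
                                 o1[, -m, drop = FALSE])) +
                     rowSums(abs(o2[, -1, drop = FALSE] -
                                 o2[, -m, drop = FALSE]))
    }
    blocks[[ch$id]] <- gt
    xo[[ch$id]] <- n_xo
  }
  gt <- do.call(cbind, blocks)
  dimnames(gt) <- list(paste0("g", seq_len(n)), panel$marker_id)
  gt <- mask_missing(gt, cfg$missing_rate)
  out <- gamete_matrix(gt, marker_panel(panel$marker_id, panel$chromosome,
                                        panel$position_bp, panel$role))
  attr(out, "true_crossovers") <- do.call(cbind, xo)
  out
}

#' Simulate gametes according to the configured mode
#'
#' @param cfg a \code{sim_config}.
#' @return a \code{gamete_matrix}.
#' @export
simulate_gametes <- function(cfg) {
  if (cfg$mode == "locus_wise") simulate_locus_wise(cfg)
  else simulate_chromosome_wise(cfg)
}

#' Triploid dose matrix from a gamete matrix
#'
#' Adds the haploid A gamete of the diploid seed parent implicitly:
#' AA gametes give dose-0 (AAA) hybrids, AM dose-1 (AAM), MM dose-2 (AMM).
#'
#' @param g a \code{gamete_matrix}.
#' @return a \code{dose_matrix}.
#' @export
make_triploid_doses <- function(g) gametes_to_doses(g)

#' Simulate two-channel fluorescence signals for a dose matrix
#'
#' Each dose is mapped to its expected theta (piecewise-linear through the
#' anchors at M-allele fractions 0, 1/3, 2/3), Gaussian angular noise is
#' added, and the radial norm is drawn uniformly within 10\% of 1.
#' Control records (AA, 1:1 het, MM at fractions 0, 1/2, 1) are emitted
#' with the same noise model for anchor calibration.
#'
#' @param d a \code{dose_matrix} (missing cells skipped).
#' @param anchors a single \code{theta_anchors} applied to every marker
#'   (default 5/45/85 degrees).
#' @param noise_sd angular noise sd in degrees.
#' @param seed RNG seed.
#' @param n_controls control replicates per class and marker.
#' @return list with \code{signals} and \code{controls} data.frames (the
#'   latter with a \code{genotype} column).
#' @export
simulate_signals <- function(d, anchors = theta_anchors(5, 45, 85),
                             noise_sd = 2, seed = 1L, n_controls = 2) {
  stopifnot(inherits(d, "dose_matrix"))
  set.seed(seed)
  idx <- which(!is.na(d$dose), arr.ind = TRUE)
  f <- d$dose[idx] / 3
  th <- expected_theta(f, anchors) +
    stats::rnorm(nrow(idx), 0, noise_sd)
  th <- pmin(pmax(th, 0), 90)
  rad <- stats::runif(nrow(idx), 0.9, 1.1)
  signals <- data.frame(
    sample_id = rownames(d$dose)[idx[, 1]],
    marker_id = colnames(d$dose)[idx[, 2]],
    x_signal = rad * cos(th * pi / 180),
    y_signal = rad * sin(th * pi / 180),
    stringsAsFactors = FALSE)
  ctrl_f <- rep(c(0, 0.5, 1), each = n_controls)
  ctrl_gt <- rep(c("AA", "AM", "MM"), each = n_controls)
  controls <- do.call(rbind, lapply(colnames(d$dose), function(mk) {
    th_c <- expected_theta(ctrl_f, anchors) +
      stats::rnorm(length(ctrl_f), 0, noise_sd)
    th_c <- pmin(pmax(th_c, 0), 90)
    rad_c <- stats::runif(length(ctrl_f), 0.9, 1.1)
    data.frame(sample_id = paste0("ctrl_", ctrl_gt, "_",
                                  seq_along(ctrl_f)),
               marker_id = mk,
               x_signal = rad_c * cos(th_c * pi / 180),
               y_signal = rad_c * sin(th_c * pi / 180),
               genotype = ctrl_gt, stringsAsFactors = FALSE)
  }))
  list(signals = signals, controls = controls)
}
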