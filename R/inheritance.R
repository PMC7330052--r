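#' Gamete genotype probabilities under mixed disomic/tetrasomic meiosis
#'
#' For a duplex (AAMM) tetraploid, the probability that a diploid gamete is
#' AA, AM or MM at a locus depends on the preferential-pairing rate
#' \code{PP} (fraction of meioses with exclusive homologous pairing), its
#' complement the tetrasomic fraction \eqn{\tau = 1 - PP}, and the double
#' reduction rate \code{beta} (relative frequency, within the tetrasomic
#' fraction, of gametes carrying two copies of the same parental
#' chromosome region; admissible maximum 1/6).
#'
#' The model: preferentially paired meioses transmit full heterozygosity
#' (AM with probability 1).  Random-pairing meioses without double
#' reduction segregate 1 AA : 4 AM : 1 MM.  Double-reduction gametes are
#' AA or MM with probability 1/2 each.  Hence
#' \deqn{p_{AM} = PP + \tau (2/3)(1-\beta), \quad
#'       p_{AA} = p_{MM} = \tau[(1-\beta)/6 + \beta/2].}
#'
#' @param PP preferential pairing rate in \[0, 1\].
#' @param beta double reduction rate in \[0, 1/6\].
#' @return named numeric vector \code{c(pAA, pAM, pMM)} summing to 1.
#' @examples
#' genotype_probs(PP = 0, beta = 0)   # fully tetrasomic: 1/6, 2/3, 1/6
#' genotype_probs(PP = 1, beta = 0)   # fully disomic: all gametes AM
#' @export
genotype_probs <- function(PP, beta = 0) {
  if (!is.finite(PP) || PP < 0 || PP > 1)
    stop("PP must lie in [0, 1]")
  if (!is.finite(beta) || beta < 0 || beta > 1 / 6 + 1e-12)
    stop("beta must lie in [0, 1/6]")
  tau <- 1 - PP
  p_hom <- tau * ((1 - beta) / 6 + beta / 2)
  p_het <- PP + tau * (2 / 3) * (1 - beta)
  c(pAA = p_hom, pAM = p_het, pMM = p_hom)
}

#' Observed genotype counts at a locus
#'
#' @param n_AA,n_AM,n_MM non-negative integer counts of diploid gametes in
#'   each genotype class.
#' @return object of class \code{genotype_counts}.
#' @export
genotype_counts <- function(n_AA, n_AM, n_MM) {
  n <- c(n_AA = n_AA, n_AM = n_AM, n_MM = n_MM)
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    stop("counts must be non-negative integers")
  structure(as.list(n), class = "genotype_counts")
}

count_total <- function(counts) counts$n_AA + counts$n_AM + counts$n_MM

as_genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  if (is.numeric(x) && length(x) == 3)
    return(genotype_counts(x[[1]], x[[2]], x[[3]]))
  stop("cannot interpret as genotype counts")
}

#' Multinomial log-likelihood of genotype counts
#'
#' @param counts a \code{genotype_counts} (or length-3 numeric
#'   \code{c(n_AA, n_AM, n_MM)}).
#' @param PP,beta model parameters as in \code{\link{genotype_probs}}.
#' @return log-likelihood including the multinomial coefficient;
#'   \code{-Inf} when an observed class has probability zero.
#' @export
loglik_counts <- function(counts, PP, beta = 0) {
  counts <- as_genotype_counts(counts)
  x <- c(counts$n_AA, counts$n_AM, counts$n_MM)
  p <- genotype_probs(PP, beta)
  if (any(x > 0 & p == 0)) return(-Inf)
  const <- lgamma(sum(x) + 1) - sum(lgamma(x + 1))
  const + sum(ifelse(x > 0, x * log(p), 0))
}

#' Estimate the tetrasomic fraction from a centromeric locus
#'
#' At the centromere double reduction is null, so homozygous gametes arise
#' only from the random-pairing fraction: \eqn{p_{AA} + p_{MM} = \tau/3}.
#' The ML estimate is the closed form \eqn{\hat\tau = 3 (n_{AA} +
#' n_{MM})/n}, clipped to \[0, 1\]; its standard error comes from the
#' binomial delta method.  \code{method = "grid"} maximises the multinomial
#' log-likelihood on a \eqn{\tau} grid instead (step \code{1e-4}) and is
#' retained as an audit path.
#'
#' @param counts a \code{genotype_counts}.
#' @param method \code{"closed_form"} (default) or \code{"grid"}.
#' @return list with \code{tau_hat}, \code{se}, \code{clipped}, \code{n}.
#' @export
estimate_tau <- function(counts, method = c("closed_form", "grid")) {
  counts <- as_genotype_counts(counts)
  method <- match.arg(method)
  n <- count_total(counts)
  if (n < 1) stop("no observed gametes")
  f_hom <- (counts$n_AA + counts$n_MM) / n
  if (method == "closed_form") {
    tau_raw <- 3 * f_hom
    tau_hat <- min(max(tau_raw, 0), 1)
  } else {
    grid <- seq(0, 1, by = 1e-4)
    ll <- vapply(grid, function(t) loglik_counts(counts, PP = 1 - t, beta = 0),
                 numeric(1))
    tau_hat <- grid[which.max(ll)]
    tau_raw <- tau_hat
  }
  # var(tau_hat) = 9 var(f_hom) = 9 f(1-f)/n
  se <- 3 * sqrt(f_hom * (1 - f_hom) / n)
  list(tau_hat = tau_hat, se = se, clipped = tau_raw < 0 || tau_raw > 1,
       n = n)
}

#' Estimate double reduction at a telomeric locus, tau fixed
#'
#' With the chromosome's tetrasomic fraction \eqn{\tau} held fixed, the
#' homozygous-gamete probability is \eqn{\tau(1 + 2\beta)/6 \cdot 2 =
#' \tau(1+2\beta)/3}, giving the closed-form ML estimate
#' \eqn{\hat\beta = (3 f_{hom}/\tau - 1)/2} with
#' \eqn{f_{hom} = (n_{AA}+n_{MM})/n}, clipped to \[0, 1/6\].
#'
#' @param counts a \code{genotype_counts}.
#' @param tau fixed tetrasomic fraction, must be > 0 (beta is
#'   unidentifiable under full disomy).
#' @param method \code{"closed_form"} (default) or \code{"grid"} (grid
#'   step \code{1e-4} over \[0, 1/6\]).
#' @return list with \code{beta_hat}, \code{se}, \code{clipped}, \code{n}.
#' @export
estimate_dr <- function(counts, tau, method = c("closed_form", "grid")) {
  counts <- as_genotype_counts(counts)
  method <- match.arg(method)
  if (!is.finite(tau) || tau <= 0)
    stop("beta unidentifiable under full disomy (tau = 0)")
  n <- count_total(counts)
  if (n < 1) stop("no observed gametes")
  f_hom <- (counts$n_AA + counts$n_MM) / n
  beta_raw <- (3 * f_hom / tau - 1) / 2
  if (method == "closed_form") {
    beta_hat <- min(max(beta_raw, 0), 1 / 6)
  } else {
    grid <- seq(0, 1 / 6, by = 1e-4)
    ll <- vapply(grid, function(b) loglik_counts(counts, PP = 1 - tau,
                                                 beta = b), numeric(1))
    beta_hat <- grid[which.max(ll)]
  }
  # d beta / d f_hom = 3/(2 tau)
  se <- (3 / (2 * tau)) * sqrt(f_hom * (1 - f_hom) / n)
  list(beta_hat = beta_hat, se = se,
       clipped = beta_raw < 0 || beta_raw > 1 / 6, n = n)
}

marker_counts <- function(g, marker_id) {
  col <- g$genotype[, marker_id]
  genotype_counts(sum(col == "AA", na.rm = TRUE),
                  sum(col == "AM", na.rm = TRUE),
                  sum(col == "MM", na.rm = TRUE))
}

#' Per-chromosome inheritance estimates
#'
#' Reproduces the standard centromeric/telomeric split: the tetrasomic
#' fraction \eqn{\tau} is the mean of the per-marker closed-form estimates
#' over the chromosome's centromeric markers (dispersion = their sd);
#' \eqn{PP = 1 - \tau}; double reduction \eqn{\beta} is the mean over the
#' designated telomeric markers, each estimated with the chromosome's
#' fixed \eqn{\tau}.
#'
#' @param g a \code{gamete_matrix} with marker roles assigned.
#' @param chromosome chromosome label to estimate; default all.
#' @param bootstrap integer; if > 0, additionally report bootstrap standard
#'   errors by resampling gametes (seeded by \code{boot_seed}).
#' @param boot_seed seed for the bootstrap resampling.
#' @param on_missing_centromere \code{"error"} (default) or \code{"skip"}:
#'   what to do with a chromosome that has no centromeric marker (e.g.
#'   after aggressive QC filtering); skipped chromosomes get NA estimates.
#' @return data.frame with one row per chromosome: \code{chromosome},
#'   \code{PP}, \code{tau}, \code{tau_sd}, \code{beta}, \code{beta_sd},
#'   \code{n_centromeric}, \code{n_telomeric} (and bootstrap columns when
#'   requested).
#' @export
estimate_chromosome <- function(g, chromosome = NULL, bootstrap = 0,
                                boot_seed = 1L,
                                on_missing_centromere = c("error", "skip")) {
  stopifnot(inherits(g, "gamete_matrix"))
  on_missing_centromere <- match.arg(on_missing_centromere)
  chroms <- if (is.null(chromosome)) unique(g$markers$chromosome)
            else chromosome
  one <- function(chr, gm) {
    mk <- gm$markers[gm$markers$chromosome == chr, , drop = FALSE]
    cen <- mk$marker_id[mk$role == "centromeric"]
    tel <- mk$marker_id[mk$role == "telomeric"]
    if (!length(cen)) {
      if (on_missing_centromere == "error")
        stop("no centromeric marker on chromosome ", chr)
      return(data.frame(chromosome = chr, PP = NA_real_, tau = NA_real_,
                        tau_sd = NA_real_, beta = NA_real_,
                        beta_sd = NA_real_, n_centromeric = 0L,
                        n_telomeric = length(tel),
                        stringsAsFactors = FALSE))
    }
    taus <- vapply(cen, function(id)
      estimate_tau(marker_counts(gm, id))$tau_hat, numeric(1))
    tau <- mean(taus)
    betas <- if (length(tel) && tau > 0)
      vapply(tel, function(id)
        estimate_dr(marker_counts(gm, id), tau = tau)$beta_hat, numeric(1))
    else numeric(0)
    data.frame(chromosome = chr, PP = 1 - tau, tau = tau,
               tau_sd = if (length(taus) > 1) stats::sd(taus) else 0,
               beta = if (length(betas)) mean(betas) else NA_real_,
               beta_sd = if (length(betas) > 1) stats::sd(betas) else
                 if (length(betas) == 1) 0 else NA_real_,
               n_centromeric = length(cen), n_telomeric = length(tel),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(chroms, one, gm = g))
  if (bootstrap > 0) {
    set.seed(boot_seed)
    reps <- replicate(bootstrap, {
      idx <- sample.int(nrow(g$genotype), replace = TRUE)
      gb <- gamete_matrix(`rownames<-`(g$genotype[idx, , drop = FALSE],
                                       paste0("b", seq_along(idx))),
                          g$markers)
      est <- do.call(rbind, lapply(chroms, one, gm = gb))
      rbind(est$PP, est$beta)
    })
    out$PP_boot_se <- apply(reps[1, , , drop = FALSE], 2, stats::sd)
    out$beta_boot_se <- apply(reps[2, , , drop = FALSE], 2, stats::sd)
  }
  rownames(out) <- NULL
  out
}

#' Per-marker inheritance table
#'
#' Genotype counts, parental heterozygosity restitution and the role-
#' appropriate estimator (\eqn{\hat\tau} for centromeric markers,
#' \eqn{\hat\beta} for telomeric ones, using the chromosome \eqn{\tau})
#' for every marker.
#'
#' @param g a \code{gamete_matrix}.
#' @return data.frame, one row per marker.
#' @export
marker_table <- function(g) {
  stopifnot(inherits(g, "gamete_matrix"))
  est <- estimate_chromosome(g, on_missing_centromere = "skip")
  rows <- lapply(seq_len(nrow(g$markers)), function(i) {
    mk <- g$markers[i, ]
    ct <- marker_counts(g, mk$marker_id)
    n <- count_total(ct)
    tau_chr <- est$tau[est$chromosome == mk$chromosome]
    tau_hat <- if (n > 0) estimate_tau(ct)$tau_hat else NA_real_
    beta_hat <- if (mk$role == "telomeric" && n > 0 &&
                    isTRUE(tau_chr > 0))
      estimate_dr(ct, tau = tau_chr)$beta_hat else NA_real_
    data.frame(marker_id = mk$marker_id, chromosome = mk$chromosome,
               position_bp = mk$position_bp, role = mk$role,
               n_AA = ct$n_AA, n_AM = ct$n_AM, n_MM = ct$n_MM,
               phr = if (n > 0) ct$n_AM / n else NA_real_,
               tau_hat = tau_hat, beta_hat = beta_hat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parental heterozygosity restitution summary
#'
#' PHR of a marker is the fraction of observed gametes heterozygous (AM)
#' there; PHR of a gamete is its heterozygous fraction over observed
#' markers.  Chromosome means average their markers' PHR.  Full-state
#' percentages count gametes whose every observed marker on the chromosome
#' is AM (fully heterozygous), MM (fully M-homozygous) or AA (fully
#' A-homozygous); gametes with no observed marker on a chromosome are
#' excluded from that chromosome's denominator.
#'
#' @param g a \code{gamete_matrix}.
#' @return list with \code{per_marker}, \code{per_gamete},
#'   \code{per_chromosome} (PHR mean/sd and full-state percentages) and
#'   \code{genome} (genome-wide means, marker-averaged).
#' @export
phr_summary <- function(g) {
  stopifnot(inherits(g, "gamete_matrix"))
  gt <- g$genotype
  het <- gt == "AM"
  per_marker <- data.frame(
    marker_id = colnames(gt),
    chromosome = g$markers$chromosome,
    n_obs = colSums(!is.na(gt)),
    phr = colMeans(het, na.rm = TRUE),
    stringsAsFactors = FALSE)
  per_marker$phr[per_marker$n_obs == 0] <- NA_real_
  per_gamete <- data.frame(
    gamete_id = rownames(gt),
    n_obs = rowSums(!is.na(gt)),
    phr = rowMeans(het, na.rm = TRUE),
    stringsAsFactors = FALSE)
  chroms <- unique(g$markers$chromosome)
  per_chr <- do.call(rbind, lapply(chroms, function(chr) {
    cols <- g$markers$marker_id[g$markers$chromosome == chr]
    sub <- gt[, cols, drop = FALSE]
    obs <- !is.na(sub)
    any_obs <- rowSums(obs) > 0
    full_state <- function(state)
      100 * mean(rowSums(sub == state, na.rm = TRUE)[any_obs] ==
                 rowSums(obs)[any_obs])
    mk_phr <- per_marker$phr[per_marker$chromosome == chr]
    data.frame(chromosome = chr,
               phr_mean = mean(mk_phr, na.rm = TRUE),
               phr_sd = stats::sd(mk_phr, na.rm = TRUE),
               pct_full_het = full_state("AM"),
               pct_full_M = full_state("MM"),
               pct_full_A = full_state("AA"),
               n_markers = length(cols),
               stringsAsFactors = FALSE)
  }))
  rownames(per_chr) <- NULL
  list(per_marker = per_marker, per_gamete = per_gamete,
       per_chromosome = per_chr,
       genome = list(phr_mean = mean(per_marker$phr, na.rm = TRUE),
                     phr_sd = stats::sd(per_marker$phr, na.rm = TRUE)))
}
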