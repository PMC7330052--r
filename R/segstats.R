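distortion_result <- function(marker_id, test, statistic, df, p_value,
                              direction, delta, flag = NA_character_) {
  data.frame(marker_id = marker_id, test = test, statistic = statistic,
             df = df, p_value = p_value, direction = direction,
             delta = delta, flag = flag, stringsAsFactors = FALSE)
}

chisq_stat <- function(obs, expected) sum((obs - expected)^2 / expected)

#' Allele-frequency segregation test
#'
#' Pearson chi-square (df = 1, no continuity correction) of the M-allele
#' count (\eqn{2 n_{MM} + n_{AM}} out of \eqn{2n} alleles) against the
#' Mendelian 1:1 expectation.  \code{delta} is the observed M frequency
#' minus 0.5 and determines the reported direction.
#'
#' @param counts a \code{genotype_counts} (or \code{c(n_AA, n_AM, n_MM)}).
#' @param marker_id label carried into the result.
#' @return one-row data.frame (\code{marker_id}, \code{test},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{direction},
#'   \code{delta}, \code{flag}).
#' @export
allele_test <- function(counts, marker_id = NA_character_) {
  counts <- as_genotype_counts(counts)
  n <- count_total(counts)
  if (n < 1) stop("no observed gametes")
  m_alleles <- 2 * counts$n_MM + counts$n_AM
  a_alleles <- 2 * counts$n_AA + counts$n_AM
  stat <- chisq_stat(c(m_alleles, a_alleles), rep(n, 2))
  delta <- m_alleles / (2 * n) - 0.5
  distortion_result(marker_id, "allele", stat, 1L,
                    stats::pchisq(stat, 1, lower.tail = FALSE),
                    direction_of(delta), delta)
}

direction_of <- function(delta) {
  if (is.na(delta) || delta == 0) "none"
  else if (delta > 0) "excess_M" else "excess_A"
}

#' Homozygous-gamete excess test
#'
#' Chi-square (df = 1) of \eqn{n_{AA}} vs \eqn{n_{MM}} against 1:1,
#' restricted to homozygous gametes — the sensitive test when
#' heterozygosity restitution keeps overall allele frequencies near 0.5.
#'
#' @inheritParams allele_test
#' @return one-row data.frame; flagged \code{"not testable"} (statistic
#'   \code{NA}) when there are no homozygous gametes.
#' @export
hom_excess_test <- function(counts, marker_id = NA_character_) {
  counts <- as_genotype_counts(counts)
  n_hom <- counts$n_AA + counts$n_MM
  if (n_hom == 0)
    return(distortion_result(marker_id, "hom_excess", NA_real_, 1L,
                             NA_real_, "none", NA_real_, "not testable"))
  stat <- chisq_stat(c(counts$n_AA, counts$n_MM), rep(n_hom / 2, 2))
  delta <- counts$n_MM / n_hom - 0.5
  distortion_result(marker_id, "hom_excess", stat, 1L,
                    stats::pchisq(stat, 1, lower.tail = FALSE),
                    direction_of(delta), delta)
}

#' Goodness-of-fit test against the tetrasomic 1:4:1 ratio
#'
#' Chi-square (df = 2) of the genotype counts against the expectation
#' (1/6, 2/3, 1/6) from fully random chromosome pairing.  A small-count
#' flag is raised when any expected class count falls below 5.
#'
#' @inheritParams allele_test
#' @return one-row data.frame; \code{delta} is the M-allele frequency
#'   deviation as in \code{\link{allele_test}}.
#' @export
genotype_141_test <- function(counts, marker_id = NA_character_) {
  counts <- as_genotype_counts(counts)
  n <- count_total(counts)
  if (n < 1) stop("no observed gametes")
  obs <- c(counts$n_AA, counts$n_AM, counts$n_MM)
  expected <- n * c(1, 4, 1) / 6
  stat <- chisq_stat(obs, expected)
  delta <- (2 * counts$n_MM + counts$n_AM) / (2 * n) - 0.5
  distortion_result(marker_id, "genotype_141", stat, 2L,
                    stats::pchisq(stat, 2, lower.tail = FALSE),
                    direction_of(delta), delta,
                    flag = if (any(expected < 5)) "small expected counts"
                           else NA_character_)
}

#' Segregation-distortion table for a gamete matrix
#'
#' Runs all three tests on every marker and classifies markers per
#' chromosome by the homozygous-gamete test at level \code{alpha}:
#' \code{NDM} (no significant deviation), \code{excess_M} or
#' \code{excess_A}.  A Bonferroni-adjusted significance column is emitted
#' alongside the raw per-marker calls (the raw calls define the classes).
#'
#' @param g a \code{gamete_matrix}.
#' @param alpha per-marker significance level (default 0.05).
#' @return list with \code{per_marker} (all tests, long format) and
#'   \code{per_chromosome} (marker counts by class, mirroring a
#'   markers-in-excess summary table).
#' @export
distortion_table <- function(g, alpha = 0.05) {
  stopifnot(inherits(g, "gamete_matrix"))
  ids <- g$markers$marker_id
  per_marker <- do.call(rbind, lapply(ids, function(id) {
    ct <- marker_counts(g, id)
    rbind(allele_test(ct, id), hom_excess_test(ct, id),
          genotype_141_test(ct, id))
  }))
  per_marker$chromosome <- g$markers$chromosome[
    match(per_marker$marker_id, ids)]
  n_tests <- length(ids)
  per_marker$significant <- !is.na(per_marker$p_value) &
    per_marker$p_value < alpha
  per_marker$significant_bonferroni <- !is.na(per_marker$p_value) &
    per_marker$p_value < alpha / n_tests
  hom <- per_marker[per_marker$test == "hom_excess", ]
  class_of <- function(row) {
    if (is.na(row$p_value) || row$p_value >= alpha) "NDM"
    else row$direction
  }
  hom$class <- vapply(seq_len(nrow(hom)), function(i) class_of(hom[i, ]),
                      character(1))
  per_chr <- do.call(rbind, lapply(unique(hom$chromosome), function(chr) {
    sub <- hom[hom$chromosome == chr, ]
    data.frame(chromosome = chr, n_markers = nrow(sub),
               NDM = sum(sub$class == "NDM"),
               excess_M = sum(sub$class == "excess_M"),
               excess_A = sum(sub$class == "excess_A"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_chr) <- NULL
  list(per_marker = per_marker, per_chromosome = per_chr, alpha = alpha)
}
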