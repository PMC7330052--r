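transition_cost <- function(a, b) {
  # minimal number of chromosome-origin switches between adjacent genotypes
  if (a == b) 0L
  else if ((a == "AA" && b == "MM") || (a == "MM" && b == "AA")) 2L
  else 1L
}

#' Count crossovers along an ordered genotype sequence
#'
#' Sums, over adjacent observed marker pairs, the minimal number of
#' chromosome-origin switches needed to explain the genotype change:
#' AM to AA or MM costs 1, AA to MM costs 2 (both chromatid origins must
#' switch), identical states cost 0.  Missing states are bridged — the
#' transition is computed between the nearest observed flanks.
#'
#' @param states character vector over \{AA, AM, MM, NA\}, ordered by
#'   position.
#' @return integer crossover count; attribute \code{flag} set when fewer
#'   than two states are observed.
#' @export
count_crossovers <- function(states) {
  obs <- states[!is.na(states)]
  if (length(obs) < 2)
    return(structure(0L, flag = "fewer than 2 observed markers"))
  sum(vapply(seq_len(length(obs) - 1),
             function(i) transition_cost(obs[i], obs[i + 1]), integer(1)))
}

#' Genome composition and crossover summary of a gamete cohort
#'
#' For each gamete: the fraction of observed markers heterozygous (AM),
#' M-homozygous (MM) and A-homozygous (AA), plus crossover counts per
#' chromosome and genome-wide.  Cohort averages and the crossover-count
#' distribution (with cumulative percentages) are attached.
#'
#' @param g a \code{gamete_matrix}.
#' @return list with \code{per_gamete} (composition fractions and total
#'   crossovers), \code{per_gamete_chromosome} (long table of crossover
#'   counts), \code{composition} (cohort means) and \code{crossover_dist}
#'   (count, n gametes, percent, cumulative percent).
#' @export
genome_composition <- function(g) {
  stopifnot(inherits(g, "gamete_matrix"))
  gt <- g$genotype
  ord <- order(g$markers$chromosome, g$markers$position_bp)
  mk <- g$markers[ord, ]
  gt <- gt[, mk$marker_id, drop = FALSE]
  chroms <- unique(mk$chromosome)
  xo <- do.call(rbind, lapply(chroms, function(chr) {
    cols <- mk$marker_id[mk$chromosome == chr]
    data.frame(gamete_id = rownames(gt), chromosome = chr,
               n_crossovers = apply(gt[, cols, drop = FALSE], 1,
                                    function(s) as.integer(count_crossovers(s))),
               stringsAsFactors = FALSE)
  }))
  total_xo <- tapply(xo$n_crossovers, xo$gamete_id, sum)
  obs <- !is.na(gt)
  per_gamete <- data.frame(
    gamete_id = rownames(gt),
    frac_het = rowSums(gt == "AM", na.rm = TRUE) / rowSums(obs),
    frac_M_hom = rowSums(gt == "MM", na.rm = TRUE) / rowSums(obs),
    frac_A_hom = rowSums(gt == "AA", na.rm = TRUE) / rowSums(obs),
    n_crossovers = as.integer(total_xo[rownames(gt)]),
    stringsAsFactors = FALSE)
  tab <- table(per_gamete$n_crossovers)
  dist <- data.frame(n_crossovers = as.integer(names(tab)),
                     n_gametes = as.integer(tab),
                     stringsAsFactors = FALSE)
  dist$percent <- 100 * dist$n_gametes / sum(dist$n_gametes)
  dist$cum_percent <- cumsum(dist$percent)
  list(per_gamete = per_gamete,
       per_gamete_chromosome = xo,
       composition = c(frac_het = mean(per_gamete$frac_het),
                       frac_M_hom = mean(per_gamete$frac_M_hom),
                       frac_A_hom = mean(per_gamete$frac_A_hom)),
       mean_crossovers = mean(per_gamete$n_crossovers),
       crossover_dist = dist)
}

#' Graphical genotypes (run-length encoding per gamete and chromosome)
#'
#' Encodes each gamete-chromosome as maximal runs of constant genotype over
#' the observed markers ordered by physical position, the usual display
#' behind graphical-genotyping software.
#'
#' @param g a \code{gamete_matrix}.
#' @return data.frame with one row per run: \code{gamete_id},
#'   \code{chromosome}, \code{state}, \code{start_bp}, \code{end_bp},
#'   \code{n_markers}.  Gamete-chromosomes with no observed marker are
#'   omitted (they have an empty run list).
#' @export
graphical_genotypes <- function(g) {
  stopifnot(inherits(g, "gamete_matrix"))
  ord <- order(g$markers$chromosome, g$markers$position_bp)
  mk <- g$markers[ord, ]
  gt <- g$genotype[, mk$marker_id, drop = FALSE]
  out <- list()
  for (chr in unique(mk$chromosome)) {
    sel <- mk$chromosome == chr
    pos <- mk$position_bp[sel]
    sub <- gt[, mk$marker_id[sel], drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      keep <- !is.na(sub[i, ])
      if (!any(keep)) next
      s <- sub[i, keep]
      p <- pos[keep]
      r <- rle(s)
      ends <- cumsum(r$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      out[[length(out) + 1]] <- data.frame(
        gamete_id = rownames(sub)[i], chromosome = chr,
        state = r$values, start_bp = p[starts], end_bp = p[ends],
        n_markers = r$lengths, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gamete_id = character(), chromosome = character(),
               state = character(), start_bp = numeric(),
               end_bp = numeric(), n_markers = integer())
  rownames(res) <- NULL
  res
}
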