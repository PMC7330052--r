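#' Two-locus gamete genotype probabilities under random pairing
#'
#' Joint distribution of diploid-gamete genotypes at two coupling-phase
#' duplex loci (both M alleles on the two M-origin chromosomes) under
#' fully tetrasomic inheritance.  Derived by enumeration: the pairing
#' configuration is uniform over the three possibilities; the homologous
#' configuration (M with M, A with A) transmits AM at both loci; in either
#' heterologous configuration each of the two M/A bivalents contributes a
#' chromatid that is non-recombinant with probability \eqn{1-r} (origin
#' probability 1/2 each), recombinant between the loci with probability
#' \eqn{r}.  With \eqn{a = (1-r)/2}, \eqn{b = r/2} the heterologous joint
#' table has corner probabilities \eqn{a^2}, anti-diagonal corners
#' \eqn{b^2}, edges \eqn{2ab} and centre \eqn{2a^2 + 2b^2}.
#'
#' @param r recombination fraction between the loci, in \[0, 0.5\].
#' @return 3x3 matrix of probabilities, rows = genotype at locus 1,
#'   columns = genotype at locus 2, dimnames \{AA, AM, MM\}; sums to 1.
#' @export
two_locus_probs <- function(r) {
  if (!is.finite(r) || r < 0 || r > 0.5)
    stop("r must lie in [0, 0.5]")
  a <- (1 - r) / 2
  b <- r / 2
  het <- matrix(c(a^2,     2 * a * b,       b^2,
                  2 * a * b, 2 * a^2 + 2 * b^2, 2 * a * b,
                  b^2,     2 * a * b,       a^2),
                nrow = 3, byrow = TRUE,
                dimnames = list(GENOTYPE_LEVELS, GENOTYPE_LEVELS))
  tab <- (2 / 3) * het
  tab["AM", "AM"] <- tab["AM", "AM"] + 1 / 3
  tab
}

#' Joint genotype counts for a marker pair
#'
#' @param g a \code{gamete_matrix}.
#' @param marker_i,marker_j marker ids.
#' @return 3x3 matrix of counts over gametes observed at both markers.
#' @export
joint_counts <- function(g, marker_i, marker_j) {
  gi <- factor(g$genotype[, marker_i], levels = GENOTYPE_LEVELS)
  gj <- factor(g$genotype[, marker_j], levels = GENOTYPE_LEVELS)
  unclass(table(gi, gj, dnn = NULL))
}

rf_loglik <- function(tab, r) {
  p <- two_locus_probs(r)
  if (any(tab > 0 & p == 0)) return(-Inf)
  sum(ifelse(tab > 0, tab * log(p), 0))
}

#' ML recombination fraction from a two-locus genotype table
#'
#' Maximises the multinomial likelihood of the 3x3 joint genotype counts
#' under \code{\link{two_locus_probs}} over \eqn{r \in [0, 0.5]} (bounded
#' scalar optimisation, tolerance \code{1e-6}).  The LOD score compares
#' the maximum to independence (\eqn{r = 0.5}).
#'
#' @param tab 3x3 count matrix as from \code{\link{joint_counts}}.
#' @param marker_i,marker_j optional labels carried into the result.
#' @return one-row data.frame: \code{marker_i}, \code{marker_j},
#'   \code{r_hat}, \code{lod}, \code{n_informative}, \code{flag}.
#' @export
estimate_rf <- function(tab, marker_i = NA_character_,
                        marker_j = NA_character_) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n < 1) stop("no informative gametes")
  flag <- NA_character_
  if (sum(tab > 0) == 1) flag <- "degenerate table"
  opt <- stats::optimize(function(r) rf_loglik(tab, r),
                         interval = c(0, 0.5), maximum = TRUE,
                         tol = 1e-6)
  r_hat <- opt$maximum
  ll_half <- rf_loglik(tab, 0.5)
  # optimize() never probes the exact endpoints; snap to a boundary when
  # the likelihood there is at least as high.
  for (rb in c(0, 0.5)) {
    if (rf_loglik(tab, rb) >= opt$objective) {
      r_hat <- rb
      opt$objective <- rf_loglik(tab, rb)
    }
  }
  lod <- max(0, (opt$objective - ll_half) / log(10))
  if (r_hat >= 0.5 - 1e-6) {
    r_hat <- 0.5
    lod <- 0
  }
  data.frame(marker_i = marker_i, marker_j = marker_j, r_hat = r_hat,
             lod = lod, n_informative = n, flag = flag,
             stringsAsFactors = FALSE)
}

#' All pairwise recombination fractions of a gamete matrix
#'
#' @param g a \code{gamete_matrix}.
#' @return data.frame of \code{\link{estimate_rf}} rows for every
#'   unordered marker pair.
#' @export
pairwise_linkage <- function(g) {
  stopifnot(inherits(g, "gamete_matrix"))
  ids <- colnames(g$genotype)
  pairs <- utils::combn(ids, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    estimate_rf(joint_counts(g, i, j), i, j)
  })
  do.call(rbind, out)
}

#' Kosambi map function
#'
#' Converts a recombination fraction to map distance allowing incomplete
#' crossover interference: \eqn{d = 25 \ln[(1+2r)/(1-2r)]} cM.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @param inf_ok if \code{TRUE}, \code{r >= 0.5} yields \code{Inf} instead
#'   of an error.
#' @return map distance(s) in centiMorgans.
#' @export
kosambi <- function(r, inf_ok = FALSE) {
  bad <- r < 0 | r >= 0.5
  if (any(bad) && !inf_ok)
    stop("r must lie in [0, 0.5) for a finite Kosambi distance")
  d <- 25 * log((1 + 2 * r) / (1 - 2 * r))
  d[r >= 0.5] <- Inf
  d
}

#' Group markers into linkage groups by LOD threshold
#'
#' Connected components of the graph whose edges join marker pairs with
#' \code{lod >= lod_threshold}.  Markers without any such edge are
#' reported unassigned.  An average-linkage dendrogram on Kosambi
#' distances is returned as an independent cross-check of the grouping.
#'
#' @param pairwise data.frame from \code{\link{pairwise_linkage}}.
#' @param lod_threshold minimum LOD for an edge.
#' @return list with \code{groups} (named list of marker-id vectors,
#'   largest first), \code{unassigned} (marker ids) and \code{dendrogram}
#'   (an \code{hclust}, or \code{NULL} for < 3 markers).
#' @export
group_markers <- function(pairwise, lod_threshold) {
  ids <- sort(unique(c(pairwise$marker_i, pairwise$marker_j)))
  keep <- pairwise$lod >= lod_threshold
  gr <- igraph::graph_from_data_frame(
    pairwise[keep, c("marker_i", "marker_j")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(gr)
  groups <- split(ids, comp$membership[ids])
  sizes <- vapply(groups, length, integer(1))
  unassigned <- unlist(groups[sizes == 1], use.names = FALSE)
  groups <- groups[order(-sizes)]
  groups <- groups[vapply(groups, length, integer(1)) > 1]
  names(groups) <- paste0("LG", seq_along(groups))
  dendro <- NULL
  if (length(ids) >= 3) {
    dmat <- complete_distances(rf_dist_matrix(pairwise, ids))
    dendro <- stats::hclust(stats::as.dist(dmat), method = "average")
  }
  list(groups = groups, unassigned = unassigned, dendrogram = dendro)
}

# Kosambi distance matrix from a pairwise table.  Near-saturated pairs
# (r_hat >= 0.4) carry almost no ordering information but huge, noisy
# Kosambi distances, so they are set NA and completed by shortest paths
# over the informative pairs.
rf_dist_matrix <- function(pairwise, ids, r_max = 0.4) {
  dmat <- matrix(NA_real_, length(ids), length(ids),
                 dimnames = list(ids, ids))
  diag(dmat) <- 0
  d <- kosambi(pmin(pairwise$r_hat, 0.49999))
  ii <- match(pairwise$marker_i, ids)
  jj <- match(pairwise$marker_j, ids)
  dmat[cbind(ii, jj)] <- d
  dmat[cbind(jj, ii)] <- d
  sat <- pairwise$r_hat >= r_max
  dmat[cbind(ii[sat], jj[sat])] <- NA
  dmat[cbind(jj[sat], ii[sat])] <- NA
  dmat
}

# Floyd-Warshall completion of missing entries (treat NA as +Inf).
complete_distances <- function(dmat) {
  d <- dmat
  d[is.na(d)] <- Inf
  n <- nrow(d)
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  # isolated pairs: fall back to the largest finite distance
  if (any(!is.finite(d))) {
    dmax <- max(d[is.finite(d)], 0)
    d[!is.finite(d)] <- dmax * 1.5
  }
  d
}

# Local search polishing: 2-opt segment reversals and single-marker
# insertions, accepting moves that reduce the sum of adjacent distances.
polish_order <- function(ord, D) {
  cost <- function(o) sum(D[cbind(o[-length(o)], o[-1])])
  n <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      cand <- ord
      cand[i:j] <- rev(cand[i:j])
      if (cost(cand) < cost(ord) - 1e-12) { ord <- cand; improved <- TRUE }
    }
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      cand <- append(ord[-i], ord[i], after = j - 1)
      if (cost(cand) < cost(ord) - 1e-12) { ord <- cand; improved <- TRUE }
    }
  }
  ord
}

#' Order markers within a linkage group
#'
#' One-dimensional seriation of the markers from the pairwise linkage
#' evidence.  The order comes from the Fiedler vector (second-smallest
#' Laplacian eigenvector) of the similarity graph weighted by
#' \eqn{LOD \cdot (0.5 - \hat r)} — spectral seriation, the graph
#' analogue of a principal-coordinate projection, which downweights the
#' noisy near-saturated pairs that destabilise classical MDS on
#' Kosambi-transformed distances (ties broken by marker id; classical
#' MDS on the shortest-path-completed Kosambi distances is the fallback
#' for degenerate weights).  The seriation order is then polished by a
#' local search (2-opt reversals and single-marker insertions) minimising
#' the total adjacent map distance.  Positions are rescaled so that adjacent
#' markers sit at the Kosambi distance of their adjacent \eqn{\hat r};
#' orientation puts the marker with the smallest bp position first when
#' physical positions are supplied.
#'
#' @param lg character vector of marker ids in the group.
#' @param pairwise data.frame from \code{\link{pairwise_linkage}}.
#' @param markers optional \code{marker_panel} used only for orientation.
#' @return data.frame: \code{marker_id}, \code{position_cM} (first marker
#'   at 0, non-decreasing).
#' @export
order_markers <- function(lg, pairwise, markers = NULL) {
  if (length(lg) < 2) stop("need at least 2 markers to order")
  sub <- pairwise[pairwise$marker_i %in% lg & pairwise$marker_j %in% lg, ]
  if (length(lg) == 2) {
    ord <- lg
    if (!is.null(markers)) {
      bp <- markers$position_bp[match(lg, markers$marker_id)]
      ord <- lg[order(bp)]
    }
    d <- kosambi(min(sub$r_hat, 0.49999))
    return(data.frame(marker_id = ord, position_cM = c(0, d),
                      stringsAsFactors = FALSE))
  }
  n <- length(lg)
  W <- matrix(0, n, n, dimnames = list(lg, lg))
  ii <- match(sub$marker_i, lg)
  jj <- match(sub$marker_j, lg)
  w <- sub$lod * (0.5 - sub$r_hat)
  W[cbind(ii, jj)] <- w
  W[cbind(jj, ii)] <- w
  if (all(w <= 0)) {
    dmat <- complete_distances(rf_dist_matrix(sub, lg))
    coord <- stats::cmdscale(stats::as.dist(dmat), k = 1)[, 1]
  } else {
    W <- W + 1e-9  # keep the graph connected
    diag(W) <- 0
    lap <- diag(rowSums(W)) - W
    coord <- eigen(lap, symmetric = TRUE)$vectors[, n - 1]
  }
  ord <- lg[order(coord, lg)]
  ord <- polish_order(ord, complete_distances(rf_dist_matrix(sub, lg)))
  if (!is.null(markers)) {
    bp <- markers$position_bp[match(ord, markers$marker_id)]
    if (length(bp) && !any(is.na(bp)) &&
        which.min(bp) > length(ord) - which.min(bp) + 1)
      ord <- rev(ord)
  }
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  lut <- stats::setNames(sub$r_hat, key(sub$marker_i, sub$marker_j))
  adj_r <- lut[key(utils::head(ord, -1), utils::tail(ord, -1))]
  adj_r[is.na(adj_r)] <- 0.49999
  pos <- c(0, cumsum(kosambi(pmin(adj_r, 0.49999))))
  data.frame(marker_id = ord, position_cM = pos, stringsAsFactors = FALSE)
}

#' Build a genetic map from a gamete matrix
#'
#' Pairwise recombination fractions, LOD grouping and MDS ordering in one
#' call, under the random-pairing (tetrasomic) model throughout.
#'
#' @param g a \code{gamete_matrix}.
#' @param lod_threshold LOD threshold for grouping.
#' @param pairwise optional precomputed \code{\link{pairwise_linkage}}
#'   table (recomputed when \code{NULL}).
#' @return object of class \code{genetic_map}: list with \code{map}
#'   (data.frame lg_id, marker_id, position_cM, chromosome, position_bp),
#'   \code{lengths} (per-LG cM length, Mb span, cM/Mb rate),
#'   \code{pairwise}, \code{unassigned}, \code{dendrogram}.
#' @export
build_map <- function(g, lod_threshold, pairwise = NULL) {
  stopifnot(inherits(g, "gamete_matrix"))
  if (is.null(pairwise)) pairwise <- pairwise_linkage(g)
  grp <- group_markers(pairwise, lod_threshold)
  maps <- lapply(names(grp$groups), function(lg_id) {
    om <- order_markers(grp$groups[[lg_id]], pairwise, g$markers)
    om$lg_id <- lg_id
    om
  })
  map <- do.call(rbind, maps)
  map$chromosome <- g$markers$chromosome[match(map$marker_id,
                                               g$markers$marker_id)]
  map$position_bp <- g$markers$position_bp[match(map$marker_id,
                                                 g$markers$marker_id)]
  map <- map[, c("lg_id", "marker_id", "position_cM", "chromosome",
                 "position_bp")]
  lengths <- do.call(rbind, lapply(split(map, map$lg_id), function(sub) {
    span_mb <- diff(range(sub$position_bp)) / 1e6
    len <- max(sub$position_cM)
    data.frame(lg_id = sub$lg_id[1], n_markers = nrow(sub),
               length_cM = len, span_Mb = span_mb,
               rate_cM_per_Mb = if (span_mb > 0) len / span_mb else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(lengths) <- NULL
  structure(list(map = map, lengths = lengths, pairwise = pairwise,
                 unassigned = grp$unassigned, dendrogram = grp$dendrogram),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d linkage groups, %d markers, %.1f cM total\n",
              nrow(x$lengths), nrow(x$map), sum(x$lengths$length_cM)))
  invisible(x)
}

#' Marey / synteny diagnostics for a genetic map
#'
#' Synteny assigns each linkage group its majority physical chromosome and
#' scores the percentage of mapped markers sitting on their group's
#' majority chromosome.  Colinearity is the per-group Spearman correlation
#' between genetic (cM) and physical (bp) position, computed over the
#' majority-chromosome markers; groups with fewer than 3 such markers are
#' flagged \code{NA}.
#'
#' @param gm a \code{genetic_map}.
#' @return list with \code{synteny_pct} (overall), \code{per_lg}
#'   (majority chromosome, n markers, synteny %, Spearman rho, cM/Mb
#'   rate) and \code{marey} (the plot table: lg_id, marker_id, bp, cM).
#' @export
marey_diagnostics <- function(gm) {
  stopifnot(inherits(gm, "genetic_map"))
  map <- gm$map
  per_lg <- do.call(rbind, lapply(split(map, map$lg_id), function(sub) {
    maj <- names(sort(table(sub$chromosome), decreasing = TRUE))[1]
    on_maj <- sub$chromosome == maj
    rho <- if (sum(on_maj) >= 3)
      suppressWarnings(stats::cor(sub$position_cM[on_maj],
                                  sub$position_bp[on_maj],
                                  method = "spearman"))
    else NA_real_
    data.frame(lg_id = sub$lg_id[1], majority_chromosome = maj,
               n_markers = nrow(sub), n_syntenic = sum(on_maj),
               synteny_pct = 100 * mean(on_maj), spearman_rho = rho,
               stringsAsFactors = FALSE)
  }))
  rownames(per_lg) <- NULL
  per_lg <- merge(per_lg, gm$lengths[, c("lg_id", "rate_cM_per_Mb")],
                  by = "lg_id")
  list(synteny_pct = 100 * sum(per_lg$n_syntenic) / sum(per_lg$n_markers),
       per_lg = per_lg,
       marey = map[, c("lg_id", "marker_id", "position_bp", "position_cM")])
}
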