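#' Pairwise Euclidean distances on dose vectors
#'
#' Distance between two samples is the Euclidean distance over markers
#' observed in both, rescaled by \eqn{\sqrt{M/m}} (total markers over
#' co-observed markers) so that missing data do not systematically shrink
#' distances.
#'
#' @param m a \code{dose_matrix} with at least 2 samples.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
euclidean_distances <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  x <- m$dose
  if (nrow(x) < 2) stop("need at least 2 samples")
  n <- nrow(x)
  M <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      co <- !is.na(x[i, ]) & !is.na(x[j, ])
      mo <- sum(co)
      if (mo == 0)
        stop("samples ", rownames(x)[i], " and ", rownames(x)[j],
             " share no observed marker")
      d[i, j] <- d[j, i] <-
        sqrt(sum((x[i, co] - x[j, co])^2) * M / mo)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration.  Negative branch lengths produced by
#' non-additive input are clipped to zero with the deficit moved onto the
#' sister branch, so path lengths between the joined pair are preserved.
#' For additive matrices the output path lengths reproduce the input
#' exactly.
#'
#' @param d symmetric distance matrix (>= 3 taxa) with taxon names.
#' @return list with \code{newick} (text, branch lengths to 6 significant
#'   digits) and \code{tree} (an \pkg{ape} \code{phylo}).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  labels <- rownames(d)
  # each active node holds its newick subtree string; an exact-precision
  # copy backs the phylo object so additive path lengths survive intact
  sub <- labels
  sub_exact <- labels
  fmt <- function(x) formatC(max(x, 0), digits = 6, format = "g")
  fmt_exact <- function(x) formatC(max(x, 0), digits = 17, format = "g")
  while (length(sub) > 3) {
    N <- nrow(d)
    r <- rowSums(d)
    q <- (N - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    new_exact <- sprintf("(%s:%s,%s:%s)", sub_exact[i], fmt_exact(li),
                         sub_exact[j], fmt_exact(lj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    sub <- c(sub[keep], new_sub)
    sub_exact <- c(sub_exact[keep], new_exact)
    rownames(d2) <- colnames(d2) <- seq_along(sub)
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    sub[1], fmt(la), sub[2], fmt(lb), sub[3], fmt(lc))
  exact <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   sub_exact[1], fmt_exact(la), sub_exact[2],
                   fmt_exact(lb), sub_exact[3], fmt_exact(lc))
  list(newick = newick, tree = ape::read.tree(text = exact))
}

#' Write a neighbor-joining tree to a newick file
#'
#' @param nj result of \code{\link{nj_tree}}.
#' @param path output file.
#' @export
write_newick <- function(nj, path) {
  writeLines(nj$newick, path)
  invisible(path)
}
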