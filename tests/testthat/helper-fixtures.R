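# Shared fixture builders.  Everything is generated in code; no data files.

tiny_panel <- function(ids, chromosome = "1", role = "other") {
  marker_panel(ids, chromosome = chromosome,
               position_bp = seq_along(ids) * 1e6, role = role)
}

tiny_dose <- function(mat, chromosome = "1", role = "other") {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("m", seq_len(ncol(mat)))
  dose_matrix(mat, tiny_panel(colnames(mat), chromosome, role))
}

tiny_gametes <- function(mat, chromosome = "1", role = "other",
                         position_bp = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("m", seq_len(ncol(mat)))
  panel <- tiny_panel(colnames(mat), chromosome, role)
  if (!is.null(position_bp)) panel$position_bp <- position_bp
  gamete_matrix(mat, panel)
}

# Independent single-locus oracle: enumerate the three pairing
# configurations and chromatid segregations instead of using the package
# formula.  Homologous config -> AM; each heterologous config -> each M/A
# bivalent transmits M or A with probability 1/2; double-reduction gametes
# (fraction beta of the tetrasomic part) are AA or MM with probability 1/2.
enum_genotype_probs <- function(PP, beta = 0) {
  het_config <- c(AA = 1 / 4, AM = 1 / 2, MM = 1 / 4)
  tetra_normal <- (1 / 3) * c(AA = 0, AM = 1, MM = 0) + (2 / 3) * het_config
  tetra <- (1 - beta) * tetra_normal + beta * c(AA = .5, AM = 0, MM = .5)
  PP * c(AA = 0, AM = 1, MM = 0) + (1 - PP) * tetra
}

# Independent two-locus oracle: explicit enumeration over configurations
# and the 4 x 4 chromatid haplotype combinations of the two bivalents.
enum_two_locus_probs <- function(r) {
  haps <- list(c("M", "M"), c("M", "A"), c("A", "M"), c("A", "A"))
  hp <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  tab <- matrix(0, 3, 3, dimnames = list(c("AA", "AM", "MM"),
                                         c("AA", "AM", "MM")))
  gt <- function(a, b) paste(sort(c(a, b)), collapse = "")
  for (i in 1:4) for (j in 1:4) {
    g1 <- gt(haps[[i]][1], haps[[j]][1])
    g2 <- gt(haps[[i]][2], haps[[j]][2])
    tab[g1, g2] <- tab[g1, g2] + (2 / 3) * hp[i] * hp[j]
  }
  tab["AM", "AM"] <- tab["AM", "AM"] + 1 / 3
  tab
}

marker_counts_acc <- function(g, marker_id) {
  col <- g$genotype[, marker_id]
  genotype_counts(sum(col == "AA", na.rm = TRUE),
                  sum(col == "AM", na.rm = TRUE),
                  sum(col == "MM", na.rm = TRUE))
}

# Brute-force grid ML for tau (step 1e-4), independent of the closed form.
grid_ml_tau <- function(n_AA, n_AM, n_MM) {
  grid <- seq(0, 1, by = 1e-4)
  p_hom <- grid / 6
  ll <- n_AA * log(p_hom) + n_AM * log(1 - 2 * p_hom) + n_MM * log(p_hom)
  ll[grid == 0] <- if (n_AA + n_MM == 0) 0 else -Inf
  grid[which.max(ll)]
}

grid_ml_beta <- function(n_AA, n_AM, n_MM, tau) {
  grid <- seq(0, 1 / 6, by = 1e-4)
  p_hom <- tau * ((1 - grid) / 6 + grid / 2)
  ll <- (n_AA + n_MM) * log(p_hom) + n_AM * log(1 - 2 * p_hom)
  grid[which.max(ll)]
}
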