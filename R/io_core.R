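# Tokens accepted as missing on input; "NA" is the canonical written form.
MISSING_TOKENS <- c("", "NA", "NaN", "-1", ".")

GENOTYPE_LEVELS <- c("AA", "AM", "MM")

#' Construct a marker definition table
#'
#' A marker panel describes the diagnostic SNPs scored in the cross: one row
#' per locus with its chromosome, physical position and meiotic role.  The
#' role (\code{"centromeric"}, \code{"telomeric"} or \code{"other"}) drives
#' which markers feed the tetrasomic-rate and double-reduction estimators;
#' it is user-assigned because centromere coordinates are panel metadata,
#' not something the dose data can reveal.
#'
#' @param marker_id character vector of unique marker ids
#'   (e.g. \code{"S03_46198875"}).
#' @param chromosome chromosome label per marker.
#' @param position_bp integer physical position (1-based bp), non-negative.
#' @param role one of \code{"centromeric"}, \code{"telomeric"}, \code{"other"}.
#' @return a \code{data.frame} of class \code{marker_panel}.
#' @export
marker_panel <- function(marker_id, chromosome, position_bp,
                         role = "other") {
  marker_id <- as.character(marker_id)
  if (anyDuplicated(marker_id))
    stop("duplicate marker id: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  position_bp <- as.numeric(position_bp)
  if (any(!is.finite(position_bp)) || any(position_bp < 0))
    stop("position_bp must be finite and non-negative")
  role <- rep_len(as.character(role), length(marker_id))
  bad <- setdiff(unique(role), c("centromeric", "telomeric", "other"))
  if (length(bad))
    stop("unknown marker role: ", paste(bad, collapse = ", "))
  out <- data.frame(marker_id = marker_id,
                    chromosome = as.character(chromosome),
                    position_bp = position_bp,
                    role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Construct a dose matrix
#'
#' Allele doses of the donor (M) allele observed in triploid hybrids:
#' 0, 1 or 2 copies per hybrid and marker, \code{NA} for missing calls.
#' Rows are samples (hybrids), columns are markers; the marker panel
#' supplies the genome coordinates.
#'
#' @param dose numeric matrix with values in \{0, 1, 2, NA\}; rownames are
#'   sample ids, colnames are marker ids.
#' @param markers a \code{marker_panel} covering every column.
#' @return object of class \code{dose_matrix}: list with elements
#'   \code{dose} and \code{markers}.
#' @export
dose_matrix <- function(dose, markers) {
  dose <- as.matrix(dose)
  storage.mode(dose) <- "double"
  if (is.null(rownames(dose)) || is.null(colnames(dose)))
    stop("dose matrix needs sample rownames and marker colnames")
  if (anyDuplicated(rownames(dose)))
    stop("duplicate sample id: ",
         paste(unique(rownames(dose)[duplicated(rownames(dose))]),
               collapse = ", "))
  if (anyDuplicated(colnames(dose)))
    stop("duplicate marker id: ",
         paste(unique(colnames(dose)[duplicated(colnames(dose))]),
               collapse = ", "))
  obs <- dose[!is.na(dose)]
  if (length(obs) && !all(obs %in% 0:2))
    stop("dose out of range: values must be 0, 1, 2 or missing")
  missing_meta <- setdiff(colnames(dose), markers$marker_id)
  if (length(missing_meta))
    stop("marker absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  markers <- markers[match(colnames(dose), markers$marker_id), , drop = FALSE]
  rownames(markers) <- NULL
  structure(list(dose = dose, markers = markers), class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("dose_matrix: %d samples x %d markers (%.1f%% missing)\n",
              nrow(x$dose), ncol(x$dose),
              100 * mean(is.na(x$dose))))
  invisible(x)
}

#' Construct a gamete matrix
#'
#' Inferred diploid-gamete genotypes, one gamete per triploid hybrid:
#' \code{"AA"}, \code{"AM"}, \code{"MM"} or \code{NA}.
#'
#' @param genotype character matrix over \{AA, AM, MM, NA\}; rownames are
#'   gamete ids, colnames marker ids.
#' @param markers a \code{marker_panel} covering every column.
#' @return object of class \code{gamete_matrix}.
#' @export
gamete_matrix <- function(genotype, markers) {
  genotype <- as.matrix(genotype)
  if (is.null(rownames(genotype)) || is.null(colnames(genotype)))
    stop("genotype matrix needs gamete rownames and marker colnames")
  obs <- genotype[!is.na(genotype)]
  if (length(obs) && !all(obs %in% GENOTYPE_LEVELS))
    stop("genotype values must be AA, AM, MM or missing")
  missing_meta <- setdiff(colnames(genotype), markers$marker_id)
  if (length(missing_meta))
    stop("marker absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  markers <- markers[match(colnames(genotype), markers$marker_id),
                     , drop = FALSE]
  rownames(markers) <- NULL
  structure(list(genotype = genotype, markers = markers),
            class = "gamete_matrix")
}

#' @export
print.gamete_matrix <- function(x, ...) {
  cat(sprintf("gamete_matrix: %d gametes x %d markers (%.1f%% missing)\n",
              nrow(x$genotype), ncol(x$genotype),
              100 * mean(is.na(x$genotype))))
  invisible(x)
}

parse_dose_token <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  is_missing <- x %in% MISSING_TOKENS | is.na(x)
  ok <- x %in% c("0", "1", "2")
  bad <- !is_missing & !ok
  if (any(bad)) {
    v <- suppressWarnings(as.numeric(x[bad]))
    if (all(!is.na(v)))
      stop("dose out of range: ", paste(unique(x[bad]), collapse = ", "))
    stop("unrecognised dose token: ", paste(unique(x[bad]), collapse = ", "))
  }
  out[ok] <- as.numeric(x[ok])
  out
}

#' Read a dose matrix and its marker metadata from disk
#'
#' The dose file is TSV/CSV with a header row of marker ids, one row per
#' sample and the sample id in the first column.  Accepted missing-data
#' tokens are \code{""}, \code{"NA"}, \code{"NaN"}, \code{"-1"} and
#' \code{"."}.  The metadata file has columns \code{marker_id},
#' \code{chromosome}, \code{position_bp}, \code{role}.
#'
#' @param path dose matrix file.
#' @param markers_path marker metadata file.
#' @param sep field separator; \code{NULL} guesses from the file extension
#'   (\code{.csv} is comma, anything else tab).
#' @return a validated \code{dose_matrix}.
#' @export
read_dose_matrix <- function(path, markers_path, sep = NULL) {
  guess <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  s1 <- if (is.null(sep)) guess(path) else sep
  s2 <- if (is.null(sep)) guess(markers_path) else sep
  raw <- utils::read.table(path, sep = s1, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"")
  hdr <- scan(path, what = character(), sep = s1, nlines = 1, quiet = TRUE)
  mk_ids <- hdr[-1]
  if (anyDuplicated(mk_ids))
    stop("duplicate marker id: ",
         paste(unique(mk_ids[duplicated(mk_ids)]), collapse = ", "))
  sample_ids <- raw[[1]]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dose <- vapply(seq_along(mk_ids) + 1L,
                 function(j) parse_dose_token(raw[[j]]),
                 numeric(nrow(raw)))
  dose <- matrix(dose, nrow = nrow(raw),
                 dimnames = list(sample_ids, mk_ids))
  meta <- utils::read.table(markers_path, sep = s2, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "position_bp", "role")
  if (!all(need %in% names(meta)))
    stop("marker metadata must have columns: ", paste(need, collapse = ", "))
  panel <- marker_panel(meta$marker_id, meta$chromosome,
                        meta$position_bp, meta$role)
  dose_matrix(dose, panel)
}

#' Write a dose matrix to TSV
#'
#' Missing cells are written as \code{"NA"}; the marker metadata goes to a
#' companion file so the pair round-trips through
#' \code{\link{read_dose_matrix}}.
#'
#' @param m a \code{dose_matrix}.
#' @param path output TSV for doses.
#' @param markers_path optional output TSV for the marker panel.
#' @export
write_dose_matrix <- function(m, path, markers_path = NULL) {
  df <- data.frame(sample_id = rownames(m$dose), m$dose,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(markers_path))
    utils::write.table(m$markers, markers_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  invisible(path)
}

qc_report <- function(removed_markers = character(),
                      marker_reason = character(),
                      removed_samples = character(),
                      sample_reason = character(),
                      thresholds = list()) {
  structure(list(
    removed_markers = data.frame(id = removed_markers,
                                 reason = marker_reason,
                                 stringsAsFactors = FALSE),
    removed_samples = data.frame(id = removed_samples,
                                 reason = sample_reason,
                                 stringsAsFactors = FALSE),
    thresholds = thresholds), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d markers removed, %d samples removed\n",
              nrow(x$removed_markers), nrow(x$removed_samples)))
  invisible(x)
}

#' Filter a dose matrix on missing data
#'
#' Markers are filtered first (fraction of missing cells over all samples),
#' then samples on the remaining markers, mirroring the two-stage panel
#' cleaning of array-genotyped populations.  Removal uses missing fraction
#' \emph{>= threshold}, i.e. retained entries have strictly less missing
#' data than the threshold.
#'
#' @param m a \code{dose_matrix}.
#' @param max_marker_missing,max_sample_missing missing-fraction thresholds
#'   in \[0, 1\] (default 0.10 each).
#' @return list with elements \code{matrix} (filtered \code{dose_matrix})
#'   and \code{qc} (a \code{qc_report}).
#' @export
filter_matrix <- function(m, max_marker_missing = 0.10,
                          max_sample_missing = 0.10) {
  stopifnot(inherits(m, "dose_matrix"))
  if (max_marker_missing < 0 || max_marker_missing > 1 ||
      max_sample_missing < 0 || max_sample_missing > 1)
    stop("thresholds must lie in [0, 1]")
  miss_m <- colMeans(is.na(m$dose))
  drop_m <- names(miss_m)[miss_m >= max_marker_missing]
  keep <- m$dose[, setdiff(colnames(m$dose), drop_m), drop = FALSE]
  miss_s <- rowMeans(is.na(keep))
  drop_s <- names(miss_s)[miss_s >= max_sample_missing]
  keep <- keep[setdiff(rownames(keep), drop_s), , drop = FALSE]
  if (nrow(keep) == 0 || ncol(keep) == 0)
    stop("filtering removed all samples or markers")
  qc <- qc_report(
    removed_markers = drop_m,
    marker_reason = rep("missing>threshold", length(drop_m)),
    removed_samples = drop_s,
    sample_reason = rep("missing>threshold", length(drop_s)),
    thresholds = list(max_marker_missing = max_marker_missing,
                      max_sample_missing = max_sample_missing))
  list(matrix = dose_matrix(keep, m$markers), qc = qc)
}

#' Remove duplicate markers and samples
#'
#' Among markers (then samples) whose genotype vectors are exactly equal —
#' missing cells must coincide too, no wildcard matching — the first in
#' input order is kept.  This drops the redundant information that inflates
#' linkage-map marker counts without adding segregation signal.
#'
#' @param m a \code{dose_matrix}.
#' @return list with \code{matrix} and \code{qc} as in
#'   \code{\link{filter_matrix}}.
#' @export
dedupe <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  key_m <- apply(m$dose, 2, paste, collapse = "\r")
  dup_m <- colnames(m$dose)[duplicated(key_m)]
  keep <- m$dose[, !duplicated(key_m), drop = FALSE]
  key_s <- apply(keep, 1, paste, collapse = "\r")
  dup_s <- rownames(keep)[duplicated(key_s)]
  keep <- keep[!duplicated(key_s), , drop = FALSE]
  qc <- qc_report(
    removed_markers = dup_m,
    marker_reason = rep("duplicate", length(dup_m)),
    removed_samples = dup_s,
    sample_reason = rep("duplicate", length(dup_s)))
  list(matrix = dose_matrix(keep, m$markers), qc = qc)
}

#' Convert triploid M-allele doses to diploid-gamete genotypes
#'
#' In a diploid (AA) x tetraploid (AAMM) cross the seed parent contributes
#' a single A allele, so the M-dose of a triploid hybrid identifies its
#' diploid gamete directly: 0 doses = AA gamete, 1 = AM, 2 = MM.
#'
#' @param m a \code{dose_matrix}.
#' @return a \code{gamete_matrix} over the same samples and markers.
#' @export
doses_to_gametes <- function(m) {
  stopifnot(inherits(m, "dose_matrix"))
  g <- matrix(GENOTYPE_LEVELS[m$dose + 1], nrow = nrow(m$dose),
              dimnames = dimnames(m$dose))
  gamete_matrix(g, m$markers)
}

#' Convert gamete genotypes back to triploid doses
#'
#' Inverse of \code{\link{doses_to_gametes}}: AA maps to dose 0, AM to 1,
#' MM to 2 (the haploid A gamete of the diploid parent is implicit).
#'
#' @param g a \code{gamete_matrix}.
#' @return a \code{dose_matrix}.
#' @export
gametes_to_doses <- function(g) {
  stopifnot(inherits(g, "gamete_matrix"))
  d <- matrix(match(g$genotype, GENOTYPE_LEVELS) - 1, nrow = nrow(g$genotype),
              dimnames = dimnames(g$genotype))
  dose_matrix(d, g$markers)
}
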