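#' Theta angle of a two-channel fluorescence point
#'
#' The angle (degrees) between the x axis (A-allele channel) and the line
#' from the origin to the point; 0 is pure A signal, 90 pure M signal.
#'
#' @param x_signal,y_signal non-negative channel intensities (vectorised).
#' @return angle(s) in \[0, 90\]; \code{NA} where both signals are zero.
#' @export
theta_angle <- function(x_signal, y_signal) {
  if (any(x_signal < 0 | y_signal < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  out <- atan2(y_signal, x_signal) * 180 / pi
  out[x_signal == 0 & y_signal == 0] <- NA_real_
  out
}

#' Theta anchors for a marker
#'
#' The three reference angles used to translate theta into allele doses:
#' a homozygous-A control, a 1:1 heterozygous control (equivalent A and M
#' doses) and a homozygous-M control, plus a minimum radial intensity
#' below which calls are set to missing.
#'
#' @param theta_AA,theta_het,theta_MM anchor angles in degrees; must be
#'   strictly increasing within \[0, 90\].
#' @param min_intensity radial-norm QC threshold (same units as signals).
#' @return object of class \code{theta_anchors}.
#' @export
theta_anchors <- function(theta_AA, theta_het, theta_MM,
                          min_intensity = 0) {
  if (!(theta_AA >= 0 && theta_AA < theta_het && theta_het < theta_MM &&
        theta_MM <= 90))
    stop("anchor ordering violated: need 0 <= theta_AA < theta_het < theta_MM <= 90")
  structure(list(theta_AA = theta_AA, theta_het = theta_het,
                 theta_MM = theta_MM, min_intensity = min_intensity),
            class = "theta_anchors")
}

#' Calibrate per-marker theta anchors from control samples
#'
#' Each anchor is the mean theta of that control class at that marker.
#' The default QC threshold is 10\% of the median control radial norm.
#'
#' @param controls data.frame with columns \code{sample_id},
#'   \code{marker_id}, \code{x_signal}, \code{y_signal}, \code{genotype}
#'   (in \{AA, AM, MM\}); \code{marker_id = "*"} rows apply to every
#'   marker.
#' @param markers character vector of marker ids to calibrate (defaults to
#'   those present in \code{controls}).
#' @return named list of \code{theta_anchors}, one per marker.
#' @export
calibrate_anchors <- function(controls, markers = NULL) {
  need <- c("sample_id", "marker_id", "x_signal", "y_signal", "genotype")
  if (!all(need %in% names(controls)))
    stop("controls must have columns: ", paste(need, collapse = ", "))
  if (!all(controls$genotype %in% GENOTYPE_LEVELS))
    stop("control genotypes must be AA, AM or MM")
  if (is.null(markers))
    markers <- setdiff(unique(controls$marker_id), "*")
  if (!length(markers)) stop("no markers to calibrate")
  out <- lapply(markers, function(mk) {
    sub <- controls[controls$marker_id %in% c(mk, "*"), ]
    th <- theta_angle(sub$x_signal, sub$y_signal)
    rad <- sqrt(sub$x_signal^2 + sub$y_signal^2)
    mean_of <- function(class) {
      v <- th[sub$genotype == class]
      if (!length(v) || all(is.na(v)))
        stop("marker ", mk, ": no ", class, " control")
      mean(v, na.rm = TRUE)
    }
    theta_anchors(mean_of("AA"), mean_of("AM"), mean_of("MM"),
                  min_intensity = 0.1 * stats::median(rad))
  })
  names(out) <- markers
  out
}

# Expected theta of M-allele fraction f by piecewise-linear interpolation
# through (0, theta_AA), (1/2, theta_het), (1, theta_MM).
expected_theta <- function(f, anchors) {
  stats::approx(x = c(0, 0.5, 1),
                y = c(anchors$theta_AA, anchors$theta_het,
                      anchors$theta_MM),
                xout = f)$y
}

#' Call M-allele doses from fluorescence signals
#'
#' Deterministic replacement of the manual cluster identification: each
#' triploid's theta is compared with the expected theta of the four
#' possible M-allele fractions \eqn{f \in \{0, 1/3, 2/3, 1\}} (piecewise
#' linear through the three anchors) and assigned the nearest.  An
#' \eqn{f = 1} (MMM) call is impossible in an AA x AAMM cross and is set
#' to missing with a flag; so are points below the radial-intensity
#' threshold or with zero signal.
#'
#' @param signals data.frame with columns \code{sample_id},
#'   \code{marker_id}, \code{x_signal}, \code{y_signal}.
#' @param anchors named list of \code{theta_anchors} (one per marker), as
#'   from \code{\link{calibrate_anchors}}, or a single \code{theta_anchors}
#'   applied to every marker.
#' @param markers optional \code{marker_panel} for the resulting matrix;
#'   a minimal panel is fabricated when absent.
#' @param ploidy \code{"triploid"} (default) calls progeny doses at
#'   fractions 0, 1/3, 2/3 (with 1 invalid); \code{"diploid"} calls
#'   diploid samples (e.g. the controls themselves) at fractions 0, 1/2,
#'   1, where dose 2 (MM) is valid.
#' @return list with \code{matrix} (a \code{dose_matrix}) and \code{calls}
#'   (long data.frame with theta, dose and flag per record).
#' @export
call_doses <- function(signals, anchors, markers = NULL,
                       ploidy = c("triploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  need <- c("sample_id", "marker_id", "x_signal", "y_signal")
  if (!all(need %in% names(signals)))
    stop("signals must have columns: ", paste(need, collapse = ", "))
  single <- inherits(anchors, "theta_anchors")
  mk_ids <- unique(signals$marker_id)
  if (!single) {
    missing_anchor <- setdiff(mk_ids, names(anchors))
    if (length(missing_anchor))
      stop("no anchors for marker(s): ",
           paste(missing_anchor, collapse = ", "))
  }
  th <- theta_angle(signals$x_signal, signals$y_signal)
  rad <- sqrt(signals$x_signal^2 + signals$y_signal^2)
  dose <- rep(NA_real_, nrow(signals))
  flag <- rep(NA_character_, nrow(signals))
  fractions <- if (ploidy == "triploid") c(0, 1 / 3, 2 / 3, 1)
               else c(0, 1 / 2, 1)
  for (mk in mk_ids) {
    a <- if (single) anchors else anchors[[mk]]
    sel <- which(signals$marker_id == mk)
    exp_th <- expected_theta(fractions, a)
    for (k in sel) {
      if (is.na(th[k])) { flag[k] <- "zero intensity"; next }
      if (rad[k] < a$min_intensity) { flag[k] <- "low intensity"; next }
      best <- which.min(abs(exp_th - th[k]))
      if (ploidy == "triploid" && best == 4L) {
        flag[k] <- "MMM invalid for cross"
        next
      }
      dose[k] <- best - 1
    }
  }
  calls <- data.frame(sample_id = signals$sample_id,
                      marker_id = signals$marker_id,
                      theta = th, dose = dose, flag = flag,
                      stringsAsFactors = FALSE)
  samples <- unique(signals$sample_id)
  mat <- matrix(NA_real_, length(samples), length(mk_ids),
                dimnames = list(samples, mk_ids))
  mat[cbind(match(signals$sample_id, samples),
            match(signals$marker_id, mk_ids))] <- dose
  if (is.null(markers))
    markers <- marker_panel(mk_ids, chromosome = "0",
                            position_bp = seq_along(mk_ids))
  list(matrix = dose_matrix(mat, markers), calls = calls)
}
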