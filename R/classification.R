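# Processing-mode classification from reference-distribution cutoffs.

#' Derive mode cutoffs from a reference FSR distribution
#'
#' Processing modes are assigned from a participant's full-preview FSR using
#' boundaries anchored to a reference distribution of FSRs obtained without
#' usable preview: the +1 SD and +3 SD points above its mean. The numeric
#' cutoffs are deliberately not hard-coded in the package -- supply either a
#' reference sample here or explicit cutoffs to \code{\link{tswp_config}}.
#'
#' @param reference_fsrs numeric vector of reference FSRs (proportions or
#'   percentages; the cutoffs inherit the scale).
#' @param provenance free-text note on where the reference sample comes from.
#' @return an object of class \code{tswp_cutoffs}: \code{c1}
#'   (mean + 1 SD), \code{c3} (mean + 3 SD), \code{reference_mean},
#'   \code{reference_sd}, \code{provenance}.
#' @export
derive_cutoffs <- function(reference_fsrs, provenance = "reference sample") {
  x <- reference_fsrs[!is.na(reference_fsrs)]
  if (length(x) < 2L) stop("reference sample must have at least 2 values")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance reference: cutoffs would be degenerate")
  mode_cutoffs(m + s, m + 3 * s, reference_mean = m, reference_sd = s,
               provenance = provenance)
}

#' Explicit mode cutoffs
#'
#' @param c1 serial / semi-overlapper boundary (same scale as the FSRs it
#'   will be compared to).
#' @param c3 semi-overlapper / overlapper boundary; must exceed \code{c1}.
#' @param reference_mean,reference_sd optional provenance statistics.
#' @param provenance free-text provenance note.
#' @return an object of class \code{tswp_cutoffs}.
#' @export
mode_cutoffs <- function(c1, c3, reference_mean = NA_real_,
                         reference_sd = NA_real_,
                         provenance = "explicit") {
  stopifnot(is.finite(c1), is.finite(c3))
  if (!(c1 < c3)) stop("cutoffs must satisfy c1 < c3")
  structure(list(c1 = c1, c3 = c3, reference_mean = reference_mean,
                 reference_sd = reference_sd, provenance = provenance),
            class = "tswp_cutoffs")
}

#' @export
print.tswp_cutoffs <- function(x, ...) {
  cat(sprintf("Mode cutoffs: c1 = %.4g, c3 = %.4g (%s)\n",
              x$c1, x$c3, x$provenance))
  invisible(x)
}

#' Classify processing modes from full-preview FSRs
#'
#' Labels each participant by comparing the basis FSR (conventionally the
#' full-preview FSR) with the cutoffs: \code{serial} below \code{c1},
#' \code{semi_overlapper} in \code{[c1, c3)}, \code{overlapper} at or above
#' \code{c3} (boundaries lower-inclusive at \code{c1}, upper-inclusive at
#' \code{c3} for overlappers). A missing FSR (participant without correct
#' switches) yields \code{unclassifiable}.
#'
#' @param basis_fsr numeric vector of FSRs, same scale as the cutoffs.
#' @param cutoffs a \code{tswp_cutoffs} object.
#' @return a factor with levels \code{serial}, \code{semi_overlapper},
#'   \code{overlapper}, \code{unclassifiable}.
#' @export
classify_mode <- function(basis_fsr, cutoffs) {
  stopifnot(inherits(cutoffs, "tswp_cutoffs"))
  lab <- ifelse(is.na(basis_fsr), "unclassifiable",
                ifelse(basis_fsr < cutoffs$c1, "serial",
                       ifelse(basis_fsr < cutoffs$c3, "semi_overlapper",
                              "overlapper")))
  factor(lab, levels = c("serial", "semi_overlapper", "overlapper",
                         "unclassifiable"))
}
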