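#' Tissue class labels
#'
#' The four tissue classes handled throughout the package, in the fixed
#' order used for confusion matrices and all tabular output: basal cell
#' carcinoma (BCC), melanoma, normal skin, squamous cell carcinoma (SCC).
#' This order is also alphabetical (case-insensitive), so plurality ties in
#' forest voting resolve to it naturally.
#'
#' @return Character vector of length 4.
#' @export
tissue_classes <- function() c("BCC", "melanoma", "normal", "SCC")

#' Canonical Mueller-element feature names
#'
#' The 15 normalized Mueller-matrix elements used as classifier features, in
#' fixed row-major order with `m11` excluded (it is the normalizer). Models
#' and CSV files all use this ordering.
#'
#' @return Character vector of length 15: `m12, m13, m14, m21, ..., m44`.
#' @export
mm_feature_names <- function() {
  nm <- as.vector(t(outer(1:4, 1:4, function(i, j) paste0("m", i, j))))
  nm[-1L]
}

#' The six canonical polarization input states
#'
#' Stokes vectors of the six probe beams of the measurement protocol: linear
#' polarization at 0, 45, 90 and 135 degrees, plus right- and left-handed
#' circular. `s3 > 0` denotes right-handed circular light.
#'
#' @return Named list of six numeric 4-vectors `(s0, s1, s2, s3)`.
#' @export
input_states <- function() {
  list(
    LIN0   = c(1,  1,  0,  0),
    LIN45  = c(1,  0,  1,  0),
    LIN90  = c(1, -1,  0,  0),
    LIN135 = c(1,  0, -1,  0),
    RHC    = c(1,  0,  0,  1),
    LHC    = c(1,  0,  0, -1)
  )
}

# state pairs feeding the four reconstruction columns; the first pair also
# provides the sum column (column 1)
.state_pairs <- list(
  lin0_90   = c("LIN0", "LIN90"),
  lin45_135 = c("LIN45", "LIN135"),
  circular  = c("RHC", "LHC")
)

#' Degree of polarization of a Stokes vector
#'
#' @param s Numeric 4-vector `(s0, s1, s2, s3)` with `s0 > 0`.
#' @return `sqrt(s1^2 + s2^2 + s3^2) / s0`. Physical states have DoP <= 1;
#'   noisy measured vectors may exceed it slightly.
#' @export
degree_of_polarization <- function(s) {
  stopifnot(is.numeric(s), length(s) == 4L)
  if (s[1] <= 0) stop("degree of polarization undefined for s0 <= 0")
  sqrt(sum(s[2:4]^2)) / s[1]
}

#' Check a Stokes vector for physicality
#'
#' @param s Numeric 4-vector.
#' @param tol Tolerance on the DoP bound (default `1e-8`).
#' @return `TRUE` if `s0 >= 0` and DoP `<= 1 + tol`, else `FALSE` (never an
#'   error: noisy measurements are flagged, not rejected).
#' @export
is_physical_stokes <- function(s, tol = 1e-8) {
  is.numeric(s) && length(s) == 4L && s[1] >= 0 &&
    (s[1] == 0 || degree_of_polarization(s) <= 1 + tol)
}

#' Propagate a Stokes vector through a Mueller matrix
#'
#' Forward model of the polarimeter: the emerging beam's Stokes vector is the
#' matrix-vector product of the sample's Mueller matrix with the input state.
#'
#' @param m 4x4 numeric Mueller matrix.
#' @param s Numeric 4-vector input Stokes state.
#' @return Numeric 4-vector output Stokes state.
#' @export
#' @examples
#' apply_mueller(diag(4), c(1, 1, 0, 0))
apply_mueller <- function(m, s) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)), is.numeric(m),
            is.numeric(s), length(s) == 4L)
  drop(m %*% s)
}

#' Simulate the six-state measurement of a sample
#'
#' Applies the Mueller matrix to each of the six canonical input states,
#' optionally perturbing the outputs with a Stokes-level noise model (see
#' [stokes_noise_model()]). Noise draws come from the ambient R random number
#' stream, so a `set.seed()` call before this function makes it reproducible.
#'
#' @param m 4x4 Mueller matrix of the sample.
#' @param noise A `stokes_noise_model` or `NULL` for noiseless measurement.
#' @return Named list of six output Stokes 4-vectors (one per input state),
#'   i.e. a measurement set.
#' @export
measure_all_states <- function(m, noise = NULL) {
  out <- lapply(input_states(), function(s) apply_mueller(m, s))
  if (!is.null(noise)) out <- add_stokes_noise(out, noise)
  out
}

#' Reconstruct a Mueller matrix from a six-state measurement set
#'
#' Sum/difference reconstruction of all 16 elements: column 1 is
#' `(S_LIN0 + S_LIN90)/2`, column 2 `(S_LIN0 - S_LIN90)/2`, column 3
#' `(S_LIN45 - S_LIN135)/2`, and column 4 `(S_RHC - S_LHC)/2`, where each
#' `S_state` is the measured output Stokes 4-vector and row k of the matrix
#' takes Stokes component k.
#'
#' @param ms Named list with the six output Stokes vectors, names as in
#'   [input_states()].
#' @param check_physical If `TRUE` (default), warn (never error) when the
#'   reconstructed matrix looks unphysical (`|m_ij| > m11 (1 + tol)`), as can
#'   happen with noisy measurements.
#' @param tol Physicality tolerance.
#' @return 4x4 numeric Mueller matrix.
#' @export
reconstruct_mueller <- function(ms, check_physical = TRUE, tol = 1e-6) {
  required <- names(input_states())
  absent <- setdiff(required, names(ms))
  if (length(absent) > 0L) {
    stop("cannot reconstruct Mueller matrix; missing measurement state(s): ",
         paste(absent, collapse = ", "))
  }
  for (nm in required) {
    s <- ms[[nm]]
    if (!is.numeric(s) || length(s) != 4L) {
      stop("measurement for state ", nm, " is not a Stokes 4-vector")
    }
  }
  m <- cbind(
    (ms$LIN0 + ms$LIN90) / 2,
    (ms$LIN0 - ms$LIN90) / 2,
    (ms$LIN45 - ms$LIN135) / 2,
    (ms$RHC - ms$LHC) / 2
  )
  dimnames(m) <- NULL
  if (check_physical && m[1, 1] > 0 && any(abs(m) > m[1, 1] * (1 + tol))) {
    warning("reconstructed Mueller matrix exceeds the physicality bound ",
            "|m_ij| <= m11; measurement noise is the usual cause")
  }
  m
}

#' Normalize a Mueller matrix and extract the 15 classifier features
#'
#' Divides all 16 elements by `m11` (total intensity transmittance), drops
#' the now-constant `m11`, and returns the remaining 15 elements in the fixed
#' row-major order of [mm_feature_names()]. The result is invariant to any
#' positive overall scaling of the matrix.
#'
#' @param m 4x4 Mueller matrix with `m11 > 0`.
#' @return Named numeric vector of 15 normalized elements.
#' @export
#' @examples
#' normalize_and_featurize(diag(4))
normalize_and_featurize <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)), is.numeric(m))
  m11 <- m[1, 1]
  if (!is.finite(m11) || m11 <= 0) {
    stop("m11 must be positive to normalize (unphysical intensity gain)")
  }
  v <- as.vector(t(m / m11))[-1L]
  names(v) <- mm_feature_names()
  v
}
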