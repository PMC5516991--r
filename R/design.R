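#' Mono-phasic design matrix
#'
#' Builds the M x 2 design for a single regression line: an intercept column
#' of ones and the visit-time column.
#'
#' @param times numeric vector of M >= 2 finite visit days, strictly
#'   increasing.
#' @return An M x 2 matrix.
#' @examples
#' build_mono_design(c(0, 21, 42))
#' @export
build_mono_design <- function(times) {
  if (length(times) < 2L)
    stop("invalid series: at least 2 visit times are required")
  if (any(!is.finite(times))) stop("invalid series: times must be finite")
  if (any(diff(times) <= 0))
    stop("invalid series: times must be strictly increasing")
  cbind(1, times, deparse.level = 0)
}

#' Bi-phasic block design matrix for a given change point
#'
#' Builds the M x 4 design in which the first `k` observations belong to the
#' first regression line (columns 1-2) and the remaining M - k to the second
#' (columns 3-4). The change point may not fall before the first or after the
#' last observation (k = 0 and k = M are excluded): there a bi-phasic subject
#' is indistinguishable from a mono-phasic one.
#'
#' @param times numeric vector of M visit days.
#' @param k number of observations in the first phase, `1 <= k <= M - 1`.
#' @return An M x 4 matrix; each row has exactly one nonzero (1, t) block.
#' @examples
#' build_biphasic_design(c(0, 21, 42), k = 1)
#' @export
build_biphasic_design <- function(times, k) {
  Qs <- build_mono_design(times)
  M <- nrow(Qs)
  if (length(k) != 1L || k != as.integer(k) || k < 1L || k > M - 1L)
    stop("change-point index k out of range: need 1 <= k <= M - 1 (k = ",
         k, ", M = ", M, ")")
  Q <- matrix(0, M, 4)
  first <- seq_len(k)
  Q[first, 1:2] <- Qs[first, , drop = FALSE]
  Q[-first, 3:4] <- Qs[-first, , drop = FALSE]
  Q
}

#' Enumerate all admissible bi-phasic designs for a series
#'
#' A subject with M observations admits M - 1 candidate change points; the
#' j-th element of the returned list is the design with k = j first-phase
#' observations.
#'
#' @param series a [patient_series].
#' @return List of M - 1 design matrices, ordered k = 1..M-1.
#' @export
enumerate_biphasic_designs <- function(series) {
  M <- length(series$times)
  lapply(seq_len(M - 1L), function(k) build_biphasic_design(series$times, k))
}
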