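check_psd <- function(Sigma, d, name) {
  if (!is.matrix(Sigma) || !all(dim(Sigma) == d))
    stop(name, " must be a ", d, "x", d, " matrix")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * (1 + max(abs(Sigma))))
    stop(name, " must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * (1 + max(abs(ev))))
    stop(name, " must be positive semi-definite")
  0.5 * (Sigma + t(Sigma))
}

#' Mono-phasic population parameters
#'
#' @param S numeric length-2 vector: population intercept and slope per day.
#' @param Sigma_S 2 x 2 symmetric positive-semidefinite between-patient
#'   covariance of individual (intercept, slope).
#' @return An object of class `mono_params`.
#' @export
mono_params <- function(S, Sigma_S) {
  stopifnot(length(S) == 2, all(is.finite(S)))
  structure(list(S = as.numeric(S),
                 Sigma_S = check_psd(Sigma_S, 2, "Sigma_S")),
            class = "mono_params")
}

#' Bi-phasic population parameters
#'
#' @param B numeric length-4 vector: first-phase intercept and slope, then
#'   second-phase intercept and slope.
#' @param Sigma_B 4 x 4 symmetric positive-semidefinite covariance.
#' @return An object of class `bi_params`.
#' @export
bi_params <- function(B, Sigma_B) {
  stopifnot(length(B) == 4, all(is.finite(B)))
  structure(list(B = as.numeric(B),
                 Sigma_B = check_psd(Sigma_B, 4, "Sigma_B")),
            class = "bi_params")
}

#' Full population-parameter set
#'
#' Bundles the mono- and bi-phasic population distributions, the residual
#' variance, the mixing weight (probability that a subject is bi-phasic) and,
#' optionally, per-patient change-point design probabilities.
#'
#' @param mono a [mono_params].
#' @param bi a [bi_params].
#' @param sigma2 residual variance, > 0.
#' @param lam mixing weight in `[0, 1]`.
#' @param pi_weights optional list of per-patient probability vectors over
#'   the M_i - 1 candidate change points (each nonnegative, summing to 1).
#' @return An object of class `population_parameters`.
#' @export
population_parameters <- function(mono, bi, sigma2, lam, pi_weights = NULL) {
  stopifnot(inherits(mono, "mono_params"), inherits(bi, "bi_params"))
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  if (!is.finite(lam) || lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  if (!is.null(pi_weights)) {
    for (p in pi_weights) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("each pi_weights element must be nonnegative and sum to 1")
    }
  }
  structure(list(mono = mono, bi = bi, sigma2 = sigma2, lam = lam,
                 pi_weights = pi_weights),
            class = "population_parameters")
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("<population_parameters>\n")
  cat(sprintf("  S  = (%.4g, %.4g)   sigma = %.4g   lambda = %.4g\n",
              x$mono$S[1], x$mono$S[2], sqrt(x$sigma2), x$lam))
  cat(sprintf("  B  = (%.4g, %.4g, %.4g, %.4g)\n",
              x$bi$B[1], x$bi$B[2], x$bi$B[3], x$bi$B[4]))
  invisible(x)
}

# Fixed flattening of the 21 scalar parameters: the 8 Table-style scalars
# (S0, S1, B0, B1, B0p, B1p, sigma, lambda), then the upper triangle of
# Sigma_S (row-wise), then the upper triangle of Sigma_B.
param_names_21 <- function() {
  c("S0", "S1", "B0", "B1", "B0p", "B1p", "sigma", "lambda",
    "SigS_11", "SigS_12", "SigS_22",
    "SigB_11", "SigB_12", "SigB_13", "SigB_14", "SigB_22", "SigB_23",
    "SigB_24", "SigB_33", "SigB_34", "SigB_44")
}

#' Flatten population parameters to the canonical 21-vector
#'
#' Order: `S0, S1, B0, B1, B0p, B1p, sigma, lambda`, then the row-wise upper
#' triangle of `Sigma_S` (3 entries) and of `Sigma_B` (10 entries). The
#' residual scale is reported as the standard deviation `sigma`, matching the
#' scale on which results are usually tabulated.
#'
#' @param params a [population_parameters].
#' @return Named numeric vector of length 21.
#' @export
flatten_params <- function(params) {
  SS <- params$mono$Sigma_S
  SB <- params$bi$Sigma_B
  ut <- function(m) {
    d <- nrow(m)
    out <- c()
    for (a in seq_len(d)) for (b in a:d) out <- c(out, m[a, b])
    out
  }
  setNames(c(params$mono$S, params$bi$B, sqrt(params$sigma2), params$lam,
             ut(SS), ut(SB)),
           param_names_21())
}
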