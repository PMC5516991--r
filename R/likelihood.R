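#' Marginal Gaussian log-density of a series under a candidate design
#'
#' Evaluates `log N(Y | Q m, Q Sigma Q' + sigma2 I)`, the marginal density of
#' the observations after integrating out the individual regression
#' parameters. The computation stays in the low-dimensional parameter space
#' (via the matrix determinant lemma and push-through identity), so singular
#' `Sigma` -- including `Sigma = 0`, where the marginal collapses to an
#' i.i.d. Gaussian around the population line -- is handled exactly.
#'
#' @param Y numeric vector of M observations.
#' @param Q M x d design matrix.
#' @param mean_params length-d population mean vector.
#' @param Sigma d x d positive-semidefinite covariance.
#' @param sigma2 residual variance, > 0.
#' @return Scalar log-density.
#' @export
log_marginal_gaussian <- function(Y, Q, mean_params, Sigma, sigma2) {
  Q <- as.matrix(Q)
  stopifnot(length(Y) == nrow(Q), length(mean_params) == ncol(Q),
            all(dim(as.matrix(Sigma)) == ncol(Q)), sigma2 > 0)
  marg_eb_cpp(as.numeric(Y), Q, as.numeric(mean_params), as.matrix(Sigma),
              sigma2)$loglik
}

#' Empirical-Bayes posterior moments of individual regression parameters
#'
#' Returns the posterior mean and covariance of a subject's regression
#' coefficients given population parameters,
#' `mean = m + (Sigma^-1 + Q'Q/sigma2)^-1 Q'(Y - Q m)/sigma2` and
#' `cov = (Sigma^-1 + Q'Q/sigma2)^-1`, evaluated in the algebraically
#' equivalent shrinkage form `cov = (I + Sigma Q'Q/sigma2)^-1 Sigma` that
#' requires no explicit `Sigma^-1` (so `Sigma = 0`, i.e. infinite shrinkage
#' to the population mean, works exactly).
#'
#' @param series a [patient_series] (its `values` are used as Y).
#' @param Q design matrix for the series.
#' @param mean_params population mean vector (length `ncol(Q)`).
#' @param Sigma population covariance.
#' @param sigma2 residual variance.
#' @return List with elements `mean` and `cov`.
#' @export
empirical_bayes <- function(series, Q, mean_params, Sigma, sigma2) {
  Q <- as.matrix(Q)
  Y <- series$values
  if (length(Y) != nrow(Q))
    stop("design matrix does not conform to patient ", series$patient_id)
  out <- marg_eb_cpp(Y, Q, as.numeric(mean_params), as.matrix(Sigma), sigma2)
  list(mean = drop(out$mean), cov = out$cov)
}
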