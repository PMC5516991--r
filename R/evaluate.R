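#' Classify patients as mono- or bi-phasic
#'
#' Hard classification at a cutoff on the expected bi-phasic probability:
#' a patient is called bi-phasic iff `z > cutoff` (strictly; a tie at the
#' cutoff is resolved to mono-phasic, consistent with the conservative
#' mono-ward lean of the BIC penalty).
#'
#' @param latent an `em_result`, a latent list with `z`, or a numeric vector
#'   of bi-phasic probabilities.
#' @param cutoff classification threshold, default 0.5.
#' @return Character vector of `"mono"` / `"bi"`.
#' @export
classify <- function(latent, cutoff = 0.5) {
  z <- if (inherits(latent, "em_result")) latent$latent$z
       else if (is.list(latent)) latent$z
       else latent
  ifelse(z > cutoff, "bi", "mono")
}

as_class <- function(x) {
  if (is.numeric(x)) ifelse(x > 0, "bi", "mono") else as.character(x)
}

#' Confusion counts and classification rates
#'
#' Sensitivity is the fraction of true mono-phasic patients classified
#' mono-phasic; specificity is the fraction of true bi-phasic patients
#' classified bi-phasic (the column convention of the accuracy tables this
#' mirrors; raw counts are returned so the opposite convention can be
#' recomputed). A rate whose truth class is absent is reported as `NA`,
#' not 0.
#'
#' @param truth true classes: `"mono"`/`"bi"`, or 0/1 indicators.
#' @param predicted predicted classes in the same encodings.
#' @return Object of class `classification_report` with `counts` (2 x 2
#'   matrix, predicted x truth), `sensitivity`, `specificity`, `n`.
#' @examples
#' confusion_metrics(c(0, 0, 1, 1), c("mono", "mono", "bi", "mono"))
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- as_class(truth)
  predicted <- as_class(predicted)
  stopifnot(length(truth) == length(predicted))
  lv <- c("mono", "bi")
  counts <- table(factor(predicted, lv), factor(truth, lv))
  dimnames(counts) <- list(predicted = lv, truth = lv)
  sens <- if (sum(counts[, "mono"]) == 0) NA_real_ else
    counts["mono", "mono"] / sum(counts[, "mono"])
  spec <- if (sum(counts[, "bi"]) == 0) NA_real_ else
    counts["bi", "bi"] / sum(counts[, "bi"])
  structure(list(counts = unclass(counts), sensitivity = sens,
                 specificity = spec, n = length(truth)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  print(x$counts)
  cat(sprintf("  sensitivity (mono|mono) %.2f%%, specificity (bi|bi) %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

# Deterministic replicate-seed derivation from a root seed (kept < 2^31).
replicate_seed <- function(seed, r) {
  (as.integer(seed) %% 100000L) * 10000L + r
}

#' Parameter-recovery and classification experiment
#'
#' For each replicate: simulate a cohort from the scenario, fit by EM,
#' classify patients at the 0.5 cutoff against the generating class, and
#' record the 8 scalar parameter estimates `(S0, S1, B0, B1, B0p, B1p,
#' sigma, lambda)`. Replicate seeds derive deterministically from the root
#' seed. Replicates whose EM fit errors are excluded and counted.
#'
#' @param which_scenario 1, 2 or 3.
#' @param n_replicates number of simulated cohorts, `>= 1`.
#' @param seed root seed.
#' @param em_opts an [em_options] used for every fit.
#' @param cutoff classification cutoff.
#' @param ... scenario overrides forwarded to [make_scenario].
#' @return Object of class `recovery_summary`: `estimates` (replicates x 8),
#'   `mean`, `sd`, `truth`, `sensitivity`/`specificity` (per-replicate
#'   vectors and their means), `n_failed`.
#' @export
run_recovery_experiment <- function(which_scenario, n_replicates, seed = 1L,
                                    em_opts = em_options(tol = 1e-5,
                                                         max_iter = 200L),
                                    cutoff = 0.5, ...) {
  stopifnot(n_replicates >= 1)
  est <- matrix(NA_real_, n_replicates, 8,
                dimnames = list(NULL, param_names_21()[1:8]))
  sens <- spec <- rep(NA_real_, n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- make_scenario(which_scenario, seed = replicate_seed(seed, r), ...)
    sim <- simulate_cohort(cfg)
    fit <- tryCatch(fit_em(sim$cohort, em_opts), error = function(e) e)
    if (inherits(fit, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    est[r, ] <- flatten_params(fit$params)[1:8]
    cm <- confusion_metrics(sim$truth$eta, classify(fit, cutoff))
    sens[r] <- cm$sensitivity
    spec[r] <- cm$specificity
  }
  cfg <- make_scenario(which_scenario, ...)
  truth <- c(cfg$S, cfg$B, cfg$sigma, cfg$lam)
  names(truth) <- param_names_21()[1:8]
  structure(list(scenario = which_scenario, estimates = est,
                 mean = colMeans(est, na.rm = TRUE),
                 sd = apply(est, 2, sd, na.rm = TRUE),
                 truth = truth,
                 sensitivity = sens, specificity = spec,
                 mean_sensitivity = mean(sens, na.rm = TRUE),
                 mean_specificity = mean(spec, na.rm = TRUE),
                 n_replicates = n_replicates, n_failed = n_failed),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> scenario %d, %d replicates (%d failed)\n",
              x$scenario, x$n_replicates, x$n_failed))
  print(round(rbind(truth = x$truth, mean = x$mean, sd = x$sd), 4))
  cat(sprintf("  mean sensitivity %.2f%%, mean specificity %.2f%%\n",
              100 * x$mean_sensitivity, 100 * x$mean_specificity))
  invisible(x)
}

#' Sensitivity-grid experiment
#'
#' Runs a reduced [run_recovery_experiment] on every configuration of a
#' sensitivity grid (see [make_sensitivity_grid]) and returns a long-format
#' table of classification rates — one row per grid point, with the varied
#' quantities (`b1`, `b1p`, or observation/patient counts) alongside the
#' averaged sensitivity and specificity. The slope grid maps how specificity
#' decays as the bi-phasic slopes approach the mono-phasic slope.
#'
#' @param grid list of scenario configurations from [make_sensitivity_grid].
#' @param n_replicates simulated cohorts per grid point.
#' @param seed root seed.
#' @param em_opts an [em_options] used for every fit.
#' @return Data frame with the grid descriptors and
#'   `sensitivity`/`specificity` (fractions).
#' @export
run_sensitivity_experiment <- function(grid, n_replicates = 10L, seed = 1L,
                                       em_opts = em_options(tol = 1e-5,
                                                            max_iter = 200L)) {
  desc <- attr(grid, "grid")
  rows <- lapply(seq_along(grid), function(g) {
    cfg <- grid[[g]]
    sens <- spec <- rep(NA_real_, n_replicates)
    for (r in seq_len(n_replicates)) {
      cfg$seed <- replicate_seed(seed + 97L * g, r)
      sim <- simulate_cohort(cfg)
      fit <- tryCatch(fit_em(sim$cohort, em_opts), error = function(e) NULL)
      if (is.null(fit)) next
      cm <- confusion_metrics(sim$truth$eta, classify(fit))
      sens[r] <- cm$sensitivity
      spec[r] <- cm$specificity
    }
    data.frame(sensitivity = mean(sens, na.rm = TRUE),
               specificity = mean(spec, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  if (!is.null(desc)) out <- cbind(desc, out)
  out
}

#' Coverage-probability experiment
#'
#' For each replicate: simulate, fit by EM, run the Gibbs sampler from the
#' EM mode, build the `level` simultaneous rectangular credible region over
#' the 8 scalar parameters (scenario 1) or all 21 parameters (scenarios 2
#' and 3), and check whether it contains the generating values. For
#' scenario 3 the marginal equal-tailed `level` interval for the covariance
#' between the bi-phasic first and second slopes is additionally checked for
#' excluding zero (correlation detection).
#'
#' @param which_scenario 1, 2 or 3.
#' @param n_replicates number of replicates, `>= 1`.
#' @param gibbs_opts a [gibbs_options] (its `init` is ignored; each
#'   replicate starts from its own EM fit, and its `seed` is re-derived per
#'   replicate from `seed`).
#' @param seed root seed.
#' @param level nominal joint level.
#' @param ... scenario overrides forwarded to [make_scenario].
#' @return Object of class `coverage_summary`: `joint_coverage`,
#'   `per_parameter` coverage fractions, `covered` per replicate,
#'   `detection` fraction (scenario 3, else `NA`), `n_failed`.
#' @export
run_coverage_experiment <- function(which_scenario, n_replicates,
                                    gibbs_opts = gibbs_options(
                                      n_iter = 5000L, burn_in = 1000L),
                                    seed = 1L, level = 0.95, ...) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  cfg0 <- make_scenario(which_scenario, ...)
  truth21 <- flatten_params(population_parameters(
    mono_params(cfg0$S, cfg0$Sigma_S), bi_params(cfg0$B, cfg0$Sigma_B),
    cfg0$sigma^2, cfg0$lam))
  idx <- if (which_scenario == 1) 1:8 else 1:21
  covered <- rep(NA, n_replicates)
  det <- rep(NA, n_replicates)
  par_cov <- matrix(NA, n_replicates, length(idx),
                    dimnames = list(NULL, param_names_21()[idx]))
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    rs <- replicate_seed(seed, r)
    cfg <- make_scenario(which_scenario, seed = rs, ...)
    sim <- simulate_cohort(cfg)
    res <- tryCatch({
      fit <- fit_em(sim$cohort, em_options(tol = 1e-5, max_iter = 200L))
      go <- gibbs_opts
      go$init <- fit$params
      go$seed <- rs
      run_chain(sim$cohort, go)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    reg <- simultaneous_credible_region(res, level = level, params = idx)
    inside <- truth21[idx] >= reg$lower & truth21[idx] <= reg$upper
    par_cov[r, ] <- inside
    covered[r] <- all(inside)
    if (which_scenario == 3) {
      x <- res$draws[, "SigB_24"]
      ci <- quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2),
                     names = FALSE)
      det[r] <- ci[1] > 0 || ci[2] < 0
    }
  }
  structure(list(scenario = which_scenario, level = level,
                 joint_coverage = mean(covered, na.rm = TRUE),
                 per_parameter = colMeans(par_cov, na.rm = TRUE),
                 covered = covered,
                 detection = if (which_scenario == 3)
                   mean(det, na.rm = TRUE) else NA_real_,
                 n_replicates = n_replicates, n_failed = n_failed),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(
    "<coverage_summary> scenario %d: joint %.1f%% at level %.0f%% (%d reps, %d failed)\n",
    x$scenario, 100 * x$joint_coverage, 100 * x$level, x$n_replicates,
    x$n_failed))
  if (!is.na(x$detection))
    cat(sprintf("  correlation detection: %.1f%%\n", 100 * x$detection))
  invisible(x)
}
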