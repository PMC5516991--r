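#' Scenario configuration for a simulated cohort
#'
#' The three standard scenarios share the population parameters
#' `S = (90, -0.25)`, `B = (91, -0.35, 55, -0.15)`, `sigma = 5`,
#' `lambda = 0.6`, `N = 100` and a visit schedule of one baseline visit at
#' day 0 plus 17 follow-ups every 21 days (last at day 357), each follow-up
#' jittered uniformly within +/- 5 days. They differ in the between-patient
#' covariances: scenario 1 has none (`Sigma_S = Sigma_B = 0`); scenario 2
#' has independent variation with variance 4 in all intercepts and 0.0009 in
#' all slopes; scenario 3 adds correlation 0.5 between the bi-phasic first
#' and second slopes (covariance 0.5 * 0.03 * 0.03 = 0.00045).
#'
#' @param which scenario number, 1, 2 or 3.
#' @param ... overrides of any config field: `S`, `Sigma_S`, `B`, `Sigma_B`,
#'   `sigma`, `lam`, `n_patients`, `baseline_day`, `visit_spacing`,
#'   `n_followup`, `jitter`, `seed`, or explicit `schedule` (full vector of
#'   scheduled days, overriding the spacing fields).
#' @return Object of class `scenario_config`.
#' @examples
#' make_scenario(1)
#' make_scenario(2, n_patients = 40)
#' @export
make_scenario <- function(which, ...) {
  stopifnot(which %in% 1:3)
  cfg <- list(
    S = c(90, -0.25),
    Sigma_S = matrix(0, 2, 2),
    B = c(91, -0.35, 55, -0.15),
    Sigma_B = matrix(0, 4, 4),
    sigma = 5,
    lam = 0.6,
    n_patients = 100L,
    baseline_day = 0,
    visit_spacing = 21,
    n_followup = 17L,
    jitter = 5,
    seed = 1L,
    schedule = NULL,
    scenario = which
  )
  if (which >= 2) {
    cfg$Sigma_S <- diag(c(4, 0.0009))
    cfg$Sigma_B <- diag(c(4, 0.0009, 4, 0.0009))
  }
  if (which == 3) {
    cfg$Sigma_B[2, 4] <- cfg$Sigma_B[4, 2] <- 0.5 * 0.03 * 0.03
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$Sigma_S <- check_psd(cfg$Sigma_S, 2, "Sigma_S")
  cfg$Sigma_B <- check_psd(cfg$Sigma_B, 4, "Sigma_B")
  stopifnot(cfg$lam >= 0, cfg$lam <= 1, cfg$sigma >= 0, cfg$n_patients >= 1)
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> scenario %s: N = %d, lambda = %g, sigma = %g, %d visits\n",
    x$scenario, x$n_patients, x$lam, x$sigma,
    length(scheduled_visits(x))))
  invisible(x)
}

scheduled_visits <- function(config) {
  if (!is.null(config$schedule)) return(sort(config$schedule))
  c(config$baseline_day,
    config$baseline_day + config$visit_spacing * seq_len(config$n_followup))
}

#' Phasic transition time of a bi-phasic parameter vector
#'
#' The time at which the two regression lines intersect,
#' `t* = (b0 - b0') / (b1' - b1)`.
#'
#' @param b numeric length-4 vector `(b0, b1, b0', b1')`.
#' @return Scalar transition time (days).
#' @examples
#' transition_time(c(91, -0.35, 55, -0.15))  # 180
#' @export
transition_time <- function(b) {
  stopifnot(length(b) == 4)
  if (b[4] == b[2])
    stop("undefined transition: the two phases have parallel slopes")
  (b[1] - b[3]) / (b[4] - b[2])
}

#' Simulate a cohort from a scenario configuration
#'
#' Per patient: the phasicity indicator is Bernoulli(`lam`); individual
#' regression parameters are drawn from the multivariate normal population
#' distribution of the assigned class; follow-up visit times are the
#' scheduled days plus independent uniform jitter (the baseline visit is not
#' jittered, anchoring the intercepts at t = 0); observations are the
#' individual line (or, for bi-phasic patients, the first line up to and
#' including the transition time and the second line after it) plus
#' N(0, sigma^2) noise. Bi-phasic patients whose transition time falls
#' outside the observation window are kept and labelled by their generating
#' class: the transition time is a ratio of jointly Gaussian quantities and
#' heavy-tailed, and such observationally mono-phasic "bi-phasic" patients
#' are a real feature of this generative process.
#'
#' @param config a scenario configuration from [make_scenario].
#' @return Object of class `simulated_cohort`: a list with `cohort` and
#'   `truth` (data frame with per-patient `eta`, `k`, coefficients and
#'   `t_star`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  sched <- scheduled_visits(config)
  Mv <- length(sched)
  N <- config$n_patients
  patients <- vector("list", N)
  truth <- data.frame(patient_id = sprintf("p%03d", seq_len(N)),
                      eta = integer(N), k = NA_integer_,
                      t_star = NA_real_,
                      c0 = NA_real_, c1 = NA_real_, c2 = NA_real_,
                      c3 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(N)) {
    eta <- rbinom(1, 1, config$lam)
    repeat {
      tt <- sched
      if (Mv > 1 && config$jitter > 0)
        tt[-1] <- tt[-1] + runif(Mv - 1, -config$jitter, config$jitter)
      if (all(diff(tt) > 0)) break
    }
    if (eta == 0) {
      s_i <- drop(MASS::mvrnorm(1, config$S, config$Sigma_S))
      mu <- s_i[1] + s_i[2] * tt
      truth$c0[i] <- s_i[1]
      truth$c1[i] <- s_i[2]
    } else {
      b_i <- drop(MASS::mvrnorm(1, config$B, config$Sigma_B))
      ts <- if (b_i[4] == b_i[2]) Inf else transition_time(b_i)
      first <- tt <= ts
      mu <- ifelse(first, b_i[1] + b_i[2] * tt, b_i[3] + b_i[4] * tt)
      truth$t_star[i] <- ts
      truth$k[i] <- sum(first)
      truth[i, c("c0", "c1", "c2", "c3")] <- as.list(b_i)
    }
    truth$eta[i] <- eta
    y <- mu + rnorm(Mv, 0, config$sigma)
    patients[[i]] <- patient_series(truth$patient_id[i], tt, y)
  }
  structure(list(cohort = cohort(patients), truth = truth, config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d patients (%d bi-phasic by truth)\n",
              nrow(x$truth), sum(x$truth$eta)))
  invisible(x)
}

#' Sensitivity-analysis grids of scenario configurations
#'
#' `kind = "slopes"` varies the bi-phasic first slope over `[-0.45, -0.26]`
#' and the second slope over `[-0.24, -0.05]` (both bracketing the
#' mono-phasic slope -0.25), holding `S`, `B0` and `sigma`, `lambda` fixed
#' and setting the second intercept so that the population-level transition
#' stays at 178 days (mid-trial): `B0' = B0 + 178 * (B1 - B1')`.
#' `kind = "design_size"` varies either the number of observations per
#' patient (evenly spaced over day 0-357) or the number of patients with 18
#' observations fixed.
#'
#' @param kind `"slopes"` or `"design_size"`.
#' @param base a scenario configuration from [make_scenario] supplying all non-varied fields.
#' @param b1_grid,b1p_grid slope grids for `kind = "slopes"`.
#' @param m_grid,n_grid observation-count and patient-count grids for
#'   `kind = "design_size"`.
#' @return List of scenario configurations with attributes describing the grid.
#' @export
make_sensitivity_grid <- function(kind = c("slopes", "design_size"), base,
                                  b1_grid = seq(-0.45, -0.26, by = 0.01),
                                  b1p_grid = seq(-0.24, -0.05, by = 0.01),
                                  m_grid = c(6L, 9L, 12L, 18L),
                                  n_grid = c(50L, 100L, 200L)) {
  kind <- match.arg(kind)
  stopifnot(inherits(base, "scenario_config"))
  out <- list()
  if (kind == "slopes") {
    for (b1 in b1_grid) for (b1p in b1p_grid) {
      B <- base$B
      B[2] <- b1
      B[4] <- b1p
      B[3] <- B[1] + 178 * (b1 - b1p)
      cfg <- base
      cfg$B <- B
      out[[length(out) + 1L]] <- cfg
    }
    attr(out, "grid") <- expand.grid(b1p = b1p_grid, b1 = b1_grid)[, 2:1]
  } else {
    for (m in m_grid) {
      cfg <- base
      cfg$schedule <- seq(0, 357, length.out = m)
      out[[length(out) + 1L]] <- cfg
    }
    for (n in n_grid) {
      cfg <- base
      cfg$n_patients <- as.integer(n)
      out[[length(out) + 1L]] <- cfg
    }
    attr(out, "grid") <- data.frame(
      m = c(m_grid, rep(NA, length(n_grid))),
      n = c(rep(NA, length(m_grid)), n_grid))
  }
  out
}

#' Write a simulated cohort (long table + truth sidecar + config echo)
#'
#' @param sim a [simulate_cohort] result.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "cohort.csv")
  p2 <- file.path(dir, "truth.csv")
  p3 <- file.path(dir, "config.json")
  write_cohort(sim$cohort, p1)
  utils::write.csv(sim$truth, p2, row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$Sigma_S <- as.vector(cfg$Sigma_S)
  cfg$Sigma_B <- as.vector(cfg$Sigma_B)
  jsonlite::write_json(cfg, p3, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(p1, p2, p3))
}
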