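# Synthetic data generators emulating the two empirical record shapes with
# known ground truth, so the estimators and empirical procedures are
# testable without field data.

#' Scenario specification for the synthetic generators
#'
#' Describes a simulated study: the rate distribution, optional between-
#' visit correlation, the layout (observers x quadrats for time-to-detection
#' experiments, sites x visits for repeat-count surveys), session lengths
#' and abundances.
#'
#' @param rate A [rate_prior()] giving the rate distribution at abundance 1.
#' @param corr A [correlation_spec()] for within-site correlation across
#'   visits (repeat-count shape only).
#' @param n_observers,n_quadrats Layout of the quadrat search experiment.
#' @param n_sites Number of sites for repeat-count surveys.
#' @param visits Visits per site: a single number or one per site.
#' @param session_length Search-session length (time units) after which an
#'   undetected quadrat search is censored.
#' @param search_time Search time per repeat-survey visit.
#' @param abundance Abundance per site (recycled); rate scales as
#'   `abundance^beta`.
#' @param beta Log-linear abundance exponent.
#' @param seed Integer seed; generation is reproducible.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(rate, corr = correlation_spec(),
                          n_observers = 14L, n_quadrats = 9L,
                          n_sites = 29L, visits = 3L,
                          session_length = 15, search_time = 1,
                          abundance = 1, beta = 1, seed = 1L) {
  stopifnot(inherits(rate, "rate_prior"), inherits(corr, "correlation_spec"))
  if (n_observers < 1L || n_quadrats < 1L || n_sites < 1L || any(visits < 1L))
    stop("layout dimensions must be positive", call. = FALSE)
  if (session_length <= 0 || search_time <= 0)
    stop("session_length and search_time must be > 0", call. = FALSE)
  if (any(abundance <= 0)) stop("abundance must be > 0", call. = FALSE)
  structure(list(rate = rate, corr = corr, n_observers = as.integer(n_observers),
                 n_quadrats = as.integer(n_quadrats), n_sites = as.integer(n_sites),
                 visits = as.integer(visits), session_length = session_length,
                 search_time = search_time, abundance = abundance, beta = beta,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a quadrat search experiment (time-to-first-detection records)
#'
#' Per observer-by-quadrat combination, draws a rate from the lognormal
#' with the scenario's `mu` and `sigma`, then an exponential time to first
#' detection, censored at the session length. A zero rate (possible when
#' `mu = 0` is emulated via `sigma = 0`) yields an all-censored record.
#'
#' @param spec A [scenario_spec()].
#' @return A data frame with columns `observer`, `quadrat`,
#'   `time_to_detection`, `session_length`, `censored`, suitable for
#'   [fit_time_to_detection()] and round-trippable through
#'   [write_detection_records()] / [read_detection_records()].
#' @export
gen_quadrat_experiment <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  rate <- spec$rate
  k <- spec$n_observers * spec$n_quadrats
  lam <- if (rate$sigma == 0) rep(rate$mu, k) else {
    sl2 <- log(1 + rate$theta^2)
    stats::rlnorm(k, log(rate$mu) - sl2 / 2, sqrt(sl2))
  }
  raw <- ifelse(lam > 0, stats::rexp(k, rate = pmax(lam, 1e-300)), Inf)
  cens <- raw > spec$session_length
  data.frame(
    observer = rep(seq_len(spec$n_observers), each = spec$n_quadrats),
    quadrat = rep(seq_len(spec$n_quadrats), times = spec$n_observers),
    time_to_detection = ifelse(cens, spec$session_length, raw),
    session_length = spec$session_length,
    censored = cens
  )
}

#' Generate repeat-survey count records
#'
#' Per site, rates across visits are jointly lognormal with log-scale
#' correlation from the scenario's [correlation_spec()] and mean scaled by
#' `abundance^beta`; detections per visit are Poisson with exposure
#' `search_time`.
#'
#' @param spec A [scenario_spec()].
#' @return A data frame with columns `site`, `visit`, `detections`,
#'   `search_time`, `abundance`, suitable for [fit_rate_counts()].
#' @export
gen_repeat_surveys <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  visits <- rep_len(spec$visits, spec$n_sites)
  abund <- rep_len(spec$abundance, spec$n_sites)
  rows <- lapply(seq_len(spec$n_sites), function(s) {
    mu_s <- spec$rate$mu * abund[s]^spec$beta
    r_s <- rate_prior(mu_s, theta = spec$rate$theta)
    lam <- drop(draw_rates(visits[s], r_s, spec$corr, 1L))
    data.frame(site = s, visit = seq_len(visits[s]),
               detections = stats::rpois(visits[s], lam * spec$search_time),
               search_time = spec$search_time, abundance = abund[s])
  })
  do.call(rbind, rows)
}

#' Shipped scenario presets
#'
#' Loads one of the scenario configurations installed with the package:
#' `"frog"` (stream transects surveyed repeatedly over a season: mean rate
#' 0.67/h at abundance 1 rising to 2.2/h at abundance 3, coefficient of
#' variation 2.5, budget 10 h, fixed cost 1 h) or `"plants"` (quadrat
#' search experiment: 14 observers by 9 quadrats, 15-minute sessions, rates
#' near 0.55-0.56/min with s.d. 0.60-0.64). Any YAML file with the same
#' fields can be supplied instead via `path`.
#'
#' @param name `"frog"` or `"plants"`; ignored when `path` is given.
#' @param path Optional YAML file to load instead of a shipped preset.
#' @return A list with the raw config plus a `spec` ([scenario_spec()]) and,
#'   where the config defines them, `problem` ([design_problem()]) and
#'   `target`.
#' @export
load_scenario <- function(name = c("frog", "plants"), path = NULL) {
  if (is.null(path)) {
    name <- match.arg(name)
    path <- system.file("extdata", paste0(name, ".yaml"), package = "surveyopt")
  }
  cfg <- yaml::read_yaml(path)
  # yaml returns mixed-type sequences as lists; flatten the numeric fields
  for (f in c("B", "c")) if (!is.null(cfg$design[[f]]))
    cfg$design[[f]] <- unlist(cfg$design[[f]])
  for (f in c("visits")) if (!is.null(cfg$layout[[f]]))
    cfg$layout[[f]] <- unlist(cfg$layout[[f]])
  if (!is.null(cfg$abundance)) cfg$abundance <- unlist(cfg$abundance)
  rate <- rate_prior(cfg$rate$mu,
                     sigma = cfg$rate$sigma,
                     theta = if (is.null(cfg$rate$sigma)) cfg$rate$theta)
  corr <- if (is.null(cfg$correlation)) correlation_spec()
          else correlation_spec(cfg$correlation$r, cfg$correlation$structure,
                                cfg$correlation$T)
  spec <- scenario_spec(
    rate = rate, corr = corr,
    n_observers = cfg$layout$observers %||% 14L,
    n_quadrats = cfg$layout$quadrats %||% 9L,
    n_sites = cfg$layout$sites %||% 29L,
    visits = cfg$layout$visits %||% 3L,
    session_length = cfg$session_length %||% 15,
    search_time = cfg$search_time %||% 1,
    abundance = cfg$abundance %||% 1,
    beta = cfg$beta %||% 1,
    seed = cfg$seed %||% 1L
  )
  out <- list(config = cfg, spec = spec)
  if (!is.null(cfg$design)) {
    out$problem <- design_problem(cfg$design$B[1], cfg$design$c[1], rate)
    out$budgets <- cfg$design$B
    out$costs <- cfg$design$c
  }
  if (!is.null(cfg$Q_c)) out$target <- satisficing_target(Q_c = cfg$Q_c)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
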