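#' Configure the mating-trial simulator
#'
#' The simulated world mirrors the observed trial regime: two strains with
#' mating propensities near 0.3 and nightly mating-time distributions whose
#' medians sit at 1.33 h (E) and 4 h (Z) of a 7-h scotophase, observed on a
#' 20-minute check grid. Latent times come from a truncated normal (default)
#' or a truncated gamma (mating-time histograms are right-skewed), truncated
#' to `(0, scotophase_h]`, then censored upward to the next check time --
#' the first check at which a mating would be seen.
#'
#' @param n_trials named count vector `c(E = , Z = )`.
#' @param p_mate named mating propensities in `[0, 1]`.
#' @param family `"truncated-normal"` or `"gamma"` latent time distribution.
#' @param location named distribution location in hours (mean of the
#'   untruncated normal, or gamma mean).
#' @param scale named scale in hours (sd of the normal, or gamma sd).
#' @param scotophase_h,check_interval_h recording span and check grid.
#' @return list of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_trials = c(E = 76, Z = 79),
                             p_mate = c(E = 0.28, Z = 0.32),
                             family = c("truncated-normal", "gamma"),
                             location = c(E = 1.33, Z = 4.0),
                             scale = c(E = 1.2, Z = 1.2),
                             scotophase_h = 7, check_interval_h = 1 / 3) {
  family <- match.arg(family)
  for (v in list(n_trials, p_mate, location, scale)) {
    if (!all(c("E", "Z") %in% names(v))) {
      stop_validation("per-strain parameters must be named vectors with E and Z")
    }
  }
  if (any(p_mate < 0 | p_mate > 1)) stop_validation("p_mate must lie in [0, 1]")
  if (any(scale <= 0)) stop_validation("scale must be positive")
  if (family == "gamma" && any(location <= 0)) {
    stop_validation("gamma location (mean) must be positive")
  }
  if (!is_near_integer(scotophase_h / check_interval_h)) {
    stop_validation("scotophase_h must be a multiple of check_interval_h")
  }
  structure(list(n_trials = n_trials, p_mate = p_mate, family = family,
                 location = location, scale = scale,
                 scotophase_h = scotophase_h,
                 check_interval_h = check_interval_h),
            class = "trial_sim_config")
}

# CDF of the latent time distribution before truncation
latent_cdf <- function(config, strain) {
  m <- config$location[[strain]]
  s <- config$scale[[strain]]
  if (config$family == "truncated-normal") {
    function(x) stats::pnorm(x, m, s)
  } else {
    shape <- (m / s)^2
    rate <- m / s^2
    function(x) stats::pgamma(x, shape = shape, rate = rate)
  }
}

# inverse-CDF sampler of the latent distribution truncated to (0, L]
draw_latent_times <- function(config, strain, n) {
  cdf <- latent_cdf(config, strain)
  m <- config$location[[strain]]
  s <- config$scale[[strain]]
  lo <- cdf(0)
  hi <- cdf(config$scotophase_h)
  if (hi <= lo) stop_validation("time distribution has no mass in (0, scotophase]")
  u <- lo + (hi - lo) * stats::runif(n)
  if (config$family == "truncated-normal") {
    stats::qnorm(u, m, s)
  } else {
    stats::qgamma(u, shape = (m / s)^2, rate = m / s^2)
  }
}

#' Simulate mating trials
#'
#' Each trial mates with probability `p_mate`; mated trials draw a latent
#' time from the truncated distribution and record its ceiling on the check
#' grid. Deterministic given `seed`.
#'
#' @param config a [trial_sim_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `mating_trials` data frame (see [load_trials()]).
#' @export
simulate_trials <- function(config = trial_sim_config(), seed = NULL) {
  if (!inherits(config, "trial_sim_config")) {
    stop_validation("config must come from trial_sim_config()")
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- config$check_interval_h
  rows <- lapply(c("E", "Z"), function(s) {
    n <- config$n_trials[[s]]
    mated <- stats::runif(n) < config$p_mate[[s]]
    t <- rep(NA_real_, n)
    if (any(mated)) {
      lat <- draw_latent_times(config, s, sum(mated))
      t[mated] <- ceiling(lat / dt - 1e-12) * dt
      t[mated] <- pmax(t[mated], dt) # times are strictly positive
    }
    data.frame(trial_id = sprintf("%s_%03d", s, seq_len(n)), strain = s,
               mated = mated, time_h = t, stringsAsFactors = FALSE)
  })
  as_mating_trials(do.call(rbind, rows),
                   check_interval_h = dt, scotophase_h = config$scotophase_h)
}

#' Large-sample isolation index of a trial-simulator configuration
#'
#' Analytic counterpart of estimating RI from simulated trials: each strain's
#' expected number of matings per window is `n_trials * p_mate * mass(k)`,
#' where `mass(k)` is the truncated time distribution's probability of window
#' `((k-1) * window_h, k * window_h]` (upward censoring to the check grid
#' never crosses a window boundary when `window_h` is a multiple of the check
#' interval). Plugging these expected counts into the Hardy-Weinberg
#' expected-offspring formula gives the RI an infinitely large study of this
#' configuration would measure.
#'
#' @param config a [trial_sim_config()].
#' @param window_h window width in hours (a multiple of the check interval).
#' @return the large-sample RI, a scalar in `[0, 1]`.
#' @export
expected_ri <- function(config, window_h = 1) {
  if (!is_near_integer(window_h / config$check_interval_h)) {
    stop_validation("window_h must be a multiple of the check interval")
  }
  w <- ceiling(config$scotophase_h / window_h - 1e-9)
  edges <- seq(0, by = window_h, length.out = w + 1)
  mass <- function(strain) {
    cdf <- latent_cdf(config, strain)
    p <- diff(cdf(edges)) / (cdf(config$scotophase_h) - cdf(0))
    p * config$n_trials[[strain]] * config$p_mate[[strain]]
  }
  windows <- data.frame(window = seq_len(w), n_Z = mass("Z"), n_E = mass("E"))
  reproductive_isolation(windows)$ri
}

#' Configure the count-matrix simulator
#'
#' Emulates the 2-strain x 3-timepoint x 4-replicate head RNA-seq design (23
#' libraries after the one failed Z 1.3 h library). Counts are negative
#' binomial with `var = mu + dispersion * mu^2`; the group mean of transcript
#' t in group g is `2^(baseline[t] + effects[t, g])`, scaled by a per-library
#' sequencing-depth factor drawn log-uniformly in `depth_range` times the
#' nominal depth. An optional correlated module adds a shared 6-point latent
#' profile to a set of transcripts so profile correlations have known
#' positives.
#'
#' @param n_transcripts number of transcripts.
#' @param replicates replicate libraries per (strain, timepoint) group.
#' @param drop_library if `TRUE` (default), the last Z 1.3 h replicate is
#'   dropped, mirroring the failed library.
#' @param baseline_log2_mean scalar or length-`n_transcripts` vector of log2
#'   baseline counts.
#' @param dispersion negative-binomial dispersion (> 0).
#' @param effects `NULL` (all-null transcripts) or an `n_transcripts` x 6
#'   matrix of log2 shifts, columns ordered `E.photophase, E.1.3h, E.4h,
#'   Z.photophase, Z.1.3h, Z.4h`.
#' @param module optional list `list(transcripts =, profile =, scale = 1)`
#'   adding `scale * profile` (a 6-vector) to those transcripts' log2 means.
#' @param depth_range range of relative library depth factors.
#' @return list of class `counts_sim_config`.
#' @export
counts_sim_config <- function(n_transcripts = 2000, replicates = 4,
                              drop_library = TRUE, baseline_log2_mean = 6,
                              dispersion = 0.05, effects = NULL,
                              module = NULL, depth_range = c(0.5, 2)) {
  if (dispersion <= 0) stop_validation("dispersion must be positive")
  if (replicates < 2) stop_validation("need at least 2 replicates per group")
  if (!is.null(effects)) {
    effects <- as.matrix(effects)
    if (nrow(effects) != n_transcripts || ncol(effects) != 6) {
      stop_validation("effects must be an n_transcripts x 6 matrix")
    }
  }
  if (!is.null(module)) {
    if (length(module$profile) != 6) stop_validation("module profile must have 6 points")
    module$scale <- module$scale %||% 1
  }
  if (length(baseline_log2_mean) == 1) {
    baseline_log2_mean <- rep(baseline_log2_mean, n_transcripts)
  }
  if (length(baseline_log2_mean) != n_transcripts) {
    stop_validation("baseline_log2_mean must be scalar or length n_transcripts")
  }
  structure(list(n_transcripts = n_transcripts, replicates = replicates,
                 drop_library = drop_library,
                 baseline_log2_mean = baseline_log2_mean,
                 dispersion = dispersion, effects = effects, module = module,
                 depth_range = depth_range),
            class = "counts_sim_config")
}

#' Simulate a count matrix with known ground truth
#'
#' @param config a [counts_sim_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `counts` (matrix), `meta` (library metadata data frame),
#'   and `truth` (`effects` matrix including any module contribution,
#'   `module`, `depth_factors`).
#' @export
simulate_counts <- function(config = counts_sim_config(), seed = NULL) {
  if (!inherits(config, "counts_sim_config")) {
    stop_validation("config must come from counts_sim_config()")
  }
  if (!is.null(seed)) set.seed(seed)
  meta <- expand.grid(replicate = seq_len(config$replicates),
                      timepoint = TIMEPOINTS, strain = c("E", "Z"),
                      stringsAsFactors = FALSE)
  meta <- meta[, c("strain", "timepoint", "replicate")]
  meta$library_id <- sprintf("%s_%s_%d", meta$strain,
                             sub("1.3h", "1.3h", meta$timepoint, fixed = TRUE),
                             meta$replicate)
  if (config$drop_library) {
    meta <- meta[!(meta$strain == "Z" & meta$timepoint == "1.3h" &
                     meta$replicate == config$replicates), ]
  }
  meta <- meta[, c("library_id", "strain", "timepoint", "replicate")]
  rownames(meta) <- NULL

  n <- config$n_transcripts
  eff <- config$effects %||% matrix(0, n, 6)
  colnames(eff) <- GROUPS
  if (!is.null(config$module)) {
    idx <- config$module$transcripts
    eff[idx, ] <- eff[idx, ] +
      rep(config$module$scale * config$module$profile, each = length(idx))
  }
  log2mu <- config$baseline_log2_mean + eff # n x 6
  depth <- exp(stats::runif(nrow(meta), log(config$depth_range[1]),
                            log(config$depth_range[2])))
  names(depth) <- meta$library_id
  g <- match(paste(meta$strain, meta$timepoint, sep = "."), GROUPS)
  mu <- 2^log2mu[, g, drop = FALSE] * rep(depth, each = n)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   nrow = n)
  dimnames(counts) <- list(sprintf("comp%05d", seq_len(n)), meta$library_id)
  rownames(eff) <- rownames(counts)
  list(counts = counts, meta = meta,
       truth = list(effects = eff, module = config$module,
                    depth_factors = depth))
}

#' Write library metadata in the canonical CSV dialect
#'
#' @param meta library metadata data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meta_csv <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
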