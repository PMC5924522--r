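#' Mating-trial tables
#'
#' A mating trial pairs a virgin female with two males of her own pheromone
#' strain for one night and records whether the group mated and, if so, the
#' first 20-minute check at which mating was observed, in hours since
#' scotophase (dark phase) onset. `load_trials()` reads the CSV dialect
#' `trial_id,strain,mated,time_h` and validates every row; `as_mating_trials()`
#' applies the same validation to an in-memory data frame.
#'
#' Invariants enforced: `strain` is `"E"` or `"Z"`; `mated` is 0/1; `time_h`
#' is present iff `mated == 1`, lies in `(0, scotophase_h]`, and is an integer
#' multiple of the check interval (the observation grid). Times are snapped to
#' exact multiples of `check_interval_h` internally so that repeated binning
#' never drifts across a window boundary.
#'
#' @param path path to a UTF-8 comma-separated file with header
#'   `trial_id,strain,mated,time_h` (`time_h` empty for unmated rows).
#' @param check_interval_h observation grid in hours (default 1/3 h = 20 min).
#' @param scotophase_h length of the nightly recording period in hours.
#' @param enforce_grid if `TRUE` (default), a `time_h` that is not a multiple
#'   of `check_interval_h` is a validation error; set `FALSE` to accept
#'   off-grid times unchanged.
#' @return a data frame of class `mating_trials` with columns `trial_id`,
#'   `strain`, `mated` (logical), `time_h` (`NA` for unmated rows), carrying
#'   `check_interval_h` and `scotophase_h` as attributes.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("trial_id,strain,mated,time_h",
#'              "t1,E,1,1.3333333", "t2,E,0,", "t3,Z,1,4"), f)
#' trials <- load_trials(f)
#' summarize_trials(trials, "E")
#' @export
load_trials <- function(path, check_interval_h = 1 / 3, scotophase_h = 7,
                        enforce_grid = TRUE) {
  if (!file.exists(path)) stop_validation("trial file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  needed <- c("trial_id", "strain", "mated", "time_h")
  if (!all(needed %in% names(raw))) {
    stop_validation("trial CSV must have header %s; found: %s",
                    paste(needed, collapse = ","),
                    paste(names(raw), collapse = ","))
  }
  mated_num <- suppressWarnings(as.numeric(raw$mated))
  bad <- which(is.na(mated_num) | !mated_num %in% c(0, 1))
  if (length(bad)) {
    stop_validation("line %d: 'mated' must be 0 or 1 (got '%s')",
                    bad[1] + 1L, raw$mated[bad[1]])
  }
  time_chr <- raw$time_h
  time_num <- suppressWarnings(as.numeric(time_chr))
  bad <- which(nzchar(time_chr) & is.na(time_num))
  if (length(bad)) {
    stop_validation("line %d: 'time_h' is not numeric (got '%s')",
                    bad[1] + 1L, time_chr[bad[1]])
  }
  time_num[!nzchar(time_chr)] <- NA_real_
  df <- data.frame(trial_id = raw$trial_id, strain = raw$strain,
                   mated = mated_num == 1, time_h = time_num,
                   stringsAsFactors = FALSE)
  as_mating_trials(df, check_interval_h = check_interval_h,
                   scotophase_h = scotophase_h, enforce_grid = enforce_grid,
                   line_offset = 1L)
}

#' @rdname load_trials
#' @param df data frame with columns `trial_id`, `strain`, `mated`, `time_h`.
#' @param line_offset added to the row index in error messages (1 when the
#'   rows came from a CSV with a header line).
#' @export
as_mating_trials <- function(df, check_interval_h = 1 / 3, scotophase_h = 7,
                             enforce_grid = TRUE, line_offset = 0L) {
  if (check_interval_h <= 0 || scotophase_h <= 0) {
    stop_validation("check_interval_h and scotophase_h must be positive")
  }
  if (!is_near_integer(scotophase_h / check_interval_h)) {
    stop_validation("scotophase_h (%g) must be a multiple of check_interval_h (%g)",
                    scotophase_h, check_interval_h)
  }
  line <- function(i) i + line_offset
  bad <- which(!df$strain %in% c("E", "Z"))
  if (length(bad)) {
    stop_validation("line %d: strain must be 'E' or 'Z' (got '%s')",
                    line(bad[1]), df$strain[bad[1]])
  }
  df$mated <- as.logical(df$mated)
  bad <- which(df$mated & is.na(df$time_h))
  if (length(bad)) {
    stop_validation("line %d: mated trial without a mating time", line(bad[1]))
  }
  bad <- which(!df$mated & !is.na(df$time_h))
  if (length(bad)) {
    stop_validation("line %d: unmated trial has a mating time", line(bad[1]))
  }
  t <- df$time_h[df$mated]
  bad <- which(t <= 0 | t > scotophase_h)
  if (length(bad)) {
    i <- which(df$mated)[bad[1]]
    stop_validation("line %d: time_h = %g outside (0, %g]",
                    line(i), df$time_h[i], scotophase_h)
  }
  k <- df$time_h / check_interval_h
  if (enforce_grid) {
    bad <- which(df$mated & !is_near_integer(k))
    if (length(bad)) {
      stop_validation(
        "line %d: time_h = %g is not a multiple of the %g-h check interval",
        line(bad[1]), df$time_h[bad[1]], check_interval_h)
    }
    # snap to the grid so times are exact multiples of the check interval
    df$time_h <- ifelse(df$mated, round(k) * check_interval_h, NA_real_)
  }
  structure(df,
            class = c("mating_trials", "data.frame"),
            check_interval_h = check_interval_h,
            scotophase_h = scotophase_h)
}

#' Summarize mating trials for one strain
#'
#' Counts trials and matings, the proportion mated, and the median and mean
#' mating time among mated females only.
#'
#' @param obs a `mating_trials` data frame (see [load_trials()]).
#' @param strain `"E"` or `"Z"`; must be present in `obs`.
#' @return list of class `strain_summary`: `strain`, `n_trials`, `n_mated`,
#'   `prop_mated`, `median_h`, `mean_h` (the last two `NA` if nothing mated).
#' @export
summarize_trials <- function(obs, strain) {
  if (!strain %in% obs$strain) {
    stop_validation("no trials for strain '%s'", strain)
  }
  sub <- obs[obs$strain == strain, , drop = FALSE]
  t <- sub$time_h[sub$mated]
  structure(list(strain = strain,
                 n_trials = nrow(sub),
                 n_mated = sum(sub$mated),
                 prop_mated = sum(sub$mated) / nrow(sub),
                 median_h = if (length(t)) stats::median(t) else NA_real_,
                 mean_h = if (length(t)) mean(t) else NA_real_),
            class = "strain_summary")
}

#' Per-strain summary table
#'
#' @param obs a `mating_trials` data frame.
#' @return one data-frame row per strain present, columns as in
#'   [summarize_trials()].
#' @export
trial_summary_table <- function(obs) {
  strains <- intersect(c("E", "Z"), unique(obs$strain))
  do.call(rbind, lapply(strains, function(s) {
    as.data.frame(unclass(summarize_trials(obs, s)))
  }))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `(a, b; c, d)` by the
#' minimum-likelihood rule: under the hypergeometric null with all margins
#' fixed, sum the point probabilities of every table no more probable than
#' the observed one. A relative tolerance absorbs floating-point near-equality
#' of point probabilities.
#'
#' @param a,b,c,d non-negative integer cell counts (row 1 = `a, b`;
#'   row 2 = `c, d`).
#' @param rel_tol relative tolerance used when comparing point probabilities.
#' @return list of class `hypothesis_test` with `statistic_name`,
#'   `statistic` (sample odds ratio), `p_value`.
#' @examples
#' fisher_exact_2x2(21, 55, 25, 54)$p_value # ~0.602
#' @export
fisher_exact_2x2 <- function(a, b, c, d, rel_tol = 1e-7) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop_validation("all cell counts must be non-negative")
  }
  if (any(!is_near_integer(cells))) {
    stop_validation("cell counts must be integers")
  }
  n <- a + b + c + d
  if (n <= 0) stop_validation("table has no observations")
  r1 <- a + b
  c1 <- a + c
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  p <- min(1, sum(prob[prob <= p_obs * (1 + rel_tol)]))
  structure(list(statistic_name = "odds_ratio",
                 statistic = unname((a * d) / (b * c)),
                 p_value = p),
            class = "hypothesis_test")
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Compares the mating-time distributions of two samples. The statistic is
#' reported in both conventions: `statistic` is W, the sum of (mid)ranks of
#' the first sample, and `u` is the equivalent Mann-Whitney U
#' (`W - n1 (n1 + 1) / 2`). Ties -- expected here because times are quantized
#' to 20-minute checks -- are handled by midranks with a tie-corrected normal
#' approximation (no continuity correction). When both samples have at most
#' `exact_max` observations and there are no ties, the p-value is computed by
#' exact enumeration of all rank assignments.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max largest per-sample size at which the exact untied
#'   enumeration is used (default 8).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) decides from sample sizes and ties.
#' @return list of class `hypothesis_test`: `statistic_name = "rank_sum_W"`,
#'   `statistic` (W), `u`, `p_value`, `method` (`"exact"` or
#'   `"normal_tie_corrected"`), `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y, exact_max = 8, exact = NULL) {
  if (!length(x) || !length(y)) stop_validation("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- if (is.null(exact)) n1 <= exact_max && n2 <= exact_max && !has_ties else exact
  if (use_exact && has_ties) {
    stop_validation("exact enumeration is only available for untied samples")
  }
  if (use_exact) {
    # all C(n1+n2, n1) assignments of ranks to the first sample
    sums <- apply(utils::combn(n1 + n2, n1), 2, sum)
    u_all <- sums - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1 # all observations identical
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_tie_corrected"
  }
  structure(list(statistic_name = "rank_sum_W", statistic = w, u = u,
                 p_value = p, method = method, n1 = n1, n2 = n2),
            class = "hypothesis_test")
}

#' @export
print.hypothesis_test <- function(x, ...) {
  cat(sprintf("%s = %g, p = %g\n", x$statistic_name, x$statistic, x$p_value))
  invisible(x)
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf("strain %s: %d/%d mated (%.1f%%), median %.2f h, mean %.2f h\n",
              x$strain, x$n_mated, x$n_trials, 100 * x$prop_mated,
              x$median_h, x$mean_h))
  invisible(x)
}

#' Write a trial table in the canonical CSV dialect
#'
#' @param obs a `mating_trials` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(obs, path) {
  out <- data.frame(trial_id = obs$trial_id, strain = obs$strain,
                    mated = as.integer(obs$mated),
                    time_h = ifelse(obs$mated, format(obs$time_h, digits = 10), ""))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
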