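# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

write_trial_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("trial_id,strain,mated,time_h", lines), path)
  path
}

# a small deterministic trial table: explicit mating times plus unmated rows
make_trials <- function(times_E = numeric(), times_Z = numeric(),
                        n_unmated_E = 0, n_unmated_Z = 0) {
  df <- data.frame(
    strain = c(rep("E", length(times_E)), rep("Z", length(times_Z)),
               rep("E", n_unmated_E), rep("Z", n_unmated_Z)),
    mated = c(rep(TRUE, length(times_E) + length(times_Z)),
              rep(FALSE, n_unmated_E + n_unmated_Z)),
    time_h = c(times_E, times_Z, rep(NA_real_, n_unmated_E + n_unmated_Z)),
    stringsAsFactors = FALSE)
  df$trial_id <- sprintf("t%03d", seq_len(nrow(df)))
  as_mating_trials(df, enforce_grid = FALSE)
}

# independent Fisher oracle: enumerate tables with fixed margins using the
# closed-form table probability from binomial coefficients
fisher_oracle <- function(a, b, c, d, rel_tol = 1e-7) {
  N <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  supp <- max(0, c1 - (N - r1)):min(r1, c1)
  prob <- choose(r1, supp) * choose(N - r1, c1 - supp) / choose(N, c1)
  min(1, sum(prob[prob <= prob[supp == a] * (1 + rel_tol)]))
}

# independent RI oracle: per window, count mixed ordered parent pairs by
# literal enumeration of the mating pool
ri_oracle <- function(n_Z, n_E) {
  hyb <- 0
  pure <- 0
  seen <- FALSE
  for (k in seq_along(n_Z)) {
    n <- n_Z[k] + n_E[k]
    if (n == 0) next
    seen <- TRUE
    pool <- c(rep("Z", n_Z[k]), rep("E", n_E[k]))
    mixed <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) if (pool[i] != pool[j]) mixed <- mixed + 1
    }
    hyb <- hyb + n * mixed / n^2
    pure <- pure + n * (n^2 - mixed) / n^2
  }
  stopifnot(seen)
  1 - hyb / pure
}

# group column pairs of the 6-group effect matrix for each contrast name
CONTRAST_GROUPS <- list(
  "E_vs_Z.photophase" = c(1, 4), "E_vs_Z.1.3h" = c(2, 5), "E_vs_Z.4h" = c(3, 6),
  "E.photophase_vs_1.3h" = c(1, 2), "E.photophase_vs_4h" = c(1, 3),
  "E.1.3h_vs_4h" = c(2, 3), "Z.photophase_vs_1.3h" = c(4, 5),
  "Z.photophase_vs_4h" = c(4, 6), "Z.1.3h_vs_4h" = c(5, 6))
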