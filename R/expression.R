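#' @name expression-pipeline
#' @title Time-course expression stage
#' @description
#' The expression stage mirrors a 2-strain (E, Z) x 3-timepoint (photophase,
#' 1.3 h and 4 h into scotophase) head-transcriptome design with four
#' replicate libraries per group (one Z 1.3 h library missing, 23 in total).
#' It runs: CPM normalisation, a weak-expression filter, nine two-group
#' contrasts (between strains at each timepoint; within each strain between
#' each pair of timepoints) with Benjamini-Hochberg correction applied within
#' each contrast, strain-by-timepoint mean profiles, and pairwise Pearson
#' correlations between transcript profiles.
#'
#' Significance in the contrasts comes from a Welch t-test on
#' `log2(CPM + prior)` replicate values. This is a deliberate, documented
#' surrogate for a negative-binomial GLM with GC/depth offsets: it preserves
#' the contrast structure and FDR procedure, but numerical agreement with
#' fits from count-model software is not claimed.
NULL

TIMEPOINTS <- c("photophase", "1.3h", "4h")
GROUPS <- c("E.photophase", "E.1.3h", "E.4h", "Z.photophase", "Z.1.3h", "Z.4h")

#' Counts-per-million normalisation
#'
#' @param counts non-negative matrix, transcripts in rows, libraries in
#'   columns; every column total must be positive.
#' @return matrix of the same shape; each column sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_validation("negative counts")
  tot <- colSums(counts)
  if (any(tot <= 0)) {
    stop_validation("library with zero total count: %s",
                    paste(colnames(counts)[tot <= 0], collapse = ", "))
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Filter weakly expressed transcripts
#'
#' Keeps transcripts with at least `min_cpm` counts per million in at least
#' `min_libraries` libraries -- by default 1 CPM in 7 libraries, seven being
#' the minimum number of libraries representing the two strains at one
#' timepoint in the 23-library design.
#'
#' @inheritParams cpm_normalize
#' @param min_cpm CPM threshold (default 1).
#' @param min_libraries minimum number of libraries meeting the threshold.
#' @return the row-subset count matrix; attribute `filter_log` records the
#'   thresholds and the kept/dropped transcript ids.
#' @export
filter_weak <- function(counts, min_cpm = 1, min_libraries = 7) {
  counts <- as.matrix(counts)
  if (min_libraries > ncol(counts)) {
    stop_validation("min_libraries (%d) exceeds number of libraries (%d)",
                    min_libraries, ncol(counts))
  }
  cpm <- cpm_normalize(counts)
  keep <- rowSums(cpm >= min_cpm) >= min_libraries
  out <- counts[keep, , drop = FALSE]
  attr(out, "filter_log") <- list(min_cpm = min_cpm,
                                  min_libraries = min_libraries,
                                  n_input = nrow(counts),
                                  n_kept = sum(keep),
                                  kept = rownames(counts)[keep],
                                  dropped = rownames(counts)[!keep])
  out
}

#' Read a count matrix / library metadata
#'
#' @param path counts: TSV whose first column is the transcript id and whose
#'   remaining columns are library counts; metadata: CSV with header
#'   `library_id,strain,timepoint,replicate`.
#' @return `read_counts_tsv`: integer matrix with transcript rownames;
#'   `read_library_meta`: validated data frame.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop_validation("counts file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(is.na(m)) || any(m < 0)) stop_validation("counts must be non-negative numbers")
  m
}

#' @rdname read_counts_tsv
#' @param transcripts,libraries paths to plain-text files with one transcript
#'   (row) or library (column) id per line, accompanying the sparse matrix.
#' @export
read_counts_mtx <- function(path, transcripts, libraries) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop_validation("the Matrix package is required for MTX input")
  }
  for (f in c(path, transcripts, libraries)) {
    if (!file.exists(f)) stop_validation("file not found: %s", f)
  }
  m <- as.matrix(Matrix::readMM(path))
  rn <- readLines(transcripts)
  cn <- readLines(libraries)
  if (nrow(m) != length(rn) || ncol(m) != length(cn)) {
    stop_validation("MTX dimensions (%d x %d) do not match id files (%d x %d)",
                    nrow(m), ncol(m), length(rn), length(cn))
  }
  dimnames(m) <- list(rn, cn)
  if (any(m < 0)) stop_validation("counts must be non-negative")
  m
}

#' @rdname read_counts_tsv
#' @export
read_library_meta <- function(path) {
  if (!file.exists(path)) stop_validation("metadata file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  validate_library_meta(df)
}

validate_library_meta <- function(df) {
  needed <- c("library_id", "strain", "timepoint", "replicate")
  if (!all(needed %in% names(df))) {
    stop_validation("metadata must have columns %s", paste(needed, collapse = ","))
  }
  if (!all(df$strain %in% c("E", "Z"))) stop_validation("strain must be 'E' or 'Z'")
  if (!all(df$timepoint %in% TIMEPOINTS)) {
    stop_validation("timepoint must be one of %s", paste(TIMEPOINTS, collapse = ", "))
  }
  key <- paste(df$strain, df$timepoint, df$replicate)
  if (anyDuplicated(key)) {
    stop_validation("duplicate (strain, timepoint, replicate): %s",
                    key[duplicated(key)][1])
  }
  if (anyDuplicated(df$library_id)) stop_validation("duplicate library_id")
  df$replicate <- as.integer(df$replicate)
  df
}

# libraries of one (strain, timepoint) group, in metadata order
group_libraries <- function(meta, strain, timepoint) {
  meta$library_id[meta$strain == strain & meta$timepoint == timepoint]
}

#' The nine contrasts of the time-course design
#'
#' Three between-strain contrasts (E vs Z at each timepoint; positive log2
#' fold change = higher in E) and, within each strain, the three timepoint
#' pairs (positive = higher at the earlier timepoint, with
#' photophase < 1.3 h < 4 h).
#'
#' @param meta validated library metadata (see [read_library_meta()]).
#' @return list of contrasts, each with `name`, `a`, `b` (library id vectors;
#'   the log fold change is a over b).
#' @export
design_contrasts <- function(meta) {
  out <- list()
  for (tp in TIMEPOINTS) {
    out[[length(out) + 1L]] <- list(name = paste0("E_vs_Z.", tp),
                                    a = group_libraries(meta, "E", tp),
                                    b = group_libraries(meta, "Z", tp))
  }
  pairs <- utils::combn(TIMEPOINTS, 2)
  for (s in c("E", "Z")) {
    for (j in seq_len(ncol(pairs))) {
      tp1 <- pairs[1, j]
      tp2 <- pairs[2, j]
      out[[length(out) + 1L]] <- list(name = sprintf("%s.%s_vs_%s", s, tp1, tp2),
                                      a = group_libraries(meta, s, tp1),
                                      b = group_libraries(meta, s, tp2))
    }
  }
  out
}

# vectorised two-sample Welch test over matrix rows
welch_rows <- function(la, lb) {
  na <- ncol(la)
  nb <- ncol(lb)
  ma <- rowMeans(la)
  mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: zero variance in both groups
  flat <- se2 == 0
  p[flat] <- ifelse(ma[flat] == mb[flat], 1, 0)
  p
}

#' Per-transcript contrast table
#'
#' For each of the nine contrasts and each transcript: the log2 fold change of
#' group-mean CPM (with a prior count added to both means), a p-value from a
#' Welch t-test on `log2(CPM + prior_count)` replicate values, and a
#' Benjamini-Hochberg q-value computed within the contrast.
#'
#' @param counts filtered count matrix (transcripts x libraries).
#' @param meta library metadata; every metadata library must be a column of
#'   `counts` and vice versa.
#' @param prior_count pseudo-CPM added before log transforms and to group
#'   means in the fold change (default 0.5).
#' @return data frame of class `contrast_table`: `transcript`, `contrast`,
#'   `log_fc`, `p_value`, `q_value`.
#' @export
contrast_table <- function(counts, meta, prior_count = 0.5) {
  counts <- as.matrix(counts)
  meta <- validate_library_meta(meta)
  orphan_meta <- setdiff(meta$library_id, colnames(counts))
  orphan_counts <- setdiff(colnames(counts), meta$library_id)
  if (length(orphan_meta) || length(orphan_counts)) {
    stop_validation("metadata/matrix mismatch; orphan libraries: %s",
                    paste(c(orphan_meta, orphan_counts), collapse = ", "))
  }
  contrasts <- design_contrasts(meta)
  sizes <- unlist(lapply(contrasts, function(ct) c(length(ct$a), length(ct$b))))
  if (any(sizes < 2)) {
    small <- contrasts[[which(matrix(sizes, nrow = 2)[1, ] < 2 |
                                matrix(sizes, nrow = 2)[2, ] < 2)[1]]]
    stop_validation("contrast %s has a group with fewer than 2 libraries",
                    small$name)
  }
  cpm <- cpm_normalize(counts)
  lcpm <- log2(cpm + prior_count)
  res <- lapply(contrasts, function(ct) {
    la <- lcpm[, ct$a, drop = FALSE]
    lb <- lcpm[, ct$b, drop = FALSE]
    lfc <- log2(rowMeans(cpm[, ct$a, drop = FALSE]) + prior_count) -
      log2(rowMeans(cpm[, ct$b, drop = FALSE]) + prior_count)
    p <- welch_rows(la, lb)
    data.frame(transcript = rownames(counts), contrast = ct$name,
               log_fc = unname(lfc), p_value = unname(p),
               q_value = unname(stats::p.adjust(p, method = "BH")),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res),
            class = c("contrast_table", "data.frame"),
            prior_count = prior_count)
}

#' Strain-by-timepoint mean expression profiles
#'
#' Averages normalised expression within each of the six (strain, timepoint)
#' groups, in the fixed order E.photophase, E.1.3h, E.4h, Z.photophase,
#' Z.1.3h, Z.4h. Groups with a missing replicate are averaged over the
#' libraries present.
#'
#' @param normalized normalised (e.g. CPM) matrix, transcripts x libraries.
#' @param meta library metadata.
#' @return matrix of class `mean_profiles`, transcripts x 6 groups.
#' @export
strain_timepoint_means <- function(normalized, meta) {
  normalized <- as.matrix(normalized)
  meta <- validate_library_meta(meta)
  cols <- lapply(GROUPS, function(g) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    libs <- group_libraries(meta, parts[1], paste(parts[-1], collapse = "."))
    if (!length(libs)) stop_validation("empty group: %s", g)
    rowMeans(normalized[, libs, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  colnames(out) <- GROUPS
  class(out) <- c("mean_profiles", class(out))
  out
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null transform `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom; with the six strain-by-timepoint profile
#' points this is a t with 4 df.
#'
#' @param r Pearson correlation(s) in `[-1, 1]`.
#' @param n number of paired points (default 6).
#' @return two-sided p-value(s) in `(0, 1]`.
#' @examples
#' profile_cor_test(-0.82) # ~0.046
#' @export
profile_cor_test <- function(r, n = 6) {
  if (any(abs(r) > 1 + 1e-12)) stop_validation("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  pmax(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin)
}

#' Pairwise correlations between mean profiles
#'
#' Pearson correlation over the six profile points for every unordered pair
#' of transcripts, with two-sided p-values from [profile_cor_test()].
#' Constant profiles carry no correlation information and are skipped with a
#' warning.
#'
#' @param profiles a `mean_profiles` matrix (see [strain_timepoint_means()]).
#' @param alpha if non-`NULL`, restrict the output to pairs with
#'   `p_value < alpha`.
#' @return data frame: `transcript_a`, `transcript_b`, `r`, `p_value`.
#' @export
profile_correlations <- function(profiles, alpha = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop_validation("need at least two profiles")
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("skipping constant profile(s): %s",
                    paste(rownames(profiles)[sds == 0], collapse = ", ")))
    profiles <- profiles[sds > 0, , drop = FALSE]
  }
  if (nrow(profiles) < 2) stop_validation("fewer than two non-constant profiles")
  cm <- stats::cor(t(profiles))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(transcript_a = rownames(profiles)[idx[, 1]],
                    transcript_b = rownames(profiles)[idx[, 2]],
                    r = cm[idx],
                    p_value = profile_cor_test(cm[idx], n = ncol(profiles)),
                    stringsAsFactors = FALSE)
  if (!is.null(alpha)) out <- out[out$p_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cap log fold changes for heatmap display
#'
#' Returns a copy of the contrast table with `log_fc` clamped to `[lo, hi]`
#' (display only -- tests and q-values are untouched) plus a `significant`
#' flag and asterisk `marker` for q < 0.05.
#'
#' @param table a `contrast_table` data frame.
#' @param lo,hi clamp bounds, `lo < hi` (defaults -2, 2).
#' @param q_cutoff significance threshold for the asterisk markers.
#' @return the capped data frame with columns `log_fc_capped`, `significant`,
#'   `marker` added.
#' @export
cap_logfc <- function(table, lo = -2, hi = 2, q_cutoff = 0.05) {
  if (lo >= hi) stop_validation("lo must be < hi")
  out <- as.data.frame(table)
  out$log_fc_capped <- pmin(hi, pmax(lo, out$log_fc))
  out$significant <- out$q_value < q_cutoff
  out$marker <- ifelse(out$significant, "*", "")
  out
}

#' Export a capped-logFC heatmap
#'
#' Draws transcripts x contrasts as a blue-white-red image of capped log2
#' fold changes, with asterisks marking significant cells, to a PDF.
#'
#' @param capped output of [cap_logfc()].
#' @param path output PDF path.
#' @param lo,hi colour scale limits (should match the capping bounds).
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(capped, path, lo = -2, hi = 2) {
  m <- stats::xtabs(log_fc_capped ~ transcript + contrast, data = capped)
  sig <- stats::xtabs(significant ~ transcript + contrast, data = capped) > 0
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  grDevices::pdf(path, width = 7, height = max(3, 0.25 * nrow(m) + 2))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(7, 8, 2, 1))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  zlim = c(lo, hi), col = pal, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2, cex.axis = 0.7)
  ij <- which(sig, arr.ind = TRUE)
  if (nrow(ij)) graphics::text(ij[, 2], ij[, 1], "*", cex = 1.2)
  invisible(path)
}

#' Write a count matrix / contrast table in the canonical dialects
#'
#' @param counts matrix with transcript rownames and library colnames.
#' @param x a data frame (contrast or correlation table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(transcript = rownames(counts), as.data.frame(counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
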