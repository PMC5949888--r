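#' Growth estimation and stop-codon-calibrated classification
#'
#' Count tables are normalized per sample and per replicate, each sequence's
#' normalized trajectory is fitted with a robust linear model whose slope is
#' the growth estimate, and a functional threshold is calibrated on the
#' empirical null of stop-codon-initiated inserts.
#'
#' @name growth_classification
NULL

#' Remove sequences with too few total raw reads
#'
#' @param counts Count table (`member_id` or `sequence`, `time_day`,
#'   `replicate`, `count`).
#' @param min_total Minimum summed raw count over all samples (default 3).
#' @param id_col Column identifying a sequence.
#' @return Filtered count table.
#' @export
prefilter_counts <- function(counts, min_total = 3L, id_col = "member_id") {
  totals <- tapply(counts$count, counts[[id_col]], sum)
  keep <- names(totals)[totals >= min_total]
  counts[counts[[id_col]] %in% keep, , drop = FALSE]
}

#' Normalize counts per sample and to the starting value
#'
#' Three steps: (i) a zero count at day 0 is set to 1 raw read when the
#' trajectory has nonzero counts later (division-by-zero guard); (ii) every
#' count is divided by the total reads of its (time point, replicate)
#' sample; (iii) each replicate trajectory is divided by its day-0 value so
#' y(0) = 1. Replicates of a sequence with no reads at all are dropped.
#'
#' @inheritParams prefilter_counts
#' @return `data.frame` with `id`, `time_day`, `replicate`, `y` (normalized
#'   value), plus per-id attribute columns `total_raw`.
#' @export
normalize_counts <- function(counts, id_col = "member_id") {
  counts <- counts[order(counts[[id_col]], counts$replicate, counts$time_day), ]
  t0 <- min(counts$time_day)
  # impute day-0 zeros for trajectories alive later
  key <- paste(counts[[id_col]], counts$replicate)
  later_alive <- tapply(counts$count[counts$time_day > t0],
                        key[counts$time_day > t0], function(x) any(x > 0))
  is_t0 <- counts$time_day == t0
  fix <- is_t0 & counts$count == 0 & key %in% names(later_alive)[later_alive]
  counts$count_imp <- counts$count
  counts$count_imp[fix] <- 1L
  # per-(time, replicate) total-sum normalization (on imputed counts)
  sample_key <- paste(counts$time_day, counts$replicate)
  totals <- tapply(counts$count_imp, sample_key, sum)
  frac <- counts$count_imp / as.numeric(totals[sample_key])
  # per-replicate normalization to the day-0 value
  out <- data.frame(id = counts[[id_col]], time_day = counts$time_day,
                    replicate = counts$replicate, raw = counts$count,
                    frac = frac, stringsAsFactors = FALSE)
  t0_val <- out$frac[out$time_day == t0]
  names(t0_val) <- paste(out$id, out$replicate)[out$time_day == t0]
  out$y <- out$frac / as.numeric(t0_val[paste(out$id, out$replicate)])
  # drop replicate trajectories that never had a read
  alive <- tapply(out$raw, paste(out$id, out$replicate), function(x) any(x > 0))
  out <- out[alive[paste(out$id, out$replicate)], , drop = FALSE]
  out <- out[is.finite(out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the growth estimate of one sequence by robust regression
#'
#' Pools the (time, normalized value) points of all replicates and fits a
#' Huber M-estimator regression of (y - 1) on time through the origin
#' (the intercept is fixed at 1 by the normalization), tuning constant
#' 1.345, at most 50 IWLS iterations. When the residual scale is zero (an
#' exact fit), ordinary least squares is used and the fit is marked
#' converged.
#'
#' @param times,values Numeric vectors of pooled time points and normalized
#'   values (>= 2 points).
#' @return List with `slope` (per day), `converged`, `n_points`.
#' @export
fit_growth <- function(times, values) {
  if (length(times) < 2L || length(values) != length(times)) {
    stop("fit error: need >= 2 (time, value) points", call. = FALSE)
  }
  x <- matrix(times, ncol = 1)
  y <- values - 1
  fit <- tryCatch(
    MASS::rlm(x, y, psi = MASS::psi.huber, k = 1.345, maxit = 50),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(coef(fit)[1])) {
    ls <- sum(x * y) / sum(x * x)
    return(list(slope = ls, converged = TRUE, n_points = length(times)))
  }
  list(slope = unname(coef(fit)[1]), converged = isTRUE(fit$converged),
       n_points = length(times))
}

#' Fit growth estimates for every sequence in a normalized table
#'
#' @param norm Output of [normalize_counts()].
#' @return `data.frame` with one row per id: `id`, `slope`,
#'   `rounded_estimate`, `n_replicates` (replicates with any read),
#'   `total_raw_reads`, `converged`.
#' @export
fit_growth_table <- function(norm) {
  ids <- unique(norm$id)
  rows <- lapply(ids, function(i) {
    d <- norm[norm$id == i, ]
    f <- fit_growth(d$time_day, d$y)
    data.frame(
      id = i, slope = f$slope, rounded_estimate = round_estimate(f$slope),
      n_replicates = length(unique(d$replicate)),
      total_raw_reads = sum(d$raw), converged = f$converged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Support filter on fitted growth estimates
#'
#' @param fits Output of [fit_growth_table()].
#' @param min_reps Minimum replicates with reads (default 2).
#' @param min_reads Minimum total raw reads (default 10).
#' @return Logical keep vector.
#' @export
filter_fits <- function(fits, min_reps = 2L, min_reads = 10L) {
  fits$n_replicates >= min_reps & fits$total_raw_reads >= min_reads &
    fits$converged
}

#' Partition fitted sequences by whether the insert starts with a stop codon
#'
#' @param fits Fits table with a logical `starts_with_stop` column.
#' @return List with `stop` and `nonstop` subsets; warns when the stop set
#'   is empty (thresholding then has no null).
#' @export
split_stop_groups <- function(fits) {
  stopifnot("starts_with_stop" %in% names(fits))
  stop_set <- fits[fits$starts_with_stop, , drop = FALSE]
  if (!nrow(stop_set)) warning("empty stop-codon set: no null for thresholding")
  list(stop = stop_set, nonstop = fits[!fits$starts_with_stop, , drop = FALSE])
}

#' Calibrate the functional growth threshold on stop-codon controls
#'
#' `design_max_stop` takes the highest stop-control estimate (the design
#' library ships exactly three stop variants). `target_fpr` scans the
#' observed stop estimates and returns the smallest value t such that the
#' fraction of stop estimates strictly above t is at most `target_fpr`.
#'
#' @param stop_estimates Rounded growth estimates of the stop-codon set.
#' @param mode `"design_max_stop"` or `"target_fpr"`.
#' @param target_fpr Tolerated false-positive rate on the stop null.
#' @return List with `threshold`, `mode`, `stop_set_size`,
#'   `fpr_at_threshold`.
#' @export
threshold_select <- function(stop_estimates,
                             mode = c("design_max_stop", "target_fpr"),
                             target_fpr = 0.01) {
  mode <- match.arg(mode)
  if (!length(stop_estimates)) stop("empty stop set", call. = FALSE)
  if (mode == "design_max_stop") {
    th <- max(stop_estimates)
  } else {
    cand <- sort(unique(stop_estimates))
    fprs <- vapply(cand, function(t) mean(stop_estimates > t), 0)
    th <- cand[which(fprs <= target_fpr)[1]]
  }
  list(threshold = th, mode = mode, stop_set_size = length(stop_estimates),
       fpr_at_threshold = mean(stop_estimates > th))
}

#' Classify growth estimates against a threshold
#'
#' Strictly-greater comparison, so a stop variant whose estimate defines the
#' threshold is itself called nonfunctional.
#'
#' @param estimates Rounded growth estimates.
#' @param threshold Calibrated threshold.
#' @return Character vector, `"functional"` / `"nonfunctional"`.
#' @export
classify_estimates <- function(estimates, threshold) {
  ifelse(estimates > threshold, "functional", "nonfunctional")
}

#' True- and false-positive rates from a confusion table
#'
#' @param tp,fn,fp,tn Non-negative counts.
#' @return List with `tpr` = TP/(TP+FN) and `fpr` = FP/(FP+TN).
#' @export
rate_metrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  if (tp + fn == 0 || fp + tn == 0) {
    stop("undefined metric: zero denominator", call. = FALSE)
  }
  list(tpr = tp / (tp + fn), fpr = fp / (fp + tn))
}

#' Label quality-control statistics
#'
#' `short_seq_fp_fraction`: fraction of functional calls whose peptide has
#' four or fewer residues (an experimental false-positive proxy, since such
#' fragments should not transactivate). `imbalance_ratio`: functional over
#' nonfunctional count.
#'
#' @param labels `"functional"` / `"nonfunctional"` vector.
#' @param peptides Matching peptide strings.
#' @param max_short Length at or below which a functional call is counted as
#'   a presumed false positive (default 4).
#' @return List with `short_seq_fp_fraction`, `imbalance_ratio`,
#'   `n_functional`, `n_nonfunctional`.
#' @export
qc_stats <- function(labels, peptides, max_short = 4L) {
  n_f <- sum(labels == "functional")
  n_n <- sum(labels == "nonfunctional")
  if (n_f == 0) stop("undefined: no functional sequences", call. = FALSE)
  short <- sum(labels == "functional" & nchar(peptides) <= max_short)
  list(short_seq_fp_fraction = short / n_f, imbalance_ratio = n_f / n_n,
       n_functional = n_f, n_nonfunctional = n_n)
}

#' Fit, filter and classify a screen count table end to end
#'
#' Convenience driver: prefilter, normalize, fit, support-filter, calibrate
#' the threshold on the stop-codon null and classify.
#'
#' @param counts Count table with `member_id`, `sequence`, `time_day`,
#'   `replicate`, `count`.
#' @param mode,target_fpr Passed to [threshold_select()].
#' @param min_total,min_reps,min_reads Filter parameters.
#' @param calibration_ids Optional ids restricting which stop-codon
#'   sequences calibrate the threshold (the rest can serve as a held-out
#'   null).
#' @return List with `fits` (including `label`), `threshold_report`.
#' @export
classify_screen <- function(counts, mode = c("target_fpr", "design_max_stop"),
                            target_fpr = 0.01, min_total = 3L, min_reps = 2L,
                            min_reads = 10L, calibration_ids = NULL) {
  mode <- match.arg(mode)
  counts <- prefilter_counts(counts, min_total = min_total)
  norm <- normalize_counts(counts)
  fits <- fit_growth_table(norm)
  seq_of <- counts$sequence[!duplicated(counts$member_id)]
  names(seq_of) <- counts$member_id[!duplicated(counts$member_id)]
  fits$sequence <- unname(seq_of[fits$id])
  tr <- lapply(fits$sequence, translate_insert)
  fits$peptide <- vapply(tr, `[[`, "", "peptide")
  fits$starts_with_stop <- vapply(tr, `[[`, logical(1), "starts_with_stop")
  fits <- fits[filter_fits(fits, min_reps, min_reads), , drop = FALSE]
  groups <- split_stop_groups(fits)
  calib <- groups$stop
  if (!is.null(calibration_ids)) {
    calib <- calib[calib$id %in% calibration_ids, , drop = FALSE]
  }
  report <- threshold_select(calib$rounded_estimate, mode = mode,
                             target_fpr = target_fpr)
  fits$label <- classify_estimates(fits$rounded_estimate, report$threshold)
  report$n_functional <- sum(fits$label == "functional")
  list(fits = fits, threshold_report = report)
}
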