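#' File formats and the end-to-end pipeline driver
#'
#' Canonical on-disk formats: FASTQ (Phred+33) for reads, tab-delimited
#' UTF-8 tables with a header row for counts/fits, JSON for nested reports.
#'
#' @name cli_io
NULL

#' Write and read FASTQ (Phred+33)
#'
#' @param reads `data.frame` with `id`, `seq`, `qual`.
#' @param path Output file.
#' @return `write_fastq`: invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual), con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("parse error: FASTQ record truncated near line ", length(lines),
         call. = FALSE)
  }
  if (!length(lines)) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  }
  ids <- lines[seq(1, length(lines), 4)]
  seqs <- lines[seq(2, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad)) {
    stop("parse error: missing '@' at line ", (bad[1] - 1) * 4 + 1,
         call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("parse error: seq/qual length mismatch at line ", (bad[1] - 1) * 4 + 2,
         call. = FALSE)
  }
  data.frame(id = sub("^@", "", ids), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write and read a screen count table (TSV)
#'
#' Duplicate (member, time, replicate) rows are aggregated with a warning
#' on read; negative counts are a schema error.
#'
#' @param counts Count table (`member_id`, `sequence`, `time_day`,
#'   `replicate`, `count`).
#' @param path File path.
#' @return `read_count_table`: the typed `data.frame`.
#' @export
write_count_table <- function(counts, path) {
  need <- c("member_id", "sequence", "time_day", "replicate", "count")
  stopifnot(all(need %in% names(counts)))
  write.table(counts[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("member_id", "sequence", "time_day", "replicate", "count")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$count < 0)) stop("schema error: negative count", call. = FALSE)
  key <- paste(x$member_id, x$time_day, x$replicate)
  if (anyDuplicated(key)) {
    warning("duplicate (member, time, replicate) rows aggregated")
    x <- stats::aggregate(count ~ member_id + sequence + time_day + replicate,
                          data = x, FUN = sum)
  }
  x[order(x$member_id, x$replicate, x$time_day), need]
}

#' Run the simulate -> fit -> classify -> featurize -> train pipeline
#'
#' End-to-end driver over a synthetic random-library screen: generates and
#' labels a library, simulates counts, estimates growth and classifies on a
#' stop-codon-calibrated threshold (stop-codon-initiated inserts are split
#' in half into a calibration set and a held-out null), featurizes the
#' classified peptides, trains lasso/ridge/boosted models with repeated
#' 5-fold cross-validation and stacks them, and reports test-set metrics
#' plus the importance table.
#'
#' @param n_members Library size.
#' @param depth Reads per sample.
#' @param seed Integer seed for every stage.
#' @param design Optional [screen_design()] override (depth is taken from
#'   `depth`).
#' @param rule Planted [ground_truth_rule()].
#' @param target_fpr Stop-null false-positive-rate target.
#' @param do_ml Train models (set FALSE for growth-only runs).
#' @param repeats Cross-validation repeats (k = 5 fixed).
#' @param out_dir Optional directory; when given, stage outputs (count
#'   table, fits, threshold report, importance table) are written there.
#' @return List with `members`, `counts`, `fits`, `threshold_report`,
#'   `holdout_fpr`, `label_metrics` (vs planted truth), and when `do_ml`,
#'   `ml` (models, test metrics, importance).
#' @export
run_pipeline <- function(n_members = 5000L, depth = 10000L, seed = 1L,
                         design = NULL, rule = ground_truth_rule(),
                         target_fpr = 0.006, do_ml = TRUE, repeats = 10L,
                         out_dir = NULL) {
  if (is.null(design)) design <- screen_design(depth = depth)
  members <- plant_ground_truth(
    generate_random_inserts(n_members, seed = seed), rule
  )
  counts <- simulate_screen(members, design, seed = seed + 1L)

  # split the stop-codon null: half calibrates the threshold, half is held out
  stop_ids <- vapply(members, `[[`, "", "member_id")[
    vapply(members, `[[`, logical(1), "starts_with_stop")]
  restore <- .local_seed(seed + 2L)
  calib_ids <- sample(stop_ids, ceiling(length(stop_ids) / 2))
  restore()
  holdout_ids <- setdiff(stop_ids, calib_ids)

  cls <- classify_screen(counts, mode = "target_fpr", target_fpr = target_fpr,
                         calibration_ids = calib_ids)
  fits <- cls$fits
  holdout <- fits[fits$id %in% holdout_ids, ]
  holdout_fpr <- if (nrow(holdout)) {
    mean(holdout$label == "functional")
  } else NA_real_

  truth <- setNames(vapply(members, `[[`, "", "true_class"),
                    vapply(members, `[[`, "", "member_id"))
  tr <- truth[fits$id]
  label_metrics <- rate_metrics(
    tp = sum(fits$label == "functional" & tr == "functional"),
    fn = sum(fits$label == "nonfunctional" & tr == "functional"),
    fp = sum(fits$label == "functional" & tr == "nonfunctional"),
    tn = sum(fits$label == "nonfunctional" & tr == "nonfunctional")
  )

  out <- list(members = members, counts = counts, fits = fits,
              threshold_report = cls$threshold_report,
              holdout_fpr = holdout_fpr, label_metrics = label_metrics)

  if (do_ml) {
    usable <- fits[nchar(fits$peptide) > 0, ]
    x <- featurize(usable$peptide)
    rownames(x) <- usable$id
    y <- usable$label
    legacy <- c("length", "isoelectric_point", "hydrophobic_fraction",
                "disorder_mean", "helicity_mean", "ninetad_presence")
    x <- nzv_prune(x)$x
    x <- lincomb_prune(x)$x
    x <- corr_prune(x, forced_keep = legacy)$x
    hold <- split_holdout(y, seed = seed + 3L)
    xtr <- x[hold$train, , drop = FALSE]; ytr <- y[hold$train]
    xte <- x[hold$test, , drop = FALSE]; yte <- y[hold$test]
    splits <- make_folds(ytr, "repeated_kfold", repeats = repeats,
                         seed = seed + 4L)
    grid <- hyper_grid()
    fits_ml <- list(
      lasso = cv_train(xtr, ytr, splits, "penalized_L1", grid, seed = seed + 5L),
      ridge = cv_train(xtr, ytr, splits, "penalized_L2", grid, seed = seed + 6L),
      boosted = cv_train(xtr, ytr, splits, "boosted", grid, seed = seed + 7L)
    )
    oof <- do.call(cbind, lapply(fits_ml, `[[`, "oof"))
    stack <- stack_models(oof, ytr, seed = seed + 8L)
    test_prob <- sapply(fits_ml, function(f) {
      f$model$predict_prob(apply_center_scale(f$transformer, xte),
                           s = if (is.numeric(f$chosen)) f$chosen else NULL)
    })
    stack_prob <- stack$predict_prob(test_prob)
    metrics <- evaluate_scores(stack_prob, yte)
    imp <- importance_table(fits_ml, stack, x = xtr, y = ytr)
    out$ml <- list(fits = fits_ml, stack = stack, test_metrics = metrics,
                   importance = imp,
                   base_test_metrics = apply(test_prob, 2, function(p)
                     evaluate_scores(p, yte)$pr_auc))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(counts, file.path(out_dir, "counts.tsv"))
    write.table(fits, file.path(out_dir, "fits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cls$threshold_report,
                         file.path(out_dir, "threshold_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (do_ml) {
      write.table(out$ml$importance, file.path(out_dir, "importance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(n_members = n_members, depth = depth, seed = seed,
           target_fpr = target_fpr,
           time_points = design$time_points,
           n_replicates = design$n_replicates),
      file.path(out_dir, "resolved_config.json"), auto_unbox = TRUE
    )
  }
  out
}

#' Growth-slope recovery error as a function of sequencing depth
#'
#' Simulates the same labeled library at several depths, fits growth
#' estimates, and compares them with the slope obtained from the exact
#' (infinite-depth) normalized trajectories of each member.
#'
#' @param depths Vector of per-sample depths.
#' @param n_members Library size.
#' @param seed Integer seed.
#' @return `data.frame` with `depth` and `median_abs_error`.
#' @export
slope_recovery_by_depth <- function(depths = c(1e3, 1e4, 1e5),
                                    n_members = 200L, seed = 1L) {
  members <- plant_ground_truth(generate_random_inserts(n_members, seed = seed))
  design0 <- screen_design()
  y_exact <- expected_trajectories(members, design0)
  tps <- design0$time_points
  target <- apply(y_exact, 1, function(y) fit_growth(tps, y)$slope)
  out <- lapply(seq_along(depths), function(i) {
    design <- screen_design(depth = depths[i])
    counts <- simulate_screen(members, design, seed = seed + i)
    norm <- normalize_counts(counts)
    fits <- fit_growth_table(norm)
    err <- abs(fits$slope - target[fits$id])
    data.frame(depth = depths[i], median_abs_error = median(err),
               n_fit = nrow(fits))
  })
  do.call(rbind, out)
}
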