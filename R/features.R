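#' Peptide feature framework: encode, view, aggregate
#'
#' Every feature is defined by a numerical encoding of residues (a scale,
#' a group membership, or a pattern), a view of the sequence (the full
#' sequence or sliding windows), and an aggregator (count, sum, mean, max,
#' min, presence). The default catalog enumerates 146 features in eight
#' named sets.
#'
#' @name sequence_features
NULL

#' Single amino-acid composition
#'
#' @param peptide Non-empty peptide over the 20 standard residues.
#' @return Named vector of 20 residue fractions in the fixed order
#'   IVLAFWYGSPKRHDETQNCM; sums to 1.
#' @export
aa_composition <- function(peptide) {
  .check_peptide(peptide)
  if (!nchar(peptide)) stop("empty peptide", call. = FALSE)
  chars <- strsplit(peptide, "")[[1]]
  counts <- vapply(AA_ORDER, function(a) sum(chars == a), 0L)
  counts / length(chars)
}

#' Grouped amino-acid composition
#'
#' Groups overlap (e.g. Y is aromatic, polar and phosphorylatable), so the
#' 11 fractions need not sum to 1.
#'
#' @inheritParams aa_composition
#' @return Named vector of 11 group fractions.
#' @export
group_composition <- function(peptide) {
  .check_peptide(peptide)
  if (!nchar(peptide)) stop("empty peptide", call. = FALSE)
  chars <- strsplit(peptide, "")[[1]]
  vapply(AA_GROUPS, function(g) mean(chars %in% g), 0)
}

#' Regular expression for a degenerate mini-motif
#'
#' One residue of `group1`, a gap of `min_gap`..`max_gap` arbitrary
#' residues, then one residue of `group2`.
#'
#' @param group1,group2 Names among negative, positive, aromatic, polar,
#'   nonpolar.
#' @param min_gap,max_gap Gap bounds in residues.
#' @return Pattern string.
#' @export
minimotif_pattern <- function(group1, group2, min_gap = 0L, max_gap = 10L) {
  g1 <- paste(MINIMOTIF_GROUPS[[group1]], collapse = "")
  g2 <- paste(MINIMOTIF_GROUPS[[group2]], collapse = "")
  sprintf("[%s].{%d,%d}[%s]", g1, min_gap, max_gap, g2)
}

#' Mini-motif feature value
#'
#' `presence` is 1 iff the pattern matches anywhere. `count` enumerates all
#' ordered residue pairs (i in group1, j in group2, j > i) whose gap
#' j - i - 1 lies in [min_gap, max_gap]; overlapping occurrences all count
#' ("DFDF" has 3 negative->aromatic pairs at gap <= 10).
#'
#' @inheritParams minimotif_pattern
#' @param peptide Peptide string.
#' @param aggregator `"presence"` or `"count"`.
#' @return Numeric feature value.
#' @export
minimotif_feature <- function(peptide, group1, group2, min_gap = 0L,
                              max_gap = 10L, aggregator = c("presence", "count")) {
  aggregator <- match.arg(aggregator)
  chars <- strsplit(peptide, "")[[1]]
  if (aggregator == "presence") {
    return(as.numeric(grepl(minimotif_pattern(group1, group2, min_gap, max_gap),
                            peptide)))
  }
  i <- which(chars %in% MINIMOTIF_GROUPS[[group1]])
  j <- which(chars %in% MINIMOTIF_GROUPS[[group2]])
  if (!length(i) || !length(j)) return(0)
  gaps <- outer(j, i, `-`) - 1L
  sum(gaps >= min_gap & gaps <= max_gap)
}

#' Load the bundled 9aaTAD patterns
#'
#' Four regular expressions of decreasing stringency describing the
#' nine-residue transactivation-domain motif. The shipped file is a
#' reconstruction from the published positional residue preferences (the
#' original web resource is not redistributable), hence its `_synthetic`
#' name; users can substitute their own pattern file.
#'
#' @param path Pattern file (one regex per line, `#` comments allowed).
#' @return Character vector of 4 patterns.
#' @export
load_ninetad_patterns <- function(path = system.file(
  "extdata", "ninetad_patterns_synthetic.txt", package = "idrscreen")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("config error: 9aaTAD pattern file not found", call. = FALSE)
  }
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  if (length(lines) != 4L) {
    stop("config error: expected 4 patterns, got ", length(lines), call. = FALSE)
  }
  lines
}

#' Presence of the 9aaTAD motif
#'
#' @param peptide Peptide string.
#' @param patterns Four regular expressions (default: bundled file).
#' @return 1 if any pattern matches, else 0.
#' @export
nine_aa_tad <- function(peptide, patterns = load_ninetad_patterns()) {
  as.numeric(any(vapply(patterns, grepl, logical(1), x = peptide)))
}

#' Isoelectric point by bisection on the net-charge curve
#'
#' Henderson-Hasselbalch net charge with the EMBOSS pKa set (free N/C
#' termini plus K, R, H positive and D, E, C, Y negative side chains);
#' bisection on pH 0..14 until |net charge| < 1e-4 (at most 100
#' iterations).
#'
#' @inheritParams aa_composition
#' @return pI estimate.
#' @export
compute_pi <- function(peptide) {
  .check_peptide(peptide)
  if (!nchar(peptide)) stop("empty peptide", call. = FALSE)
  chars <- strsplit(peptide, "")[[1]]
  pos_k <- c(PKA_EMBOSS$nterm, PKA_EMBOSS$positive[
    chars[chars %in% names(PKA_EMBOSS$positive)]])
  neg_k <- c(PKA_EMBOSS$cterm, PKA_EMBOSS$negative[
    chars[chars %in% names(PKA_EMBOSS$negative)]])
  charge <- function(ph) {
    sum(1 / (1 + 10^(ph - pos_k))) - sum(1 / (1 + 10^(neg_k - ph)))
  }
  lo <- 0; hi <- 14
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    q <- charge(mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Scalar physicochemical properties of a peptide
#'
#' @inheritParams aa_composition
#' @return List with `length`, `molecular_weight` (Da, average masses),
#'   `pi` (isoelectric point), `hydrophobic_fraction` (fraction VILFWCM),
#'   `disorder_proxy` (min-max-normalized mean TOP-IDP propensity) and
#'   `helicity_proxy` (normalized mean helix propensity; higher = more
#'   helical).
#' @export
scalar_properties <- function(peptide) {
  .check_peptide(peptide)
  if (!nchar(peptide)) stop("empty peptide", call. = FALSE)
  chars <- strsplit(peptide, "")[[1]]
  list(
    length = length(chars),
    molecular_weight = sum(AA_MASS[chars]) + WATER_MASS,
    pi = compute_pi(peptide),
    hydrophobic_fraction = mean(chars %in% AA_GROUPS$hydrophobic),
    disorder_proxy = mean(SCALE_DISORDER01[chars]),
    helicity_proxy = mean(SCALE_HELICITY01[chars])
  )
}

# window means of a residue scale; peptides shorter than the window give a
# single whole-sequence window
.window_means <- function(chars, scale, window) {
  v <- scale[chars]
  n <- length(v)
  if (n <= window) return(mean(v))
  vapply(seq_len(n - window + 1L), function(i) mean(v[i:(i + window - 1L)]), 0)
}

#' The default 146-feature catalog
#'
#' Reads the bundled catalog file and validates it: exactly 146 unique
#' feature ids over the eight named feature sets, including the always-kept
#' legacy features (length, pI, hydrophobic fraction, disorder, helicity,
#' 9aaTAD presence).
#'
#' @param path Catalog TSV (feature_id, feature_set, encoding, view,
#'   aggregator, payload).
#' @return `data.frame` catalog.
#' @export
build_default_catalog <- function(path = system.file(
  "extdata", "feature_catalog.tsv", package = "idrscreen")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("config error: catalog file not found", call. = FALSE)
  }
  cat_df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "feature_set", "encoding", "view", "aggregator",
            "payload")
  if (!all(need %in% names(cat_df))) {
    stop("config error: catalog is missing columns", call. = FALSE)
  }
  if (anyDuplicated(cat_df$feature_id)) {
    stop("config error: duplicated feature ids in catalog", call. = FALSE)
  }
  sets <- c("aa_composition", "group_composition", "minimotif", "ninetad",
            "disorder", "helicity", "general", "pi")
  if (!setequal(unique(cat_df$feature_set), sets)) {
    stop("config error: catalog feature sets malformed", call. = FALSE)
  }
  if (nrow(cat_df) != 146L) {
    stop("config error: catalog must have 146 features, has ", nrow(cat_df),
         call. = FALSE)
  }
  legacy <- c("length", "isoelectric_point", "hydrophobic_fraction",
              "disorder_mean", "helicity_mean", "ninetad_presence")
  if (!all(legacy %in% cat_df$feature_id)) {
    stop("config error: catalog is missing legacy features", call. = FALSE)
  }
  cat_df
}

#' Compute one catalog feature for one peptide
#'
#' @param peptide Peptide string (length >= 1, standard residues).
#' @param def One catalog row (list or single-row data.frame).
#' @param ninetad_patterns Patterns used by the 9aaTAD feature.
#' @return Numeric feature value.
#' @export
compute_feature <- function(peptide, def,
                            ninetad_patterns = load_ninetad_patterns()) {
  .check_peptide(peptide)
  if (!nchar(peptide)) stop("empty peptide", call. = FALSE)
  chars <- strsplit(peptide, "")[[1]]
  set <- def$feature_set
  if (set == "aa_composition") {
    return(mean(chars == def$payload))
  }
  if (set == "group_composition") {
    return(mean(chars %in% strsplit(def$payload, "")[[1]]))
  }
  if (set == "minimotif") {
    p <- strsplit(def$payload, "|", fixed = TRUE)[[1]]
    return(minimotif_feature(peptide, p[1], p[2], as.integer(p[3]),
                             as.integer(p[4]), def$aggregator))
  }
  if (set == "ninetad") {
    return(nine_aa_tad(peptide, ninetad_patterns))
  }
  if (set %in% c("disorder", "helicity")) {
    scale <- if (set == "disorder") SCALE_DISORDER01 else SCALE_HELICITY01
    if (def$view == "full") {
      return(mean(scale[chars]))
    }
    w <- as.integer(sub("^w", "", def$view))
    wm <- .window_means(chars, scale, w)
    return(switch(def$aggregator, max = max(wm), min = min(wm), mean = mean(wm)))
  }
  if (set == "general") {
    sp <- switch(def$payload,
      length = length(chars),
      molecular_weight = sum(AA_MASS[chars]) + WATER_MASS,
      hydrophobic_fraction = mean(chars %in% AA_GROUPS$hydrophobic)
    )
    return(sp)
  }
  if (set == "pi") {
    return(compute_pi(peptide))
  }
  stop("unknown feature set: ", set, call. = FALSE)
}

#' Feature matrix for a set of peptides
#'
#' @param peptides Character vector of peptides (length >= 1 each).
#' @param catalog Catalog from [build_default_catalog()].
#' @return Numeric matrix, rows = peptides, columns = feature ids.
#' @export
featurize <- function(peptides, catalog = build_default_catalog()) {
  pats <- load_ninetad_patterns()
  defs <- split(catalog, seq_len(nrow(catalog)))
  out <- vapply(peptides, function(p) {
    vapply(defs, function(d) compute_feature(p, d, pats), 0)
  }, numeric(nrow(catalog)))
  out <- t(out)
  dimnames(out) <- list(peptides, catalog$feature_id)
  rownames(out) <- NULL
  out
}

#' Amino-acid enrichment between functional and nonfunctional sets
#'
#' log2 of per-residue frequencies in the functional set over the
#' nonfunctional set, with 0.5 added to every raw count before frequency
#' computation so that unseen residues stay finite.
#'
#' @param functional,nonfunctional Character vectors of peptides.
#' @return Named vector of 20 log2 ratios (order IVLAFWYGSPKRHDETQNCM).
#' @export
aa_enrichment <- function(functional, nonfunctional) {
  if (!length(functional) || !length(nonfunctional)) {
    stop("empty peptide set", call. = FALSE)
  }
  count_set <- function(peps) {
    chars <- strsplit(paste(peps, collapse = ""), "")[[1]]
    vapply(AA_ORDER, function(a) sum(chars == a), 0L)
  }
  f <- count_set(functional) + 0.5
  n <- count_set(nonfunctional) + 0.5
  log2((f / sum(f)) / (n / sum(n)))
}

#' Motif enrichment odds ratio
#'
#' (with/without in the functional set) over (with/without in the
#' nonfunctional set).
#'
#' @param with_pos,without_pos,with_neg,without_neg Counts.
#' @return Odds ratio.
#' @export
motif_enrichment <- function(with_pos, without_pos, with_neg, without_neg) {
  if (without_pos == 0 || without_neg == 0 || with_neg == 0) {
    stop("zero denominator in motif enrichment", call. = FALSE)
  }
  (with_pos / without_pos) / (with_neg / without_neg)
}

#' Compare a property between functional and nonfunctional sequences
#'
#' Two-sided Wilcoxon rank-sum test (exact for small tie-free samples,
#' tie-corrected normal approximation otherwise) plus the difference of
#' medians.
#'
#' @param values_pos,values_neg Numeric samples.
#' @return List with `statistic` (U), `p_value`, `median_difference`
#'   (pos - neg).
#' @export
compare_distributions <- function(values_pos, values_neg) {
  stopifnot(length(values_pos) >= 1, length(values_neg) >= 1)
  wt <- suppressWarnings(wilcox.test(values_pos, values_neg))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_difference = median(values_pos) - median(values_neg))
}
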