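#' Mutational-tolerance analytics for designed TAD variant libraries
#'
#' @name screen_analysis
NULL

#' Tolerance score of one TAD set
#'
#' Fraction of labeled variants that are functional; `missing` labels are
#' excluded from numerator and denominator.
#'
#' @param labels Variant labels (`"functional"`, `"nonfunctional"`,
#'   `"missing"`).
#' @return Fraction in [0, 1].
#' @export
tolerance_score <- function(labels) {
  labeled <- labels[labels != "missing"]
  if (!length(labeled)) stop("undefined: zero labeled variants", call. = FALSE)
  mean(labeled == "functional")
}

#' Substitution-tolerance matrix pooled across TAD sets
#'
#' Cell (substituted-into residue, wild-type residue) is the fraction of
#' functional variants among all observed variants with that substitution
#' pair; unobserved pairs stay NA (not 0). Rows and columns are ordered by
#' decreasing mean of their observed cells.
#'
#' @param variants `data.frame` with `wt_aa`, `sub_aa`, `label`.
#' @return Numeric matrix (rows = substituted-into, columns = wild-type
#'   residue), NA for unobserved pairs.
#' @export
substitution_matrix <- function(variants) {
  v <- variants[variants$label != "missing", , drop = FALSE]
  wt_res <- sort(unique(v$wt_aa))
  sub_res <- sort(unique(v$sub_aa))
  m <- matrix(NA_real_, length(sub_res), length(wt_res),
              dimnames = list(sub_res, wt_res))
  for (s in sub_res) {
    for (w in wt_res) {
      sel <- v$wt_aa == w & v$sub_aa == s
      if (any(sel)) m[s, w] <- mean(v$label[sel] == "functional")
    }
  }
  row_tol <- rowMeans(m, na.rm = TRUE)
  col_tol <- colMeans(m, na.rm = TRUE)
  m[order(-row_tol), order(-col_tol), drop = FALSE]
}

#' Parse and apply a point-variant notation such as "W30R"
#'
#' @param notation String `<wt_aa><position><sub_aa>` (1-based).
#' @param wt_peptide Reference peptide the position refers to.
#' @param offset Added to the parsed position before indexing, for
#'   protein-coordinate notations applied to an excised domain (default 0).
#' @return List with `wt_aa`, `position` (as parsed), `sub_aa`, `mutated`
#'   peptide, and `identity` (TRUE for no-op substitutions like "A5A").
#' @export
parse_apply_variant <- function(notation, wt_peptide, offset = 0L) {
  m <- regexec("^([A-Y])([0-9]+)([A-Y])$", notation)[[1]]
  if (m[1] == -1L) stop("parse error: malformed variant '", notation, "'",
                        call. = FALSE)
  parts <- regmatches(notation, regexec("^([A-Y])([0-9]+)([A-Y])$", notation))[[1]]
  wt_aa <- parts[2]; pos <- as.integer(parts[3]); sub_aa <- parts[4]
  .check_peptide(wt_aa, "variant notation")
  .check_peptide(sub_aa, "variant notation")
  local_pos <- pos + offset
  if (local_pos < 1L || local_pos > nchar(wt_peptide)) {
    stop("validation error: position ", pos, " outside peptide", call. = FALSE)
  }
  at <- substring(wt_peptide, local_pos, local_pos)
  if (at != wt_aa) {
    stop("validation error: expected ", wt_aa, " at position ", pos,
         ", found ", at, call. = FALSE)
  }
  mutated <- wt_peptide
  substring(mutated, local_pos, local_pos) <- sub_aa
  list(wt_aa = wt_aa, position = pos, sub_aa = sub_aa, mutated = mutated,
       identity = wt_aa == sub_aa)
}

#' Per-TAD tolerance table from a labeled variant data frame
#'
#' @param variants `data.frame` with `tad_set_id` and `label`.
#' @return `data.frame` with `tad_set_id`, `n_labeled`, `tolerance`.
#' @export
tolerance_table <- function(variants) {
  ids <- unique(variants$tad_set_id)
  out <- do.call(rbind, lapply(ids, function(i) {
    lab <- variants$label[variants$tad_set_id == i]
    data.frame(tad_set_id = i, n_labeled = sum(lab != "missing"),
               tolerance = tolerance_score(lab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
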