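#' Synthetic growth-selection screen
#'
#' The simulator generates sequence libraries with hidden functional labels
#' and time-course sequencing counts with the statistical structure the
#' downstream analysis assumes: exponential clone growth, multinomial
#' sampling at a fixed per-sample depth, and optional read emission with
#' per-base substitution errors.
#'
#' @name synthetic_screen
NULL

#' Screen design parameters
#'
#' @param time_points Sampling days, strictly increasing from 0.
#' @param n_replicates Replicates per time point (3 for the random-library
#'   protocol, 6 barcode replicates for the design-library protocol).
#' @param depth Reads per (time point, replicate) sample.
#' @param substitution_error_rate Per-base substitution probability used when
#'   emitting reads; must be in [0, 0.1).
#' @param abundance Initial clone abundance model, `"uniform"` or
#'   `"lognormal"` (sdlog 1).
#' @return A `screen_design` list.
#' @export
screen_design <- function(time_points = c(0, 2, 4, 6, 8), n_replicates = 3L,
                          depth = 10000L, substitution_error_rate = 0,
                          abundance = c("uniform", "lognormal")) {
  stopifnot(
    length(time_points) >= 2L, time_points[1] == 0,
    all(diff(time_points) > 0),
    depth >= 1, n_replicates >= 1,
    substitution_error_rate >= 0, substitution_error_rate < 0.1
  )
  structure(list(
    time_points = time_points, n_replicates = as.integer(n_replicates),
    depth = as.integer(depth),
    substitution_error_rate = substitution_error_rate,
    abundance = match.arg(abundance)
  ), class = "screen_design")
}

#' Planted functionality rule
#'
#' A peptide is planted functional iff it carries at least `min_acidic`
#' acidic (D/E) residues, at least `min_aromatic` aromatic (F/W/Y) residues,
#' and at most `max_positive` positively charged (K/R/H) residues. The rule
#' mirrors the acidic-plus-aromatic, positive-charge-depleted signature of
#' functional transactivation domains, so downstream feature-importance
#' recovery can be checked against a known answer.
#'
#' @param min_acidic,min_aromatic,max_positive Integer thresholds.
#' @param g_functional,g_nonfunctional Planted clone growth rates (per day);
#'   `g_functional` must exceed `g_nonfunctional`.
#' @return A `ground_truth_rule` list.
#' @export
ground_truth_rule <- function(min_acidic = 2L, min_aromatic = 1L,
                              max_positive = 0L, g_functional = 0.4,
                              g_nonfunctional = -0.4) {
  stopifnot(g_functional > g_nonfunctional)
  structure(list(
    min_acidic = min_acidic, min_aromatic = min_aromatic,
    max_positive = max_positive, g_functional = g_functional,
    g_nonfunctional = g_nonfunctional
  ), class = "ground_truth_rule")
}

#' Check that a 3' tail contains a stop codon in all three reading frames
#'
#' @param tail Nucleotide string over ACGT.
#' @return TRUE iff each of the three frames of the tail contains a complete
#'   stop codon (TAA/TAG/TGA).
#' @export
validate_stop_tail <- function(tail) {
  .check_dna(tail, "stop tail")
  all(vapply(0:2, function(off) {
    any(.codons(substring(tail, off + 1L)) %in% STOP_CODONS)
  }, logical(1)))
}

# default emitted tail; has TAA in all three frames
DEFAULT_STOP_TAIL <- "TAATTAATTAA"

.new_member <- function(member_id, insert_dna, origin, tad_set_id = NA_character_,
                        barcode = NA_character_) {
  tr <- translate_insert(insert_dna)
  list(
    member_id = member_id, insert_dna = insert_dna, peptide = tr$peptide,
    starts_with_stop = tr$starts_with_stop, origin = origin,
    tad_set_id = tad_set_id, barcode = barcode,
    true_class = NA_character_, true_growth_rate = NA_real_
  )
}

#' Generate a random insert library
#'
#' Uniform-random inserts of fixed length (default 60 nt, hence peptides of
#' at most 20 residues after stop truncation).
#'
#' @param n Number of members.
#' @param length Insert length in nt; must be divisible by 3.
#' @param seed Integer seed.
#' @return List of library members.
#' @export
generate_random_inserts <- function(n, length = 60L, seed = 1L) {
  stopifnot(n >= 1)
  if (length %% 3L != 0L) {
    stop("config error: insert length must be divisible by 3", call. = FALSE)
  }
  withr_seed <- .local_seed(seed)
  on.exit(withr_seed())
  inserts <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, "")
  mapply(function(s, i) .new_member(sprintf("rand_%06d", i), s, "random"),
         inserts, seq_len(n), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# save/restore RNG state so generators are seeded but side-effect free
.local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate a designed variant library from wild-type peptides
#'
#' For each wild-type domain of length L, emits the wild type plus up to 5L
#' single-residue substitutions (A/G/P/K/R scans; identity substitutions are
#' skipped), each back-translated with a fixed codon table. Three stop-codon
#' control members (first codon TAA/TGA/TAG) are appended per library.
#'
#' @param wt_tads Named character vector or list of wild-type peptides
#'   (names are the TAD set ids), each 8-30 aa.
#' @param substitutions Residues scanned at every position.
#' @return List of library members (`origin` is `design_variant` or
#'   `stop_control`; variant members carry `tad_set_id`, `position`,
#'   `wt_aa`, `sub_aa`).
#' @export
generate_design_library <- function(wt_tads,
                                    substitutions = c("A", "G", "P", "K", "R")) {
  wt_tads <- unlist(wt_tads)
  stopifnot(length(wt_tads) >= 1, !is.null(names(wt_tads)))
  for (p in wt_tads) {
    .check_peptide(p, "wild-type TAD")
    stopifnot(nchar(p) >= 8L, nchar(p) <= 30L)
  }
  members <- list()
  for (tad_id in names(wt_tads)) {
    wt <- wt_tads[[tad_id]]
    m <- .new_member(paste0(tad_id, "_WT"), back_translate(wt), "design_variant",
                     tad_set_id = tad_id)
    m$position <- NA_integer_; m$wt_aa <- NA_character_; m$sub_aa <- NA_character_
    members[[length(members) + 1L]] <- m
    aa <- strsplit(wt, "")[[1]]
    for (pos in seq_along(aa)) {
      for (sub in substitutions) {
        if (aa[pos] == sub) next
        mut <- aa; mut[pos] <- sub
        m <- .new_member(sprintf("%s_%s%d%s", tad_id, aa[pos], pos, sub),
                         back_translate(paste(mut, collapse = "")),
                         "design_variant", tad_set_id = tad_id)
        m$position <- pos; m$wt_aa <- aa[pos]; m$sub_aa <- sub
        members[[length(members) + 1L]] <- m
      }
    }
  }
  filler <- back_translate(wt_tads[[1]])
  for (stop in c("TAA", "TGA", "TAG")) {
    m <- .new_member(paste0("stop_", stop), paste0(stop, filler), "stop_control")
    m$position <- NA_integer_; m$wt_aa <- NA_character_; m$sub_aa <- NA_character_
    members[[length(members) + 1L]] <- m
  }
  members
}

#' Generate replicate barcodes with a minimum pairwise Levenshtein distance
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt (default 8).
#' @param min_lev Minimum pairwise Levenshtein distance (default 4).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per barcode.
#' @return Character vector of barcodes.
#' @export
generate_barcodes <- function(n, length = 8L, min_lev = 4L, seed = 1L,
                              max_tries = 2000L) {
  stopifnot(n >= 1)
  restore <- .local_seed(seed)
  on.exit(restore())
  out <- character(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      if (!length(out) || all(adist(cand, out) >= min_lev)) {
        out <- c(out, cand); ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("capacity error: could not place barcode ", i,
           " at min distance ", min_lev, call. = FALSE)
    }
  }
  out
}

#' Apply the planted functionality rule to library members
#'
#' Stop-control members (and empty peptides) are always nonfunctional.
#'
#' @param members List of library members.
#' @param rule A [ground_truth_rule()].
#' @return Members with `true_class` and `true_growth_rate` filled in.
#' @export
plant_ground_truth <- function(members, rule = ground_truth_rule()) {
  lapply(members, function(m) {
    p <- m$peptide
    functional <- if (m$origin == "stop_control" || nchar(p) == 0L) {
      FALSE
    } else {
      chars <- strsplit(p, "")[[1]]
      sum(chars %in% c("D", "E")) >= rule$min_acidic &&
        sum(chars %in% c("F", "W", "Y")) >= rule$min_aromatic &&
        sum(chars %in% c("K", "R", "H")) <= rule$max_positive
    }
    m$true_class <- if (functional) "functional" else "nonfunctional"
    m$true_growth_rate <- if (functional) rule$g_functional else rule$g_nonfunctional
    m
  })
}

#' Simulate time-course sequencing counts for a labeled library
#'
#' Clone abundance follows a_i(t) = a_i(0) exp(r_i t); each (time point,
#' replicate) sample draws `depth` reads from a multinomial over the clone
#' proportions. Counts are noise-free at the sequence level (substitution
#' errors only enter via [emit_fastq()]).
#'
#' @param members Labeled members (see [plant_ground_truth()]).
#' @param design A [screen_design()].
#' @param seed Integer seed.
#' @return A `data.frame` count table with columns `member_id`, `sequence`,
#'   `time_day`, `replicate`, `count` (one row per member x sample).
#' @export
simulate_screen <- function(members, design = screen_design(), seed = 1L) {
  if (!length(members)) stop("empty member list", call. = FALSE)
  rates <- vapply(members, `[[`, 0, "true_growth_rate")
  if (anyNA(rates)) stop("members must be labeled with true_growth_rate", call. = FALSE)
  restore <- .local_seed(seed)
  on.exit(restore())
  n <- length(members)
  a0 <- switch(design$abundance,
    uniform = rep(1, n),
    lognormal = exp(rnorm(n, 0, 1))
  )
  ids <- vapply(members, `[[`, "", "member_id")
  seqs <- vapply(members, `[[`, "", "insert_dna")
  rows <- list()
  for (t in design$time_points) {
    prop <- a0 * exp(rates * t)
    prop <- prop / sum(prop)
    for (rep_i in seq_len(design$n_replicates)) {
      counts <- as.integer(rmultinom(1, design$depth, prop))
      rows[[length(rows) + 1L]] <- data.frame(
        member_id = ids, sequence = seqs, time_day = t, replicate = rep_i,
        count = counts, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected (infinite-depth) normalized trajectories for labeled members
#'
#' Closed-form clone proportions normalized to the day-0 value; the noiseless
#' input to the growth fit, used as the recovery target when measuring how
#' estimation error shrinks with sequencing depth.
#'
#' @inheritParams simulate_screen
#' @return Matrix (members x time points) of expected normalized values.
#' @export
expected_trajectories <- function(members, design = screen_design()) {
  rates <- vapply(members, `[[`, 0, "true_growth_rate")
  props <- sapply(design$time_points, function(t) {
    p <- exp(rates * t)
    p / sum(p)
  })
  y <- props / props[, 1]
  rownames(y) <- vapply(members, `[[`, "", "member_id")
  colnames(y) <- design$time_points
  y
}

#' Emit FASTQ-style reads for a simulated count table
#'
#' Each counted molecule becomes one read: optional 5' replicate barcode +
#' insert + stop tail (random-library construct) + 3' adaptor, with i.i.d.
#' per-base substitution errors and a constant Phred quality.
#'
#' @param counts Count table from [simulate_screen()].
#' @param design A [screen_design()].
#' @param barcodes Optional character vector, one barcode per replicate.
#' @param adaptor 3' adaptor appended to every read.
#' @param stop_tail Tail appended after the insert (set `""` to disable).
#' @param quality Constant Phred score for all bases.
#' @param seed Integer seed.
#' @return `data.frame` with `id`, `seq`, `qual` (Phred+33 string),
#'   `time_day`, `replicate`, `true_member`.
#' @export
emit_fastq <- function(counts, design = screen_design(), barcodes = NULL,
                       adaptor = "AGATCGGAAGAGCACACGTCT", stop_tail = DEFAULT_STOP_TAIL,
                       quality = 30L, seed = 1L) {
  restore <- .local_seed(seed)
  on.exit(restore())
  keep <- counts$count > 0
  counts <- counts[keep, , drop = FALSE]
  idx <- rep(seq_len(nrow(counts)), counts$count)
  bc <- if (is.null(barcodes)) "" else barcodes[counts$replicate[idx]]
  seqs <- paste0(bc, counts$sequence[idx], stop_tail, adaptor)
  err <- design$substitution_error_rate
  if (err > 0) {
    seqs <- vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      hit <- runif(length(chars)) < err
      if (any(hit)) {
        chars[hit] <- vapply(chars[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
      }
      paste(chars, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  data.frame(
    id = sprintf("read_%07d", seq_along(idx)),
    seq = seqs,
    qual = vapply(nchar(seqs), function(n) {
      paste(rep(rawToChar(as.raw(quality + 33L)), n), collapse = "")
    }, ""),
    time_day = counts$time_day[idx],
    replicate = counts$replicate[idx],
    true_member = counts$member_id[idx],
    stringsAsFactors = FALSE
  )
}
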