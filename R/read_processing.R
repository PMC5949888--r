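#' Read preprocessing: from raw reads to a per-centroid count table
#'
#' The processing stage resembles amplicon/metagenomics pipelines: merge
#' read pairs, filter on expected errors, demultiplex replicate barcodes,
#' trim adaptors, dereplicate, greedy-cluster at a sequence-identity
#' threshold, and map all reads back to the centroids.
#'
#' @name read_processing
NULL

#' Levenshtein edit distance
#'
#' Number of substitutions, insertions and deletions needed to turn `a`
#' into `b`.
#'
#' @param a,b Character strings.
#' @return Integer distance.
#' @export
levenshtein <- function(a, b) {
  as.integer(adist(a, b))
}

#' Expected sequencing errors of a read
#'
#' @param quals Integer vector of per-base Phred scores.
#' @return Sum over bases of 10^(-Q/10).
#' @export
expected_errors <- function(quals) {
  if (!length(quals)) return(0)
  stopifnot(all(quals >= 0), all(quals <= 60))
  sum(10^(-quals / 10))
}

#' Expected-error read filter
#'
#' @param quals Per-base Phred scores.
#' @param max_ee Maximum tolerated expected errors (default 1).
#' @return TRUE iff the read passes.
#' @export
ee_filter <- function(quals, max_ee = 1.0) {
  expected_errors(quals) <= max_ee
}

.phred_from_string <- function(q) {
  as.integer(charToRaw(q)) - 33L
}

#' Merge a forward/reverse read pair over their overlap
#'
#' The reverse read is reverse-complemented and overlap-aligned against the
#' forward read (match +1, mismatch -1, gap -2). Disagreements in the overlap
#' are resolved toward the higher-quality base. The merge is accepted only if
#' the merged length equals `target_len` and the overlap alignment contains
#' at most `max_gaps` gap columns.
#'
#' @param fwd,rev Lists with `seq` and integer `quals` (rev as sequenced,
#'   reverse strand).
#' @param target_len Required merged length (default 60).
#' @param max_gaps Maximum gap columns tolerated in the overlap alignment.
#' @param min_overlap Minimum overlap width to accept at all.
#' @return List with `merged` (string or NA) and `reason`
#'   (`"ok"`, `"no_overlap"`, `"bad_length"`, `"too_many_gaps"`).
#' @export
merge_pairs <- function(fwd, rev, target_len = 60L, max_gaps = 2L,
                        min_overlap = 10L) {
  rc_seq <- .revcomp(rev$seq)
  rc_qual <- rev(rev$quals)
  aln <- Biostrings::pairwiseAlignment(
    pattern = rc_seq, subject = fwd$seq, type = "overlap",
    substitutionMatrix = .nuc_submat(), gapOpening = 0, gapExtension = 2
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sub_start <- Biostrings::subject(aln)@range@start
  pat_start <- Biostrings::pattern(aln)@range@start
  width <- length(pa)
  if (width < min_overlap || Biostrings::score(aln) <= 0) {
    return(list(merged = NA_character_, reason = "no_overlap"))
  }
  n_gaps <- sum(pa == "-") + sum(sa == "-")
  if (n_gaps > max_gaps) {
    return(list(merged = NA_character_, reason = "too_many_gaps"))
  }
  # consensus over the aligned overlap: higher-quality base wins
  sub_pos <- cumsum(sa != "-") + sub_start - 1L
  pat_pos <- cumsum(pa != "-") + pat_start - 1L
  cons <- character(width)
  for (i in seq_len(width)) {
    if (sa[i] == "-") {
      cons[i] <- pa[i]
    } else if (pa[i] == "-") {
      cons[i] <- sa[i]
    } else if (pa[i] == sa[i]) {
      cons[i] <- sa[i]
    } else {
      qf <- fwd$quals[sub_pos[i]]
      qr <- rc_qual[pat_pos[i]]
      cons[i] <- if (qf >= qr) sa[i] else pa[i]
    }
  }
  prefix <- substring(fwd$seq, 1L, sub_start - 1L)
  pat_end <- pat_pos[width]
  suffix <- substring(rc_seq, pat_end + 1L)
  merged <- paste0(prefix, paste(cons, collapse = ""), suffix)
  if (nchar(merged) != target_len) {
    return(list(merged = NA_character_, reason = "bad_length"))
  }
  list(merged = merged, reason = "ok")
}

.nuc_submat <- function(match = 1, mismatch = -1) {
  alpha <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(alpha, alpha))
  diag(m) <- match
  m
}

#' Assign a replicate barcode to the 5' end of a read
#'
#' Prefix-anchored Levenshtein matching: the read prefix (lengths within
#' `max_err` of the barcode length) is compared against every barcode; the
#' barcode minimizing the distance is assigned when that distance is at most
#' `max_err` (default floor(0.25 x barcode length), i.e. 2 errors for 8-nt
#' barcodes). Ties between two barcodes leave the read unassigned.
#'
#' @param seq Read sequence.
#' @param barcodes Character vector of equal-length barcodes.
#' @param max_err Maximum tolerated edit distance within the barcode.
#' @return List with `barcode_index` (integer or NA), `distance`, and `rest`
#'   (read with the matched prefix stripped; NA when unassigned).
#' @export
assign_barcode <- function(seq, barcodes,
                           max_err = floor(0.25 * nchar(barcodes[1]))) {
  bl <- nchar(barcodes[1])
  stopifnot(all(nchar(barcodes) == bl))
  lens <- max(1L, bl - max_err):min(nchar(seq), bl + max_err)
  prefixes <- substring(seq, 1L, lens)
  d <- adist(barcodes, prefixes) # barcodes x prefix-lengths
  best_per_bc <- apply(d, 1L, min)
  dmin <- min(best_per_bc)
  if (dmin > max_err || sum(best_per_bc == dmin) > 1L) {
    return(list(barcode_index = NA_integer_, distance = dmin, rest = NA_character_))
  }
  bi <- which(best_per_bc == dmin)
  cand_lens <- lens[d[bi, ] == dmin]
  strip <- cand_lens[which.min(abs(cand_lens - bl))]
  list(barcode_index = bi, distance = dmin, rest = substring(seq, strip + 1L))
}

#' Locate and trim an adaptor, tolerating a bounded edit rate
#'
#' The adaptor is located anywhere in the read allowing up to
#' `floor(err_rate * nchar(adaptor))` edits (2 for a 21-nt adaptor at 10%);
#' the match and everything downstream of it are removed. Reads without a
#' locatable adaptor are dropped.
#'
#' @param seq Read sequence.
#' @param adaptor Adaptor sequence (21 nt in the screen protocol).
#' @param err_rate Tolerated edit fraction within the adaptor.
#' @return List with `trimmed` (string or NA) and `reason` (`"ok"` or
#'   `"no_adaptor"`).
#' @export
trim_adaptor <- function(seq, adaptor, err_rate = 0.10) {
  max_err <- floor(err_rate * nchar(adaptor))
  m <- aregexec(adaptor, seq, max.distance = max_err, fixed = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(trimmed = NA_character_, reason = "no_adaptor"))
  }
  list(trimmed = substring(seq, 1L, m[1] - 1L), reason = "ok")
}

# strip a 3'-terminal construct tail, tolerating ~10% edits (the tail sits
# between insert and adaptor, so sequencing errors in it must not leave
# length-shifted sequences behind)
.trim_tail <- function(seq, tail, max_err = max(1L, floor(0.1 * nchar(tail)))) {
  m <- aregexec(tail, seq, max.distance = max_err, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(seq)
  m_end <- m[1] + attr(m, "match.length") - 1L
  if (m_end >= nchar(seq) - 1L) substring(seq, 1L, m[1] - 1L) else seq
}

#' Dereplicate reads into unique sequences with counts
#'
#' @param seqs Character vector of sequences.
#' @param min_count Minimum count to keep a unique sequence (default 2).
#' @return `data.frame` with `sequence` and `count`, count-descending,
#'   ties broken lexicographically.
#' @export
dereplicate <- function(seqs, min_count = 2L) {
  if (!length(seqs)) {
    return(data.frame(sequence = character(0), count = integer(0)))
  }
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$count >= min_count, , drop = FALSE]
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global pairwise sequence identity
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' gap -2 (linear); identity is matching columns over all alignment
#' columns, terminal gaps included. Among equal-score alignments the one
#' with the most matches (then fewest columns) defines the identity, so
#' the value does not depend on traceback order.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence", call. = FALSE)
  .identity_many(a, b)
}

# vectorized global identity of many sequences against one reference
.identity_many <- function(seqs, ref) {
  .nw_identity_many(seqs, ref)
}

#' Greedy abundance-ordered centroid clustering
#'
#' Dereplicated sequences are visited in decreasing-count order (ties
#' lexicographic); each joins the first existing centroid with identity at
#' least `id_threshold`, otherwise founds a new centroid.
#'
#' @param dereps `data.frame` from [dereplicate()].
#' @param id_threshold Minimum identity to join a centroid (default 0.90).
#' @return `data.frame` with `centroid`, `member_count` (summed read counts)
#'   and `n_members` (unique sequences absorbed).
#' @export
greedy_cluster <- function(dereps, id_threshold = 0.90) {
  dereps <- dereps[order(-dereps$count, dereps$sequence), , drop = FALSE]
  centroids <- character(0)
  member_count <- integer(0)
  n_members <- integer(0)
  for (i in seq_len(nrow(dereps))) {
    s <- dereps$sequence[i]
    cnt <- dereps$count[i]
    assigned <- FALSE
    if (length(centroids)) {
      hits <- which(.identity_many(centroids, s) >= id_threshold)
      if (length(hits)) {
        j <- hits[1] # first (most abundant) matching centroid wins
        member_count[j] <- member_count[j] + cnt
        n_members[j] <- n_members[j] + 1L
        assigned <- TRUE
      }
    }
    if (!assigned) {
      centroids <- c(centroids, s)
      member_count <- c(member_count, cnt)
      n_members <- c(n_members, 1L)
    }
  }
  data.frame(centroid = centroids, member_count = member_count,
             n_members = n_members, stringsAsFactors = FALSE)
}

#' Map reads to their closest centroid and tabulate counts per sample
#'
#' Each read is assigned to the centroid with highest global identity when
#' that identity reaches `id_threshold` (0.90 for de-novo random-library
#' centroids, 0.80 when mapping against a designed reference).
#'
#' @param reads `data.frame` with `seq`, `time_day`, `replicate`.
#' @param centroids Character vector of centroid sequences.
#' @param id_threshold Minimum identity for assignment.
#' @return List with `counts` (`data.frame`: `sequence`, `time_day`,
#'   `replicate`, `count`) and `n_unmapped`.
#' @export
map_reads <- function(reads, centroids, id_threshold = 0.90) {
  uniq <- unique(reads$seq)
  id_mat <- vapply(centroids, function(ctr) .identity_many(uniq, ctr),
                   numeric(length(uniq)))
  id_mat <- matrix(id_mat, nrow = length(uniq))
  best <- max.col(id_mat, ties.method = "first")
  best_id <- id_mat[cbind(seq_along(uniq), best)]
  assign_of <- setNames(ifelse(best_id >= id_threshold, centroids[best],
                               NA_character_), uniq)
  hit <- assign_of[reads$seq]
  mapped <- !is.na(hit)
  if (!any(mapped)) {
    return(list(counts = data.frame(sequence = character(0),
                                    time_day = numeric(0),
                                    replicate = integer(0),
                                    count = integer(0)),
                n_unmapped = sum(!mapped)))
  }
  agg <- stats::aggregate(
    list(count = rep(1L, sum(mapped))),
    by = list(sequence = hit[mapped], time_day = reads$time_day[mapped],
              replicate = reads$replicate[mapped]),
    FUN = sum
  )
  list(counts = agg, n_unmapped = sum(!mapped))
}

#' Run the full read-processing stage on emitted reads
#'
#' Applies, in order: expected-error filtering, optional barcode
#' demultiplexing (design mode), adaptor trimming, stop-tail removal,
#' dereplication, greedy clustering (random mode) or use of the designed
#' reference (design mode), and read mapping. Per-stage read counts are
#' returned so that reads in = mapped + unmapped + rejected at each stage.
#'
#' @param reads `data.frame` from [emit_fastq()] (columns `seq`, `qual`,
#'   `time_day`, `replicate`).
#' @param mode `"random"` (de-novo centroids, identity 0.90) or `"design"`
#'   (map to `reference`, identity 0.80).
#' @param barcodes Barcode vector for design mode (position = replicate).
#' @param reference Designed centroid sequences (design mode).
#' @param adaptor 3' adaptor to trim.
#' @param stop_tail Construct tail removed after adaptor trimming.
#' @param max_ee,min_derep_count,id_threshold Stage parameters.
#' @return List with `counts`, `centroids`, and `stage_counts`.
#' @export
process_reads <- function(reads, mode = c("random", "design"), barcodes = NULL,
                          reference = NULL,
                          adaptor = "AGATCGGAAGAGCACACGTCT",
                          stop_tail = DEFAULT_STOP_TAIL,
                          max_ee = 1.0, min_derep_count = 2L,
                          id_threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(id_threshold)) id_threshold <- if (mode == "design") 0.80 else 0.90
  n_in <- nrow(reads)
  keep <- vapply(reads$qual, function(q) ee_filter(.phred_from_string(q), max_ee),
                 logical(1), USE.NAMES = FALSE)
  n_ee_reject <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]

  n_unassigned <- 0L
  if (mode == "design") {
    if (is.null(barcodes)) stop("design mode requires barcodes", call. = FALSE)
    res <- lapply(reads$seq, assign_barcode, barcodes = barcodes)
    bc <- vapply(res, `[[`, 0L, "barcode_index")
    ok <- !is.na(bc)
    n_unassigned <- sum(!ok)
    reads <- reads[ok, , drop = FALSE]
    reads$replicate <- bc[ok]
    reads$seq <- vapply(res[ok], `[[`, "", "rest")
  }

  trimmed <- lapply(reads$seq, trim_adaptor, adaptor = adaptor)
  ok <- vapply(trimmed, function(x) x$reason == "ok", logical(1))
  n_no_adaptor <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  reads$seq <- vapply(trimmed[ok], `[[`, "", "trimmed")
  if (nzchar(stop_tail)) {
    reads$seq <- vapply(reads$seq, .trim_tail, "", tail = stop_tail,
                        USE.NAMES = FALSE)
  }

  dereps <- dereplicate(reads$seq, min_count = min_derep_count)
  centroids <- if (mode == "design") {
    reference
  } else {
    greedy_cluster(dereps, id_threshold = id_threshold)$centroid
  }
  mapped <- map_reads(reads, centroids, id_threshold = id_threshold)
  list(
    counts = mapped$counts,
    centroids = centroids,
    stage_counts = c(
      input = n_in, ee_rejected = n_ee_reject,
      barcode_unassigned = n_unassigned, no_adaptor = n_no_adaptor,
      mapped = sum(mapped$counts$count), unmapped = mapped$n_unmapped
    )
  )
}
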