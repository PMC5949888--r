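rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("levenshtein agrees with the DP oracle on random pairs", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("AAAAAAAA", "AAAATAAA"), 1L)
  set.seed(11)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:10, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:10, 1), TRUE), collapse = "")
    expect_equal(levenshtein(a, b), oracle_levenshtein(a, b))
  }
})

test_that("expected errors sum Phred-implied probabilities", {
  expect_equal(expected_errors(rep(20L, 60)), 0.6)
  expect_true(ee_filter(rep(20L, 60)))
  expect_equal(expected_errors(rep(10L, 60)), 6.0)
  expect_false(ee_filter(rep(10L, 60)))
  expect_equal(expected_errors(integer(0)), 0)
  expect_true(ee_filter(integer(0)))
})

test_that("pair merging accepts exact 60-nt overlaps and rejects bad merges", {
  set.seed(21)
  ins <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  fwd <- list(seq = substr(ins, 1, 40), quals = rep(30L, 40))
  rev_ <- list(seq = rc(substr(ins, 21, 60)), quals = rep(30L, 40))
  m <- merge_pairs(fwd, rev_)
  expect_equal(m$reason, "ok")
  expect_identical(m$merged, ins)
  # wrong target length is rejected even when the alignment is perfect
  expect_equal(merge_pairs(fwd, rev_, target_len = 59)$reason, "bad_length")
  # overlap disagreements resolve toward the higher-quality base
  fwd_err <- fwd
  wrong <- setdiff(c("A", "C", "G", "T"), substr(ins, 30, 30))[1]
  substr(fwd_err$seq, 30, 30) <- wrong
  fwd_err$quals[30] <- 5L
  m2 <- merge_pairs(fwd_err, rev_)
  expect_identical(m2$merged, ins)
  # a 2-nt deletion in the reverse read needs 2 gap columns: accepted at
  # max_gaps = 2, rejected at max_gaps = 1
  rev_del <- substr(ins, 21, 60)
  rev_del <- paste0(substr(rev_del, 1, 9), substr(rev_del, 12, 40))
  pair_del <- list(seq = rc(rev_del), quals = rep(30L, 38))
  expect_equal(merge_pairs(fwd, pair_del, max_gaps = 2)$reason, "ok")
  expect_equal(merge_pairs(fwd, pair_del, max_gaps = 1)$reason,
               "too_many_gaps")
  # disjoint sequences do not merge
  out <- merge_pairs(list(seq = "ACGTACGTACGTACG", quals = rep(30L, 15)),
                     list(seq = "TTTTGGGGCCCCAAA", quals = rep(30L, 15)))
  expect_equal(out$reason, "no_overlap")
})

test_that("barcode assignment tolerates 2 edits, ties are unassigned", {
  bcs <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG")
  hit <- assign_barcode(paste0(bcs[2], "ACGTACGTACGT"), bcs)
  expect_equal(hit$barcode_index, 2L)
  expect_equal(hit$distance, 0L)
  expect_equal(hit$rest, "ACGTACGTACGT")
  # two substitutions still assign
  two <- assign_barcode(paste0("AATAAATA", "ACGT"), bcs)
  expect_equal(two$barcode_index, 1L)
  expect_equal(two$distance, 2L)
  # distance 3 from every barcode -> unassigned (verified by the DP oracle)
  pre <- "AATTATTA"
  expect_true(all(vapply(bcs, oracle_levenshtein, 0L, a = pre) >= 3))
  miss <- assign_barcode(paste0(pre, "ACGT"), bcs)
  expect_true(is.na(miss$barcode_index))
  # equidistant barcodes -> unassigned
  tie <- assign_barcode(paste0("AAAACCCC", "ACGT"), c("AAAAAAAA", "CCCCCCCC"))
  expect_true(is.na(tie$barcode_index))
})

test_that("adaptor trimming allows 2 edits in a 21-nt adaptor, drops at 3", {
  ad <- "AGATCGGAAGAGCACACGTCT"
  expect_equal(trim_adaptor(paste0("ACGTACGT", ad), ad)$trimmed, "ACGTACGT")
  ad2 <- paste0("TT", substring(ad, 3)) # 2 substitutions
  expect_equal(trim_adaptor(paste0("ACGTACGT", ad2), ad)$trimmed, "ACGTACGT")
  ad3 <- paste0("TTT", substring(ad, 4)) # 3 substitutions
  expect_equal(trim_adaptor(paste0("ACGTACGT", ad3), ad)$reason, "no_adaptor")
})

test_that("dereplication keeps counted uniques at the minimum count", {
  out <- dereplicate(c("A", "A", "A", "B"))
  expect_equal(out$sequence, "A")
  expect_equal(out$count, 3L)
  expect_equal(nrow(dereplicate(character(0))), 0L)
  expect_equal(nrow(dereplicate(c("A", "B", "C"))), 0L) # all singletons
  expect_equal(nrow(dereplicate(c("A", "B", "C"), min_count = 1L)), 3L)
})

test_that("pairwise identity matches the exhaustive alignment oracle", {
  s60 <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")
  expect_equal(pairwise_identity(s60, s60), 1.0)
  s60b <- s60
  substr(s60b, 7, 7) <- "A"
  expect_equal(pairwise_identity(s60, s60b), 59 / 60)
  set.seed(31)
  for (i in 1:12) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:8, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:8, 1), TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), oracle_global_identity(a, b)$identity,
                 info = paste(a, b))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("greedy clustering groups by identity threshold deterministically", {
  set.seed(41)
  base <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  near <- base
  for (p in c(3, 20, 45)) {
    substr(near, p, p) <- setdiff(c("A", "C", "G", "T"), substr(base, p, p))[1]
  }
  far <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  expect_gte(pairwise_identity(base, near), 0.95)
  expect_lt(pairwise_identity(base, far), 0.90)
  dereps <- data.frame(sequence = c(base, near, far), count = c(10L, 5L, 3L))
  cl <- greedy_cluster(dereps, 0.90)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$centroid[1], base) # most abundant founds the cluster
  expect_equal(cl$member_count[1], 15L)
  # duplicates only -> a single centroid
  cl2 <- greedy_cluster(data.frame(sequence = base, count = 7L))
  expect_equal(nrow(cl2), 1L)
  # deterministic rerun
  expect_identical(cl, greedy_cluster(dereps, 0.90))
})

test_that("read mapping assigns by best identity with a floor", {
  set.seed(51)
  c1 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  c2 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  nearly_c1 <- c1
  substr(nearly_c1, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(c1, 5, 5))[1]
  reads <- data.frame(seq = c(c1, nearly_c1, strrep("A", 60)),
                      time_day = 0, replicate = 1L)
  out <- map_reads(reads, c(c1, c2), id_threshold = 0.90)
  expect_equal(sum(out$counts$count), 2L)
  expect_equal(out$n_unmapped, 1L)
  expect_true(all(out$counts$sequence == c1))
})

test_that("translation truncates at the first stop and flags stop starts", {
  expect_equal(translate_insert("GATGAA")$peptide, "DE")
  out <- translate_insert("TAAGATGAA")
  expect_equal(out$peptide, "")
  expect_true(out$starts_with_stop)
  expect_error(translate_insert("GATNAA"), "invalid alphabet")
  # trailing bases are trimmed and flagged
  out2 <- translate_insert("GATGAAG")
  expect_equal(out2$peptide, "DE")
  expect_true(out2$trimmed)
})

test_that("processing simulator reads maps >=99% to their true centroid", {
  members <- plant_ground_truth(generate_random_inserts(25, seed = 61))
  design <- screen_design(time_points = c(0, 4), n_replicates = 2,
                          depth = 400, substitution_error_rate = 0.01)
  counts <- simulate_screen(members, design, seed = 62)
  reads <- emit_fastq(counts, design, seed = 63)
  out <- process_reads(reads, mode = "random")
  expect_equal(unname(out$stage_counts["input"]),
               unname(out$stage_counts["ee_rejected"] +
                      out$stage_counts["no_adaptor"] +
                      out$stage_counts["mapped"] + out$stage_counts["unmapped"]))
  # fraction of mapped reads whose centroid equals their true insert
  truth <- setNames(vapply(members, `[[`, "", "insert_dna"),
                    vapply(members, `[[`, "", "member_id"))
  total_true <- sum(counts$count)
  per_true <- tapply(counts$count, counts$member_id, sum)
  mapped <- out$counts
  correct <- 0L
  for (id in names(per_true)) {
    sel <- mapped$sequence == truth[[id]]
    correct <- correct + min(sum(mapped$count[sel]), per_true[[id]])
  }
  expect_gte(correct / sum(mapped$count), 0.99)
})
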