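# Independent brute-force oracles used to validate the implementations.

# classic dynamic-programming edit distance
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1L, d[i + 1, j] + 1L,
        d[i, j] + (x[i] != y[j])
      )
    }
  }
  d[length(x) + 1L, length(y) + 1L]
}

# exhaustive global alignment: enumerate every alignment recursively and
# keep the lexicographically best (score, matches, -columns); feasible for
# len <= 12. Identity = matches / columns of that alignment.
oracle_global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  best <- new.env()
  best$key <- c(-Inf, -Inf, Inf)
  recurse <- function(i, j, score, matches, cols) {
    if (i > length(x) && j > length(y)) {
      key <- c(score, matches, cols)
      b0 <- best$key
      if (key[1] > b0[1] ||
          (key[1] == b0[1] && key[2] > b0[2]) ||
          (key[1] == b0[1] && key[2] == b0[2] && key[3] < b0[3])) {
        best$key <- key
      }
      return(invisible())
    }
    if (i <= length(x) && j <= length(y)) {
      s <- if (x[i] == y[j]) match else mismatch
      recurse(i + 1L, j + 1L, score + s, matches + (x[i] == y[j]), cols + 1L)
    }
    if (i <= length(x)) recurse(i + 1L, j, score + gap, matches, cols + 1L)
    if (j <= length(y)) recurse(i, j + 1L, score + gap, matches, cols + 1L)
  }
  recurse(1L, 1L, 0, 0L, 0L)
  list(score = best$key[1], identity = best$key[2] / best$key[3])
}

# brute-force mini-motif pair count: literal nested loop
oracle_minimotif_count <- function(peptide, g1, g2, min_gap, max_gap) {
  groups <- list(
    negative = c("D", "E"), positive = c("K", "R", "H"),
    aromatic = c("F", "W", "Y"),
    polar = c("R", "K", "D", "E", "Q", "N", "Y"),
    nonpolar = setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       c("R", "K", "D", "E", "Q", "N", "Y"))
  )
  chars <- strsplit(peptide, "")[[1]]
  n <- 0L
  for (i in seq_along(chars)) {
    for (j in seq_along(chars)) {
      if (j <= i) next
      gap <- j - i - 1L
      if (chars[i] %in% groups[[g1]] && chars[j] %in% groups[[g2]] &&
          gap >= min_gap && gap <= max_gap) {
        n <- n + 1L
      }
    }
  }
  n
}

# exact two-sided rank-sum p-value by enumerating all rank assignments
oracle_ranksum_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled)) # tie-free only
  obs_w <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ranks <- rank(pooled)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(ws - mu) >= abs(obs_w - mu) - 1e-9)
}

# brute-force correlation-component pruning
oracle_corr_prune_kept <- function(x, r_threshold = 0.75) {
  cm <- cor(x)
  n <- ncol(x)
  adj <- abs(cm) >= r_threshold
  diag(adj) <- FALSE
  # components by repeated closure
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  kept <- character(0)
  for (k in unique(comp)) {
    members <- colnames(x)[comp == k]
    if (length(members) == 1) { kept <- c(kept, members); next }
    mar <- sapply(members, function(m) mean(abs(cm[m, setdiff(members, m)])))
    kept <- c(kept, sort(members[mar == min(mar)])[1])
  }
  sort(kept)
}

# random peptides over the 20 standard residues
random_peptides <- function(n, len_range = c(5, 20), seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, "")
}

# tiny labeled synthetic screen shared by several tests
make_small_screen <- function(n = 300, depth = 5000, seed = 42) {
  members <- plant_ground_truth(generate_random_inserts(n, seed = seed))
  counts <- simulate_screen(members, screen_design(depth = depth),
                            seed = seed + 1)
  list(members = members, counts = counts)
}
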