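#' Feature pruning and preprocessing
#'
#' Redundancy reduction before model training: correlation-graph pruning,
#' iterative QR linear-combination removal, near-zero-variance removal, and
#' a train-only center/scale transformer.
#'
#' @name feature_preprocessing
NULL

#' Prune correlated features via graph components
#'
#' Features are nodes, connected when |Pearson r| >= `r_threshold`. Within
#' each connected component the member with the smallest mean |r| to the
#' other members survives (ties broken by lexicographic feature id);
#' `forced_keep` features are always retained as well.
#'
#' @param x Numeric matrix with column names.
#' @param r_threshold Correlation threshold (default 0.75).
#' @param forced_keep Feature ids always retained.
#' @return List with `x` (reduced matrix), `kept`, `clusters` (list of
#'   component memberships).
#' @export
corr_prune <- function(x, r_threshold = 0.75, forced_keep = character(0)) {
  stopifnot(ncol(x) >= 2, !is.null(colnames(x)))
  sds <- apply(x, 2, sd)
  variable <- sds > 0
  cm <- suppressWarnings(cor(x[, variable, drop = FALSE]))
  cm[is.na(cm)] <- 0
  adj <- abs(cm) >= r_threshold
  diag(adj) <- FALSE
  nms <- colnames(cm)
  comp <- rep(NA_integer_, length(nms))
  cid <- 0L
  for (i in seq_along(nms)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  kept <- character(0)
  clusters <- list()
  for (k in seq_len(cid)) {
    members <- nms[comp == k]
    clusters[[k]] <- members
    if (length(members) == 1L) {
      kept <- c(kept, members)
    } else {
      mean_abs_r <- vapply(members, function(m) {
        mean(abs(cm[m, setdiff(members, m)]))
      }, 0)
      best <- members[mean_abs_r == min(mean_abs_r)]
      kept <- c(kept, sort(best)[1])
    }
  }
  kept <- union(kept, intersect(forced_keep, colnames(x)))
  kept <- colnames(x)[colnames(x) %in% kept] # original order
  list(x = x[, kept, drop = FALSE], kept = kept, clusters = clusters)
}

#' Remove exact linear combinations of features
#'
#' Iterative QR-based rank check: while the matrix is column-rank
#' deficient, the pivoted-out dependent columns are removed (earlier
#' columns, i.e. lexicographically earlier feature ids when the matrix is
#' id-ordered, survive). The rank of the matrix is preserved.
#'
#' @param x Numeric matrix with column names.
#' @param tol Rank tolerance passed to [qr()].
#' @return List with `x` (full-column-rank matrix) and `removed`.
#' @export
lincomb_prune <- function(x, tol = 1e-7) {
  removed <- character(0)
  repeat {
    q <- qr(x, tol = tol)
    if (q$rank == ncol(x)) break
    drop_idx <- q$pivot[(q$rank + 1L):ncol(x)]
    removed <- c(removed, colnames(x)[drop_idx])
    x <- x[, -drop_idx, drop = FALSE]
  }
  list(x = x, removed = removed)
}

#' Remove near-zero-variance features
#'
#' A feature is removed when the frequency ratio of its most common value
#' to its second most common value exceeds `freq_ratio` (95/5 = 19);
#' constant features are always removed.
#'
#' @param x Numeric matrix with column names.
#' @param freq_ratio Ratio cutoff (default 19).
#' @return List with `x` and `removed`.
#' @export
nzv_prune <- function(x, freq_ratio = 95 / 5) {
  bad <- vapply(seq_len(ncol(x)), function(j) {
    tab <- sort(table(x[, j]), decreasing = TRUE)
    if (length(tab) == 1L) return(TRUE)
    tab[1] / tab[2] > freq_ratio
  }, logical(1))
  list(x = x[, !bad, drop = FALSE], removed = colnames(x)[bad])
}

#' Fit a center/scale transformer on training rows
#'
#' Column means and standard deviations are estimated on the training rows
#' only and applied unchanged elsewhere; zero-variance columns are centered
#' but not scaled.
#'
#' @param x_train Training matrix.
#' @return A `center_scale` object; apply with [apply_center_scale()].
#' @export
center_scale <- function(x_train) {
  mu <- colMeans(x_train)
  s <- apply(x_train, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  structure(list(mean = mu, sd = s), class = "center_scale")
}

#' Apply a fitted center/scale transformer
#'
#' @param transformer From [center_scale()].
#' @param x Matrix with the same columns.
#' @return Transformed matrix.
#' @export
apply_center_scale <- function(transformer, x) {
  sweep(sweep(x, 2, transformer$mean), 2, transformer$sd, "/")
}
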