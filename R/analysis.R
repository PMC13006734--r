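# Pattern-similarity analytics: classic dynamic time warping (symmetric
# step pattern, squared-Euclidean local cost over channels), DTW-based
# K-means with medoid centres, and mean pairwise DTW heatmaps between
# labeled condition groups.

# Local squared-Euclidean cost matrix between two T x C sequences.
dtw_cost_matrix <- function(a, b) {
  a <- as_sequence(a); b <- as_sequence(b)
  abort_if(ncol(a) != ncol(b), "channel counts differ")
  sa <- rowSums(a^2); sb <- rowSums(b^2)
  outer(sa, sb, `+`) - 2 * tcrossprod(a, b)
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming alignment with symmetric steps
#' (up, right, diagonal), boundary-matched, local cost the squared
#' Euclidean distance across channels. Lower distance means more similar
#' patterns, tolerant of local speed differences and time delays.
#'
#' @param a,b non-empty sequences (vectors or T x C matrices with matching
#'   C).
#' @param return_path also backtrack and return the optimal warping path.
#' @param band optional Sakoe-Chiba band half-width (steps); `Inf` = none.
#' @return a `dtw_result`: list with `distance` and, when requested,
#'   `path` (m x 2 matrix of aligned index pairs, 1-based).
#' @export
dtw_distance <- function(a, b, return_path = FALSE, band = Inf) {
  a <- as_sequence(a); b <- as_sequence(b)
  abort_if(nrow(a) == 0 || nrow(b) == 0, "empty sequence")
  cost <- dtw_cost_matrix(a, b)
  n <- nrow(cost); m <- ncol(cost)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    jlo <- if (is.finite(band)) max(1L, i - band) else 1L
    jhi <- if (is.finite(band)) min(m, i + band) else m
    row_cost <- cost[i, ]
    for (j in jlo:jhi) {
      D[i + 1, j + 1] <- row_cost[j] + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  res <- list(distance = D[n + 1, m + 1])
  if (return_path) {
    path <- list(c(n, m))
    i <- n; j <- m
    while (i > 1 || j > 1) {
      choices <- c(if (i > 1 && j > 1) D[i - 1 + 1, j - 1 + 1] else Inf,
                   if (i > 1) D[i - 1 + 1, j + 1] else Inf,
                   if (j > 1) D[i + 1, j - 1 + 1] else Inf)
      k <- which.min(choices)
      if (k == 1) { i <- i - 1; j <- j - 1 }
      else if (k == 2) i <- i - 1
      else j <- j - 1
      path[[length(path) + 1]] <- c(i, j)
    }
    res$path <- do.call(rbind, rev(path))
    colnames(res$path) <- c("i", "j")
  }
  class(res) <- "dtw_result"
  res
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("DTW distance: %.6g\n", x$distance))
  invisible(x)
}

# Pairwise DTW distance matrix over a list of sequences.
dtw_pairwise <- function(sequences, band = Inf) {
  n <- length(sequences)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- dtw_distance(sequences[[i]], sequences[[j]], band = band)$distance
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' DTW-based K-means clustering (medoid centres)
#'
#' Alternates nearest-centre assignment under DTW distance with medoid
#' updates (the member minimising total DTW distance to its cluster) until
#' labels stabilise or `max_iter` is reached. The objective (sum of
#' within-cluster distances to centres) is non-increasing across
#' iterations.
#'
#' @param sequences list of sequences.
#' @param k number of clusters (`1 <= k <= length(sequences)`).
#' @param max_iter iteration cap.
#' @param seed integer seed for the initial medoid draw.
#' @param band optional Sakoe-Chiba band half-width.
#' @return a `dtw_clustering`: list with `labels` (1..k per sequence),
#'   `medoids` (sequence indices), `objective`, `objective_trace` (the
#'   objective after each iteration), `mean_intra` (mean within-cluster DTW
#'   per cluster), `distance_matrix`.
#' @export
dtw_kmeans <- function(sequences, k, max_iter = 50, seed = 1, band = Inf) {
  n <- length(sequences)
  abort_if(k < 1, "k must be >= 1")
  abort_if(k > n, "k larger than the number of sequences")
  D <- dtw_pairwise(sequences, band = band)
  with_seed(seed, {
    medoids <- sample.int(n, k)
    labels <- rep(1L, n)
    obj_trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      labels_new <- apply(D[, medoids, drop = FALSE], 1, which.min)
      labels_new <- as.integer(labels_new)
      for (c_ in seq_len(k)) {
        members <- which(labels_new == c_)
        if (!length(members)) {                       # re-seed an empty cluster
          members <- which.max(D[cbind(seq_len(n), medoids[labels_new])])
          labels_new[members] <- c_
        }
        sub <- D[members, members, drop = FALSE]
        medoids[c_] <- members[which.min(rowSums(sub))]
      }
      obj_trace <- c(obj_trace, sum(D[cbind(seq_len(n), medoids[labels_new])]))
      if (identical(labels_new, labels) && iter > 1) break
      labels <- labels_new
    }
    mean_intra <- vapply(seq_len(k), function(c_) {
      members <- which(labels == c_)
      if (length(members) < 2) return(0)
      sub <- D[members, members]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    structure(list(labels = labels, medoids = medoids,
                   objective = sum(D[cbind(seq_len(n), medoids[labels])]),
                   objective_trace = obj_trace,
                   mean_intra = mean_intra, distance_matrix = D),
              class = "dtw_clustering")
  })
}

#' Mean pairwise DTW distance between labeled groups
#'
#' Entry (i, j) is the mean DTW distance over all pairs from group i x
#' group j; the diagonal is the mean intra-group distance over distinct
#' pairs (0 for singleton groups). Symmetric for the symmetric step
#' pattern.
#'
#' @param groups named list of sequence lists (e.g. one group per
#'   tightness/vocal-intensity condition).
#' @param band optional Sakoe-Chiba band half-width.
#' @return a symmetric matrix with group names on both dimensions.
#' @export
distance_heatmap <- function(groups, band = Inf) {
  abort_if(any(vapply(groups, length, integer(1)) == 0), "empty group")
  g <- length(groups)
  M <- matrix(0, g, g, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(g)) for (j in i:g) {
    if (i == j) {
      seqs <- groups[[i]]
      if (length(seqs) > 1) {
        D <- dtw_pairwise(seqs, band = band)
        M[i, i] <- mean(D[upper.tri(D)])
      }
    } else {
      vals <- vapply(groups[[i]], function(a) {
        vapply(groups[[j]], function(b)
          dtw_distance(a, b, band = band)$distance, numeric(1))
      }, numeric(length(groups[[j]])))
      M[i, j] <- mean(vals); M[j, i] <- M[i, j]
    }
  }
  M
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and reference labels
#' (1 = identical partitions, ~0 = random).
#'
#' @param a,b integer label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  abort_if(length(a) != length(b), "label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
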