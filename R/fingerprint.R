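#' Time-resolved behavioral distribution
#'
#' For each of the 96 quarter-hour ZT intervals `[0, 0.25), ..., [23.75, 24)`
#' the proportion of minutes spent in each behavioral state (quiescence,
#' micromovement, walking), pooled over the selected complete days. This
#' empirical distribution triple per interval is the unit on which the
#' fingerprint distance operates.
#'
#' @param eth An [ethogram()] with at least one complete ZT day.
#' @param days Optional integer vector of day indices to use (default all
#'   complete days).
#' @return A `behavior_distribution`: 96 x 3 matrix of probabilities (rows
#'   sum to 1), row names the interval start in hours, with attribute
#'   `animal_id`.
#' @export
behavior_distribution <- function(eth, days = NULL) {
  rel <- eth$minutes$t_start - eth$lights_on_s
  day <- floor(rel / 86400)
  full <- as.numeric(names(which(table(day) == 1440)))
  if (!length(full)) stop("need at least one complete ZT day of minute states")
  if (!is.null(days)) {
    full <- intersect(full, days)
    if (!length(full)) stop("requested days are not complete in this ethogram")
  }
  keep <- day %in% full
  zt <- (rel[keep] / 3600) %% 24
  interval <- floor(zt * 4) # 96 quarter-hour bins
  st <- eth$minutes$state[keep]
  counts <- table(factor(interval, levels = 0:95), st)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("interval with zero minutes (incomplete day?)")
  p <- sweep(unclass(counts), 1, tot, "/")
  dimnames(p) <- list(sprintf("%.2f", (0:95) / 4), .states)
  structure(p, animal_id = eth$animal_id, class = "behavior_distribution")
}

#' Bhattacharyya coefficient and distance
#'
#' For two discrete distributions over the same states,
#' `BC = sum(sqrt(p * q))` in `[0, 1]` and `BD = -log(BC)`. BD is symmetric
#' with `BD(p, p) = 0` but violates the triangle inequality in general: it is
#' a divergence, not a metric. Disjoint supports give `BC = 0`; BD is then
#' capped at `-log(eps)` so downstream clustering stays finite while
#' preserving the ordering.
#'
#' @param p,q Numeric probability vectors of equal length.
#' @param eps Cap parameter: `BD_max = -log(eps)` (default `1e-6`).
#' @return A list with `bc` and `bd`.
#' @export
#' @examples
#' bhattacharyya(c(0.25, 0.25, 0.5), c(0.5, 0.25, 0.25))
bhattacharyya <- function(p, q, eps = 1e-6) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("p and q must be probability distributions")
  }
  bc <- sum(sqrt(p * q))
  bc <- min(bc, 1) # guard rounding
  list(bc = bc, bd = -log(max(bc, eps)))
}

#' Pairwise behavioral fingerprint distance
#'
#' The distance between two animals is the mean Bhattacharyya distance over
#' the 96 quarter-hour intervals of their behavioral distributions.
#'
#' @param dists Named list of [behavior_distribution()] matrices sharing the
#'   interval grid.
#' @param eps Cap passed to [bhattacharyya()].
#' @return A symmetric matrix with zero diagonal and animal labels, class
#'   `fingerprint_dist`.
#' @export
pairwise_distance <- function(dists, eps = 1e-6) {
  n <- length(dists)
  if (n < 2) stop("need at least two animals")
  dims <- vapply(dists, function(d) paste(dim(d), collapse = "x"), "")
  if (length(unique(dims)) != 1L) stop("interval grid mismatch between animals")
  labs <- names(dists)
  if (is.null(labs)) {
    labs <- vapply(dists, function(d) {
      id <- attr(d, "animal_id")
      if (is.null(id)) NA_character_ else id
    }, "")
    if (anyNA(labs)) labs <- paste0("animal_", seq_len(n))
  }
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bd <- vapply(seq_len(nrow(dists[[i]])), function(tt) {
        bhattacharyya(dists[[i]][tt, ], dists[[j]][tt, ], eps = eps)$bd
      }, numeric(1))
      D[i, j] <- D[j, i] <- mean(bd)
    }
  }
  structure(D, class = c("fingerprint_dist", "matrix", "array"))
}

#' UPGMA hierarchical clustering
#'
#' Classical unweighted pair-group agglomeration with arithmetic-mean
#' linkage: at each step the two closest clusters merge, and the distance of
#' the merged cluster to any other is the leaf-count-weighted average of the
#' members' distances. Node heights are half the merge distance (the
#' ultrametric convention), so the cophenetic distance between two leaves
#' equals their merge distance. Ties are broken deterministically by the
#' lexicographically smallest leaf label in each candidate pair.
#'
#' @param d A symmetric distance matrix (or `dist`) with finite entries and
#'   >= 2 leaves; labels from dimnames.
#' @return An `hclust`-compatible object (classes `upgma`, `hclust`) with
#'   `merge`, `height` (merge distances), `order`, `labels`.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 leaves")
  if (any(!is.finite(m))) stop("non-finite entries in distance matrix")
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("L", seq_len(n))
  # active clusters: id (hclust convention: -leaf or +merge-step), size,
  # representative label (lexicographic minimum of member leaf labels)
  ids <- -(seq_len(n))
  sizes <- rep(1L, n)
  reps <- labs
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- nrow(m)
    dm <- m
    dm[!upper.tri(dm)] <- Inf
    best <- which(dm == min(dm), arr.ind = TRUE)
    if (nrow(best) > 1) {
      key <- apply(best, 1, function(ij) {
        r <- sort(c(reps[ij[1]], reps[ij[2]]))
        paste(r, collapse = "\r")
      })
      best <- best[order(key)[1], , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    height[step] <- m[i, j]
    merge[step, ] <- c(ids[i], ids[j])
    si <- sizes[i]; sj <- sizes[j]
    others <- setdiff(seq_len(k), c(i, j))
    newd <- (si * m[i, others] + sj * m[j, others]) / (si + sj)
    m <- m[others, others, drop = FALSE]
    m <- rbind(cbind(m, newd), c(newd, 0))
    ids <- c(ids[others], step)
    sizes <- c(sizes[others], si + sj)
    reps <- c(reps[others], min(reps[c(i, j)]))
  }
  leaf_order <- function(id) {
    if (id < 0) -id else c(leaf_order(merge[id, 1]), leaf_order(merge[id, 2]))
  }
  structure(list(
    merge = merge, height = height, order = leaf_order(n - 1),
    labels = labs, method = "upgma", call = match.call(),
    dist.method = "behavioral fingerprint"
  ), class = c("upgma", "hclust"))
}

#' Ternary (barycentric) coordinates of a behavioral trajectory
#'
#' Maps each quarter-hour distribution triple to 2-D barycentric coordinates
#' of the quiescence/micromovement/walking simplex (vertices at (0,0), (1,0)
#' and (1/2, sqrt(3)/2)); with time as the remaining dimension this is the
#' "four-dimensional" behavioral trajectory ready for plotting.
#'
#' @param dist A [behavior_distribution()].
#' @return Data frame `zt`, `x`, `y` plus the three probabilities.
#' @export
ternary_trajectory <- function(dist) {
  V <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  xy <- unclass(dist) %*% V
  out <- data.frame(
    zt = (seq_len(nrow(dist)) - 1) / 4,
    x = xy[, 1], y = xy[, 2],
    quiescence = dist[, 1], micromovement = dist[, 2], walking = dist[, 3]
  )
  rownames(out) <- NULL
  out
}
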