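#' Binary occupancy matrix for clustering
#'
#' Converts one reporter's events into a molecules x frames binary occupancy
#' matrix over the common usable time span (molecules are compared over
#' `[t0, min(usable end))`; a frame is 1 when the molecule is bound for at
#' least half of it). Each molecule carries a weight equal to its number of
#' binding events, used by the weighted clustering.
#'
#' @param events Event table.
#' @param annotations [select_molecules()] output.
#' @param reporter Reporter name.
#' @param frame_period Seconds per frame.
#' @param t0 Start of the compared span, seconds.
#' @param molecule_ids Optional subset/order of molecules.
#' @return List with `occupancy` (binary matrix, rownames = molecule ids),
#'   `weights` (event counts) and `frame_period`.
#' @export
occupancy_matrix <- function(events, annotations, reporter, frame_period,
                             t0 = 0, molecule_ids = NULL) {
  ann <- annotations[annotations$selected, , drop = FALSE]
  if (!is.null(molecule_ids)) {
    ann <- ann[match(molecule_ids, ann$molecule_id), , drop = FALSE]
  }
  end <- ifelse(is.na(ann$donor_bleach_time), Inf, ann$donor_bleach_time)
  span_end <- min(end)
  n_frames <- max(0L, floor((span_end - t0) / frame_period))
  boundaries <- t0 + seq(0, by = frame_period, length.out = n_frames + 1L)
  ev <- events[events$reporter == reporter, , drop = FALSE]
  occ <- t(vapply(ann$molecule_id, function(id) {
    sub <- ev[ev$molecule_id == id, , drop = FALSE]
    occupancy_frames(sub$t_start, sub$t_end, boundaries) >= 0.5
  }, logical(n_frames)))
  storage.mode(occ) <- "integer"
  rownames(occ) <- ann$molecule_id
  weights <- vapply(ann$molecule_id, function(id)
    sum(ev$molecule_id == id), integer(1))
  list(occupancy = occ, weights = weights, frame_period = frame_period)
}

#' Spearman dissimilarity between occupancy vectors
#'
#' `1 - Spearman rank correlation` between rows. Constant rows (all bound or
#' all unbound) have undefined rank correlation; by convention they are at
#' maximal distance (2) from every non-identical row and at distance 0 from
#' identical rows.
#'
#' @param occupancy Molecules x frames matrix.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
spearman_distance <- function(occupancy) {
  n <- nrow(occupancy)
  d <- matrix(0, n, n, dimnames = list(rownames(occupancy),
                                       rownames(occupancy)))
  if (n < 2L) return(d)
  const <- apply(occupancy, 1, function(x) stats::sd(x) == 0)
  ok <- which(!const)
  if (length(ok) >= 2L) {
    cc <- suppressWarnings(
      stats::cor(t(occupancy[ok, , drop = FALSE]), method = "spearman"))
    d[ok, ok] <- 1 - cc
  }
  for (i in which(const)) {
    same <- vapply(seq_len(n), function(j)
      identical(occupancy[i, ], occupancy[j, ]), logical(1))
    d[i, ] <- ifelse(same, 0, 2)
    d[, i] <- d[i, ]
  }
  diag(d) <- 0
  d
}

#' Weighted WPGMA clustering of molecules by occupancy similarity
#'
#' Agglomerative hierarchical clustering with the weighted pair group method
#' with arithmetic mean (WPGMA) on the Spearman dissimilarity between
#' per-molecule occupancy vectors. Individual molecules can be weighted (by
#' their number of binding events): when merging clusters i and j, the
#' distance to any third cluster k becomes
#' `(w_i d(i,k) + w_j d(j,k)) / (w_i + w_j)` with cluster weights summing
#' their members' weights. With equal weights this reduces exactly to plain
#' WPGMA (`hclust(method = "mcquitty")`). Zero weights are lifted to a small
#' floor so event-free molecules still merge.
#'
#' @param occ An [occupancy_matrix()] result, or a list with `occupancy` and
#'   optionally `weights`.
#' @param weighted Use the per-molecule weights (`FALSE` = plain WPGMA).
#' @return An object of class `hclust` (with `merge`, `height`, `order`,
#'   `labels`), usable with [stats::cutree()] and plotting.
#' @export
cluster_molecules <- function(occ, weighted = TRUE) {
  x <- occ$occupancy
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 molecules to cluster")
  d <- spearman_distance(x)
  w <- if (weighted && !is.null(occ$weights)) pmax(occ$weights, 0.5)
       else rep(1, n)
  labels <- rownames(x)

  active <- seq_len(n)
  id <- -seq_len(n)              # hclust convention: negatives are leaves
  weight <- as.numeric(w)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n)) # leaf order bookkeeping
  dm <- d
  diag(dm) <- Inf
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    idx <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    merge[step, ] <- c(id[i], id[j])
    height[step] <- dm[i, j]
    new_d <- (weight[i] * dm[i, ] + weight[j] * dm[j, ]) /
      (weight[i] + weight[j])
    new_members <- c(members[[i]], members[[j]])
    # replace i with the merged cluster, drop j
    dm[i, ] <- new_d
    dm[, i] <- new_d
    dm[i, i] <- Inf
    keep <- setdiff(seq_len(k), j)
    dm <- dm[keep, keep, drop = FALSE]
    id <- c(id[keep])
    id[which(keep == i)] <- step
    # weighted variant accumulates event-count weights; plain WPGMA keeps
    # every cluster at unit weight (mcquitty)
    if (weighted) weight[i] <- weight[i] + weight[j]
    weight <- weight[keep]
    members[[i]] <- new_members
    members <- members[keep]
    active <- active[keep]
  }
  structure(list(merge = merge, height = height,
                 order = members[[1]],
                 labels = labels, method = "wpgma(weighted)",
                 dist.method = "spearman",
                 call = match.call()),
            class = "hclust")
}
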