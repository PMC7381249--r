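#' Spearman-correlation distance matrix
#'
#' `d(i, j) = 1 - rho_spearman(i, j)` with pairwise-complete observations
#' (each pair is ranked over its own complete cases), giving distances in
#' [0, 2] with a zero diagonal. A constant vector within a pair's complete
#' cases has undefined rank correlation and is an error naming the offender.
#'
#' When clustering samples, per-feature baselines shared by every sample
#' dominate the within-sample ranks and can mask group structure;
#' `center_features = TRUE` removes each feature's mean first (a no-op for
#' `axis = "features"`, where centering a vector never changes its own
#' ranks). The pipeline's sample-clustering stage enables this.
#'
#' @param mat `expr_matrix` (any kind).
#' @param axis `"samples"` (correlate columns, the default) or `"features"`.
#' @param min_obs minimum complete observations per correlated pair.
#' @param center_features subtract each feature's mean (over non-missing
#'   samples) before correlating samples.
#' @return symmetric `dist`-convertible matrix with unit labels.
#' @export
spearman_distance_matrix <- function(mat, axis = c("samples", "features"),
                                     min_obs = 3, center_features = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"))
  axis <- match.arg(axis)
  v <- unclass(mat)
  if (center_features) v <- v - rowMeans(v, na.rm = TRUE)
  if (axis == "features") v <- t(v)
  n <- ncol(v)
  if (n < 2) stop("need >= 2 units to build distances", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(v[, i]) & !is.na(v[, j])
      if (sum(ok) < min_obs)
        stop(sprintf("pair (%s, %s) has only %d complete observations (< %d)",
                     colnames(v)[i], colnames(v)[j], sum(ok), min_obs),
             call. = FALSE)
      xi <- v[ok, i]; xj <- v[ok, j]
      for (k in c(i, j)) {
        vv <- if (k == i) xi else xj
        if (length(unique(vv)) == 1)
          stop("constant values make Spearman correlation undefined for '",
               colnames(v)[k], "'", call. = FALSE)
      }
      rho <- stats::cor(rank(xi), rank(xj))
      d[i, j] <- d[j, i] <- 1 - rho
    }
  }
  d
}

#' Ward hierarchical clustering on a precomputed distance matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion applied
#' through the Lance-Williams update directly on the supplied distances
#' (`d(k, ij) = ((n_i + n_k) d(ki) + (n_j + n_k) d(kj) - n_k d(ij)) /
#' (n_i + n_j + n_k)`), deterministic tie-breaking by the smallest index
#' pair. Note Ward's criterion formally assumes squared Euclidean distances;
#' applying it to correlation distances mirrors common practice for
#' expression heatmaps and is a documented caveat, not an error.
#'
#' @param dist symmetric numeric matrix with zero diagonal (e.g. from
#'   [spearman_distance_matrix()]), or a `dist` object.
#' @param k number of clusters for the stored cut, `2 <= k <= n`.
#' @return list of class `fx_dendrogram`: `hclust` (a standard `hclust`
#'   object: merge/height/order/labels), `clusters` (named cut at `k`), `k`.
#' @export
ward_cluster <- function(dist, k = 2) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist)) || any(diag(dist) != 0))
    stop("`dist` must be symmetric with a zero diagonal", call. = FALSE)
  n <- nrow(dist)
  if (k < 2 || k > n) stop("k must lie in 2..n", call. = FALSE)
  labels <- rownames(dist) %||% paste0("unit", seq_len(n))
  d <- dist
  size <- rep(1, n)
  id <- -(seq_len(n))         # hclust convention: negatives are leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    act <- which(active)
    for (a in seq_along(act)[-length(act)]) {
      for (b in (a + 1):length(act)) {
        i <- act[a]; j <- act[b]
        if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort_merge_pair(id[i], id[j])
    height[step] <- best_d
    # Lance-Williams Ward update into slot i
    for (m in which(active)) {
      if (m == i || m == j) next
      d[i, m] <- d[m, i] <-
        ((size[i] + size[m]) * d[i, m] + (size[j] + size[m]) * d[j, m] -
           size[m] * d[i, j]) / (size[i] + size[j] + size[m])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_leaf_order(merge),
                       labels = labels, method = "ward.lance-williams",
                       call = match.call(), dist.method = "precomputed"),
                  class = "hclust")
  clusters <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, clusters = clusters, k = k),
            class = "fx_dendrogram")
}

# hclust merge-row convention: singletons (negative) first, by ascending
# absolute value, then internal nodes ascending
sort_merge_pair <- function(a, b) {
  neg <- sort(c(a, b)[c(a, b) < 0], decreasing = TRUE)
  pos <- sort(c(a, b)[c(a, b) > 0])
  as.integer(c(neg, pos))
}

hclust_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand_row <- nrow(merge)
  expand(expand_row)
}

#' @export
print.fx_dendrogram <- function(x, ...) {
  cat("<fx_dendrogram>", length(x$hclust$labels), "leaves, cut at k =", x$k, "\n")
  print(table(x$clusters))
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' @param dend an [ward_cluster()] result.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "fx_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Check cluster separation against a sample attribute
#'
#' For the k = 2 cut, tabulates cluster membership against a binary sample
#' attribute (default smoker status) and reports purity: the best achievable
#' agreement between clusters and attribute levels under either cluster-to-
#' level matching.
#'
#' @param dend an [ward_cluster()] result (k = 2 cut used).
#' @param meta a [sample_table()] covering all leaves.
#' @param attribute metadata column name.
#' @return list: `table` (2 x levels contingency), `purity` in [0.5, 1],
#'   `pure` (logical).
#' @export
cluster_separation_check <- function(dend, meta, attribute = "smoker") {
  stopifnot(inherits(dend, "fx_dendrogram"))
  if (!attribute %in% names(meta))
    stop("attribute '", attribute, "' not in metadata", call. = FALSE)
  cl <- stats::cutree(dend$hclust, k = 2)
  att <- meta[[attribute]][match(names(cl), meta$sample_id)]
  if (anyNA(att))
    stop("attribute missing for leaf/leaves: ",
         paste(names(cl)[is.na(att)], collapse = ", "), call. = FALSE)
  tab <- table(cluster = cl, attribute = att)
  if (ncol(tab) == 1) {
    purity <- 1
  } else {
    purity <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / sum(tab)
  }
  list(table = tab, purity = purity, pure = purity == 1)
}
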