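#' Agglomerative clustering with squared Euclidean distance and
#' between-groups linkage
#'
#' Implements the Q-type (case-wise) hierarchical clustering used to delimit
#' scale morphotypes: pairwise squared Euclidean distances on the selected
#' length variables (unstandardized - all variables share the millimetre
#' dimension), then repeated merging of the pair of clusters with the
#' smallest between-groups linkage, i.e. the mean of the squared Euclidean
#' distances over all cross-pairs of members. The mean is maintained
#' incrementally with the Lance-Williams update
#' `d(ab,k) = (n_a d(a,k) + n_b d(b,k)) / (n_a + n_b)`,
#' which is exact for this linkage.
#'
#' Ties in the minimum linkage are broken deterministically: among tied
#' pairs, the pair whose (lexicographically smallest member scale_id,
#' then second-smallest) sorts first is merged. Average linkage is
#' reducible, so merge heights are non-decreasing; this is asserted on
#' every run.
#'
#' @param table a [measurement_table()].
#' @param variables character vector of length variables to cluster on
#'   (default: all variables in the table).
#' @return object of class `scale_dendrogram`: `n_leaves`, `leaf_ids`,
#'   and `merges`, a data.frame with columns `a`, `b` (negative values are
#'   leaf indices, positive values index earlier merges, as in
#'   [stats::hclust()]), `height` (linkage at the merge) and `size` (members
#'   of the new cluster).
#' @export
agglomerate <- function(table, variables = table$variables) {
  stopifnot(inherits(table, "measurement_table"))
  miss <- setdiff(variables, names(table$data))
  if (length(miss))
    stop_scalemorph("schema", "variables not in table: %s",
                    paste(miss, collapse = ", "))
  X <- as.matrix(table$data[variables])
  n <- nrow(X)
  if (n < 2)
    stop_scalemorph("data", "need at least 2 records to cluster")
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad))
    stop_scalemorph("data", "non-finite value at row %d, variable %s",
                    bad[1, 1], variables[bad[1, 2]])
  ids <- table$data$scale_id

  D <- as.matrix(stats::dist(X))^2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  min_id <- ids                      # lexicographically smallest member id per slot
  node_of <- -seq_len(n)             # hclust-style node id currently in each slot
  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L))
  prev_h <- -Inf
  for (step in seq_len(n - 1L)) {
    dmin <- min(D)
    cand <- which(D == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      key <- apply(cand, 1L, function(p) {
        mm <- sort(c(min_id[p[1]], min_id[p[2]]))
        paste(mm, collapse = "\r")
      })
      cand <- cand[order(key)[1L], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    if (dmin < prev_h - 1e-8 * max(1, abs(prev_h)))
      stop_scalemorph("internal", "merge heights decreased: average linkage must be monotone")
    prev_h <- max(prev_h, dmin)

    merges$a[step] <- node_of[i]; merges$b[step] <- node_of[j]
    merges$height[step] <- dmin
    merges$size[step] <- sizes[i] + sizes[j]

    # Lance-Williams average-linkage update into slot i
    upd <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    D[i, ] <- upd; D[, i] <- upd
    D[i, i] <- Inf
    D[j, ] <- Inf; D[, j] <- Inf
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    min_id[i] <- min(min_id[i], min_id[j])
    node_of[i] <- step
  }
  structure(list(n_leaves = n, leaf_ids = ids, merges = merges,
                 variables = variables,
                 method_params = list(distance = "squared Euclidean",
                                      linkage = "between-groups (average)")),
            class = "scale_dendrogram")
}

#' @export
print.scale_dendrogram <- function(x, ...) {
  cat(sprintf("<scale_dendrogram> %d leaves, %s distance, %s linkage\n",
              x$n_leaves, x$method_params$distance, x$method_params$linkage))
  invisible(x)
}

#' Cut a dendrogram into k groups
#'
#' Undoes the last `k - 1` merges: the first `n - k` merges are applied and
#' connected leaves share a group. Groups are renumbered 1..k by descending
#' size, ties broken by the lexicographically smallest member scale_id, so
#' labels are invariant to row permutations of the input.
#'
#' @param dendrogram a `scale_dendrogram`.
#' @param k number of groups, `1 <= k <= n_leaves`.
#' @return object of class `scale_partition`: `labels` (integer vector named
#'   by scale_id), `k`, `method_params`.
#' @export
cut_k <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "scale_dendrogram"))
  n <- dendrogram$n_leaves
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k))
    stop_scalemorph("argument", "k must be an integer in [1, %d]", n)
  k <- as.integer(k)
  comp <- seq_len(n)                # leaf -> component representative
  node_members <- vector("list", n - 1L)
  apply_n <- n - k
  for (s in seq_len(apply_n)) {
    a <- dendrogram$merges$a[s]; b <- dendrogram$merges$b[s]
    mem_a <- if (a < 0) -a else node_members[[a]]
    mem_b <- if (b < 0) -b else node_members[[b]]
    node_members[[s]] <- c(mem_a, mem_b)
    comp[node_members[[s]]] <- min(comp[node_members[[s]]])
  }
  # also track memberships of unapplied merges' nodes for later steps
  if (apply_n < n - 1L) for (s in seq(apply_n + 1L, n - 1L)) {
    a <- dendrogram$merges$a[s]; b <- dendrogram$merges$b[s]
    mem_a <- if (a < 0) -a else node_members[[a]]
    mem_b <- if (b < 0) -b else node_members[[b]]
    node_members[[s]] <- c(mem_a, mem_b)
  }
  groups <- split(seq_len(n), comp)
  sizes <- lengths(groups)
  first_id <- vapply(groups, function(g) min(dendrogram$leaf_ids[g]),
                     character(1))
  ord <- order(-sizes, first_id)
  labels <- integer(n)
  for (r in seq_along(ord)) labels[groups[[ord[r]]]] <- r
  partition(stats::setNames(labels, dendrogram$leaf_ids),
            method_params = dendrogram$method_params)
}

#' Construct a partition of scales into groups
#'
#' @param labels integer (or coercible) group labels named by scale_id;
#'   groups must be numbered 1..k with no empty group.
#' @param method_params optional descriptor of how the partition was made.
#' @return object of class `scale_partition`.
#' @export
partition <- function(labels, method_params = list()) {
  lab <- as.integer(labels)
  names(lab) <- names(labels)
  if (anyNA(lab)) stop_scalemorph("argument", "labels must be integers")
  k <- length(unique(lab))
  if (!setequal(unique(lab), seq_len(k)))
    stop_scalemorph("argument", "labels must be 1..k with every group non-empty")
  structure(list(labels = lab, k = k, method_params = method_params),
            class = "scale_partition")
}

#' @export
print.scale_partition <- function(x, ...) {
  cat(sprintf("<scale_partition> %d scales in %d groups (sizes %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Compare candidate group counts
#'
#' Cuts one dendrogram at each candidate `k` and reports per-k diagnostics
#' for a user decision: group sizes, total within-group dispersion (sum of
#' squared Euclidean distances to group centroids), and the mean silhouette
#' width (Euclidean distance; `NA` when `k` is 1 or n). Two-dimensional
#' principal-component coordinates of the scales are attached for scatter
#' inspection. No automatic choice is made: picking k is a judgement against
#' the fossil evidence, not an optimisation.
#'
#' @param table a [measurement_table()].
#' @param variables variables to cluster on.
#' @param ks integer vector of candidate group counts.
#' @return list with `diagnostics` (data.frame: k, sizes, within_ss,
#'   mean_silhouette), `partitions` (list of `scale_partition` keyed by k),
#'   and `scores` (n x 2 PCA coordinates).
#' @export
compare_k <- function(table, variables = table$variables, ks) {
  if (!length(ks))
    stop_scalemorph("argument", "ks must name at least one candidate k")
  dend <- agglomerate(table, variables)
  X <- as.matrix(table$data[variables])
  dEuc <- stats::dist(X)
  parts <- lapply(ks, function(k) cut_k(dend, k))
  names(parts) <- as.character(ks)
  diag_df <- do.call(rbind, lapply(seq_along(ks), function(ii) {
    p <- parts[[ii]]
    within <- sum(vapply(seq_len(p$k), function(g) {
      Xi <- X[p$labels == g, , drop = FALSE]
      sum(sweep(Xi, 2, colMeans(Xi))^2)
    }, numeric(1)))
    sil <- if (p$k > 1 && p$k < nrow(X))
      mean(cluster::silhouette(p$labels, dEuc)[, "sil_width"]) else NA_real_
    data.frame(k = ks[ii],
               sizes = paste(sort(tabulate(p$labels, p$k), decreasing = TRUE),
                             collapse = "/"),
               within_ss = within, mean_silhouette = sil)
  }))
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(min(2, ncol(pca$x))), drop = FALSE]
  rownames(scores) <- table$data$scale_id
  list(diagnostics = diag_df, partitions = parts, scores = scores)
}
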