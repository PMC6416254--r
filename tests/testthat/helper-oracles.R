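# Independent oracles. Each recomputes the quantity it checks by the most
# direct method available, sharing no code with the package internals.

# O(n^3) average-linkage agglomeration over squared Euclidean distances:
# at every step the mean over all cross-pairs of point distances is
# recomputed from scratch. Tie-break: lexicographically smallest pair of
# (smallest member id, second member id).
oracle_average_linkage <- function(X, ids = as.character(seq_len(nrow(X)))) {
  n <- nrow(X)
  D0 <- as.matrix(dist(X))^2
  clusters <- lapply(seq_len(n), identity)   # member row indices
  nodes <- -seq_len(n)
  merges <- data.frame(a = integer(0), b = integer(0), height = numeric(0))
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      h <- mean(D0[clusters[[i]], clusters[[j]]])
      key <- sort(c(min(ids[clusters[[i]]]), min(ids[clusters[[j]]])))
      cand <- list(i = i, j = j, h = h, key = key)
      if (is.null(best) || h < best$h ||
          (h == best$h && (key[1] < best$key[1] ||
                           (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- cand
    }
    merges <- rbind(merges, data.frame(
      a = nodes[best$i], b = nodes[best$j], height = best$h))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    nodes[best$i] <- step
    clusters[[best$j]] <- NULL
    nodes <- nodes[-best$j]
  }
  merges
}

# canonical form of a merge list: per step the sorted node pair + height
canon_merges <- function(m) {
  data.frame(lo = pmin(m$a, m$b), hi = pmax(m$a, m$b), height = m$height)
}

# dense-algebra CVA oracle: explicit inversion of the within scatter and
# eigendecomposition of W^-1 B; Mahalanobis distances computed directly.
oracle_cva <- function(X, lab) {
  g <- max(lab); p <- ncol(X); n <- nrow(X)
  grand <- colMeans(X)
  means <- t(sapply(seq_len(g), function(i) colMeans(X[lab == i, , drop = FALSE])))
  W <- Reduce(`+`, lapply(seq_len(g), function(i) {
    Z <- sweep(X[lab == i, , drop = FALSE], 2, means[i, ])
    t(Z) %*% Z
  }))
  sizes <- tabulate(lab, g)
  B <- Reduce(`+`, lapply(seq_len(g), function(i)
    sizes[i] * tcrossprod(means[i, ] - grand)))
  ev <- eigen(solve(W) %*% B)
  vals <- sort(Re(ev$values), decreasing = TRUE)
  Sw <- W / (n - g)
  Swi <- solve(Sw)
  d2 <- t(apply(X, 1, function(x) sapply(seq_len(g), function(i) {
    z <- x - means[i, ]
    drop(t(z) %*% Swi %*% z)
  })))
  list(eigenvalues = vals, assigned = apply(d2, 1, which.min), d2 = d2)
}

# independent coordinate geometry for the landmark-derived lengths
oracle_lengths <- function(P) {
  P <- unname(as.matrix(P))
  d <- function(i, j) sqrt((P[i, 1] - P[j, 1])^2 + (P[i, 2] - P[j, 2])^2)
  # distance of LM1 from line through LM4, LM5 via the triangle-area formula
  x1 <- P[4, 1]; y1 <- P[4, 2]; x2 <- P[5, 1]; y2 <- P[5, 2]
  area2 <- abs((x2 - x1) * (P[1, 2] - y1) - (P[1, 1] - x1) * (y2 - y1))
  dist1 <- area2 / d(4, 5)
  # side test: is LM1 on the same side as LM7?
  side <- function(i) sign((x2 - x1) * (P[i, 2] - y1) - (P[i, 1] - x1) * (y2 - y1))
  L1 <- if (side(1) != 0 && side(1) == side(7)) 0 else dist1
  ux <- (P[5, 1] - P[6, 1]) / d(5, 6); uy <- (P[5, 2] - P[6, 2]) / d(5, 6)
  pr <- sapply(2:7, function(i) P[i, 1] * ux + P[i, 2] * uy)
  c(L1 = L1, L2 = d(1, 11), L3 = d(2, 4), L4 = diff(range(pr)),
    L5 = d(5, 6), L6 = d(5, 7), L8 = d(9, 10))
}

# exact assignment by full permutation enumeration (n <= 8)
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  cols <- utils::combn(ncol(cost), n, simplify = FALSE)
  best <- NULL
  for (cs in cols) for (p in perms(cs)) {
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (is.null(best) || tot < best$cost) best <- list(cost = tot, sel = p)
  }
  best
}
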