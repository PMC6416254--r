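#' Correlation-based pruning of collinear length variables
#'
#' Reproduces the variable-dependence step that precedes clustering: Pearson
#' correlations are computed pairwise on complete cases for every candidate
#' pair of length variables, variables are linked when `|r| >= threshold`,
#' connected components of the resulting graph form clusters of mutually
#' dependent variables, and within each cluster the variable that comes
#' earliest in `priority` is kept as the representative. The default priority
#' encodes the "easiest to measure" preferences of the original analysis:
#' scale height L6 stands in for keel length L2 and base posterior margin L8,
#' and scale length L5 stands in for concealed-field length L7.
#'
#' Variables are analysed on raw millimetre values, unstandardized: all share
#' the same dimension, and Pearson correlation is scale-invariant anyway.
#'
#' @param table a [measurement_table()].
#' @param threshold correlation magnitude at or above which two variables are
#'   considered dependent. Default 0.90.
#' @param priority character vector ordering the variables by preference;
#'   within a dependent cluster the earliest listed variable is kept.
#' @return object of class `correlation_report`: `variables`, `matrix`
#'   (Pearson correlations), `clusters` (list of variable groups), `kept`,
#'   `dropped` (named character vector, dropped variable -> representative),
#'   `threshold`.
#' @export
select_variables <- function(table, threshold = 0.90,
                             priority = c("L6", "L5", "L1", "L3",
                                          "L4", "L2", "L7", "L8")) {
  stopifnot(inherits(table, "measurement_table"))
  vars <- table$variables
  X <- table$data[vars]
  complete <- stats::complete.cases(X)
  if (sum(complete) < 3)
    stop_scalemorph("data", "fewer than 3 complete rows; cannot estimate correlations")
  sds <- vapply(X[complete, , drop = FALSE], stats::sd, numeric(1))
  if (any(sds == 0))
    stop_scalemorph("degenerate", "zero-variance variable(s): %s",
                    paste(vars[sds == 0], collapse = ", "))
  R <- stats::cor(X, use = "pairwise.complete.obs", method = "pearson")

  # connected components of the |r| >= threshold graph (union-find; the
  # graph has at most 8 nodes)
  parent <- seq_along(vars)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(vars)) for (j in seq_len(i - 1L)) {
    if (!is.na(R[i, j]) && abs(R[i, j]) >= threshold)
      parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_along(vars), find, integer(1))
  clusters <- split(vars, comp)
  names(clusters) <- NULL
  # order clusters by their first variable's position in `vars`
  clusters <- clusters[order(vapply(clusters, function(cl)
    min(match(cl, vars)), integer(1)))]

  rank_of <- function(v) {
    r <- match(v, priority)
    r[is.na(r)] <- length(priority) + match(v, vars)[is.na(r)]
    r
  }
  kept <- vapply(clusters, function(cl) cl[which.min(rank_of(cl))],
                 character(1))
  dropped_list <- lapply(seq_along(clusters), function(i)
    stats::setNames(rep(kept[i], length(clusters[[i]]) - 1L),
                    setdiff(clusters[[i]], kept[i])))
  dropped <- unlist(dropped_list)
  if (is.null(dropped)) dropped <- stats::setNames(character(0), character(0))
  kept <- vars[sort(match(kept, vars))]
  structure(list(variables = vars, matrix = R, clusters = clusters,
                 kept = kept, dropped = dropped, threshold = threshold),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> threshold %.2f\n", x$threshold))
  cat("  kept:   ", paste(x$kept, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped:", paste(sprintf("%s (-> %s)", names(x$dropped), x$dropped),
                            collapse = ", "), "\n")
  invisible(x)
}
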