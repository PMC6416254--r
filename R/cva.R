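#' Fit a canonical variate analysis to grouped scales
#'
#' Computes the between-group scatter matrix `B` (group-size-weighted outer
#' products of group-mean deviations from the grand mean) and the pooled
#' within-group scatter `W` on the selected variables, and solves the
#' generalized eigenproblem of `W^-1 B` via symmetric whitening: with the
#' pooled within-group covariance `Sw = W / (n - g)` and its inverse square
#' root, the eigendecomposition of `Sw^-1/2 B Sw^-1/2` yields the canonical
#' axes. Coefficients are scaled so the pooled within-group variance along
#' each axis is 1. At most `min(g - 1, p)` axes carry signal; trailing
#' near-zero eigenvalues are truncated.
#'
#' A single-member group contributes a mean (and so a between-group
#' deviation) but no within-group scatter; this is permitted. If `W` is
#' singular the fit aborts, advising the ridge option
#' (`W + lambda * diag(W)`).
#'
#' @param table a [measurement_table()].
#' @param labels a `scale_partition` (or integer labels named by scale_id).
#' @param variables variables to use (default: all in the table).
#' @param ridge non-negative ridge coefficient `lambda`; default 0.
#' @return object of class `cva_model`: `group_means`, `pooled_within_cov`,
#'   `canonical_coefficients` (p x m), `eigenvalues` (descending, of
#'   `W^-1 B`), `groups`, `n_per_group`, `variables`, `grand_mean`.
#' @export
fit_cva <- function(table, labels, variables = table$variables, ridge = 0) {
  stopifnot(inherits(table, "measurement_table"))
  lab <- if (inherits(labels, "scale_partition")) labels$labels else labels
  X <- as.matrix(table$data[variables])
  n <- nrow(X); p <- ncol(X)
  if (length(lab) != n)
    stop_scalemorph("label", "labels (%d) do not cover the table (%d rows)",
                    length(lab), n)
  g <- max(lab)
  sizes <- tabulate(lab, g)
  if (any(sizes == 0))
    stop_scalemorph("label", "empty group(s): %s",
                    paste(which(sizes == 0), collapse = ", "))

  grand <- colMeans(X)
  means <- do.call(rbind, lapply(seq_len(g), function(i)
    colMeans(X[lab == i, , drop = FALSE])))
  dimnames(means) <- list(paste0("G", seq_len(g)), variables)

  W <- matrix(0, p, p)
  for (i in seq_len(g)) {
    Xi <- sweep(X[lab == i, , drop = FALSE], 2, means[i, ])
    W <- W + crossprod(Xi)
  }
  B <- crossprod(sweep(means, 2, grand) * sqrt(sizes))
  if (ridge > 0) {
    # ridge on the scatter diagonal; a variable with zero within-group
    # scatter falls back to a unit ridge so the rescue always works
    d <- diag(W)
    d[d == 0] <- if (any(d > 0)) mean(d[d > 0]) else 1
    W <- W + ridge * diag(d, p)
  }
  Sw <- W / (n - g)
  dimnames(Sw) <- list(variables, variables)

  ew <- eigen(Sw, symmetric = TRUE)
  if (min(ew$values) <= max(ew$values) * 1e-10)
    stop_scalemorph("singularity",
                    "pooled within-group scatter is singular; consider ridge > 0")
  Sw_inv_half <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)

  A <- Sw_inv_half %*% (B / (n - g)) %*% Sw_inv_half
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
  m <- min(g - 1L, p)
  vals <- pmax(ea$values, 0)[seq_len(m)]
  m <- max(1L, sum(vals > max(vals[1], .Machine$double.eps) * 1e-9))
  coef <- Sw_inv_half %*% ea$vectors[, seq_len(m), drop = FALSE]
  dimnames(coef) <- list(variables, paste0("CV", seq_len(m)))

  structure(list(group_means = means, pooled_within_cov = Sw,
                 canonical_coefficients = coef,
                 eigenvalues = vals[seq_len(m)],
                 groups = seq_len(g), n_per_group = sizes,
                 variables = variables, grand_mean = grand,
                 ridge = ridge),
            class = "cva_model")
}

#' @export
print.cva_model <- function(x, ...) {
  cat(sprintf("<cva_model> %d groups, %d variables, %d canonical axes\n",
              length(x$groups), length(x$variables),
              length(x$eigenvalues)))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Classify scales by Mahalanobis distance to group means
#'
#' Assigns each scale to the group whose mean is nearest in Mahalanobis
#' distance under the pooled within-group covariance (equal priors - linear
#' discrimination). Exact ties go to the lowest group id. When reference
#' labels are supplied (or present in the partition used to fit), a
#' confusion matrix (rows = given labels, columns = predictions) and the
#' resubstitution accuracy `trace(confusion) / n` are reported, along with
#' per-scale canonical-axis scores for scatter plotting.
#'
#' @param model a [fit_cva()] model.
#' @param table a [measurement_table()] carrying the model's variables.
#' @param labels optional reference labels (a `scale_partition` or integer
#'   vector) for confusion/accuracy.
#' @return object of class `classification_result`: `predicted`,
#'   `confusion` (or NULL), `accuracy` (or NA), `scores`, `mahalanobis_sq`
#'   (n x g squared distances).
#' @export
classify <- function(model, table, labels = NULL) {
  stopifnot(inherits(model, "cva_model"))
  miss <- setdiff(model$variables, names(table$data))
  if (length(miss))
    stop_scalemorph("schema", "table lacks model variable(s): %s",
                    paste(miss, collapse = ", "))
  X <- as.matrix(table$data[model$variables])
  g <- length(model$groups)
  Sinv <- chol2inv(chol(model$pooled_within_cov))
  d2 <- vapply(seq_len(g), function(i) {
    Z <- sweep(X, 2, model$group_means[i, ])
    rowSums((Z %*% Sinv) * Z)
  }, numeric(nrow(X)))
  d2 <- matrix(d2, nrow = nrow(X))
  predicted <- apply(d2, 1L, which.min)   # which.min: lowest index on ties
  scores <- sweep(X, 2, model$grand_mean) %*% model$canonical_coefficients
  rownames(scores) <- table$data$scale_id

  lab <- if (inherits(labels, "scale_partition")) labels$labels else labels
  confusion <- NULL; accuracy <- NA_real_
  if (!is.null(lab)) {
    confusion <- table(factor(lab, levels = seq_len(g)),
                       factor(predicted, levels = seq_len(g)))
    dimnames(confusion) <- list(given = paste0("G", seq_len(g)),
                                predicted = paste0("G", seq_len(g)))
    accuracy <- sum(diag(confusion)) / length(lab)
  }
  structure(list(predicted = stats::setNames(predicted, table$data$scale_id),
                 confusion = confusion, accuracy = accuracy,
                 scores = scores, mahalanobis_sq = d2),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>",
      if (!is.na(x$accuracy)) sprintf("accuracy %.4f", x$accuracy) else "",
      "\n")
  invisible(x)
}

#' Iteratively refine group labels by CVA reclassification
#'
#' Per round: fit a CVA on the current labels, classify all scales, move
#' every misclassified scale to its predicted group, and refit. Stops when
#' no scale moves or after `max_rounds`. The default of one round mirrors a
#' single adjust-and-revalidate pass. If a reassignment empties a group,
#' that group is retired and the group count drops by one, with a warning.
#'
#' The returned history holds one `classification_result` per fitted model:
#' `history[[1]]` is the classification under the initial labels (its
#' accuracy is the pre-adjustment rate), `history[[r+1]]` under the labels
#' after round r.
#'
#' @param table a [measurement_table()].
#' @param labels starting `scale_partition`.
#' @param max_rounds maximum refinement rounds (default 1).
#' @param variables variables to use.
#' @param ridge passed to [fit_cva()].
#' @return list: `partition` (refined), `history` (classification results),
#'   `accuracy` (numeric vector across history), `moves` (scales moved per
#'   round), `models` (fitted `cva_model`s).
#' @export
refine_labels <- function(table, labels, max_rounds = 1,
                          variables = table$variables, ridge = 0) {
  if (max_rounds < 1)
    stop_scalemorph("argument", "max_rounds must be >= 1")
  lab <- if (inherits(labels, "scale_partition")) labels$labels else labels
  history <- list(); models <- list(); moves <- integer(0)
  for (round in seq_len(max_rounds + 1L)) {
    model <- fit_cva(table, lab, variables = variables, ridge = ridge)
    res <- classify(model, table, labels = lab)
    history[[round]] <- res
    models[[round]] <- model
    if (round > max_rounds) break
    moved <- sum(res$predicted != lab)
    if (moved == 0) break
    moves <- c(moves, moved)
    lab <- res$predicted
    kept <- sort(unique(lab))
    if (length(kept) < length(model$groups)) {
      warning(sprintf("group(s) %s emptied by reassignment and retired",
                      paste(setdiff(model$groups, kept), collapse = ", ")),
              call. = FALSE)
      lab <- match(lab, kept)
      names(lab) <- names(res$predicted)
    }
  }
  list(partition = partition(lab, method_params = list(method = "cva_refined")),
       history = history,
       accuracy = vapply(history, `[[`, numeric(1), "accuracy"),
       moves = moves, models = models)
}
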