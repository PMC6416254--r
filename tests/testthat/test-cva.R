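three_group_table <- function(seed = 8, per = 10) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(4, 1), c(1, 5))
  X <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(per * 2, sd = 0.7), per, 2), 2, centers[i, ], `+`)))
  X <- X - min(X) + 0.1
  colnames(X) <- c("L5", "L6")
  list(table = table_from_matrix(X), lab = rep(1:3, each = per))
}

test_that("two groups separated on one variable yield exactly one positive eigenvalue", {
  tab <- measurement_table(data.frame(
    scale_id = sprintf("s%d", 1:6),
    L5 = c(0, 0.1, 0.2, 10, 10.1, 9.9)))
  model <- fit_cva(tab, rep(1:2, each = 3))
  expect_length(model$eigenvalues, 1)
  expect_gt(model$eigenvalues[1], 0)
})

test_that("eigenvalues and assignments match the dense-algebra oracle", {
  for (seed in c(8, 21, 34)) {
    d <- three_group_table(seed)
    model <- fit_cva(d$table, d$lab)
    orc <- oracle_cva(as.matrix(d$table$data[c("L5", "L6")]), d$lab)
    expect_equal(model$eigenvalues,
                 orc$eigenvalues[seq_along(model$eigenvalues)],
                 tolerance = 1e-8)
    res <- classify(model, d$table, labels = d$lab)
    expect_equal(unname(res$predicted), orc$assigned)
    expect_equal(unname(res$mahalanobis_sq), unname(orc$d2), tolerance = 1e-8)
    expect_lte(length(model$eigenvalues), min(2, 2))  # min(g-1, p)
  }
})

test_that("classification agrees with an equal-prior linear discriminant cross-check", {
  d <- three_group_table(55, per = 15)
  df <- data.frame(d$table$data[c("L5", "L6")], grp = factor(d$lab))
  ld <- MASS::lda(grp ~ L5 + L6, data = df, prior = rep(1 / 3, 3))
  pred <- as.integer(predict(ld)$class)
  model <- fit_cva(d$table, d$lab)
  res <- classify(model, d$table, labels = d$lab)
  expect_equal(unname(res$predicted), pred)
  # eigenvalue ratios match lda's squared singular values
  expect_equal(model$eigenvalues / model$eigenvalues[1],
               ld$svd^2 / ld$svd[1]^2, tolerance = 1e-6)
})

test_that("the fit is invariant to within-group row permutation", {
  d <- three_group_table(3)
  m1 <- fit_cva(d$table, d$lab)
  set.seed(1)
  perm <- unlist(lapply(1:3, function(g) sample(which(d$lab == g))))
  tab2 <- measurement_table(d$table$data[perm, ])
  m2 <- fit_cva(tab2, d$lab[perm])
  expect_equal(m2$group_means, m1$group_means)
  expect_equal(m2$eigenvalues, m1$eigenvalues, tolerance = 1e-10)
})

test_that("classification is invariant under invertible affine transforms", {
  set.seed(12)
  d <- three_group_table(12)
  base <- classify(fit_cva(d$table, d$lab), d$table)$predicted
  for (rep in 1:10) {
    A <- matrix(rnorm(4), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
    Xt <- as.matrix(d$table$data[c("L5", "L6")]) %*% t(A)
    Xt <- Xt - min(Xt) + 1             # translate to keep lengths positive
    colnames(Xt) <- c("L5", "L6")
    tabt <- table_from_matrix(Xt)
    predt <- classify(fit_cva(tabt, d$lab), tabt)$predicted
    expect_equal(unname(predt), unname(base))
  }
})

test_that("exact group means and equidistant points resolve as documented", {
  tab <- measurement_table(data.frame(
    scale_id = sprintf("s%d", 1:8),
    L5 = c(0, 0, 1, 1, 10, 10, 11, 11)))
  lab <- rep(1:2, each = 4)
  model <- fit_cva(tab, lab)
  at_mean <- measurement_table(data.frame(scale_id = "q", L5 = 0.5))
  expect_equal(unname(classify(model, at_mean)$predicted), 1L)
  midpoint <- measurement_table(data.frame(scale_id = "q", L5 = 5.5))
  expect_equal(unname(classify(model, midpoint)$predicted), 1L)  # tie -> lowest id
})

test_that("eigenvalue count respects min(g-1, p) across random fits", {
  set.seed(90)
  for (rep in 1:12) {
    g <- sample(2:5, 1); p <- sample(2:5, 1); per <- sample(4:8, 1)
    b <- random_blobs(g, per, p = p, sep = 6)
    colnames(b$X) <- paste0("L", seq_len(p))
    model <- fit_cva(table_from_matrix(b$X), b$lab)
    expect_lte(length(model$eigenvalues), min(g - 1, p))
    expect_true(all(diff(model$eigenvalues) <= 1e-12))
    expect_true(all(model$eigenvalues >= 0))
  }
})

test_that("singular within-scatter aborts with ridge advice; ridge rescues it", {
  tab <- measurement_table(data.frame(
    scale_id = c("a", "b", "c", "d"),
    L5 = c(1, 1, 2, 2), L6 = c(3, 3, 4, 4)))
  expect_error(fit_cva(tab, c(1, 1, 2, 2)), "ridge",
               class = "scalemorph_singularity")
  expect_s3_class(fit_cva(tab, c(1, 1, 2, 2), ridge = 1e-3), "cva_model")
})

test_that("a self-consistent partition is a refinement fixpoint", {
  d <- three_group_table(64, per = 12)
  part <- partition(stats::setNames(d$lab, d$table$data$scale_id))
  ref <- refine_labels(d$table, part, max_rounds = 3)
  expect_equal(ref$partition$labels, part$labels)
  expect_equal(ref$accuracy[1], 1.0)
  expect_length(ref$moves, 0)
})

test_that("after one round every label equals the previous model's prediction", {
  spec <- default_reference_spec(label_noise = 0.05)
  gen <- generate_measurements(spec, seed = 2)
  ref <- refine_labels(gen$table, gen$noisy_labels, max_rounds = 1)
  if (ref$partition$k == gen$noisy_labels$k)   # no group retired
    expect_equal(ref$partition$labels, ref$history[[1]]$predicted)
})

test_that("one refinement round strictly improves noisy labels in >= 18/20 seeds", {
  improved <- vapply(1:20, function(seed) {
    gen <- generate_measurements(default_reference_spec(label_noise = 0.05),
                                 seed = seed)
    ref <- suppressWarnings(
      refine_labels(gen$table, gen$noisy_labels, max_rounds = 1))
    acc <- ref$accuracy
    acc[2] > acc[1]
  }, logical(1))
  expect_gte(sum(improved), 18)
})
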