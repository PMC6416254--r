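# small builders used across test files

table_from_matrix <- function(X, ids = sprintf("s%02d", seq_len(nrow(X)))) {
  df <- data.frame(scale_id = ids, as.data.frame(X))
  measurement_table(df, provenance = "test fixture")
}

# two tight 3-point blobs far apart in 2 variables
blob_table <- function() {
  X <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
             c(10, 10), c(10.1, 10), c(10, 10.1))
  colnames(X) <- c("L5", "L6")
  table_from_matrix(X)
}

# random gaussian blobs for property tests
random_blobs <- function(n_groups, per_group, p = 2, sep = 8, sd = 1) {
  centers <- matrix(runif(n_groups * p, 0, sep * n_groups), n_groups, p)
  X <- do.call(rbind, lapply(seq_len(n_groups), function(i)
    sweep(matrix(rnorm(per_group * p, sd = sd), per_group, p), 2,
          centers[i, ], `+`)))
  X <- X - min(X) + 0.1              # lengths must be non-negative
  list(X = X, lab = rep(seq_len(n_groups), each = per_group))
}

# the full synthetic pipeline result is reused by several files; built once
pipeline_cache <- new.env(parent = emptyenv())
default_pipeline_result <- function() {
  if (is.null(pipeline_cache$res))
    pipeline_cache$res <- run_pipeline(list(seed = 1))
  pipeline_cache$res
}

rigid_motion <- function(P, angle, shift, reflect = FALSE) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  if (reflect) R <- R %*% diag(c(1, -1))
  sweep(P %*% t(R), 2, shift, `+`)
}
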