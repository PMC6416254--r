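#' Construct a synthetic-data specification
#'
#' A synthetic spec lists multivariate clusters of scales, each with a
#' morphotype id, a size, and per-variable normal means and SDs (mm) over
#' the five analysis variables L1, L3, L4, L5, L6. Variables are drawn
#' independently (only marginal SDs are published); a covariance hook can be
#' added per cluster via a `cov` element for harder tests.
#'
#' @param clusters data.frame with columns `morphotype`, `size`, and
#'   `<V>_mean` / `<V>_sd` for V in L1, L3, L4, L5, L6.
#' @param label_noise fraction in `[0, 1)` of records whose true label is
#'   replaced by a uniformly chosen *different* group label when noisy
#'   labels are requested.
#' @param seed default seed for generation (overridable per call).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(clusters, label_noise = 0, seed = 1L) {
  vars <- c("L1", "L3", "L4", "L5", "L6")
  need <- c("morphotype", "size", paste0(vars, "_mean"), paste0(vars, "_sd"))
  miss <- setdiff(need, names(clusters))
  if (length(miss))
    stop_scalemorph("argument", "spec clusters lack column(s): %s",
                    paste(miss, collapse = ", "))
  if (any(clusters$size < 1))
    stop_scalemorph("argument", "cluster sizes must be >= 1")
  if (any(as.matrix(clusters[paste0(vars, "_sd")]) < 0))
    stop_scalemorph("argument", "SDs must be >= 0")
  if (label_noise < 0 || label_noise >= 1)
    stop_scalemorph("argument", "label_noise must be in [0, 1)")
  structure(list(clusters = clusters, variables = vars,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d clusters, %d scales total, label_noise %.2f\n",
              nrow(x$clusters), sum(x$clusters$size), x$label_noise))
  invisible(x)
}

#' Default synthetic spec from the published morphotype parameters
#'
#' Builds the study-condition spec: 8 clusters with the published group
#' sizes (23, 64, 49, 37, 27, 15, 10, 1; the single scale is morphotype 12),
#' L5 and L6 means/SDs straight from the reference table, and L1, L3 means
#' recovered from the ratio columns (`L1_mean = mean(L1/L6) * mean(L6)`,
#' likewise L3) with SDs propagated to first order
#' (`sd^2 = (mean_L6 * sd_ratio)^2 + (mean_ratio * sd_L6)^2`). L4 (extent
#' along the body axis) has no published statistics; it defaults to L5's
#' mean and SD, both measuring anteroposterior extent of a rhombic scale.
#'
#' @param label_noise passed through to [synthetic_spec()].
#' @return a `synthetic_spec` totalling 226 scales in 8 clusters.
#' @export
default_reference_spec <- function(label_noise = 0) {
  ref <- morphotype_reference()
  cl <- data.frame(
    morphotype = ref$morphotype,
    size = ref$size,
    L1_mean = ref$L1_over_L6_mean * ref$L6_mean,
    L1_sd = sqrt((ref$L6_mean * ref$L1_over_L6_sd)^2 +
                 (ref$L1_over_L6_mean * ref$L6_sd)^2),
    L3_mean = ref$L3_over_L6_mean * ref$L6_mean,
    L3_sd = sqrt((ref$L6_mean * ref$L3_over_L6_sd)^2 +
                 (ref$L3_over_L6_mean * ref$L6_sd)^2),
    L4_mean = ref$L5_mean, L4_sd = ref$L5_sd,
    L5_mean = ref$L5_mean, L5_sd = ref$L5_sd,
    L6_mean = ref$L6_mean, L6_sd = ref$L6_sd)
  synthetic_spec(cl, label_noise = label_noise)
}

#' Generate a synthetic measurement table
#'
#' Draws each scale's variables independently from
#' `Normal(mean, SD)` truncated at 0 (negative draws clamp to 0; at the
#' reference mean/SD ratios this is vanishingly rare). True cluster labels
#' are returned separately from the table; when the spec requests label
#' noise, a noisy copy of the labels is returned as well, with the selected
#' records relabeled to a uniformly chosen different group.
#'
#' @param spec a [synthetic_spec()].
#' @param seed seed override; defaults to the spec's own seed.
#' @return list: `table` (a `measurement_table` with scale_id `syn_0001`...),
#'   `labels` (true group index per record, a `scale_partition`),
#'   `noisy_labels` (`scale_partition` or NULL), `morphotypes` (true
#'   morphotype id per record).
#' @export
generate_measurements <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  cl <- spec$clusters
  vars <- spec$variables
  n <- sum(cl$size)
  lab <- rep(seq_len(nrow(cl)), cl$size)
  X <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  row0 <- 0L
  for (i in seq_len(nrow(cl))) {
    for (v in vars) {
      X[row0 + seq_len(cl$size[i]), v] <-
        pmax(0, rnorm(cl$size[i], cl[[paste0(v, "_mean")]][i],
                      cl[[paste0(v, "_sd")]][i]))
    }
    row0 <- row0 + cl$size[i]
  }
  ids <- sprintf("syn_%04d", seq_len(n))
  tab <- measurement_table(
    data.frame(scale_id = ids, X),
    provenance = sprintf("synthetic (seed %d)", seed))
  names(lab) <- ids
  noisy <- NULL
  if (spec$label_noise > 0) {
    nl <- lab
    k <- nrow(cl)
    pick <- sample(n, round(spec$label_noise * n))
    nl[pick] <- vapply(nl[pick], function(g)
      sample(setdiff(seq_len(k), g), 1L), integer(1))
    noisy <- partition(nl, method_params = list(
      method = "true labels + noise", noise = spec$label_noise))
  }
  list(table = tab,
       labels = partition(lab, method_params = list(method = "true labels")),
       noisy_labels = noisy,
       morphotypes = cl$morphotype[lab])
}

#' Generate an 11-landmark configuration with prescribed lengths
#'
#' Inverse construction for morphometry fixtures: builds a crown-view
#' rhombic-scale landmark configuration whose derived L5 (scale length),
#' L6 (height), L1 (peg length) and L3 (anterodorsal process length) equal
#' the requested values exactly, then optionally jitters every coordinate
#' with independent normal noise. Requests may come from a morphotype id
#' (reference means are used) or explicit lengths.
#'
#' @param morphotype optional reference morphotype id; fills unspecified
#'   lengths from [morphotype_reference()] means.
#' @param L5,L6,L1,L3 requested lengths (mm); all must be positive except
#'   L1 >= 0.
#' @param jitter SD (mm) of independent normal coordinate noise, default 0.
#' @param seed seed for the jitter.
#' @param scale_id identifier for the configuration.
#' @return a [landmark_config()].
#' @export
generate_landmarks <- function(morphotype = NULL, L5 = NULL, L6 = NULL,
                               L1 = NULL, L3 = NULL, jitter = 0,
                               seed = NULL, scale_id = "synthetic") {
  if (!is.null(morphotype)) {
    ref <- morphotype_reference()
    row <- ref[ref$morphotype == morphotype, ]
    if (!nrow(row))
      stop_scalemorph("argument", "unknown reference morphotype %s", morphotype)
    if (is.null(L5)) L5 <- row$L5_mean
    if (is.null(L6)) L6 <- row$L6_mean
    if (is.null(L1)) L1 <- row$L1_over_L6_mean * row$L6_mean
    if (is.null(L3)) L3 <- row$L3_over_L6_mean * row$L6_mean
  }
  if (is.null(L5) || is.null(L6) || is.null(L1) || is.null(L3))
    stop_scalemorph("argument", "L5, L6, L1 and L3 must all be resolvable")
  if (L5 <= 0 || L6 <= 0 || L1 < 0 || L3 <= 0)
    stop_scalemorph("construction",
                    "impossible lengths: need L5 > 0, L6 > 0, L1 >= 0, L3 > 0")
  # dorsal crown margin along the x-axis; posterior margin down the y-axis
  theta <- 35 * pi / 180          # anterodorsal process leaves LM4 at 35 deg
  P <- rbind(
    LM1  = c(-0.30 * L5, L1),                       # peg tip, above the margin
    LM2  = c(-0.60 * L5 - L3 * cos(theta), L3 * sin(theta)),
    LM3  = c(-0.30 * L5, 0),                        # dorsal margin midpoint
    LM4  = c(-0.60 * L5, 0),
    LM5  = c(0, 0),
    LM6  = c(-L5, 0),
    LM7  = c(0, -L6),
    LM8  = c(0.10 * L5, 0),
    LM9  = c(0.10 * L5, 0.05 * L6),
    LM10 = c(0.10 * L5, -0.80 * L6),
    LM11 = c(-0.40 * L5, -0.80 * L6))
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    P <- P + matrix(rnorm(22, 0, jitter), 11, 2)
  }
  landmark_config(P, scale_id = scale_id)
}
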