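#' Construct an 11-landmark scale configuration
#'
#' Crown-view landmark scheme for a rhombic scale, indices 1-11:
#' 1 tip of the peg; 2 tip of the anterodorsal process; 3 midpoint of the
#' dorsal crown margin; 4 intersection of the anterior crown margin and the
#' anterodorsal process; 5 intersection of the dorsal and posterior crown
#' margins; 6 projection of landmark 5 on the anterior margin; 7 intersection
#' of the posterior and ventral crown margins; 8 projection of landmark 5 on
#' the posterior base margin; 9 intersection of the posterior and dorsal base
#' margins; 10 intersection of the posterior and ventral base margins;
#' 11 intersection of the keel and the ventral base margin.
#'
#' @param points 11 x 2 numeric matrix of coordinates (mm).
#' @param scale_id identifier string.
#' @param view `"crown"` or `"basal"`.
#' @return object of class `landmark_config`.
#' @export
landmark_config <- function(points, scale_id = "scale", view = "crown") {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2 || nrow(points) != 11)
    stop_scalemorph("geometry", "landmark configuration must be an 11 x 2 numeric matrix")
  if (!all(is.finite(points)))
    stop_scalemorph("geometry", "non-finite landmark coordinates in '%s'", scale_id)
  view <- match.arg(view, c("crown", "basal"))
  # crown corners (4,5,6,7) must span the plane
  corners <- points[c(4, 5, 6, 7), ]
  rel <- sweep(corners[-1, , drop = FALSE], 2, corners[1, ])
  if (qr(rel)$rank < 2)
    stop_scalemorph("geometry", "crown corner landmarks 4,5,6,7 are collinear in '%s'",
                    scale_id)
  dimnames(points) <- list(paste0("LM", 1:11), c("x", "y"))
  structure(list(points = points, scale_id = scale_id, view = view),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> '%s', %d landmarks, %s view\n",
              x$scale_id, nrow(x$points), x$view))
  invisible(x)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Compute length variables from an 11-landmark configuration
#'
#' Derives the inter-landmark length variables used by the morphotype
#' analysis. With `P[i]` the i-th landmark:
#' \describe{
#'   \item{L1 (peg length)}{perpendicular distance of landmark 1 from the
#'     dorsal crown margin (the line through landmarks 4 and 5), counted only
#'     on the side away from the crown interior (landmark 7 marks the
#'     interior side); clamped at 0.}
#'   \item{L2 (keel length, proxy)}{distance P1-P11. An approximation: the
#'     keel has no dedicated landmark pair; L2 is pruned by variable
#'     selection before clustering, so the proxy never reaches the analysis.}
#'   \item{L3 (anterodorsal process length)}{distance P2-P4.}
#'   \item{L4 (anteroposterior extent)}{extent (max minus min) of the
#'     projections of landmarks 2..7 on the anteroposterior unit axis
#'     `u = unit(P5 - P6)`. Isolated scales carry no body frame, so the
#'     scale's own length axis stands in for the longitudinal body axis.}
#'   \item{L5 (scale length)}{distance P5-P6.}
#'   \item{L6 (crown posterior-margin length, scale height)}{distance P5-P7.}
#'   \item{L8 (base posterior-margin length)}{distance P9-P10.}
#' }
#' L7 (concealed-field length) is not derivable from this landmark scheme; it
#' is treated as a directly measured optional input and never computed here.
#' All outputs are invariant under rotation, translation and reflection, and
#' scale linearly with the coordinates.
#'
#' @param cfg a [landmark_config()] in crown view.
#' @return named numeric vector with elements L1, L2, L3, L4, L5, L6, L8 (mm).
#' @export
compute_length_variables <- function(cfg) {
  if (!inherits(cfg, "landmark_config"))
    stop_scalemorph("geometry", "cfg must be a landmark_config")
  if (!isTRUE(attr(cfg, "conforming")) && nrow(cfg$points) != 11)
    stop_scalemorph("geometry", "configuration '%s' does not have 11 landmarks",
                    cfg$scale_id)
  if (cfg$view != "crown")
    stop_scalemorph("geometry", "length variables are defined on the crown view")
  P <- cfg$points
  if (euclid(P[4, ], P[5, ]) == 0)
    stop_scalemorph("geometry", "degenerate dorsal margin: landmarks 4 and 5 coincide")
  if (euclid(P[5, ], P[6, ]) == 0)
    stop_scalemorph("geometry", "degenerate length axis: landmarks 5 and 6 coincide")

  # signed distance from the dorsal-margin line, positive on the peg side
  # (the side opposite the crown interior, marked by landmark 7)
  m <- P[5, ] - P[4, ]
  nrm <- c(-m[2], m[1]) / sqrt(sum(m^2))
  s1 <- sum((P[1, ] - P[4, ]) * nrm)
  s7 <- sum((P[7, ] - P[4, ]) * nrm)
  L1 <- max(0, if (s7 > 0) -s1 else s1)

  u <- (P[5, ] - P[6, ]) / euclid(P[5, ], P[6, ])
  proj <- as.vector(P[2:7, ] %*% u)
  c(L1 = L1,
    L2 = euclid(P[1, ], P[11, ]),
    L3 = euclid(P[2, ], P[4, ]),
    L4 = max(proj) - min(proj),
    L5 = euclid(P[5, ], P[6, ]),
    L6 = euclid(P[5, ], P[7, ]),
    L8 = euclid(P[9, ], P[10, ]))
}

#' Per-scale shape ratios
#'
#' Computes the dimensionless ratios used in the morphotype summaries:
#' height/length `L6/L5`, relative peg length `L1/L6`, relative anterodorsal
#' process length `L3/L6`, and relative concealed-field length `L7/L5`
#' (absent when L7 was not measured). Group-level ratio statistics are means
#' of these per-scale ratios, never ratios of group means.
#'
#' @param lengths named numeric vector with at least `L5 > 0` and `L6 > 0`;
#'   `L1`, `L3` required, `L7` optional.
#' @return named numeric vector `L6_over_L5`, `L1_over_L6`, `L3_over_L6`,
#'   and `L7_over_L5` when L7 is present.
#' @export
compute_ratios <- function(lengths) {
  need <- c("L1", "L3", "L5", "L6")
  if (!all(need %in% names(lengths)))
    stop_scalemorph("schema", "lengths must name %s", paste(need, collapse = ", "))
  if (is.na(lengths[["L5"]]) || lengths[["L5"]] == 0 ||
      is.na(lengths[["L6"]]) || lengths[["L6"]] == 0)
    stop_scalemorph("ratio", "undefined ratio: L5 and L6 must be positive")
  out <- c(L6_over_L5 = lengths[["L6"]] / lengths[["L5"]],
           L1_over_L6 = lengths[["L1"]] / lengths[["L6"]],
           L3_over_L6 = lengths[["L3"]] / lengths[["L6"]])
  if ("L7" %in% names(lengths) && !is.na(lengths[["L7"]]))
    out <- c(out, L7_over_L5 = lengths[["L7"]] / lengths[["L5"]])
  out
}

#' Convert landmark configurations to measurement-table rows
#'
#' Runs [compute_length_variables()] on each conforming configuration and
#' assembles the results into a [measurement_table()]. Non-conforming
#' configurations (landmark count != 11, as flagged by [read_tps()]) are
#' skipped with a warning.
#'
#' @param configs list of `landmark_config` objects.
#' @return a `measurement_table` with variables L1-L6, L8.
#' @export
landmarks_to_table <- function(configs) {
  ok <- vapply(configs, function(cfg) !isFALSE(attr(cfg, "conforming")),
               logical(1))
  if (any(!ok))
    warning(sprintf("%d non-conforming configuration(s) skipped", sum(!ok)),
            call. = FALSE)
  configs <- configs[ok]
  if (!length(configs))
    stop_scalemorph("data", "no conforming landmark configurations")
  rows <- lapply(configs, function(cfg) {
    L <- compute_length_variables(cfg)
    data.frame(scale_id = cfg$scale_id, as.list(L))
  })
  measurement_table(do.call(rbind, rows), provenance = "derived from landmarks")
}
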