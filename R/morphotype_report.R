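#' Built-in reference parameters for the eight clustered morphotypes
#'
#' Per-morphotype measurement statistics of the flank-scale morphotypes that
#' were delimited quantitatively (morphotypes 1, 2, 3, 6, 8, 10, 11, 12):
#' mean and SD of scale length L5 and scale height L6 (mm), means and SDs of
#' the per-scale ratios L6/L5, L1/L6, L3/L6, the squamation area each
#' morphotype occupies, the ornament ridge-count range (metadata only, not
#' computable from lengths), the average concealed-field fraction of scale
#' length (percent, where reported), and the published group sizes
#' (23, 64, 49, 37, 27, 15, 10, 1; the single-scale group is morphotype 12).
#'
#' For two morphotypes the descriptive text and the table disagree on the
#' height/length ratio (morphotype 6: 2.34 in text vs 2.73 in table;
#' morphotype 11: 1.04 vs 1.11). The table values are the reference used for
#' matching; the text readings are carried in `ratio_text` and not "fixed".
#'
#' @return data.frame, one row per morphotype.
#' @export
morphotype_reference <- function() {
  data.frame(
    morphotype = c(1L, 2L, 3L, 6L, 8L, 10L, 11L, 12L),
    area       = c("M1", "M2", "M3", "D2", "V1", "V3", "V4", "V5"),
    ridges     = c("25-35", "25-30", "10-25", "15-20", "15-25", "5-10",
                   "~10", "10-15"),
    size       = c(23L, 64L, 49L, 37L, 27L, 15L, 10L, 1L),
    L5_mean = c(1.75, 2.03, 1.76, 1.48, 1.95, 1.42, 2.37, 3.35),
    L5_sd   = c(0.18, 0.18, 0.27, 0.26, 0.28, 0.27, 0.39, 0.00),
    L6_mean = c(8.25, 7.17, 5.24, 3.90, 6.55, 2.27, 2.55, 5.66),
    L6_sd   = c(0.51, 0.41, 0.46, 0.38, 0.40, 0.52, 0.50, 0.00),
    L6_over_L5_mean = c(4.75, 3.55, 3.06, 2.73, 3.41, 1.66, 1.11, 1.69),
    L6_over_L5_sd   = c(0.55, 0.34, 0.63, 0.65, 0.53, 0.44, 0.32, 0.00),
    L1_over_L6_mean = c(0.25, 0.32, 0.12, 0.08, 0.18, 0.10, 0.31, 0.14),
    L1_over_L6_sd   = c(0.06, 0.05, 0.07, 0.09, 0.07, 0.13, 0.07, 0.00),
    L3_over_L6_mean = c(0.16, 0.29, 0.15, 0.14, 0.18, 0.30, 0.36, 0.14),
    L3_over_L6_sd   = c(0.04, 0.04, 0.07, 0.09, 0.05, 0.21, 0.20, 0.00),
    concealed_pct = c(38, 34, 35, 35, 38, 37, 35, NA),
    ratio_text = c(NA, NA, 3.06, 2.34, NA, 1.66, 1.04, NA),
    stringsAsFactors = FALSE
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-group summary statistics in the style of the published table
#'
#' For each group of a partition: n, mean and SD of scale length L5 and
#' scale height L6 (mm), mean and SD of the per-scale ratios L6/L5, L1/L6,
#' L3/L6, and the mean concealed-field fraction L7/L5 (percent) when L7 was
#' measured. SDs use the population convention (divisor n), consistent with
#' a single-member group printing SD 0.00. Ratio statistics are computed per
#' scale and then averaged, never as ratios of group means.
#'
#' @param table a [measurement_table()] with at least L1, L3, L5, L6.
#' @param labels a `scale_partition` (or integer labels) covering the table.
#' @return data.frame of class `morphotype_summary`, one row per group.
#' @export
summarize_groups <- function(table, labels) {
  stopifnot(inherits(table, "measurement_table"))
  lab <- if (inherits(labels, "scale_partition")) labels$labels else labels
  df <- table$data
  if (length(lab) != nrow(df))
    stop_scalemorph("label", "labels do not cover the table")
  bad <- which(df$L5 == 0 | df$L6 == 0)
  if (length(bad))
    stop_scalemorph("ratio", "undefined ratio for scale(s) %s (L5 or L6 is 0)",
                    paste(df$scale_id[bad], collapse = ", "))
  g <- max(lab)
  rows <- lapply(seq_len(g), function(i) {
    d <- df[lab == i, , drop = FALSE]
    r65 <- d$L6 / d$L5; r16 <- d$L1 / d$L6; r36 <- d$L3 / d$L6
    concealed <- if ("L7" %in% names(d) && !anyNA(d$L7))
      mean(d$L7 / d$L5) * 100 else NA_real_
    data.frame(group = i, n = nrow(d),
               L5_mean = mean(d$L5), L5_sd = pop_sd(d$L5),
               L6_mean = mean(d$L6), L6_sd = pop_sd(d$L6),
               L6_over_L5_mean = mean(r65), L6_over_L5_sd = pop_sd(r65),
               L1_over_L6_mean = mean(r16), L1_over_L6_sd = pop_sd(r16),
               L3_over_L6_mean = mean(r36), L3_over_L6_sd = pop_sd(r36),
               concealed_pct = concealed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("morphotype_summary", "data.frame")
  out
}

# exact minimum-cost one-to-one assignment by depth-first branch and bound;
# rows of `cost` are assigned to distinct columns (nrow <= ncol required)
assign_min_cost <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc)
  best <- list(cost = Inf, sel = integer(nr))
  lb_tail <- rev(cumsum(rev(c(apply(cost, 1, min), 0))))  # lower bound for rows i..nr
  sel <- integer(nr)
  used <- rep(FALSE, nc)
  recurse <- function(i, acc) {
    if (acc + lb_tail[i] >= best$cost) return()
    if (i > nr) { best <<- list(cost = acc, sel = sel); return() }
    for (j in order(cost[i, ])) {
      if (used[j]) next
      used[j] <<- TRUE; sel[i] <<- j
      recurse(i + 1L, acc + cost[i, j])
      used[j] <<- FALSE
    }
  }
  recurse(1L, 0)
  best
}

#' Match anonymous cluster groups to reference morphotypes
#'
#' The clustering labels groups by size, not by morphotype; this finds the
#' one-to-one assignment of groups to reference morphotypes that minimizes
#' the total Euclidean distance between group feature vectors
#' (L5 mean, L6 mean, L6/L5 mean) and the reference's. The total assignment
#' cost is reported so a poor match is visible. If the group and reference
#' counts differ, the smaller side is matched fully and the unmatched
#' remainder listed.
#'
#' @param summary a [summarize_groups()] result (or data.frame with columns
#'   `group`, `L5_mean`, `L6_mean`, `L6_over_L5_mean`).
#' @param reference reference parameter table; default [morphotype_reference()].
#' @return list: `mapping` (data.frame group, morphotype, area, cost),
#'   `total_cost`, `unmatched_groups`, `unmatched_morphotypes`.
#' @export
match_to_reference <- function(summary, reference = morphotype_reference()) {
  feats <- c("L5_mean", "L6_mean", "L6_over_L5_mean")
  G <- as.matrix(summary[feats])
  Rf <- as.matrix(reference[feats])
  cost <- outer(seq_len(nrow(G)), seq_len(nrow(Rf)),
                Vectorize(function(i, j) sqrt(sum((G[i, ] - Rf[j, ])^2))))
  swap <- nrow(G) > nrow(Rf)
  sol <- if (swap) assign_min_cost(t(cost)) else assign_min_cost(cost)
  if (swap) {
    mt_idx <- seq_len(nrow(Rf)); gr_idx <- sol$sel
  } else {
    gr_idx <- seq_len(nrow(G)); mt_idx <- sol$sel
  }
  mapping <- data.frame(
    group = summary$group[gr_idx],
    morphotype = reference$morphotype[mt_idx],
    area = reference$area[mt_idx],
    cost = cost[cbind(gr_idx, mt_idx)])
  mapping <- mapping[order(mapping$group), ]
  rownames(mapping) <- NULL
  list(mapping = mapping, total_cost = sol$cost,
       unmatched_groups = setdiff(summary$group, mapping$group),
       unmatched_morphotypes = setdiff(reference$morphotype,
                                       mapping$morphotype))
}

squamation_area_ids <- function() c(paste0("D", 1:3), paste0("M", 1:5),
                                    paste0("V", 1:6), "I", "II")

#' The 4-belt / 16-area squamation map
#'
#' Encodes the squamation model of the body: four belts (dorsal, middle,
#' ventral, unpaired) subdivided into 16 areas (D1-D3, M1-M5, V1-V6, I, II),
#' each tied to at most one scale morphotype, with free-text anatomical
#' bounds. Area M5 carries no morphotype: that body region is not preserved
#' on the fossil material. Auxiliary squamation elements that are not flank
#' morphotypes - basal fin scales, lepidotrichia, the lateral-line modifier
#' (carried by scales of morphotypes 1-4), and the median dorsal plates -
#' are attached alongside.
#'
#' @return object of class `squamation_map`: `areas` (data.frame area,
#'   belt, morphotype, bounds) and `auxiliary` (list).
#' @export
squamation_map <- function() {
  areas <- data.frame(
    area = squamation_area_ids(),
    belt = c(rep("dorsal", 3), rep("middle", 5), rep("ventral", 6),
             rep("unpaired", 2)),
    morphotype = c(5L, 6L, 7L,
                   1L, 2L, 3L, 4L, NA,
                   8L, 9L, 10L, 11L, 12L, 13L,
                   NA, NA),
    bounds = c(
      "around the three median dorsal plates",
      "post-temporal to the base of the second dorsal fin spine (~30 scale rows)",
      "behind D2, to the posterior edge of the caudal peduncle",
      "median extrascapular to the base of the first dorsal fin spine (~10 rows)",
      "behind M1, to the anterior edge of the pelvic girdle (~14 rows)",
      "behind M2, to the anterior edge of the pelvic girdle",
      "behind M3, to the posterior edge of the pelvic girdle",
      "behind M4; region not preserved on the fossil",
      "below M1-M3, to the posterior edge of the pelvic girdle",
      "behind V1, to the posterior edge of the caudal peduncle",
      "immediately behind the pectoral girdle",
      "below V1 and behind V3",
      "near the ventral midline, pectoral girdle to interpelvic plate",
      "near the ventral midline, interpelvic plate to anal fin",
      "dorsal midline between the first and second median dorsal fins",
      "dorsal midline between the second median dorsal fin and the tail fin"),
    stringsAsFactors = FALSE)
  areas$note <- ifelse(areas$area == "M5", "unpreserved", "")
  areas$note[areas$belt == "unpaired"] <- "dorsal median ridge scales"
  belt_sizes <- table(factor(areas$belt,
                             c("dorsal", "middle", "ventral", "unpaired")))
  stopifnot(nrow(areas) == 16L,
            all(belt_sizes == c(dorsal = 3L, middle = 5L,
                                ventral = 6L, unpaired = 2L)))
  structure(list(
    areas = areas,
    auxiliary = list(
      basal_fin_scales = "small rhombic scales at the pectoral and pelvic fin bases",
      lepidotrichia = "elongate rhomboid fin-ray scales, uniform in shape and size",
      lateral_line = list(applies_to_morphotypes = 1:4,
                          note = "canal pierces some scales of the middle flank row"),
      median_dorsal_plates = c("MD1", "MD2", "MD3"))),
    class = "squamation_map")
}

#' @export
print.squamation_map <- function(x, ...) {
  cat("<squamation_map> 4 belts, 16 areas (3 dorsal / 5 middle / 6 ventral / 2 unpaired)\n")
  print(x$areas[c("area", "belt", "morphotype")], row.names = FALSE)
  invisible(x)
}

#' Look up squamation areas and morphotypes
#'
#' Queries the built-in squamation map by area id (`"D2"`, `"M5"`, `"I"`, ...)
#' or morphotype id (`"Mt6"`, `"6"`, or the integer 6).
#'
#' @param query an area id or morphotype id.
#' @param map a [squamation_map()]; defaults to the built-in one.
#' @return data.frame of matching map rows (area, belt, morphotype, bounds,
#'   note).
#' @export
squamation_lookup <- function(query, map = squamation_map()) {
  areas <- map$areas
  q <- as.character(query)
  if (toupper(q) %in% toupper(areas$area))
    return(areas[toupper(areas$area) == toupper(q), , drop = FALSE])
  mt <- suppressWarnings(as.integer(sub("^[Mm][Tt]", "", q)))
  if (!is.na(mt) && mt %in% areas$morphotype)
    return(areas[!is.na(areas$morphotype) & areas$morphotype == mt, ,
                 drop = FALSE])
  stop_scalemorph("lookup",
                  "unknown id '%s'; valid areas: %s; valid morphotypes: Mt1-Mt13 (except the unmapped)",
                  q, paste(areas$area, collapse = ", "))
}
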