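test_that("single-member groups print population SD 0 and ratios follow per-scale convention", {
  tab <- measurement_table(data.frame(
    scale_id = c("a", "b", "c"),
    L1 = c(0.5, 0.6, 0.4), L3 = c(0.3, 0.2, 0.25),
    L5 = c(2, 1, 3.35), L6 = c(4, 4, 5.66)))
  s <- summarize_groups(tab, c(1, 1, 2))
  # singleton group: all SDs exactly 0
  expect_equal(unlist(s[2, grep("_sd$", names(s))]),
               stats::setNames(rep(0, 5), names(s)[grep("_sd$", names(s))]))
  # two scales with L6/L5 = 2 and 4: mean 3, population SD 1
  expect_equal(s$L6_over_L5_mean[1], 3.0)
  expect_equal(s$L6_over_L5_sd[1], 1.0)
  # mean of per-scale ratios, not ratio of means (which would be 8/3)
  expect_false(isTRUE(all.equal(s$L6_over_L5_mean[1],
                                s$L6_mean[1] / s$L5_mean[1])))
  expect_equal(s$n, c(2, 1))
  expect_equal(sum(s$n), n_scales(tab))
})

test_that("concealed-field percentages appear when L7 is measured", {
  tab <- measurement_table(data.frame(
    scale_id = c("a", "b"), L1 = c(1, 1), L3 = c(1, 1),
    L5 = c(2, 2), L6 = c(4, 4), L7 = c(0.76, 0.76)))
  s <- summarize_groups(tab, c(1, 1))
  expect_equal(s$concealed_pct, 38)
  tab2 <- measurement_table(data.frame(
    scale_id = c("a", "b"), L1 = c(1, 1), L3 = c(1, 1),
    L5 = c(0, 2), L6 = c(4, 4)))
  expect_error(summarize_groups(tab2, c(1, 1)), "scale\\(s\\) a",
               class = "scalemorph_ratio")
})

test_that("summaries are invariant to row order", {
  gen <- generate_measurements(default_reference_spec(), seed = 3)
  s1 <- summarize_groups(gen$table, gen$labels)
  set.seed(6)
  perm <- sample(n_scales(gen$table))
  tab2 <- measurement_table(gen$table$data[perm, ])
  s2 <- summarize_groups(tab2, gen$labels$labels[perm])
  expect_equal(as.data.frame(s2), as.data.frame(s1), tolerance = 1e-12)
})

test_that("matching maps the reference onto itself at zero cost, order-free", {
  ref <- morphotype_reference()
  fake_summary <- data.frame(group = seq_len(nrow(ref)),
                             L5_mean = ref$L5_mean, L6_mean = ref$L6_mean,
                             L6_over_L5_mean = ref$L6_over_L5_mean)
  m <- match_to_reference(fake_summary)
  expect_equal(m$mapping$morphotype, ref$morphotype)
  expect_equal(m$total_cost, 0)
  # shuffling reference row order changes nothing
  set.seed(10)
  m2 <- match_to_reference(fake_summary, ref[sample(nrow(ref)), ])
  expect_equal(m2$mapping$morphotype, m$mapping$morphotype)
})

test_that("matching equals the permutation-enumeration oracle on perturbed summaries", {
  ref <- morphotype_reference()
  set.seed(23)
  for (rep in 1:5) {
    fake <- data.frame(group = 1:8,
                       L5_mean = ref$L5_mean + rnorm(8, 0, 0.3),
                       L6_mean = ref$L6_mean + rnorm(8, 0, 0.5),
                       L6_over_L5_mean = ref$L6_over_L5_mean + rnorm(8, 0, 0.3))
    m <- match_to_reference(fake)
    cost <- as.matrix(stats::dist(rbind(
      as.matrix(fake[c("L5_mean", "L6_mean", "L6_over_L5_mean")]),
      as.matrix(ref[c("L5_mean", "L6_mean", "L6_over_L5_mean")]))))[1:8, 9:16]
    orc <- oracle_assignment(cost)
    expect_equal(m$total_cost, orc$cost, tolerance = 1e-10)
    expect_equal(m$mapping$morphotype, ref$morphotype[orc$sel])
  }
})

test_that("count mismatches match the smaller side and list the remainder", {
  ref <- morphotype_reference()
  fake <- data.frame(group = 1:6, L5_mean = ref$L5_mean[1:6],
                     L6_mean = ref$L6_mean[1:6],
                     L6_over_L5_mean = ref$L6_over_L5_mean[1:6])
  m <- match_to_reference(fake)
  expect_equal(nrow(m$mapping), 6)
  expect_setequal(m$unmatched_morphotypes, c(11, 12))
  expect_length(m$unmatched_groups, 0)
})

test_that("the squamation map has 4 belts, 16 areas, 3/5/6/2, with M5 unmapped", {
  map <- squamation_map()
  expect_equal(nrow(map$areas), 16)
  expect_equal(as.integer(table(map$areas$belt)[c("dorsal", "middle",
                                                  "ventral", "unpaired")]),
               c(3L, 5L, 6L, 2L))
  expect_true(is.na(map$areas$morphotype[map$areas$area == "M5"]))
  mapped <- map$areas$morphotype[!is.na(map$areas$morphotype)]
  expect_equal(sort(mapped), 1:13)            # each area <= 1 morphotype, none reused
  expect_equal(map$auxiliary$lateral_line$applies_to_morphotypes, 1:4)
})

test_that("lookups resolve areas, morphotypes and flag the unpreserved area", {
  d2 <- squamation_lookup("D2")
  expect_equal(d2$morphotype, 6L)
  expect_equal(d2$belt, "dorsal")
  m2 <- squamation_lookup("Mt2")
  expect_equal(m2$area, "M2")
  expect_equal(m2$belt, "middle")
  m5 <- squamation_lookup("M5")
  expect_true(is.na(m5$morphotype))
  expect_equal(m5$note, "unpreserved")
  expect_error(squamation_lookup("X9"), "valid areas",
               class = "scalemorph_lookup")
})
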