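test_that("CSV measurement tables parse with schema mapping and strict cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scale_id,L1,L3,L4,L5,L6",
               "a,0.5,0.3,1.7,1.8,8.1",
               "b,0.4,0.2,1.6,1.7,7.9",
               "c,0.6,0.4,1.8,1.9,8.3"), path)
  tab <- read_measurement_table(path)
  expect_equal(n_scales(tab), 3)
  expect_equal(tab$variables, c("L1", "L3", "L4", "L5", "L6"))
  expect_equal(tab$data$scale_id, c("a", "b", "c"))
  expect_equal(tab$data$L6, c(8.1, 7.9, 8.3))

  # schema absorbs arbitrary headers
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,peg,process,long,len,height",
               "a,0.5,0.3,1.7,1.8,8.1",
               "b,0.4,0.2,1.6,1.7,7.9",
               "c,0.6,0.4,1.8,1.9,8.3"), path2)
  tab2 <- read_measurement_table(path2, schema = c(
    scale_id = "id", L1 = "peg", L3 = "process", L4 = "long",
    L5 = "len", L6 = "height"))
  expect_equal(tab2$data[tab2$variables], tab$data[tab$variables])
})

test_that("malformed cells, missing columns and duplicate ids are rejected with names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scale_id,L1,L3,L4,L5,L6",
               "a,0.5,0.3,1.7,1.8,8.1",
               "b,0.4,0.2,1.6,abc,7.9"), path)
  expect_error(read_measurement_table(path), "column L5, row\\(s\\) 2",
               class = "scalemorph_parse")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scale_id,L1,L3,L4,L5", "a,1,1,1,1"), path2)
  expect_error(read_measurement_table(path2), "'L6'",
               class = "scalemorph_schema")

  expect_error(
    measurement_table(data.frame(scale_id = c("a", "a"), L5 = c(1, 2))),
    "duplicate scale_id: a", class = "scalemorph_integrity")
})

test_that("write -> read round-trips a 226-record synthetic table to 1e-12", {
  gen <- generate_measurements(default_reference_spec(), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurement_table(gen$table, path)
  back <- read_measurement_table(path)
  expect_equal(n_scales(back), 226)
  for (v in gen$table$variables)
    expect_equal(back$data[[v]], gen$table$data[[v]], tolerance = 1e-12)
})

test_that("TPS blocks parse with ID, SCALE, and non-conforming flags", {
  path <- withr::local_tempfile(fileext = ".tps")
  pts <- generate_landmarks(L5 = 2, L6 = 6, L1 = 0.8, L3 = 0.5)$points
  pts <- round(pts + 0.1 * sin(seq_len(22)), 4)   # wobble, fixed digits
  coords11 <- apply(pts, 1, function(r) paste(r, collapse = " "))
  writeLines(c("LM=11", coords11, "ID=sc1"), path)
  cfgs <- read_tps(path)
  expect_length(cfgs, 1)
  expect_equal(cfgs[[1]]$scale_id, "sc1")
  expect_equal(unname(cfgs[[1]]$points), unname(pts))

  # SCALE multiplies coordinates
  path2 <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=11", coords11, "ID=sc1", "SCALE=0.5"), path2)
  cfg2 <- read_tps(path2)[[1]]
  expect_equal(cfg2$points, cfgs[[1]]$points * 0.5)

  # 4 blocks, block 3 has LM=10: all parsed, block 3 flagged
  path3 <- withr::local_tempfile(fileext = ".tps")
  block <- function(n, id) c(sprintf("LM=%d", n),
                             apply(matrix(runif(2 * n), n, 2), 1,
                                   function(r) paste(r, collapse = " ")),
                             sprintf("ID=%s", id))
  writeLines(c(block(11, "b1"), block(11, "b2"), block(10, "b3"),
               block(11, "b4")), path3)
  expect_warning(cfgs3 <- read_tps(path3), "block 3.*LM=10")
  expect_length(cfgs3, 4)
  expect_false(attr(cfgs3[[3]], "conforming"))
  expect_true(all(vapply(cfgs3[c(1, 2, 4)], attr, logical(1), "conforming")))

  # structural failures
  path4 <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=11", coords11[1:9], "ID=x"), path4)
  expect_error(read_tps(path4), "block 1", class = "scalemorph_format")
  path5 <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("0.1 0.2", "0.3 0.4"), path5)
  expect_error(read_tps(path5), class = "scalemorph_format")
})

test_that("JSON reports are stable: write -> load -> write is byte-identical", {
  res <- default_pipeline_result()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(res, p1)
  loaded <- read_report(p1)
  write_report(loaded, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(nrow(loaded$summary), 8)
  expect_equal(loaded$refinement$accuracy, res$refinement$accuracy)
})

test_that("a minimal self-consistent result reports accuracy 1", {
  X <- rbind(c(1, 8), c(1.1, 8.2), c(5, 2), c(5.2, 2.1))
  colnames(X) <- c("L5", "L6")
  tab <- table_from_matrix(X)
  lab <- partition(stats::setNames(c(1, 1, 2, 2), tab$data$scale_id))
  res <- classify(fit_cva(tab, lab), tab, labels = lab)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(list(accuracy = res$accuracy), path)
  expect_equal(read_report(path)$accuracy, 1.0)
})
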