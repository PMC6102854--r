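test_that("arrayed table reading round-trips and validates structure", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    feature_id = c("g1", "g2", "n1", "n2", "p1", "p2"),
    well_type = c("lib", "lib", "neg", "neg", "pos", "pos"),
    cell_line = "A", replicate = "A_1",
    readout = c(1.5, 0.8, 1.0, 1.1, 0.2, 0.15))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

  st <- read_arrayed_table(path)
  expect_s3_class(st, "screen_study")
  expect_equal(nrow(st), 6)
  expect_equal(length(unique(st$replicate)), 1)
  expect_equal(st$readout, df$readout)  # row order preserved
  expect_setequal(unique(st$well_type),
                  c("library", "neg_control", "pos_control"))

  # write -> read round-trips readouts bit-identically
  out <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(st), out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  again <- read_arrayed_table(out, well_type_map = NULL)
  expect_identical(again$readout, st$readout)
})

test_that("structural invariant violations are rejected with the culprit named", {
  base <- data.frame(
    feature_id = c("g1", "n1", "p1"),
    well_type = c("library", "neg_control", "pos_control"),
    cell_line = "A", replicate = "A_1", readout = c(1, 1, 0.2))

  no_pos <- base[base$well_type != "pos_control", ]
  expect_error(screen_study(no_pos), "A_1")

  part_plate <- base
  part_plate$plate <- c("plate1", NA, "plate1")
  expect_error(screen_study(part_plate), "plate")

  two_lines <- rbind(base, transform(base, cell_line = "B"))
  expect_error(screen_study(two_lines), "more than one cell line")

  inf_read <- base
  inf_read$readout[1] <- Inf
  expect_error(screen_study(inf_read), "non-finite")
})

test_that("non-numeric readouts in a file are reported by row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\twell_type\tcell_line\treplicate\treadout",
               "g1\tlib\tA\tA_1\t1.0",
               "n1\tneg\tA\tA_1\toops",
               "p1\tpos\tA\tA_1\t0.2"), path)
  expect_error(read_arrayed_table(path), "row")
})

test_that("count matrix reading labels controls and splits samples", {
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(101)
  counts <- data.frame(sgRNA = sprintf("sg%02d", 1:10),
                       gene = sprintf("G%02d", 1:10),
                       lineA_r1 = rpois(10, 100), lineB_r1 = rpois(10, 120))
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ctrl <- c(sg01 = "neg", sg02 = "neg", sg03 = "pos", sg04 = "pos")

  st <- read_count_matrix(path, controls = ctrl)
  expect_equal(nrow(st), 20)
  expect_equal(length(unique(st$replicate)), 2)
  expect_equal(sort(unique(st$cell_line)), c("lineA", "lineB"))
  expect_equal(sum(st$well_type == "neg_control"), 4)
  expect_equal(sum(st$well_type == "pos_control"), 4)

  expect_error(read_count_matrix(path, controls = NULL), "control")

  neg <- counts; neg$lineA_r1[5] <- -5
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(neg, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_matrix(path2, controls = ctrl), "sg05")

  dup <- counts; dup$sgRNA[2] <- "sg01"
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(dup, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_matrix(path3, controls = ctrl), "duplicate")
})

test_that("readout transforms are elementwise and idempotent for identity", {
  st <- tiny_study(lib = c(7, 3))
  expect_identical(transform_readout(st, "identity"), st)
  expect_identical(transform_readout(transform_readout(st, "identity"),
                                     "identity"), st)
  expect_equal(transform_readout(st, "asinh")$readout[1], asinh(7))
  expect_equal(asinh(0), 0)
  expect_equal(transform_readout(st, "log2", pseudocount = 1)$readout[1], 3)
  expect_equal(transform_readout(st, "negate")$readout, -st$readout)

  zero <- tiny_study(lib = c(0, 3))
  expect_error(transform_readout(zero, "log2"), "pseudocount")
})

test_that("control adequacy report follows the per-plate minima and is pure", {
  ok <- screen_study(data.frame(
    feature_id = c(paste0("g", 1:4), paste0("n", 1:4), paste0("p", 1:4)),
    well_type = c(rep("library", 4), rep("neg_control", 4),
                  rep("pos_control", 4)),
    cell_line = "A", replicate = "A_1", plate = "plate1",
    readout = c(runif(4), rnorm(4, 1, 0.1), rnorm(4, 0.2, 0.1))))
  before <- ok
  rep_ok <- validate_controls(ok, "arrayed")
  expect_true(all(rep_ok$level == "ok"))
  expect_identical(ok, before)  # report-only

  one_pos <- screen_study(data.frame(
    feature_id = c("g1", "n1", "n2", "p1"),
    well_type = c("library", "neg_control", "neg_control", "pos_control"),
    cell_line = "A", replicate = "A_1", plate = "plate1",
    readout = c(0.5, 1, 1.1, 0.2)))
  rep_bad <- validate_controls(one_pos, "arrayed")
  expect_true(any(rep_bad$level == "error" &
                  rep_bad$well_type == "pos_control"))

  pooled0 <- screen_study(data.frame(
    feature_id = c(paste0("g", 1:3), paste0("n", 1:25), paste0("p", 1:25)),
    well_type = c(rep("library", 3), rep("neg_control", 25),
                  rep("pos_control", 25)),
    cell_line = "A", replicate = "A_1",
    readout = c(runif(3), rnorm(25, 1, 0.1), rep(0, 25))))
  rep0 <- validate_controls(pooled0, "pooled")
  expect_true(any(rep0$zero_variability & rep0$well_type == "pos_control"))
})

test_that("unreliable positive controls are demoted by the lethal-phenotype rule", {
  set.seed(57)
  n_reps <- 57
  blocks <- lapply(seq_len(n_reps), function(k) {
    data.frame(
      feature_id = c(sprintf("g%03d", 1:100), "always", "boundary", "never",
                     "n1", "n2"),
      well_type = c(rep("library", 100), rep("pos_control", 3),
                    rep("neg_control", 2)),
      cell_line = "A", replicate = paste0("A_", k),
      readout = c(runif(100, 0.5, 1.5),
                  0.01,                                  # always lethal
                  if (k <= 49) 0.01 else 2,              # lethal in 49 reps
                  2,                                     # never lethal
                  1, 1.05),
      stringsAsFactors = FALSE)
  })
  st <- screen_study(do.call(rbind, blocks))
  out <- filter_reference_controls(st, min_lethal_replicates = 50,
                                   lethal_rule = 0.10)
  demoted <- attr(out, "demoted")
  expect_true("never" %in% demoted)
  expect_true("boundary" %in% demoted)  # 49 < 50: just misses the cut
  expect_false("always" %in% demoted)
  expect_true(all(out$well_type[out$feature_id == "always"] == "pos_control"))
  expect_true(all(out$well_type[out$feature_id == "never"] == "library"))

  # demoting every candidate is an error, not a silent empty set
  st_all_bad <- st
  st_all_bad$readout[st_all_bad$well_type == "pos_control"] <- 2
  st_all_bad <- screen_study(as.data.frame(st_all_bad))
  expect_error(filter_reference_controls(st_all_bad, 50), "all candidate")
})

test_that("the shipped example files load through both readers", {
  arr <- read_arrayed_table(system.file("extdata", "example_arrayed.tsv",
                                        package = "screenorm"))
  expect_s3_class(arr, "screen_study")
  expect_equal(length(unique(arr$replicate)), 2)
  expect_equal(length(unique(arr$plate)), 2)
  expect_true(all(table(arr$plate, arr$well_type) > 0))

  st <- read_count_matrix(
    system.file("extdata", "example_counts.tsv", package = "screenorm"),
    controls = system.file("extdata", "example_controls.tsv",
                           package = "screenorm"))
  expect_equal(length(unique(st$replicate)), 4)
  expect_equal(sum(st$well_type == "pos_control"), 16)
})
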