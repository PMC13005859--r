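test_that("cohorts survive a write/read round trip", {
  coh <- tiny_cohort(n_subjects = 2, n_regions = 7,
                     trials_per_condition = 1, seed = 31)
  dir <- file.path(tempdir(), "rt")
  mp <- write_cohort(coh, dir)
  back <- read_cohort(mp)
  expect_equal(length(back$trials), length(coh$trials))
  for (i in seq_along(coh$trials)) {
    expect_equal(back$trials[[i]]$X, coh$trials[[i]]$X, tolerance = 1e-12)
    expect_identical(back$trials[[i]]$subject, coh$trials[[i]]$subject)
    expect_equal(back$trials[[i]]$duration_s, coh$trials[[i]]$duration_s)
  }
  expect_equal(back$behavior$report_s, coh$behavior$report_s,
               tolerance = 1e-12)
  expect_identical(back$config$network_labels, coh$config$network_labels)
  unlink(dir, recursive = TRUE)
})

test_that("a manifest referencing a missing file names it", {
  coh <- tiny_cohort(n_subjects = 1, n_regions = 7,
                     trials_per_condition = 1, seed = 32)
  dir <- file.path(tempdir(), "miss")
  mp <- write_cohort(coh, dir)
  victim <- list.files(dir, pattern = "tsv$", full.names = TRUE)[1]
  file.remove(victim)
  expect_error(read_cohort(mp), basename(victim))
  unlink(dir, recursive = TRUE)
})

test_that("a shape mismatch against the manifest is a validation error", {
  coh <- tiny_cohort(n_subjects = 1, n_regions = 7,
                     trials_per_condition = 1, seed = 33)
  dir <- file.path(tempdir(), "shape")
  mp <- write_cohort(coh, dir)
  m <- jsonlite::read_json(mp, simplifyVector = TRUE)
  m$trials$n_timepoints[1] <- m$trials$n_timepoints[1] + 3
  jsonlite::write_json(m, mp, auto_unbox = TRUE, digits = NA)
  expect_error(read_cohort(mp), "shape mismatch")
  unlink(dir, recursive = TRUE)
})

test_that("ROI extraction reproduces a constructed volume exactly", {
  dim3 <- c(5, 4, 3)
  n_tp <- 6
  lab <- array(0L, dim3)
  lab[1:2, 1, 1] <- 1L
  lab[4:5, 3:4, 2] <- 2L
  ser <- array(0, c(dim3, n_tp))
  for (t in seq_len(n_tp)) {
    s <- array(0, dim3)
    s[lab == 1L] <- 2 * t       # known ramp per region
    s[lab == 2L] <- -3 * t
    ser[, , , t] <- s
  }
  sp <- file.path(tempdir(), "series.nii")
  ap <- file.path(tempdir(), "atlas.nii")
  RNifti::writeNifti(RNifti::asNifti(ser), sp)
  RNifti::writeNifti(RNifti::asNifti(lab), ap)
  nt <- data.frame(label = c(1L, 2L), region = c("ra", "rb"),
                   network = c("vis", "aud"))
  res <- extract_roi_series(sp, ap, nt)
  expect_equal(unname(res$voxel_counts), c(2L, 4L))
  expect_equal(unname(res$sum["ra", ]), 2 * 2 * seq_len(n_tp))
  expect_equal(unname(res$sum["rb", ]), 4 * -3 * seq_len(n_tp))
  expect_equal(unname(res$mean["ra", ]), 2 * seq_len(n_tp))
  # identical grids: resampling must be the identity
  expect_equal(unname(res$mean["rb", ]), -3 * seq_len(n_tp))
  # a label missing from the table is an error naming it
  expect_error(extract_roi_series(sp, ap, nt[1, ]), "2")
  file.remove(sp, ap)
})

test_that("nearest-neighbor resampling maps a coarser atlas onto the series grid", {
  # atlas at 2 mm, series at 1 mm: each atlas voxel covers 2 series voxels
  # along each axis
  alab <- array(1L, c(2, 2, 2))
  alab[2, , ] <- 3L
  atl <- RNifti::asNifti(alab)
  RNifti::pixdim(atl) <- c(2, 2, 2)
  ser <- array(rep(seq_len(4), each = 4 * 4 * 4), c(4, 4, 4, 4))
  srn <- RNifti::asNifti(ser)
  RNifti::pixdim(srn) <- c(1, 1, 1)
  sp <- file.path(tempdir(), "s2.nii")
  ap <- file.path(tempdir(), "a2.nii")
  RNifti::writeNifti(srn, sp)
  RNifti::writeNifti(atl, ap)
  nt <- data.frame(label = c(1L, 3L), region = c("left", "right"))
  res <- extract_roi_series(sp, ap, nt)
  # series voxels at the far world edge fall outside the atlas extent and
  # stay unlabelled (27 of 64 voxel centers map inside); the series is
  # spatially constant, so region means equal the global ramp
  expect_equal(sum(res$voxel_counts), 27)
  expect_equal(unname(res$voxel_counts), c(18L, 9L))
  expect_equal(unname(res$mean["left", ]), 1:4)
  expect_equal(unname(res$mean["right", ]), 1:4)
  file.remove(sp, ap)
})

test_that("event, grid and FC writers produce parseable tables", {
  coh <- tiny_cohort(n_subjects = 2, trials_per_condition = 1, seed = 41)
  ef <- accumulate_events(coh$trials, coh$config$network_labels,
                          criterion_params(seed = 3))
  f <- file.path(tempdir(), "events.tsv")
  write_event_features(ef, f)
  tab <- read.table(f, sep = "\t", header = TRUE)
  expect_equal(nrow(tab), length(coh$trials) * 7)
  expect_equal(sum(tab$count), sum(ef$counts))
  file.remove(f)

  g <- criterion_grid(n_min = 2, n_max = 2)
  rg <- robustness_grid(coh$trials, coh$config$network_labels,
                        human_bias(coh), grid = g, networks = "vis",
                        k = 5, seed = 2)
  d <- file.path(tempdir(), "grid")
  write_robustness_grid(rg, d)
  gt <- read.table(file.path(d, "grid_vis.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(gt), 4)
  js <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(js$significant_fraction$vis,
               unname(rg$significant_fraction["vis"]))
  unlink(d, recursive = TRUE)

  feats <- cohort_fc(coh)
  d2 <- file.path(tempdir(), "fc")
  write_fc_features(feats, d2)
  fc <- read.table(file.path(d2, "fc.tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE)
  expect_equal(dim(fc), dim(feats$fc) + c(0, 1))
  ei <- read.csv(file.path(d2, "edge_index.csv"))
  expect_equal(nrow(ei), ncol(feats$fc))
  unlink(d2, recursive = TRUE)
})
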