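test_that("roi_means: constant map, label-valued map, hand mean, NaN handling", {
  lab <- array(0L, dim = c(4, 4, 4))
  lab[1:2, 1, 1] <- 1L; lab[3:4, 1, 1] <- 2L
  lv <- label_volume(lab, label_names = c(`1` = "a", `2` = "b"))

  cm <- roi_means(const_volume(0.7, c(4, 4, 4)), lv)
  expect_equal(cm$mean, c(0.7, 0.7))

  idm <- volume3d(array(as.numeric(lab), dim = dim(lab)))
  expect_equal(roi_means(idm, lv)$mean, c(1, 2))

  two <- array(NaN, dim = c(4, 4, 4))
  two[1, 1, 1] <- 0.10; two[2, 1, 1] <- 0.14
  rm2 <- roi_means(volume3d(two), lv)
  expect_equal(rm2$mean[rm2$roi == "a"], 0.12)
  expect_true(is.na(rm2$mean[rm2$roi == "b"]))  # all-NaN ROI reported missing
  expect_equal(rm2$n_voxels, c(2L, 0L))

  expect_error(roi_means(const_volume(1, c(5, 4, 4)), lv), "grid mismatch")
  empty <- label_volume(array(0L, dim = c(4, 4, 4)))
  expect_error(roi_means(const_volume(1, c(4, 4, 4)), empty), "empty label set")
})

test_that("cov_between: hand arithmetic, zero for constants, scale invariance", {
  expect_equal(cov_between(c(5, 5, 5)), 0)
  expect_equal(cov_between(c(8, 10, 12, 10)), sd(c(8, 10, 12, 10)) / 10)
  expect_equal(round(cov_between(c(8, 10, 12, 10)), 5), 0.16330)
  expect_equal(cov_between(3 * c(8, 10, 12, 10)), cov_between(c(8, 10, 12, 10)))
  expect_true(is.na(cov_between(c(-1, 1))))
  expect_error(cov_between(5), ">= 2 values")
})

test_that("cov_within averages per-subject CoVs and excludes single-scan subjects", {
  tab <- roi_table(data.frame(
    subject = rep(1:2, each = 4), session = rep(rep(1:2, each = 2), 2),
    rep = rep(1:2, 4), roi = "r1", metric = "m",
    value = c(10, 10, 10, 10, 4, 5, 5, 6)))
  # subject 1 CoV 0; subject 2 CoV sd(4,5,5,6)/5
  expect_equal(cov_within(tab, metric = "m", roi = "r1"),
               mean(c(0, sd(c(4, 5, 5, 6)) / 5)))
  expect_equal(cov_within(c(0.10, 0.20)), 0.15)

  one_scan <- roi_table(data.frame(subject = c(1, 1, 2),
                                   session = c(1, 1, 1), rep = c(1, 2, 1),
                                   roi = "r1", metric = "m", value = c(1, 2, 3)))
  expect_warning(v <- cov_within(one_scan, metric = "m", roi = "r1"), "excluded")
  expect_equal(v, sd(c(1, 2)) / 1.5)
})

test_that("cov_map reproduces the scalar definitions voxelwise", {
  dims <- c(3, 3, 3)
  stack <- lapply(c(8, 10, 12, 10), const_volume, dims = dims)
  cm <- cov_map(stack, "between")
  expect_equal(unique(as.vector(cm$data)), cov_between(c(8, 10, 12, 10)))

  ident <- lapply(rep(5, 4), const_volume, dims = dims)
  expect_true(all(cov_map(ident, "between")$data == 0))

  # a NaN voxel in one scan propagates
  v2 <- const_volume(10, dims); v2$data[1, 1, 1] <- NaN
  cm2 <- cov_map(list(stack[[1]], v2, stack[[3]], stack[[4]]), "between")
  expect_true(is.nan(cm2$data[1, 1, 1]))
  expect_false(is.nan(cm2$data[2, 2, 2]))

  # within grouping: per-subject CoV then average across subjects
  win <- cov_map(stack, "within", subjects = c(1, 1, 2, 2))
  expect_equal(unique(as.vector(win$data)),
               mean(c(sd(c(8, 10)) / 9, sd(c(12, 10)) / 11)))
  expect_error(cov_map(stack[1], "between"), ">= 2 volumes")
})

test_that("within-subject CoV falls below between-subject CoV when subjects vary", {
  diffs <- vapply(1:50, function(i) {
    sp <- phantom_spec(angle_slope = 0, sd_subject = 0.008, sd_scan = 0.002,
                       seed = 61000 + i)
    tab <- simulate_roi_study(sp)$table
    g <- tab[tab$metric == "ihmtr" & tab$roi == "roi03", ]
    cov_between(g$value) - suppressWarnings(cov_within(g))
  }, 0)
  expect_gt(mean(diffs), 0)
  # and with scan variance dominating, the two coincide closely
  close <- vapply(1:20, function(i) {
    sp <- phantom_spec(angle_slope = 0, sd_subject = 0, sd_scan = 0.01,
                       seed = 62000 + i)
    tab <- simulate_roi_study(sp)$table
    g <- tab[tab$metric == "ihmtr" & tab$roi == "roi03", ]
    cov_between(g$value) / suppressWarnings(cov_within(g))
  }, 0)
  expect_equal(mean(close), 1, tolerance = 0.15)
})

test_that("roi_table validation catches structural errors", {
  good <- data.frame(subject = 1, session = 1, rep = 1, roi = "a",
                     metric = "m", value = 0.1)
  expect_s3_class(roi_table(good), "roi_table")
  expect_error(roi_table(good[, -6]), "missing columns")
  expect_error(roi_table(rbind(good, good)), "duplicate")
  bad <- good; bad$value <- Inf
  expect_error(roi_table(bad), "finite")
})

test_that("roi_summary_table reports subject-level mean and SD in percent", {
  tab <- roi_table(data.frame(
    subject = rep(1:3, each = 4), session = rep(rep(1:2, each = 2), 3),
    rep = rep(1:2, 6), roi = "genu", metric = "ihmtr",
    value = c(0.10, 0.11, 0.12, 0.11, 0.12, 0.13, 0.12, 0.11, 0.13, 0.12, 0.14, 0.13)))
  out <- roi_summary_table(tab, metrics = "ihmtr")
  subj_means <- c(mean(c(0.10, 0.11, 0.12, 0.11)), mean(c(0.12, 0.13, 0.12, 0.11)),
                  mean(c(0.13, 0.12, 0.14, 0.13)))
  expect_equal(out$ihmtr_mean_pct, 100 * mean(subj_means))
  expect_equal(out$ihmtr_sd_pct, 100 * sd(subj_means))
})

test_that("read_roi_csv round-trips a long table with alias columns", {
  dir <- withr::local_tempdir()
  tab <- simulate_roi_study(tiny_spec())$table
  df <- as.data.frame(tab)
  names(df)[names(df) == "rep"] <- "repeat"
  p <- file.path(dir, "roi.csv")
  write.csv(df, p, row.names = FALSE)
  back <- read_roi_csv(p)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(sort(unique(back$metric)), sort(unique(tab$metric)))
})
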