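test_that("phantom construction: label set, ROI voxel counts, WM containment", {
  lv <- make_phantom(phantom_spec())
  expect_setequal(unique(as.vector(lv$labels)), c(0:3, 11:20))
  boxes <- attr(lv, "roi_boxes")
  expect_length(boxes, 10)
  for (k in 1:10) {
    b <- boxes[[k]]
    expect_equal(sum(lv$labels == 10L + k),
                 length(b$x) * length(b$y) * length(b$z))
  }
  # ROI voxels sit inside the WM core: a one-voxel dilation of each box may
  # meet WM, other ROI labels or the interior ventricles, but never the GM
  # shell or background
  for (k in 1:10) {
    b <- boxes[[k]]
    hull <- lv$labels[(min(b$x):(max(b$x) + 2)), (min(b$y):(max(b$y) + 2)),
                      (min(b$z):(max(b$z) + 2))]
    expect_true(all(hull %in% c(1L, 3L, 11:20)))
  }
})

test_that("signal synthesis inverts the ratio definitions exactly", {
  s <- signals_from_truth(100, 0.20, 0.26, 0, 0.9)
  expect_equal(unlist(s), c(S0 = 100, Splus = 80, Sminus = 80,
                            Spm = 74, Smp = 74, ST1 = 90))
  ws <- const_ws(s$S0, s$Splus, s$Sminus, s$Spm, s$Smp, s$ST1)
  maps <- compute_ratio_maps(ws)
  expect_equal(unique(as.vector(maps$mtr$data)), 0.20)
  expect_equal(unique(as.vector(maps$emtr$data)), 0.26)
  expect_equal(unique(as.vector(maps$mtasym$data)), 0)
  expect_equal(unique(as.vector(maps$ihmtr$data)), 0.12)
  expect_equal(unique(as.vector(maps$ihmtr_inv$data)), 0.364865, tolerance = 1e-6)

  z <- signals_from_truth(100, 0, 0, 0, 1)
  expect_equal(unlist(z[c("Splus", "Sminus", "Spm", "Smp")]),
               c(Splus = 100, Sminus = 100, Spm = 100, Smp = 100))

  a <- signals_from_truth(100, 0.2, 0.26, 0.04, 0.9)
  expect_equal(a$Splus - a$Sminus, 4)

  expect_error(signals_from_truth(100, 1.2, 0.3), "non-physical")
})

test_that("truth_metrics matches the computed maps on synthesized signals", {
  tm <- truth_metrics(0.20, 0.26, 0.01, 0.37)
  s <- signals_from_truth(100, 0.20, 0.26, 0.01, 0.37)
  ws <- const_ws(s$S0, s$Splus, s$Sminus, s$Spm, s$Smp, s$ST1)
  expect_equal(unique(as.vector(compute_ihmtr(ws)$data)), tm$ihmtr, tolerance = 1e-12)
  expect_equal(unique(as.vector(compute_ihmtr_inv(ws)$data)), tm$ihmtr_inv,
               tolerance = 1e-12)
})

test_that("Rician noise: zero-sigma identity, Rayleigh mean, determinism", {
  v <- const_volume(50, c(8, 8, 8))
  expect_identical(add_rician(v, 0)$data, v$data)

  z <- const_volume(0, c(25, 25, 25))  # >= 10^4 draws
  noisy <- add_rician(z, 2, seed = 99)
  expect_equal(mean(noisy$data), 2 * sqrt(pi / 2), tolerance = 0.02)

  a <- add_rician(v, 1.5, seed = 42)
  b <- add_rician(v, 1.5, seed = 42)
  expect_identical(a$data, b$data)
})

test_that("noise-free, effect-free study round-trips ROI means to the truth", {
  st <- simulate_study(tiny_spec())
  tab <- study_roi_table(st)
  merged <- merge(as.data.frame(tab[tab$metric == "ihmtr", ]), st$truth,
                  by = c("subject", "session", "rep", "roi"))
  expect_equal(nrow(merged), 2 * 2 * 2 * 10)
  expect_lt(max(abs(merged$value - merged$ihmtr)), 1e-10)
  merged_inv <- merge(as.data.frame(tab[tab$metric == "ihmtr_inv", ]), st$truth,
                      by = c("subject", "session", "rep", "roi"))
  expect_lt(max(abs(merged_inv$value - merged_inv$ihmtr_inv)), 1e-10)
})

test_that("emitted transforms encode the per-session head angle", {
  sp <- tiny_spec(angle_mean = 8, angle_sd = 4)
  st <- simulate_study(sp)
  for (sc in st$scans) {
    expect_equal(head_angle(sc$transform), sc$angle, tolerance = 1e-9)
  }
  # repeats within a session share the angle
  ang <- st$angles
  expect_equal(nrow(ang), sp$n_subjects * sp$n_sessions)
})

test_that("simulation is deterministic and extending subjects preserves scans", {
  sp <- tiny_spec(noise_sigma = 0.5, sd_subject = 0.004, sd_scan = 0.003)
  s1 <- simulate_study(sp)
  s2 <- simulate_study(sp)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$scans[[1]]$volumes$S0$data, s2$scans[[1]]$volumes$S0$data)

  sp3 <- tiny_spec(noise_sigma = 0.5, sd_subject = 0.004, sd_scan = 0.003,
                   n_subjects = 3L)
  s3 <- simulate_study(sp3)
  t1 <- s1$truth[s1$truth$subject <= 2, ]
  t3 <- s3$truth[s3$truth$subject <= 2, ]
  rownames(t1) <- rownames(t3) <- NULL
  expect_identical(t1, t3)
})

test_that("study writes a BIDS-flavoured layout with volumes, transforms and truth", {
  dir <- withr::local_tempdir()
  sp <- tiny_spec(n_subjects = 1L, n_sessions = 1L, n_repeats = 1L)
  st <- simulate_study(sp, out_dir = dir)
  run <- file.path(dir, "sub-01", "ses-1", "run-1")
  expect_setequal(list.files(run),
                  c("s0.nii.gz", "splus.nii.gz", "sminus.nii.gz", "spm.nii.gz",
                    "smp.nii.gz", "st1.nii.gz", "native_to_atlas.txt"))
  expect_true(file.exists(file.path(dir, "labels.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  tr <- read_affine(st$scans[[1]]$transform_path)
  expect_equal(head_angle(tr), st$scans[[1]]$angle, tolerance = 1e-6)
})

test_that("table-level generator matches the volume pipeline statistically", {
  # same spec, no noise anywhere: table generator equals volume-derived table
  sp <- tiny_spec()
  tab_v <- study_roi_table(simulate_study(sp))
  tab_t <- simulate_roi_study(sp)$table
  m <- merge(as.data.frame(tab_v[tab_v$metric == "ihmtr", ]),
             as.data.frame(tab_t[tab_t$metric == "ihmtr", ]),
             by = c("subject", "session", "rep", "roi"))
  expect_lt(max(abs(m$value.x - m$value.y)), 1e-10)
})

test_that("empirical ICC of simulated ROI means converges to the design value", {
  # var components on the ihMTR scale are (2*sd)^2 of the eMTR-scale effects
  sd_s <- 0.005; sd_r <- 0.004; sd_e <- 0.002
  true_icc <- sd_s^2 / (sd_s^2 + sd_r^2 + sd_e^2)
  iccs <- vapply(1:50, function(i) {
    sp <- phantom_spec(angle_slope = 0, sd_subject = sd_s, sd_scan = sd_r,
                       sigma_resid = sd_e, seed = 52000 + i)
    tab <- simulate_roi_study(sp)$table
    g <- tab[tab$metric == "ihmtr" & tab$roi == "roi05", ]
    icc21(fit_two_way_random(g, prior = NULL))
  }, 0)
  expect_lt(abs(mean(iccs) - true_icc), 0.05)
})
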