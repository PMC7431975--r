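#' Define a synthetic ihMT study
#'
#' The phantom specification fixes everything a synthetic study needs: the
#' grid, the tissue-wise ground-truth ratios that the weighted signals are
#' synthesized from, the repeatability design (subjects x sessions x repeats
#' with subject and scan variance components on eMTR), the head-orientation
#' effect (per-session rotation angle with a linear decrement of WM eMTR),
#' and the Rician noise level.
#'
#' Default truths echo healthy white matter at 3T: WM ihMTR 0.12 and inverse
#' ihMTR about 0.15, lower values in GM, and a CSF compartment whose
#' dual-sided saturation is slightly weaker than single-sided so ihMTR is
#' slightly negative there. Ten ROI boxes are carved into WM with small
#' deterministic eMTR offsets so ROI is a genuine factor.
#'
#' @param grid_shape voxel dimensions (length-3 integer).
#' @param voxel_size isotropic voxel size, mm.
#' @param tissue_truths named list (wm, gm, csf) of lists with elements
#'   \code{S0} (a.u.), \code{mtr}, \code{emtr}, \code{mtasym} (fractions) and
#'   \code{t1_factor} (ST1 as a fraction of S0).
#' @param roi_emtr_offsets length-10 numeric: per-ROI additive offsets on WM
#'   eMTR (fractions).
#' @param n_subjects,n_sessions,n_repeats design size (default 12 x 2 x 2).
#' @param sd_subject,sd_scan SDs of the additive subject and scan random
#'   effects on eMTR (fractions).
#' @param sigma_resid residual SD on ROI-mean eMTR used by the table-level
#'   generator (fraction); emulates what voxel noise averages down to over an
#'   ROI.
#' @param noise_sigma Rician noise SD for the volume-level generator (a.u.,
#'   same units as S0).
#' @param angle_mean,angle_sd mean and SD (degrees) of the per-session head
#'   rotation angle, drawn from a normal truncated at 0.
#' @param angle_slope linear decrement of WM eMTR per degree of head rotation
#'   (fraction per degree).
#' @param seed master seed; per-scan streams are derived at fixed offsets so
#'   adding subjects never reshuffles existing scans.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size = 3,
                         tissue_truths = list(
                           wm  = list(S0 = 100, mtr = 0.20, emtr = 0.26, mtasym = 0.010, t1_factor = 0.37),
                           gm  = list(S0 = 110, mtr = 0.18, emtr = 0.21, mtasym = 0.005, t1_factor = 0.50),
                           csf = list(S0 = 120, mtr = 0.05, emtr = 0.04, mtasym = -0.010, t1_factor = 0.90)),
                         roi_emtr_offsets = seq(-0.009, 0.009, length.out = 10),
                         n_subjects = 12L, n_sessions = 2L, n_repeats = 2L,
                         sd_subject = 0.005, sd_scan = 0.004,
                         sigma_resid = 0.002, noise_sigma = 1,
                         angle_mean = 7, angle_sd = 5, angle_slope = 0.001,
                         seed = 20260922L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 32L),
            voxel_size > 0, n_subjects >= 1, n_sessions >= 1, n_repeats >= 1,
            sd_subject >= 0, sd_scan >= 0, sigma_resid >= 0, noise_sigma >= 0,
            angle_sd >= 0, length(roi_emtr_offsets) == 10L)
  for (tn in c("wm", "gm", "csf")) {
    tt <- tissue_truths[[tn]]
    if (is.null(tt)) stop("tissue_truths must contain '", tn, "'")
    if (any(abs(c(tt$mtr, tt$emtr, tt$mtasym)) >= 1))
      stop("tissue fractions must lie in (-1, 1)")
    if (tn != "csf" && tt$emtr < tt$mtr)
      stop("emtr must be >= mtr for ", tn, " (only the CSF compartment may invert)")
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 tissue_truths = tissue_truths,
                 roi_emtr_offsets = roi_emtr_offsets,
                 n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_repeats = as.integer(n_repeats),
                 sd_subject = sd_subject, sd_scan = sd_scan,
                 sigma_resid = sigma_resid, noise_sigma = noise_sigma,
                 angle_mean = angle_mean, angle_sd = angle_sd,
                 angle_slope = angle_slope, seed = as.integer(seed)),
            class = "phantom_spec")
}

# tissue codes: 1 WM, 2 GM, 3 CSF; ROI labels 11..20 are WM tissue
phantom_roi_labels <- 11:20
phantom_roi_names <- sprintf("roi%02d", 1:10)

tissue_of_label <- function(label) {
  out <- rep(NA_character_, length(label))
  out[label == 1L | label %in% phantom_roi_labels] <- "wm"
  out[label == 2L] <- "gm"
  out[label == 3L] <- "csf"
  out
}

#' Build the digital head phantom
#'
#' An ellipsoidal head: grey-matter shell (label 2), white-matter core
#' (label 1), two CSF ventricles (label 3) and background 0. Ten ROI boxes
#' (labels 11-20, named roi01..roi10) are carved into the WM core on two
#' rings, standing in for bilateral white-matter tract ROIs. Construction is
#' validated: ROI boxes must lie inside WM and must not overlap each other
#' or the ventricles.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A \code{\link{label_volume}} with 13 distinct labels, and
#'   attribute \code{roi_boxes} (list of voxel extents per ROI).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ctr <- (d - 1) / 2
  aff <- diag(c(rep(spec$voxel_size, 3), 1))
  ax <- function(i) (seq_len(d[i]) - 1 - ctr[i])
  gx <- ax(1); gy <- ax(2); gz <- ax(3)
  ell <- function(sa) {
    outer(outer((gx / sa[1])^2, (gy / sa[2])^2, "+"), (gz / sa[3])^2, "+") <= 1
  }
  head_sa <- 0.42 * d
  wm_sa <- c(0.32, 0.36, 0.34) * d
  lab <- array(0L, dim = d)
  lab[ell(head_sa)] <- 2L
  lab[ell(wm_sa)] <- 1L
  # two ventricles, offset along x
  voff <- round(0.09 * d[1])
  vent_sa <- c(0.05, 0.12, 0.05) * d
  for (s in c(-1, 1)) {
    vx <- ((gx - s * voff) / vent_sa[1])^2
    vent <- outer(outer(vx, (gy / vent_sa[2])^2, "+"), (gz / vent_sa[3])^2, "+") <= 1
    lab[vent] <- 3L
  }
  # ten ROI boxes on two rings in the WM core
  half <- max(1L, round(0.03125 * min(d)))
  ring_r <- 0.2 * min(d[1:2])
  zoff <- round(0.08 * d[3])
  boxes <- vector("list", 10)
  k <- 0
  for (lev in c(-1, 1)) {
    for (a in (0:4) * 2 * pi / 5 + (lev + 1) / 2 * pi / 5) {
      k <- k + 1
      cx <- round(ctr[1] + ring_r * cos(a))
      cy <- round(ctr[2] + ring_r * sin(a))
      cz <- round(ctr[3] + lev * zoff)
      boxes[[k]] <- list(x = (cx - half):(cx + half), y = (cy - half):(cy + half),
                         z = (cz - half):(cz + half))
    }
  }
  for (k in seq_along(boxes)) {
    b <- boxes[[k]]
    ix <- b$x + 1L; iy <- b$y + 1L; iz <- b$z + 1L
    if (any(ix < 1) || any(iy < 1) || any(iz < 1) ||
        any(ix > d[1]) || any(iy > d[2]) || any(iz > d[3]))
      stop("ROI box ", k, " extends outside the grid")
    region <- lab[ix, iy, iz]
    if (any(region != 1L))
      stop(if (any(region %in% phantom_roi_labels))
        "overlapping ROI boxes" else paste0("ROI box ", k, " is not fully inside WM"))
    lab[ix, iy, iz] <- phantom_roi_labels[k]
  }
  names(boxes) <- phantom_roi_names
  lv <- label_volume(lab, aff,
                     label_names = stats::setNames(
                       c("wm", "gm", "csf", phantom_roi_names),
                       as.character(c(1L, 2L, 3L, phantom_roi_labels))))
  attr(lv, "roi_boxes") <- boxes
  lv
}

#' Invert the ratio definitions: weighted signals from ground truth
#'
#' Given true MTR, eMTR and MT asymmetry, returns the six weighted signal
#' values that reproduce them exactly:
#' S+ = S0 (1 - mtr + mtasym/2), S- = S0 (1 - mtr - mtasym/2),
#' S+/- = S-/+ = S0 (1 - emtr), ST1 = S0 * t1_factor. Vectorized.
#'
#' @param S0 unsaturated signal (a.u.).
#' @param mtr,emtr,mtasym true ratios (fractions).
#' @param t1_factor ST1 as a fraction of S0.
#' @return A list with elements \code{S0}, \code{Splus}, \code{Sminus},
#'   \code{Spm}, \code{Smp}, \code{ST1}.
#' @export
signals_from_truth <- function(S0, mtr, emtr, mtasym = 0, t1_factor = 1) {
  sp <- S0 * (1 - mtr + mtasym / 2)
  sm <- S0 * (1 - mtr - mtasym / 2)
  sd2 <- S0 * (1 - emtr)
  st1 <- S0 * t1_factor
  if (any(c(sp, sm, sd2, st1) <= 0, na.rm = TRUE))
    stop("non-physical truth: a synthesized signal is non-positive")
  list(S0 = S0, Splus = sp, Sminus = sm, Spm = sd2, Smp = sd2, ST1 = st1)
}

#' True metric values implied by a truth tuple
#'
#' Forward arithmetic used for truth tables: ihMTR = 2 (emtr - mtr) and the
#' inverse ihMTR implied by the synthesized signals.
#'
#' @inheritParams signals_from_truth
#' @return A list with \code{mtr}, \code{emtr}, \code{mtasym}, \code{ihmtr},
#'   \code{ihmtr_inv}.
#' @export
truth_metrics <- function(mtr, emtr, mtasym = 0, t1_factor = 1) {
  list(mtr = mtr, emtr = emtr, mtasym = mtasym,
       ihmtr = 2 * (emtr - mtr),
       ihmtr_inv = 2 * t1_factor *
         (2 / (1 - emtr) - 1 / (1 - mtr + mtasym / 2) - 1 / (1 - mtr - mtasym / 2)))
}

#' Add Rician noise to a volume
#'
#' Magnitude-MRI noise model: each voxel x becomes
#' sqrt((x + n1)^2 + n2^2) with n1, n2 ~ Normal(0, sigma^2). At zero signal
#' this is Rayleigh with mean sigma * sqrt(pi/2). NaN voxels stay NaN.
#'
#' @param v a \code{\link{volume3d}}.
#' @param sigma noise SD (a.u.); 0 returns the input unchanged.
#' @param seed optional integer seed for reproducibility.
#' @return A \code{\link{volume3d}}.
#' @export
add_rician <- function(v, sigma, seed = NULL) {
  stopifnot(inherits(v, "volume3d"), sigma >= 0)
  if (sigma == 0) return(v)
  if (!is.null(seed)) set.seed(seed)
  n <- length(v$data)
  noisy <- sqrt((v$data + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  noisy[is.na(v$data)] <- NaN
  volume3d(array(noisy, dim = dim(v$data)), v$voxel_to_mm)
}

# fixed per-scan/per-entity seed streams: adding subjects never reshuffles
# existing scans
scan_seed <- function(master, subject, session, rep, offset = 0L) {
  as.integer((master + 100003 * subject + 1009 * session + 101 * rep + offset) %% 2147483647)
}

draw_trunc_normal <- function(n, mean, sd, seed) {
  set.seed(seed)
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= 0) break
    }
    out[i] <- x
  }
  out
}

# per-scan effect structure shared by both generators: additive subject and
# scan effects on eMTR, and a per-session angle that decrements WM eMTR
study_design <- function(spec) {
  design <- expand.grid(rep = seq_len(spec$n_repeats),
                        session = seq_len(spec$n_sessions),
                        subject = seq_len(spec$n_subjects))[, 3:1]
  design$subject_effect <- vapply(design$subject, function(s) {
    set.seed(scan_seed(spec$seed, s, 0L, 0L, 3L))
    stats::rnorm(1, 0, spec$sd_subject)
  }, 0)
  design$scan_effect <- mapply(function(s, se, r) {
    set.seed(scan_seed(spec$seed, s, se, r, 5L))
    stats::rnorm(1, 0, spec$sd_scan)
  }, design$subject, design$session, design$rep)
  angles <- unique(design[, c("subject", "session")])
  angles$angle <- mapply(function(s, se)
    draw_trunc_normal(1, spec$angle_mean, spec$angle_sd,
                      scan_seed(spec$seed, s, se, 0L, 7L)),
    angles$subject, angles$session)
  design <- merge(design, angles, by = c("subject", "session"), sort = FALSE)
  design[order(design$subject, design$session, design$rep), ]
}

scan_truths <- function(spec, row) {
  # per-tissue truths for one scan after subject/scan/angle effects on eMTR
  shift <- row$subject_effect + row$scan_effect
  tt <- spec$tissue_truths
  out <- list()
  for (tn in names(tt)) {
    e <- tt[[tn]]$emtr + shift
    if (tn == "wm") e <- e - spec$angle_slope * row$angle
    out[[tn]] <- utils::modifyList(tt[[tn]], list(emtr = e))
  }
  # ROI-specific WM truths (deterministic eMTR offsets)
  for (k in 1:10) {
    out[[phantom_roi_names[k]]] <-
      utils::modifyList(out$wm, list(emtr = out$wm$emtr + spec$roi_emtr_offsets[k]))
  }
  for (tn in names(out)) {
    if (out[[tn]]$emtr >= 1 || out[[tn]]$emtr <= -1)
      stop("non-physical truth after effects: emtr = ", out[[tn]]$emtr, " for ", tn)
  }
  out
}

truth_rows <- function(spec, design) {
  rows <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    tr <- scan_truths(spec, row)
    do.call(rbind, lapply(phantom_roi_names, function(rn) {
      m <- truth_metrics(tr[[rn]]$mtr, tr[[rn]]$emtr, tr[[rn]]$mtasym, tr[[rn]]$t1_factor)
      data.frame(subject = row$subject, session = row$session, rep = row$rep,
                 roi = rn, mtr = m$mtr, emtr = m$emtr, ihmtr = m$ihmtr,
                 ihmtr_inv = m$ihmtr_inv, head_angle = row$angle)
    }))
  })
  do.call(rbind, rows)
}

render_scan <- function(spec, labels, truths, seed) {
  lab <- labels$labels
  d <- dim(lab)
  lut_names <- c("wm", "gm", "csf", phantom_roi_names)
  lut_codes <- c(1L, 2L, 3L, phantom_roi_labels)
  vols <- lapply(c("S0", "Splus", "Sminus", "Spm", "Smp", "ST1"),
                 function(x) array(0, dim = d))
  names(vols) <- c("S0", "Splus", "Sminus", "Spm", "Smp", "ST1")
  for (i in seq_along(lut_codes)) {
    tt <- truths[[lut_names[i]]]
    sig <- signals_from_truth(tt$S0, tt$mtr, tt$emtr, tt$mtasym, tt$t1_factor)
    sel <- lab == lut_codes[i]
    for (nm in names(vols)) vols[[nm]][sel] <- sig[[nm]]
  }
  out <- lapply(names(vols), function(nm) {
    v <- volume3d(vols[[nm]], labels$voxel_to_mm)
    add_rician(v, spec$noise_sigma, seed = seed + match(nm, names(vols)))
  })
  names(out) <- names(vols)
  do.call(weighted_volume_set, out)
}

#' Simulate a complete synthetic ihMT study with volumes
#'
#' For every scan of the subjects x sessions x repeats design: draws the
#' subject and scan effects (additive on eMTR) and the per-session head
#' angle (shared by the session's repeats), reduces WM eMTR linearly with
#' the angle, synthesizes the six weighted volumes from the resulting
#' truths, adds Rician noise, and emits the scan's native-to-atlas transform
#' as a rotation by -angle about the x axis so that
#' \code{\link{head_angle}} recovers the angle. Identical (spec, seed) give
#' bit-identical output.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param out_dir if non-NULL, volumes and transforms are written under
#'   \code{out_dir} in a sub-XX/ses-Y/run-Z layout (plus labels.nii.gz and
#'   truth.csv) and file paths are returned instead of in-memory volumes.
#' @return A list with elements \code{labels} (\code{\link{label_volume}}),
#'   \code{truth} (data.frame: subject, session, rep, roi, true mtr/emtr/
#'   ihmtr/ihmtr_inv, head_angle), \code{angles} (subject, session, angle)
#'   and \code{scans} (list per scan: subject, session, rep, angle,
#'   \code{volumes} (a \code{\link{weighted_volume_set}}) or \code{paths},
#'   and \code{transform}, an \code{\link{affine_transform}} native->atlas).
#' @export
simulate_study <- function(spec = phantom_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- make_phantom(spec)
  design <- study_design(spec)
  truth <- truth_rows(spec, design)
  angles <- unique(design[, c("subject", "session", "angle")])
  rownames(angles) <- NULL
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scans <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    truths <- scan_truths(spec, row)
    ws <- render_scan(spec, labels, truths,
                      scan_seed(spec$seed, row$subject, row$session, row$rep, 50L))
    tmat <- rotation_affine(-row$angle, axis = "x")
    tr <- affine_transform(tmat, from_space = "native", to_space = "atlas")
    entry <- list(subject = row$subject, session = row$session, rep = row$rep,
                  angle = row$angle, transform = tr)
    if (is.null(out_dir)) {
      entry$volumes <- ws
    } else {
      sdir <- file.path(out_dir, sprintf("sub-%02d", row$subject),
                        sprintf("ses-%d", row$session), sprintf("run-%d", row$rep))
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      paths <- character(0)
      for (nm in names(ws)) {
        p <- file.path(sdir, paste0(tolower(nm), ".nii.gz"))
        write_volume(ws[[nm]], p)
        paths[nm] <- p
      }
      write_affine(tr, file.path(sdir, "native_to_atlas.txt"))
      entry$paths <- paths
      entry$transform_path <- file.path(sdir, "native_to_atlas.txt")
    }
    scans[[i]] <- entry
  }
  if (!is.null(out_dir)) {
    write_labels(labels, file.path(out_dir, "labels.nii.gz"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(labels = labels, truth = truth, angles = angles, scans = scans)
}

#' Simulate ROI-mean tables without rendering volumes
#'
#' Table-level counterpart of \code{\link{simulate_study}}: the same design,
#' effects and angle structure, but the response is generated directly at
#' the ROI-mean level, with residual noise of SD \code{sigma_resid} added to
#' each scan-and-ROI eMTR (emulating what voxelwise noise averages down to
#' over an ROI). Used for replicate-study statistics where rendering volumes
#' would be pointless.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list with \code{table} (an \code{\link{roi_table}} in long
#'   format with metrics mtr, emtr, ihmtr, ihmtr_inv), \code{angles}
#'   (subject, session, angle) and \code{truth} (as in
#'   \code{\link{simulate_study}}).
#' @export
simulate_roi_study <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  design <- study_design(spec)
  truth <- truth_rows(spec, design)
  angles <- unique(design[, c("subject", "session", "angle")])
  rownames(angles) <- NULL
  rows <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    tr <- scan_truths(spec, row)
    set.seed(scan_seed(spec$seed, row$subject, row$session, row$rep, 9L))
    eps <- stats::rnorm(10, 0, spec$sigma_resid)
    do.call(rbind, lapply(1:10, function(k) {
      rn <- phantom_roi_names[k]
      tk <- tr[[rn]]
      m <- truth_metrics(tk$mtr, tk$emtr + eps[k], tk$mtasym, tk$t1_factor)
      data.frame(subject = row$subject, session = row$session, rep = row$rep,
                 roi = rn,
                 metric = c("mtr", "emtr", "ihmtr", "ihmtr_inv"),
                 value = c(m$mtr, m$emtr, m$ihmtr, m$ihmtr_inv))
    }))
  })
  tab <- roi_table(do.call(rbind, rows))
  list(table = tab, angles = angles, truth = truth)
}

#' Simulate a balanced subject-by-scan measurement table
#'
#' Draws y_ij = mu + s_i + r_j + e_ij with independent normal subject, scan
#' and residual effects: the sampling model behind ICC(2,1). Used for ICC
#' recovery and bootstrap coverage studies.
#'
#' @param n_subjects,n_scans design size.
#' @param var_subject,var_scan,var_resid variance components.
#' @param mu grand mean.
#' @param seed integer seed.
#' @return A numeric matrix (subjects x scans).
#' @export
simulate_icc_study <- function(n_subjects = 12, n_scans = 4,
                               var_subject = 1, var_scan = 0.5, var_resid = 0.5,
                               mu = 0.15, seed = 1L) {
  stopifnot(n_subjects >= 2, n_scans >= 2,
            var_subject >= 0, var_scan >= 0, var_resid >= 0)
  set.seed(seed)
  s <- stats::rnorm(n_subjects, 0, sqrt(var_subject))
  r <- stats::rnorm(n_scans, 0, sqrt(var_scan))
  e <- matrix(stats::rnorm(n_subjects * n_scans, 0, sqrt(var_resid)),
              n_subjects, n_scans)
  y <- mu + outer(s, r, "+") + e
  dimnames(y) <- list(paste0("sub", seq_len(n_subjects)),
                      paste0("scan", seq_len(n_scans)))
  y
}
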