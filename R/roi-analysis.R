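#' Long-format ROI measurement table
#'
#' Validates a data.frame of ROI-mean measurements with columns
#' \code{subject}, \code{session}, \code{rep}, \code{roi}, \code{metric},
#' \code{value}: one row per ROI-mean of one metric in one scan. This is the
#' y_ij of the reliability model and the response of the head-orientation
#' model.
#'
#' @param df data.frame with the six columns above. \code{repeat} is accepted
#'   as an alias for \code{rep}.
#' @return The validated data.frame with class \code{c("roi_table", "data.frame")}.
#' @export
roi_table <- function(df) {
  df <- as.data.frame(df)
  if ("repeat." %in% names(df)) names(df)[names(df) == "repeat."] <- "rep"
  if ("repeat" %in% names(df)) names(df)[names(df) == "repeat"] <- "rep"
  need <- c("subject", "session", "rep", "roi", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("roi_table missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  if (!is.numeric(df$value)) stop("value must be numeric")
  if (any(!is.finite(df$value))) stop("values must be finite")
  key <- do.call(paste, c(df[, c("subject", "session", "rep", "roi", "metric")], sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate (subject, session, rep, roi, metric) rows")
  class(df) <- c("roi_table", "data.frame")
  df
}

#' Read a long-format ROI summary CSV
#'
#' Reads deposited-style ROI summary tables. Column names are matched
#' case-insensitively; \code{repeat}/\code{run} are accepted for \code{rep}.
#'
#' @param path CSV path.
#' @return An \code{\link{roi_table}}.
#' @export
read_roi_csv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  nm[nm %in% c("repeat", "run")] <- "rep"
  names(df) <- nm
  roi_table(df)
}

#' Per-ROI means of a scalar map
#'
#' Arithmetic mean of the non-NaN voxels of \code{map} within each nonzero
#' label of \code{labels}. ROIs whose voxels are all NaN are reported with
#' \code{NA} mean.
#'
#' @param map a \code{\link{volume3d}}.
#' @param labels a \code{\link{label_volume}} on the same grid.
#' @return data.frame with columns \code{label}, \code{roi}, \code{n_voxels}
#'   (non-NaN count) and \code{mean}.
#' @export
roi_means <- function(map, labels) {
  stopifnot(inherits(map, "volume3d"), inherits(labels, "label_volume"))
  if (!same_grid(map, labels)) stop("grid mismatch: map and labels")
  lab <- as.vector(labels$labels)
  sel <- lab != 0L
  if (!any(sel)) stop("empty label set: no nonzero labels")
  vals <- as.vector(map$data)[sel]
  lab <- lab[sel]
  ok <- !is.na(vals)
  n <- tapply(ok, lab, sum)
  s <- tapply(ifelse(ok, vals, 0), lab, sum)
  codes <- as.integer(names(n))
  data.frame(label = codes,
             roi = unname(labels$label_names[as.character(codes)]),
             n_voxels = as.integer(n),
             mean = ifelse(n > 0, s / n, NA_real_),
             row.names = NULL)
}

#' Build an ROI table from a simulated study
#'
#' Runs the mapping stage on every scan of a \code{\link{simulate_study}}
#' result — computes the five ratio maps and the per-ROI means — and stacks
#' them into a long \code{\link{roi_table}}. Statistics are computed in the
#' scans' native space; only the ten ROI labels (not the bulk tissue labels)
#' are tabulated.
#'
#' @param study result of \code{\link{simulate_study}} (in-memory volumes).
#' @param s0_threshold passed to \code{\link{compute_ratio_maps}}.
#' @return An \code{\link{roi_table}} with metrics mtr, emtr, mtasym, ihmtr,
#'   ihmtr_inv.
#' @export
study_roi_table <- function(study, s0_threshold = 0.05) {
  roi_only <- study$labels
  roi_only$labels[!(roi_only$labels %in% phantom_roi_labels)] <- 0L
  rows <- lapply(study$scans, function(sc) {
    if (is.null(sc$volumes)) stop("study must hold in-memory volumes (out_dir = NULL)")
    maps <- compute_ratio_maps(sc$volumes, s0_threshold = s0_threshold)
    do.call(rbind, lapply(c("mtr", "emtr", "mtasym", "ihmtr", "ihmtr_inv"),
                          function(met) {
      rm <- roi_means(maps[[met]], roi_only)
      data.frame(subject = sc$subject, session = sc$session, rep = sc$rep,
                 roi = rm$roi, metric = met, value = rm$mean)
    }))
  })
  roi_table(do.call(rbind, rows))
}

#' Between-subject coefficient of variation
#'
#' Sample SD (n-1 denominator) over mean, across all supplied values
#' (all scans and subjects pooled).
#'
#' @param values numeric vector, length >= 2.
#' @return CoV as a fraction; \code{NA} if the mean is not positive.
#' @export
cov_between <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("cov_between needs >= 2 values")
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  stats::sd(values) / m
}

#' Average within-subject coefficient of variation
#'
#' Per subject, the SD/mean over that subject's scan values; then the
#' unweighted average across subjects. Subjects with fewer than two scans
#' are excluded with a warning.
#'
#' @param table an \code{\link{roi_table}} (or data.frame with subject and
#'   value columns, already restricted to one roi and metric), or a numeric
#'   vector of per-subject CoVs to average.
#' @param metric,roi optional filters applied when \code{table} is a table.
#' @return Average within-subject CoV (fraction) when filtered to one
#'   roi/metric; otherwise a data.frame per (roi, metric).
#' @export
cov_within <- function(table, metric = NULL, roi = NULL) {
  if (is.numeric(table)) return(mean(table))
  df <- as.data.frame(table)
  if (!is.null(metric)) df <- df[df$metric == metric, ]
  if (!is.null(roi)) df <- df[df$roi == roi, ]
  one <- function(sub) {
    per <- vapply(split(sub$value, sub$subject), function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      if (mean(v) <= 0) return(NA_real_)
      stats::sd(v) / mean(v)
    }, 0)
    if (anyNA(per)) warning("subjects with < 2 scans (or non-positive mean) excluded")
    mean(per, na.rm = TRUE)
  }
  if (length(unique(df$roi)) == 1 && length(unique(df$metric)) == 1) return(one(df))
  groups <- split(df, list(df$roi, df$metric), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(roi = g$roi[1], metric = g$metric[1], cov_within = one(g))))
  rownames(out) <- NULL
  out
}

#' Per-ROI CoV summary
#'
#' Between-subject CoV (across all scans and subjects) and average
#' within-subject CoV, per ROI and metric.
#'
#' @param table an \code{\link{roi_table}}.
#' @return data.frame with columns roi, metric, cov_between, cov_within.
#' @export
roi_cov <- function(table) {
  df <- as.data.frame(table)
  groups <- split(df, list(df$roi, df$metric), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(roi = g$roi[1], metric = g$metric[1],
               cov_between = cov_between(g$value),
               cov_within = suppressWarnings(cov_within(g)))))
  rownames(out) <- NULL
  out[order(out$metric, out$roi), ]
}

#' Voxelwise coefficient-of-variation map
#'
#' Between grouping: voxelwise SD/mean across all volumes. Within grouping:
#' per subject the voxelwise SD/mean over that subject's volumes, then the
#' voxelwise average over subjects. A voxel that is NaN in any input is NaN
#' in the output.
#'
#' @param stack list of \code{\link{volume3d}} on one grid (>= 2).
#' @param grouping \code{"between"} or \code{"within"}.
#' @param subjects subject id per volume; required for \code{"within"}.
#' @return A \code{\link{volume3d}} of CoV fractions.
#' @export
cov_map <- function(stack, grouping = c("between", "within"), subjects = NULL) {
  grouping <- match.arg(grouping)
  if (length(stack) < 2) stop("cov_map needs >= 2 volumes")
  for (v in stack) {
    if (!inherits(v, "volume3d")) stop("stack must contain volume3d objects")
    if (!same_grid(v, stack[[1]])) stop("grid mismatch in stack")
  }
  mat <- vapply(stack, function(v) as.vector(v$data), numeric(length(stack[[1]]$data)))
  voxel_cov <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    out <- sdv / mu
    out[!is.finite(out)] <- NaN
    out
  }
  if (grouping == "between") {
    res <- voxel_cov(mat)
  } else {
    if (is.null(subjects) || length(subjects) != length(stack))
      stop("'within' grouping needs one subject id per volume")
    per <- sapply(unique(subjects), function(s) {
      cols <- which(subjects == s)
      if (length(cols) < 2) stop("subject ", s, " has < 2 volumes")
      voxel_cov(mat[, cols, drop = FALSE])
    })
    res <- rowMeans(per)
  }
  res[is.na(res)] <- NaN
  volume3d(array(res, dim = dim(stack[[1]]$data)), stack[[1]]$voxel_to_mm)
}

#' Per-ROI summary table (mean and SD across subjects, percent scale)
#'
#' Averages each subject's scans, then reports the mean and sample SD of the
#' subject means per ROI, in percent: the layout of a repeatability study's
#' summary table.
#'
#' @param table an \code{\link{roi_table}}.
#' @param metrics metrics to include (default ihmtr and ihmtr_inv).
#' @return data.frame with roi and, per metric, \code{<metric>_mean_pct} and
#'   \code{<metric>_sd_pct}.
#' @export
roi_summary_table <- function(table, metrics = c("ihmtr", "ihmtr_inv")) {
  df <- as.data.frame(table)
  df <- df[df$metric %in% metrics, ]
  if (!nrow(df)) stop("no rows for requested metrics")
  subj <- stats::aggregate(value ~ subject + roi + metric, df, mean)
  agg <- stats::aggregate(value ~ roi + metric, subj,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  agg <- data.frame(roi = agg$roi, metric = agg$metric,
                    mean_pct = 100 * agg$value[, "mean"],
                    sd_pct = 100 * agg$value[, "sd"])
  out <- Reduce(function(a, b) merge(a, b, by = "roi"),
                lapply(metrics, function(m) {
                  g <- agg[agg$metric == m, c("roi", "mean_pct", "sd_pct")]
                  names(g)[2:3] <- paste0(m, c("_mean_pct", "_sd_pct"))
                  g
                }))
  out[order(out$roi), ]
}
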