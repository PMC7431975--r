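#' Rotation affine about a coordinate axis
#'
#' Homogeneous 4x4 rotation (degrees, right-handed) about x, y or z, with no
#' translation.
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis "x", "y" or "z".
#' @return A 4x4 matrix.
#' @export
rotation_affine <- function(angle_deg, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  r <- switch(axis,
              x = rbind(c(1, 0, 0), c(0, c2, -s2), c(0, s2, c2)),
              y = rbind(c(c2, 0, s2), c(0, 1, 0), c(-s2, 0, c2)),
              z = rbind(c(c2, -s2, 0), c(s2, c2, 0), c(0, 0, 1)))
  m <- diag(4)
  m[1:3, 1:3] <- r
  m
}

#' Concatenate a chain of affine transforms
#'
#' Composes transforms in application order: the first element of the chain
#' is applied first. Adjacent space names must match (the to_space of each
#' transform equals the from_space of the next).
#'
#' @param ... \code{\link{affine_transform}} objects, or a single list of them.
#' @return A single \code{\link{affine_transform}} from the first transform's
#'   from_space to the last one's to_space.
#' @export
concat_affines <- function(...) {
  chain <- list(...)
  if (length(chain) == 1L && is.list(chain[[1]]) && !inherits(chain[[1]], "affine_transform"))
    chain <- chain[[1]]
  if (!length(chain)) stop("empty chain")
  for (t in chain) stopifnot(inherits(t, "affine_transform"))
  for (k in seq_len(length(chain) - 1)) {
    if (!identical(chain[[k]]$to_space, chain[[k + 1]]$from_space))
      stop("space mismatch: '", chain[[k]]$to_space, "' -> '",
           chain[[k + 1]]$from_space, "' at position ", k)
  }
  m <- diag(4)
  for (t in chain) m <- t$matrix %*% m
  affine_transform(m, from_space = chain[[1]]$from_space,
                   to_space = chain[[length(chain)]]$to_space)
}

#' Head rotation angle from an affine transform
#'
#' Applies the linear part of the transform to the head-foot unit vector
#' Z = (0, 0, 1), normalizes the image (the transform may carry scale), and
#' returns the angle between it and Z in degrees: the bulk head rotation
#' away from the atlas head-foot axis. The translation component is ignored
#' and the angle is unsigned (in [0, 180]).
#'
#' @param t an \code{\link{affine_transform}} (e.g. the concatenated
#'   native-to-atlas transform).
#' @return angle in degrees.
#' @export
head_angle <- function(t) {
  stopifnot(inherits(t, "affine_transform"))
  v <- t$matrix[1:3, 1:3] %*% c(0, 0, 1)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("transform maps Z to the zero vector")
  acos(min(1, max(-1, v[3] / nv))) * 180 / pi
}

#' Median and quartiles of head angles
#'
#' Linear-interpolation quantiles (R's default type-7 rule).
#'
#' @param angles numeric vector of angles (degrees), or a data.frame with an
#'   \code{angle} column.
#' @return list with \code{median}, \code{q1}, \code{q3}.
#' @export
summarize_angles <- function(angles) {
  if (is.data.frame(angles)) angles <- angles$angle
  if (!length(angles)) stop("no angles")
  q <- stats::quantile(angles, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Mixed-effects model for the head-angle effect on an ihMT metric
#'
#' Fits, by REML, value ~ angle + ROI + angle:ROI + subject (fixed) with
#' random intercepts for subject, subject:ROI and scan, on the ROI means of
#' one metric. The per-scan intercept (one level per subject-session-repeat)
#' absorbs the correlation between the ROI values of a single scan; without
#' it a session-level covariate such as head angle is tested against far too
#' many effective degrees of freedom. ROI and subject use sum-to-zero
#' contrasts so the angle main effect is the average within-subject linear
#' slope across ROIs. F-tests
#' for the angle main effect and the angle-by-ROI interaction use
#' Satterthwaite denominator degrees of freedom; a parametric-bootstrap
#' p-value for the angle effect is available as a cross-check.
#'
#' Each (subject, session) must have an angle; repeats within a session
#' share it. If every subject has only a single distinct angle the
#' within-subject slope is aliased with the subject fixed effects and the
#' fit is refused.
#'
#' @param table an \code{\link{roi_table}}.
#' @param angles data.frame with columns subject, session, angle (degrees).
#' @param metric metric to model (default \code{"ihmtr_inv"}).
#' @param exclude_subjects subjects to drop before fitting (e.g. an outlier
#'   re-analysis).
#' @param method \code{"satterthwaite"} (default) or \code{"bootstrap"} for
#'   a parametric-bootstrap p-value of the angle main effect.
#' @param n_boot parametric-bootstrap draws when \code{method = "bootstrap"}.
#' @param seed seed for the parametric bootstrap.
#' @return An object of class \code{angle_model_result}: list with
#'   \code{slope_angle} (metric units per degree), \code{f_angle},
#'   \code{p_angle}, \code{df_num}, \code{df_den}, \code{f_interaction},
#'   \code{p_interaction}, \code{df_num_int}, \code{df_den_int},
#'   \code{method}, \code{n_obs} and the fitted \code{model}.
#' @export
fit_angle_model <- function(table, angles, metric = "ihmtr_inv",
                            exclude_subjects = NULL,
                            method = c("satterthwaite", "bootstrap"),
                            n_boot = 200, seed = 1L) {
  method <- match.arg(method)
  df <- as.data.frame(table)
  df <- df[df$metric == metric, ]
  if (!nrow(df)) stop("no rows for metric ", metric)
  if (!is.null(exclude_subjects)) {
    df <- df[!(df$subject %in% exclude_subjects), ]
    angles <- angles[!(angles$subject %in% exclude_subjects), ]
  }
  if (length(unique(df$roi)) < 2) stop("need >= 2 ROIs")
  dat <- merge(df, angles[, c("subject", "session", "angle")],
               by = c("subject", "session"))
  if (nrow(dat) < nrow(df))
    stop("missing angle for some (subject, session) pairs")
  dat$roi <- factor(dat$roi)
  dat$subject <- factor(dat$subject)
  per_subj <- tapply(dat$angle, dat$subject, function(a) length(unique(a)))
  if (max(per_subj) < 2)
    stop("rank deficiency: head angle is aliased with the subject fixed effect ",
         "(every subject has a single angle value)")
  dat$scan_id <- interaction(dat$subject, dat$session, dat$rep, drop = TRUE)
  fit <- suppressMessages(lmerTest::lmer(
    value ~ angle * roi + subject + (1 | subject) + (1 | subject:roi) + (1 | scan_id),
    data = dat, REML = TRUE,
    contrasts = list(roi = stats::contr.sum, subject = stats::contr.sum),
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  an <- suppressMessages(stats::anova(fit, type = 3))
  rows <- rownames(an)
  a_row <- which(rows == "angle")
  i_row <- which(rows == "angle:roi")
  if (!length(a_row) || !length(i_row))
    stop("rank deficiency: the angle or angle:roi term was dropped from the fit")
  res <- list(slope_angle = unname(lme4::fixef(fit)["angle"]),
              f_angle = an[a_row, "F value"], p_angle = an[a_row, "Pr(>F)"],
              df_num = an[a_row, "NumDF"], df_den = an[a_row, "DenDF"],
              f_interaction = an[i_row, "F value"],
              p_interaction = an[i_row, "Pr(>F)"],
              df_num_int = an[i_row, "NumDF"], df_den_int = an[i_row, "DenDF"],
              method = method, n_obs = nrow(dat), model = fit)
  if (method == "bootstrap") {
    null_fit <- suppressMessages(lme4::lmer(
      value ~ roi + subject + (1 | subject) + (1 | subject:roi) + (1 | scan_id),
      data = dat, REML = TRUE,
      contrasts = list(roi = stats::contr.sum, subject = stats::contr.sum),
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    set.seed(seed)
    sims <- stats::simulate(null_fit, nsim = n_boot)
    f_null <- vapply(seq_len(n_boot), function(b) {
      db <- dat
      db$value <- sims[[b]]
      fb <- try(suppressMessages(lmerTest::lmer(
        value ~ angle * roi + subject + (1 | subject) + (1 | subject:roi) + (1 | scan_id),
        data = db, REML = TRUE,
        contrasts = list(roi = stats::contr.sum, subject = stats::contr.sum),
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE))), silent = TRUE)
      if (inherits(fb, "try-error")) return(NA_real_)
      ab <- suppressMessages(stats::anova(fb, type = 3))
      ab[rownames(ab) == "angle", "F value"]
    }, 0)
    f_null <- f_null[!is.na(f_null)]
    res$p_angle_boot <- (1 + sum(f_null >= res$f_angle)) / (1 + length(f_null))
  }
  class(res) <- "angle_model_result"
  res
}

#' @export
print.angle_model_result <- function(x, ...) {
  cat(sprintf("angle effect: slope %.4g per degree, F(%g, %.1f) = %.2f, p = %.3g\n",
              x$slope_angle, x$df_num, x$df_den, x$f_angle, x$p_angle))
  cat(sprintf("angle x ROI:  F(%g, %.1f) = %.2f, p = %.3g\n",
              x$df_num_int, x$df_den_int, x$f_interaction, x$p_interaction))
  if (!is.null(x$p_angle_boot))
    cat(sprintf("parametric-bootstrap p (angle): %.3g\n", x$p_angle_boot))
  invisible(x)
}
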