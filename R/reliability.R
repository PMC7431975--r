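#' Weakly informative gamma prior for random-effect SDs
#'
#' Regularizer for the variance-component fit: a gamma density evaluated at
#' each random-effect standard deviation and added to the REML
#' log-likelihood. The default (shape 2, rate 0.5) has zero density at 0, so
#' it keeps SD estimates off the boundary while barely informing their
#' magnitude (mode at SD = 2).
#'
#' @param shape,rate gamma parameters, both > 0.
#' @return An object of class \code{gamma_prior}.
#' @export
gamma_prior <- function(shape = 2, rate = 0.5) {
  stopifnot(shape > 0, rate > 0)
  structure(list(shape = shape, rate = rate), class = "gamma_prior")
}

# accepts subjects-x-scans matrix (NA = missing) or long data.frame
as_icc_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  df <- as.data.frame(table)
  if (all(c("session", "rep") %in% names(df)) && !("scan" %in% names(df)))
    df$scan <- paste0("s", df$session, "r", df$rep)
  if (!all(c("subject", "scan", "value") %in% names(df)))
    stop("need a subjects-x-scans matrix or columns subject, scan, value")
  y <- stats::xtabs(value ~ subject + scan, df, sparse = FALSE)
  # xtabs puts 0 where missing; mark empty cells NA
  cnt <- stats::xtabs(~subject + scan, df)
  y[cnt == 0] <- NA
  unclass(y)
}

# balanced two-way crossed REML log-likelihood from the ANOVA decomposition:
# subject-contrast, scan-contrast and residual spaces are eigenspaces of V
# with eigenvalues J*vs + ve, I*vr + ve and ve
balanced_reml_ll <- function(vs, vr, ve, ss) {
  lA <- ss$J * vs + ve
  lB <- ss$I * vr + ve
  -0.5 * (ss$dfA * log(lA) + ss$SSA / lA +
            ss$dfB * log(lB) + ss$SSB / lB +
            ss$dfE * log(ve) + ss$SSE / ve +
            (ss$n - 1) * log(2 * pi))
}

balanced_ss <- function(y) {
  I <- nrow(y); J <- ncol(y)
  rm <- rowMeans(y); cm <- colMeans(y); gm <- mean(y)
  list(I = I, J = J, n = I * J,
       SSA = J * sum((rm - gm)^2), dfA = I - 1,
       SSB = I * sum((cm - gm)^2), dfB = J - 1,
       SSE = sum((y - outer(rm, cm, "+") + gm)^2), dfE = (I - 1) * (J - 1))
}

# dense REML for incomplete designs
general_reml_ll <- function(vs, vr, ve, dat) {
  V <- vs * dat$ZZs + vr * dat$ZZr + diag(ve, dat$n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), dat$y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, dat$n)))
  xvx <- sum(Vi_1)
  beta <- sum(Vi_y) / xvx
  yPy <- sum(dat$y * Vi_y) - beta * sum(dat$y * Vi_1)
  -0.5 * (logdetV + log(xvx) + yPy + (dat$n - 1) * log(2 * pi))
}

#' Fit the two-way random-effects model with regularized variance components
#'
#' Fits y_ij = mu + s_i + r_j + e_ij (subjects i, scans j, both random) by
#' maximizing the REML log-likelihood plus, when \code{prior} is given, the
#' log gamma prior density evaluated at each random-effect standard deviation
#' (subject and scan; the residual SD is unpenalized). The penalty keeps the
#' subject and scan SDs off the zero boundary on small samples. Optimization
#' is over log-SDs (unconstrained, deterministic Nelder-Mead from
#' method-of-moments starting values floored at a small positive value;
#' relative tolerance 1e-8), so the fit is reproducible.
#'
#' Complete designs use the closed-form balanced REML likelihood (the three
#' ANOVA sums of squares are sufficient); incomplete designs fall back to a
#' dense-matrix REML, and more than 20\% missingness is an error.
#'
#' @param table subjects-x-scans numeric matrix (NA = missing) or long
#'   data.frame with columns subject, scan (or session + rep) and value.
#' @param prior a \code{\link{gamma_prior}}, or \code{NULL} for plain
#'   (unpenalized) REML.
#' @return An object of class \code{variance_components}: list with
#'   \code{var_subject}, \code{var_scan}, \code{var_resid}, \code{loglik}
#'   (penalized objective at the optimum), \code{regularized},
#'   \code{n_subjects}, \code{n_scans} and \code{convergence} (0 = converged).
#' @export
fit_two_way_random <- function(table, prior = gamma_prior()) {
  y <- as_icc_matrix(table)
  I <- nrow(y); J <- ncol(y)
  if (I < 3) stop("need >= 3 subjects")
  if (J < 2) stop("need >= 2 scans")
  n_miss <- sum(is.na(y))
  if (n_miss / length(y) > 0.2)
    stop("unbalanced missingness beyond 20% (", n_miss, " of ", length(y), " cells)")
  if (!is.null(prior) && !inherits(prior, "gamma_prior"))
    stop("prior must be a gamma_prior or NULL")
  balanced <- n_miss == 0L
  if (balanced) {
    ss <- balanced_ss(y)
    ll_fun <- function(vs, vr, ve) balanced_reml_ll(vs, vr, ve, ss)
    mom <- list(mse = ss$SSE / ss$dfE,
                msa = ss$SSA / ss$dfA, msb = ss$SSB / ss$dfB)
    mom_est <- c(max((mom$msa - mom$mse) / J, 0),
                 max((mom$msb - mom$mse) / I, 0), mom$mse)
  } else {
    obs <- which(!is.na(y), arr.ind = TRUE)
    Zs <- outer(obs[, 1], seq_len(I), "==") * 1
    Zr <- outer(obs[, 2], seq_len(J), "==") * 1
    dat <- list(y = y[!is.na(y)], n = nrow(obs),
                ZZs = tcrossprod(Zs), ZZr = tcrossprod(Zr))
    ll_fun <- function(vs, vr, ve) general_reml_ll(vs, vr, ve, dat)
    tot <- stats::var(dat$y)
    mom_est <- c(tot / 3, tot / 3, tot / 3)  # crude start; optimizer refines
  }
  vary <- stats::var(as.vector(y), na.rm = TRUE)
  floor_sd <- sqrt(max(vary, .Machine$double.eps)) * 1e-3
  start <- log(pmax(sqrt(mom_est), floor_sd))
  pen <- function(sdv) {
    if (is.null(prior)) 0
    else stats::dgamma(sdv[1], prior$shape, prior$rate, log = TRUE) +
      stats::dgamma(sdv[2], prior$shape, prior$rate, log = TRUE)
  }
  negobj <- function(theta) {
    sdv <- exp(theta)
    val <- ll_fun(sdv[1]^2, sdv[2]^2, sdv[3]^2) + pen(sdv)
    if (!is.finite(val)) return(1e300)
    -val
  }
  opt <- stats::optim(start, negobj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  sdv <- exp(opt$par)
  structure(list(var_subject = sdv[1]^2, var_scan = sdv[2]^2,
                 var_resid = sdv[3]^2, loglik = -opt$value,
                 regularized = !is.null(prior),
                 n_subjects = I, n_scans = J,
                 convergence = opt$convergence), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components (%s): subject %.4g | scan %.4g | residual %.4g | ICC(2,1) %.3f\n",
              if (x$regularized) "penalized REML" else "REML",
              x$var_subject, x$var_scan, x$var_resid, icc21(x)))
  invisible(x)
}

#' ICC(2,1) from variance components
#'
#' Intraclass correlation for single measurements under the two-way random
#' model: var_subject / (var_subject + var_scan + var_resid).
#'
#' @param components a \code{variance_components} object from
#'   \code{\link{fit_two_way_random}}, or a numeric vector of the three
#'   variances (subject, scan, residual).
#' @return ICC in [0, 1]; \code{NA} when all three variances are zero.
#' @export
icc21 <- function(components) {
  v <- if (inherits(components, "variance_components"))
    c(components$var_subject, components$var_scan, components$var_resid)
  else as.numeric(components)
  if (length(v) != 3) stop("need three variance components")
  if (any(v < 0)) stop("negative input variance")
  tot <- sum(v)
  if (tot == 0) return(NA_real_)
  v[1] / tot
}

#' Bootstrap percentile confidence interval for ICC(2,1)
#'
#' Refits the penalized model on bootstrap replicates and takes the 2.5th
#' and 97.5th percentiles of the resampled ICCs. Two resampling schemes are
#' provided. \code{"parametric"} (the default) simulates whole studies from
#' the fitted variance components, which propagates the uncertainty of the
#' subject, scan and residual components alike; in simulation its 95\%
#' interval covers the true ICC at close to the nominal rate for a
#' 12-subject, 4-scan design. \code{"subject"} resamples subjects with
#' replacement, keeping each sampled subject's full scan record; with few
#' subjects it understates the between-subject variance of the resamples
#' and its intervals undercover, so it is offered for comparison rather
#' than as the default. Seeded, so identical inputs give identical
#' intervals. Data with zero variance admit no resampling uncertainty and
#' return a zero-width interval at the fitted ICC.
#'
#' @inheritParams fit_two_way_random
#' @param n_boot number of resamples (>= 100).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @param type \code{"parametric"} or \code{"subject"} (see above).
#' @return A list with \code{ci_low}, \code{ci_high}, \code{n_boot} and
#'   \code{n_failed} (refits that errored; more than 10\% is an error).
#' @export
bootstrap_ci <- function(table, n_boot = 1000, seed = 1L, prior = gamma_prior(),
                         conf = 0.95, type = c("parametric", "subject")) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  type <- match.arg(type)
  y <- as_icc_matrix(table)
  fit0 <- fit_two_way_random(y, prior = prior)
  if (stats::var(as.vector(y), na.rm = TRUE) == 0) {
    ic <- icc21(fit0)
    return(list(ci_low = ic, ci_high = ic, n_boot = n_boot, n_failed = 0L))
  }
  I <- nrow(y); J <- ncol(y); mu <- mean(y, na.rm = TRUE)
  set.seed(seed)
  iccs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    yb <- if (type == "subject") {
      y[sample.int(I, I, replace = TRUE), , drop = FALSE]
    } else {
      mu + outer(stats::rnorm(I, 0, sqrt(fit0$var_subject)),
                 stats::rnorm(J, 0, sqrt(fit0$var_scan)), "+") +
        matrix(stats::rnorm(I * J, 0, sqrt(fit0$var_resid)), I, J)
    }
    fit <- tryCatch(fit_two_way_random(yb, prior = prior), error = function(e) NULL)
    if (!is.null(fit)) iccs[b] <- icc21(fit)
  }
  n_failed <- sum(is.na(iccs))
  if (n_failed > 0.1 * n_boot)
    stop("more than 10% of bootstrap refits failed (", n_failed, "/", n_boot, ")")
  qs <- stats::quantile(iccs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], n_boot = n_boot, n_failed = n_failed)
}

#' Classify an ICC value
#'
#' Reliability categories: poor below 0.5, moderate from 0.5 up to 0.75,
#' good from 0.75 up to 0.9, excellent from 0.9. Boundary values take the
#' higher category.
#'
#' @param icc ICC value(s) in [0, 1].
#' @return character vector of categories.
#' @export
classify_icc <- function(icc) {
  if (any(is.na(icc)) || any(icc < 0 | icc > 1))
    stop("icc must lie in [0, 1]")
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |> as.character()
}

#' Per-ROI ICC(2,1) reliability analysis
#'
#' For one metric of an \code{\link{roi_table}}: per ROI, flattens session
#' and repeat into a single scan factor, fits the regularized two-way random
#' model, and reports ICC(2,1), its bootstrap percentile CI, the variance
#' components and the reliability category.
#'
#' @param table an \code{\link{roi_table}}.
#' @param metric metric to analyse (e.g. \code{"ihmtr_inv"}).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param prior a \code{\link{gamma_prior}} (or NULL for unpenalized REML).
#' @return data.frame with one row per ROI: roi, metric, icc, ci_low,
#'   ci_high, var_subject, var_scan, var_resid, category.
#' @export
icc_reliability <- function(table, metric = "ihmtr_inv", n_boot = 1000,
                            seed = 1L, prior = gamma_prior()) {
  df <- as.data.frame(table)
  df <- df[df$metric == metric, ]
  if (!nrow(df)) stop("no rows for metric ", metric)
  rois <- sort(unique(df$roi))
  out <- do.call(rbind, lapply(seq_along(rois), function(k) {
    g <- df[df$roi == rois[k], ]
    fit <- fit_two_way_random(g, prior = prior)
    ic <- icc21(fit)
    ci <- bootstrap_ci(g, n_boot = n_boot, seed = seed + k, prior = prior)
    data.frame(roi = rois[k], metric = metric, icc = ic,
               ci_low = ci$ci_low, ci_high = ci$ci_high,
               var_subject = fit$var_subject, var_scan = fit$var_scan,
               var_resid = fit$var_resid,
               category = classify_icc(min(max(ic, 0), 1)))
  }))
  rownames(out) <- NULL
  out
}
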