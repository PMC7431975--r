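# small-grid phantom spec for fast end-to-end tests (the default spec is the
# full study design; tests that exercise plumbing use this reduced geometry)
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(32L, 32L, 32L), n_subjects = 2L,
         noise_sigma = 0, sd_subject = 0, sd_scan = 0, angle_slope = 0,
         sigma_resid = 0),
    list(...))
  do.call(phantom_spec, args)
}

const_volume <- function(value, dims = c(6, 6, 6), affine = diag(4)) {
  volume3d(array(value, dim = dims), affine)
}

# weighted set from scalar signals on a small constant grid
const_ws <- function(s0, splus, sminus, spm, smp, st1, dims = c(6, 6, 6)) {
  weighted_volume_set(const_volume(s0, dims), const_volume(splus, dims),
                      const_volume(sminus, dims), const_volume(spm, dims),
                      const_volume(smp, dims), const_volume(st1, dims))
}

# independent method-of-moments oracle for the two-way random model,
# via the classical ANOVA mean squares from lm()
mom_oracle <- function(y) {
  I <- nrow(y); J <- ncol(y)
  df <- data.frame(v = as.vector(y),
                   s = factor(rep(seq_len(I), J)),
                   r = factor(rep(seq_len(J), each = I)))
  a <- anova(lm(v ~ s + r, df))
  msa <- a["s", "Mean Sq"]; msb <- a["r", "Mean Sq"]; mse <- a["Residuals", "Mean Sq"]
  c(var_subject = (msa - mse) / J, var_scan = (msb - mse) / I, var_resid = mse)
}
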