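# Independent oracles used across tests. These re-derive quantities by
# brute force and must stay independent of the package implementation.

# Per-frequency least-squares sine+cosine fit: the spectral ordinate equals
# half the sum-of-squares reduction, scaled to density by 2*T/n.
ls_density_oracle <- function(t, y, freqs) {
  yc <- y - mean(y)
  tspan <- max(t) - min(t)
  vapply(freqs, function(f) {
    X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
    fit <- stats::lm.fit(X, yc)
    ((sum(yc^2) - sum(fit$residuals^2)) / 2) * 2 * tspan / length(y)
  }, numeric(1))
}

# Brute-force projection-matrix ANOVA for a balanced 2x2x2 design with
# sum-to-zero coding: per-term SS via explicit projections.
anova_F_oracle <- function(tbl, outcome) {
  y <- tbl[[outcome]]
  tbl$genotype <- factor(tbl$genotype, c("WT", "TG"))
  tbl$sex <- factor(tbl$sex, c("M", "F"))
  tbl$age_group <- factor(as.character(tbl$age_group), c("6", "12"))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X <- stats::model.matrix(~ genotype * sex * age_group, tbl)
  terms <- attr(X, "assign")
  proj_ss <- function(cols) {
    Xe <- X[, cols, drop = FALSE]
    P <- Xe %*% solve(crossprod(Xe), t(Xe))
    drop(crossprod(y, P %*% y))
  }
  ss_res <- sum(stats::lm.fit(X, y)$residuals^2)
  df_den <- length(y) - ncol(X)
  vapply(1:7, function(k) {
    ss <- proj_ss(which(terms == k))
    (ss / sum(terms == k)) / (ss_res / df_den)
  }, numeric(1))
}

# build a beat series directly from an RR sequence (ms), first beat at t0
bs_from_rr <- function(rr_ms, t0 = 0, sbp = NULL, valid = NULL) {
  beat_series(t0 + c(0, cumsum(rr_ms)) / 1000, sbp = sbp, valid = valid)
}

cell_labels <- function() {
  expand.grid(genotype = c("WT", "TG"), sex = c("M", "F"),
              age_group = c("6", "12"), stringsAsFactors = FALSE)
}
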