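#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`; monotone in both `p` and
#' the family size `m`.
#'
#' @param p_raw Raw p value(s) in `[0, 1]` (vectorised).
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p value(s).
#' @examples
#' sidak_adjust(0.01, 12)   # 0.113615...
#' @export
sidak_adjust <- function(p_raw, m) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop("domain error: p values must lie in [0, 1]", call. = FALSE)
  if (any(m < 1)) stop("domain error: m must be >= 1", call. = FALSE)
  pmin(1, pmax(0, 1 - (1 - p_raw)^m))
}

# the 2x2x2 cell grid in a fixed order, and the 12 one-factor-different pairs
cell_grid <- function() {
  expand.grid(genotype = c("WT", "TG"), sex = c("M", "F"),
              age_group = c("6", "12"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

one_factor_pairs <- function() {
  g <- cell_grid()
  pairs <- list()
  for (a in 1:7) for (b in (a + 1):8) {
    differ <- sum(g[a, ] != g[b, ])
    if (differ == 1L)
      pairs[[length(pairs) + 1L]] <-
        list(a = a, b = b, factor = names(g)[which(g[a, ] != g[b, ])])
  }
  pairs
}

check_group_table <- function(tbl, outcome) {
  need <- c("genotype", "sex", "age_group", outcome)
  if (!all(need %in% names(tbl)))
    stop("group table must have columns genotype, sex, age_group and the outcome",
         call. = FALSE)
  tbl$genotype <- factor(as.character(tbl$genotype), levels = c("WT", "TG"))
  tbl$sex <- factor(as.character(tbl$sex), levels = c("M", "F"))
  tbl$age_group <- factor(as.character(tbl$age_group), levels = c("6", "12"))
  if (any(is.na(tbl$genotype)) || any(is.na(tbl$sex)) || any(is.na(tbl$age_group)))
    stop("factors must be WT/TG, M/F and 6/12", call. = FALSE)
  cnt <- table(tbl$genotype, tbl$sex, tbl$age_group)
  if (any(cnt == 0)) {
    empty <- which(cnt == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("design error: empty cell %s/%s/%s mo",
                 dimnames(cnt)[[1]][empty[1]], dimnames(cnt)[[2]][empty[2]],
                 dimnames(cnt)[[3]][empty[3]]), call. = FALSE)
  }
  if (sum(cnt) <= 8L)
    stop("design error: no residual degrees of freedom (need n > 8)",
         call. = FALSE)
  tbl
}

#' Three-way factorial ANOVA with Sidak one-factor contrasts
#'
#' Fits the full fixed-effects model `outcome ~ genotype * sex * age_group`
#' with sum-to-zero factor coding and computes type-III sums of squares
#' (marginal tests, appropriate for the unbalanced cell sizes of the
#' study design). The 12 pairwise contrasts between cells differing in
#' exactly one factor are tested on cell means against the pooled residual
#' mean square and Sidak-adjusted over the family of 12.
#'
#' @param tbl Data frame with columns `genotype` (WT/TG), `sex` (M/F),
#'   `age_group` (6/12) and the outcome.
#' @param outcome Name of the outcome column.
#' @param alpha Significance level used for flagging (default 0.05).
#' @return Object of class `"cv_anova"`: `effects` (7 rows: F, dfs, p),
#'   `contrasts` (12 rows: cells, mean difference, raw and Sidak p),
#'   `cells` (means and ns), the underlying `lm` fit, `outcome`, `alpha`.
#' @export
three_way_anova <- function(tbl, outcome, alpha = 0.05) {
  tbl <- check_group_table(tbl, outcome)
  tbl$.y <- tbl[[outcome]]
  fit <- stats::lm(.y ~ genotype * sex * age_group, data = tbl,
                   contrasts = list(genotype = "contr.sum", sex = "contr.sum",
                                    age_group = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  rows <- c("genotype", "sex", "age_group", "genotype:sex",
            "genotype:age_group", "sex:age_group", "genotype:sex:age_group")
  df_den <- a3["Residuals", "Df"]
  effects <- data.frame(
    effect = rows,
    F = a3[rows, "F value"],
    df_num = a3[rows, "Df"],
    df_den = df_den,
    p = a3[rows, "Pr(>F)"],
    row.names = NULL
  )

  mse <- sum(stats::residuals(fit)^2) / df_den
  grid <- cell_grid()
  key <- interaction(tbl$genotype, tbl$sex, tbl$age_group, drop = FALSE)
  gkey <- interaction(factor(grid$genotype, c("WT", "TG")),
                      factor(grid$sex, c("M", "F")),
                      factor(grid$age_group, c("6", "12")))
  means <- tapply(tbl$.y, key, mean)[as.character(gkey)]
  ns <- as.integer(table(key)[as.character(gkey)])
  cells <- cbind(grid, mean = as.numeric(means), n = ns)

  pairs <- one_factor_pairs()
  contrasts <- do.call(rbind, lapply(pairs, function(p) {
    diff <- cells$mean[p$a] - cells$mean[p$b]
    se <- sqrt(mse * (1 / cells$n[p$a] + 1 / cells$n[p$b]))
    tval <- diff / se
    praw <- 2 * stats::pt(-abs(tval), df_den)
    data.frame(
      cell_a = paste(grid$genotype[p$a], grid$sex[p$a], grid$age_group[p$a],
                     sep = "/"),
      cell_b = paste(grid$genotype[p$b], grid$sex[p$b], grid$age_group[p$b],
                     sep = "/"),
      factor = p$factor, diff = diff, se = se, t = tval,
      p_raw = praw, p_sidak = sidak_adjust(praw, length(pairs)))
  }))
  contrasts$significant <- contrasts$p_sidak < alpha

  structure(list(effects = effects, contrasts = contrasts, cells = cells,
                 fit = fit, outcome = outcome, alpha = alpha,
                 df_den = df_den, mse = mse),
            class = "cv_anova")
}

#' One-factor-difference contrasts of a fitted three-way ANOVA
#'
#' Convenience accessor returning the 12 contrasts between cells that
#' differ in exactly one of genotype, sex or age.
#'
#' @param x A `"cv_anova"` from [three_way_anova()], or a group table (with
#'   `outcome`) to fit first.
#' @param outcome Outcome column name when `x` is a data frame.
#' @return The 12-row contrast data.frame.
#' @export
one_factor_contrasts <- function(x, outcome = NULL) {
  if (is.data.frame(x)) x <- three_way_anova(x, outcome)
  stopifnot(inherits(x, "cv_anova"))
  x$contrasts
}

#' @export
print.cv_anova <- function(x, ...) {
  cat(sprintf("Three-way ANOVA (genotype x sex x age) on %s\n", x$outcome))
  eff <- x$effects
  eff$F <- round(eff$F, 3); eff$p <- signif(eff$p, 4)
  print(eff, row.names = FALSE)
  nsig <- sum(x$contrasts$significant)
  cat(sprintf("%d of %d Sidak-adjusted one-factor contrasts significant at alpha = %.2f\n",
              nsig, nrow(x$contrasts), x$alpha))
  invisible(x)
}

#' @export
summary.cv_anova <- function(object, ...) {
  print(object)
  cat("\nOne-factor contrasts (Sidak-adjusted):\n")
  ct <- object$contrasts
  ct$diff <- round(ct$diff, 3); ct$p_raw <- signif(ct$p_raw, 4)
  ct$p_sidak <- signif(ct$p_sidak, 4)
  print(ct[, c("cell_a", "cell_b", "factor", "diff", "p_raw", "p_sidak",
               "significant")], row.names = FALSE)
  invisible(object)
}
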