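test_that("exactly 12 one-factor-difference pairs exist among the 8 cells", {
  g <- sim_group_data(n_per_cell = 2, seed = 1)
  a <- three_way_anova(g, "outcome")
  ct <- a$contrasts
  expect_equal(nrow(ct), 12L)
  # each pair differs in exactly one coordinate
  split_cell <- function(s) strsplit(s, "/")[[1]]
  for (k in seq_len(12L)) {
    expect_equal(sum(split_cell(ct$cell_a[k]) != split_cell(ct$cell_b[k])), 1L)
  }
  # each cell appears in exactly 3 pairs
  counts <- table(c(ct$cell_a, ct$cell_b))
  expect_true(all(counts == 3L))
})

test_that("F statistics match the projection-matrix oracle on balanced data", {
  for (s in 1:3) {
    g <- sim_group_data(genotype_eff = 1, sex_eff = 0.5, gs_int = 0.3,
                        residual_sd = 1, n_per_cell = 4, seed = 100 + s)
    a <- three_way_anova(g, "outcome")
    expect_equal(a$effects$F, anova_F_oracle(g, "outcome"), tolerance = 1e-8)
    expect_equal(a$effects$df_den, rep(nrow(g) - 8L, 7L))
    # balanced: type-III coincides with sequential sums of squares
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    seqF <- anova(lm(outcome ~ genotype * sex * age_group,
                     transform(g, age_group = factor(age_group))))
    options(old)
    expect_equal(a$effects$F, seqF$`F value`[1:7], tolerance = 1e-8)
  }
})

test_that("F values are invariant to shifting and scaling the outcome", {
  g <- sim_group_data(genotype_eff = 1, n_per_cell = 5, seed = 7)
  a <- three_way_anova(g, "outcome")
  g2 <- g; g2$outcome <- g$outcome + 100
  g3 <- g; g3$outcome <- g$outcome * 3.5
  expect_equal(three_way_anova(g2, "outcome")$effects$F, a$effects$F,
               tolerance = 1e-9)
  expect_equal(three_way_anova(g3, "outcome")$effects$F, a$effects$F,
               tolerance = 1e-9)
})

test_that("Sidak adjustment is exact, monotone, and clipped", {
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 12), 0.1136151283, tolerance = 1e-9)
  expect_equal(sidak_adjust(1, 12), 1)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, 12)) >= 0))          # monotone in p
  expect_true(all(sidak_adjust(0.02, 1:20) ==
                    cummax(sidak_adjust(0.02, 1:20))))      # monotone in m
  expect_true(all(sidak_adjust(p, 12) >= p))                # adjusted >= raw
  expect_error(sidak_adjust(1.2, 3), "domain error")
})

test_that("a single shifted cell owns the three smallest raw contrast p values", {
  hits <- 0L
  for (s in 1:50) {
    g <- sim_group_data(n_per_cell = 8, residual_sd = 1, seed = 200 + s)
    sel <- g$genotype == "TG" & g$sex == "F" & g$age_group == "12"
    g$outcome[sel] <- g$outcome[sel] + 2.5
    ct <- one_factor_contrasts(g, "outcome")
    touches <- grepl("TG/F/12", ct$cell_a) | grepl("TG/F/12", ct$cell_b)
    if (all(rank(ct$p_raw)[touches] <= 3)) hits <- hits + 1L
  }
  expect_gte(hits, 45L)                                     # >= 90% of runs
})

test_that("a strong genotype shift is detected while null effects stay null", {
  hits <- matrix(0L, nrow = 100L, ncol = 7L)
  for (s in 1:100) {
    g <- sim_group_data(genotype_eff = 2, residual_sd = 1, n_per_cell = 10,
                        seed = 300 + s)
    hits[s, ] <- as.integer(three_way_anova(g, "outcome")$effects$p <
                              c(0.01, rep(0.05, 6)))
  }
  expect_gte(sum(hits[, 1]), 90L)            # genotype detected at p < 0.01
  # each truly-null effect stays non-significant at its nominal level
  for (j in 2:7) expect_gte(sum(1L - hits[, j]), 90L)
})

test_that("degenerate designs are rejected with an informative error", {
  g <- sim_group_data(n_per_cell = 3, seed = 5)
  miss <- g[!(g$genotype == "TG" & g$sex == "F" & g$age_group == "12"), ]
  expect_error(three_way_anova(miss, "outcome"), "TG/F/12")
  one <- do.call(rbind, lapply(split(g, interaction(g$genotype, g$sex,
                                                    g$age_group)),
                               function(d) d[1, ]))
  expect_error(three_way_anova(one, "outcome"), "degrees of freedom")
})

test_that("contrasts agree with emmeans as an independent cross-check", {
  skip_if_not_installed("emmeans")
  g <- sim_group_data(genotype_eff = 1.5, age_eff = 1, n_per_cell = 6,
                      seed = 11)
  a <- three_way_anova(g, "outcome")
  em <- emmeans::emmeans(a$fit, ~ genotype * sex * age_group)
  prs <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  emlab <- function(cell) {
    parts <- strsplit(cell, "/")[[1]]
    sprintf("%s %s age_group%s", parts[1], parts[2], parts[3])
  }
  for (k in seq_len(nrow(a$contrasts))) {
    ca <- emlab(a$contrasts$cell_a[k])
    cb <- emlab(a$contrasts$cell_b[k])
    hit <- which(prs$contrast == sprintf("%s - %s", ca, cb) |
                   prs$contrast == sprintf("%s - %s", cb, ca))
    expect_length(hit, 1L)
    expect_equal(abs(prs$estimate[hit]), abs(a$contrasts$diff[k]),
                 tolerance = 1e-9)
    expect_equal(prs$p.value[hit], a$contrasts$p_raw[k], tolerance = 1e-9)
  }
})
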