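# Distal-phalanx shape pipeline: standardization, ratios, and the
# classification statistics.

test_that("geometric mean matches closed forms and a log-domain oracle", {
  rec <- as.list(setNames(rep(2, 8), unguis:::LINEAR_VARS))
  expect_equal(geometric_mean(rec), 2)
  rec2 <- as.list(setNames(c(1, 1, 1, 1, 1, 1, 1, 256),
                           unguis:::LINEAR_VARS))
  expect_equal(geometric_mean(rec2), 2)  # 256^(1/8)
  # the dp2 fossil row, augmented with synthetic shaft heights consistent
  # with its printed tapering index
  t3 <- fixtures("table3")["143612-03", ]
  rec3 <- list(BH = t3$BH, BW = t3$BW, TPL = t3$TPL, VFL = t3$VFL,
               SW34 = t3$SW34, SH34 = 1.30, SH14 = 1.30 * t3$SH14_SH34,
               SW14 = 3.10)
  x <- unlist(rec3[unguis:::LINEAR_VARS])
  expect_equal(geometric_mean(rec3), exp(mean(log(x))), tolerance = 1e-12)
  expect_error(geometric_mean(modifyList(rec, list(TPL = -1))), "TPL")
})

test_that("standardization is scale invariant with unit product", {
  set.seed(1)
  d <- gen_phalanx_dataset(phalanx_group_spec("grooming", 20), seed = 11)
  s1 <- standardize_phalanx(d)
  d2 <- d
  d2[unguis:::LINEAR_VARS] <- d2[unguis:::LINEAR_VARS] * 3.7
  s2 <- standardize_phalanx(d2)
  std_cols <- paste0(unguis:::LINEAR_VARS, "_GM")
  expect_equal(s1[std_cols], s2[std_cols], tolerance = 1e-12)
  expect_equal(s2$GM, s1$GM * 3.7, tolerance = 1e-12)
  prods <- apply(s1[std_cols], 1, prod)
  expect_true(all(abs(prods - 1) < 1e-10))
  # all-equal record standardizes to all ones
  eq <- data.frame(specimen_id = "x", as.list(setNames(rep(5, 8),
                   unguis:::LINEAR_VARS)), FSA = 80)
  expect_true(all(abs(unlist(standardize_phalanx(eq)[std_cols]) - 1) <
                    1e-12))
})

test_that("large-sample standardized means approach the grooming targets", {
  d <- gen_phalanx_dataset(phalanx_group_spec("grooming", 20000), seed = 5)
  s <- standardize_phalanx(d)
  expect_equal(mean(s$BH_GM), 1.255, tolerance = 0.02)
  expect_equal(mean(s$TPL_GM), 3.303, tolerance = 0.02)
  expect_equal(mean(s$VFL_GM), 1.230, tolerance = 0.02)
})

test_that("shape ratios recover the printed fossil indices", {
  t3 <- fixtures("table3")
  r <- phalanx_ratios(t3)
  expect_equal(round(r$VFL_TPL[r$specimen_id == "143612-03"], 2), 0.41)
  expect_equal(round(r$VFL_TPL[r$specimen_id == "143640-24"], 2), 0.90)
  # printed SW34/TPL column matches recomputation at 2 dp for all fossils
  expect_equal(round(r$SW34_TPL, 2), t3$SW34_TPL, tolerance = 0.006)
  one <- data.frame(specimen_id = "e", VFL = 4, TPL = 4, SH14 = 2,
                    SH34 = 1, SW34 = 1)
  expect_equal(phalanx_ratios(one)$VFL_TPL, 1)
  bad <- data.frame(specimen_id = "z", VFL = 4, TPL = 0, SH14 = 2,
                    SH34 = 1, SW34 = 1)
  expect_error(phalanx_ratios(bad), "denominator")
})

test_that("single-specimen t is exact: null calibration and z limit", {
  st <- single_specimen_t(5, mean = 5, variance = 2, n = 10)
  expect_equal(st$t, 0)
  expect_equal(st$df, 9)
  # t approaches the z-score as n grows
  big <- single_specimen_t(1.7, 0.5, 4, n = 1e6)
  expect_equal(big$t, (1.7 - 0.5) / 2, tolerance = 1e-5)
  # exact type-I error under the null
  set.seed(202)
  n <- 21
  hits <- replicate(1000, {
    y <- rnorm(n)
    x <- rnorm(1)
    single_specimen_t(x, mean(y), var(y), n)$p < 0.05
  })
  ci <- binom.test(sum(hits), 1000, p = 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  expect_error(single_specimen_t(1, 0, 0, 10), "degenerate")
  expect_error(single_specimen_t(1, 0, 1, 1), "insufficient")
})

test_that("published fossil-vs-baseline t-values reproduce within slack", {
  t3 <- fixtures("table3")
  t6 <- fixtures("table6")
  bl <- table5_baselines()
  value_of <- function(sp, v) switch(v,
    FSA = t3[sp, "FSA"],
    VFL_TPL = t3[sp, "VFL"] / t3[sp, "TPL"],
    SH14_SH34 = t3[sp, "SH14_SH34"],
    SW34_TPL = t3[sp, "SW34"] / t3[sp, "TPL"])
  for (v in c("FSA", "VFL_TPL", "SH14_SH34", "SW34_TPL")) {
    for (g in c("ungular", "grooming")) {
      b <- bl[bl$group == g & bl$variable == v, ]
      code <- if (g == "ungular") "U" else "G"
      for (sp in setdiff(t3$specimen_id, "143640-24")) {
        printed <- t6[t6$variable == v & t6$baseline == code, sp]
        if (abs(printed) < 0.5) next  # printed rounding swamps tiny t
        got <- single_specimen_t(value_of(sp, v), b$mean, b$variance,
                                 b$n)$t
        expect_equal(got, printed, tolerance = 0.08,
                     label = paste(v, g, sp))
        expect_identical(sign(got), sign(printed),
                         label = paste("sign", v, g, sp))
      }
    }
  }
})

test_that("t-values are invariant to uniform scaling of the raw record", {
  bl <- table5_baselines()
  d <- gen_phalanx_dataset(phalanx_group_spec("grooming", 1), seed = 3)
  scaled <- d
  scaled[unguis:::LINEAR_VARS] <- scaled[unguis:::LINEAR_VARS] * 11
  f1 <- cbind(phalanx_ratios(d), FSA = d$FSA)
  f2 <- cbind(phalanx_ratios(scaled), FSA = scaled$FSA)
  c1 <- classify_fossil(f1[1, ], bl)
  c2 <- classify_fossil(f2[1, ], bl)
  expect_equal(c1$tests$t_ungular, c2$tests$t_ungular, tolerance = 1e-12)
  expect_identical(c1$verdict, c2$verdict)
})

test_that("bonferroni threshold matches the published alphas", {
  expect_equal(round(bonferroni_alpha(0.05, 12), 4), 0.0042)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
})

test_that("one-way ANOVA: identity, t^2 equivalence, and power", {
  g <- rep(c("a", "b"), each = 6)
  x <- rep(c(1, 2, 3), 4)
  res <- anova_oneway(x, g)
  expect_lt(res$F, 1e-20)
  set.seed(7)
  x2 <- rnorm(12)
  res2 <- anova_oneway(x2, g)
  tt <- t.test(x2[g == "a"], x2[g == "b"], var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "insufficient")
  # VFL/GM separates the four unguis groups at the published parameters
  set.seed(71)
  hits <- replicate(200, {
    d <- gen_phalanx_dataset(four_group_specs(),
                             seed = sample.int(1e6, 1))
    s <- standardize_phalanx(d)
    anova_oneway(s$VFL_GM, d$unguis_group)$p < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Tamhane T2 adjusts Welch p-values monotonically", {
  set.seed(12)
  x <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  tt <- tamhane_t2(x, g)
  expect_true(all(tt$p_adj >= tt$p - 1e-12))
  expect_true(all(tt$p_adj <= 1))
  # identical groups: adjusted p near 1
  x2 <- rep(seq(0, 1, length.out = 10), 2)
  g2 <- rep(c("a", "b"), each = 10)
  expect_gt(tamhane_t2(x2, g2)$p_adj[1], 0.99)
  # ungular vs grooming VFL/TPL separates at the published values
  set.seed(72)
  hits <- replicate(200, {
    d <- gen_phalanx_dataset(four_group_specs()[1:2],
                             seed = sample.int(1e6, 1))
    r <- phalanx_ratios(d)
    tt <- tamhane_t2(r$VFL_TPL, d$unguis_group)
    tt$p_adj[1] < 0.0042
  })
  expect_gte(mean(hits), 0.95)
})

test_that("MANOVA/Hotelling: null behaviour, power, and degeneracy", {
  # identical groups give T2 = 0
  set.seed(31)
  x <- matrix(rnorm(40), 20, 2)
  xx <- rbind(x, x)
  g <- rep(c("a", "b"), each = 20)
  res <- manova_pairwise(xx, g)
  expect_equal(res$pairwise$T2[1], 0, tolerance = 1e-20)
  # null calibration of the pairwise Hotelling p
  set.seed(32)
  ps <- replicate(400, {
    y <- matrix(rnorm(60), 30, 2)
    manova_pairwise(y, rep(c("a", "b"), each = 15))$pairwise$p[1]
  })
  hits <- sum(ps < 0.05)
  ci <- binom.test(hits, 400, p = 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  # a 3-pooled-SD shift on one variable is essentially always detected
  set.seed(33)
  found <- replicate(100, {
    a <- matrix(rnorm(20 * 3), 20, 3)
    b <- matrix(rnorm(20 * 3), 20, 3)
    b[, 1] <- b[, 1] + 3
    manova_pairwise(rbind(a, b), rep(c("a", "b"), each = 20))$pairwise$p[1] <
      0.001
  })
  expect_gte(mean(found), 0.95)
})

test_that("fossil classification yields the published verdicts", {
  t3 <- fixtures("table3")
  bl <- table5_baselines()
  fos <- function(sp) {
    list(specimen_id = sp, FSA = t3[sp, "FSA"],
         VFL_TPL = t3[sp, "VFL"] / t3[sp, "TPL"],
         SH14_SH34 = t3[sp, "SH14_SH34"],
         SW34_TPL = t3[sp, "SW34"] / t3[sp, "TPL"])
  }
  dp2 <- classify_fossil(fos("143612-03"), bl)
  expect_identical(dp2$verdict, "grooming-like")
  amnh11474 <- classify_fossil(fos("11474"), bl)
  expect_identical(amnh11474$verdict, "mixed")
  # a specimen at the ungular means scores t = 0 against ungular
  t5 <- fixtures("table5")
  synth <- list(specimen_id = "synthetic-ungular-mean",
                FSA = t5["FSA", "ungular_mean"],
                VFL_TPL = t5["VFL_TPL", "ungular_mean"],
                SH14_SH34 = t5["SH14_SH34", "ungular_mean"],
                SW34_TPL = t5["SW34_TPL", "ungular_mean"])
  res <- classify_fossil(synth, bl)
  expect_identical(res$verdict, "ungular-like")
  expect_true(all(abs(res$tests$t_ungular) < 1e-12))
  # nearest agrees with argmin |t|
  with(dp2$tests, expect_identical(
    nearest,
    ifelse(abs(t_ungular) <= abs(t_grooming), "ungular", "grooming")))
  expect_error(classify_fossil(fos("11474"), bl[bl$variable != "FSA", ]),
               "baseline missing")
})
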