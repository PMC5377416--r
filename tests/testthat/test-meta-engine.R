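test_that("Hedges' g matches the hand-computed formula on the largest cohort", {
  studies <- table1_studies()
  tcga <- studies[studies$study_id == "TCGA_2016", ]
  e <- hedges_g(tcga)
  expect_equal(e$g, -0.583, tolerance = 0.001)
  expect_equal(e$se, 0.1525, tolerance = 0.001)

  # equal means: g = 0 and the variance reduces to N/(n1 n2)
  e0 <- smd_effect(20, 3, 1, 30, 3, 2, correction = "hedges")
  expect_equal(e0$g, 0)
  expect_equal(e0$variance, 50 / 600)

  # doubling both sds halves |g|
  e1 <- smd_effect(15, 4, 1, 15, 2, 1.5)
  e2 <- smd_effect(15, 4, 2, 15, 2, 3)
  expect_equal(e2$g, e1$g / 2)

  expect_error(smd_effect(10, 1, 0, 10, 2, 0), "pooled sd")
})

test_that("fixed-effect pooling is an inverse-variance mean with Q and I2", {
  one <- data.frame(study_id = "a", g = 0.4, variance = 0.05)
  m <- pool_fixed(one)
  expect_equal(m$pooled, 0.4)
  expect_equal(m$Q, 0)
  expect_equal(m$tau2, 0)

  two <- data.frame(study_id = c("a", "b"), g = c(0.2, 0.6),
                    variance = c(0.1, 0.1))
  expect_equal(pool_fixed(two)$pooled, 0.4)

  set.seed(71)
  for (i in 1:15) {
    ef <- random_effects_panel(sample(3:20, 1), seed = i)
    m <- pool_fixed(ef)
    expect_gte(m$pooled, min(ef$g))
    expect_lte(m$pooled, max(ef$g))
    expect_gte(m$Q, 0)
    expect_true(m$I2 >= 0 && m$I2 <= 100)
  }
  expect_error(pool_fixed(data.frame(g = numeric(), variance = numeric())),
               "at least 1")
})

test_that("DerSimonian-Laird pooling matches an independent implementation", {
  ef <- random_effects_panel(12, seed = 42)
  m <- pool_random(ef)
  r <- metafor::rma(yi = ef$g, vi = ef$variance, method = "DL")
  expect_equal(m$pooled, as.numeric(r$b), tolerance = 1e-10)
  expect_equal(m$tau2, r$tau2, tolerance = 1e-10)
  expect_equal(m$Q, r$QE, tolerance = 1e-10)
  expect_equal(m$I2, r$I2, tolerance = 1e-8)
  expect_equal(m$ci_low, r$ci.lb, tolerance = 1e-4)  # 1.96 vs qnorm(0.975)
})

test_that("random-effects pooling has the expected structural properties", {
  # zero heterogeneity: identical effects collapse to the fixed model
  ef <- data.frame(study_id = letters[1:4], g = rep(-0.3, 4),
                   variance = c(0.05, 0.1, 0.2, 0.08))
  mr <- pool_random(ef); mf <- pool_fixed(ef)
  expect_equal(mr$pooled, mf$pooled)
  expect_equal(mr$tau2, 0)
  expect_equal(mr$se, mf$se)

  # equal variances with tau2 estimated: pooled equals the arithmetic mean
  ef2 <- data.frame(study_id = letters[1:5], g = c(-1, -0.5, 0, 0.2, 0.4),
                    variance = rep(0.04, 5))
  expect_equal(pool_random(ef2)$pooled, mean(ef2$g))

  set.seed(81)
  for (i in 1:15) {
    ef <- random_effects_panel(sample(3:20, 1), seed = 100 + i)
    expect_gte(pool_random(ef)$se, pool_fixed(ef)$se - 1e-12)
    expect_gte(pool_random(ef)$tau2, 0)
  }
})

test_that("model selection follows the p<0.05-or-I2>50 heterogeneity rule", {
  studies <- table1_studies()
  m <- select_model(effect_sizes(studies))
  expect_identical(m$model, "random")
  expect_gt(m$I2, 50)

  # homogeneous panel: large studies, common true effect
  set.seed(91)
  hom <- data.frame(study_id = sprintf("h%d", 1:8),
                    g = rnorm(8, -0.4, 0.03), variance = rep(0.002, 8))
  expect_identical(select_model(hom)$model, "fixed")

  # OR rule: heterogeneity p below 0.05 even though I2 stays below 50
  found <- FALSE
  for (s in 1:300) {
    ef <- random_effects_panel(45, seed = 5000 + s, tau2 = 0.004)
    h <- pool_fixed(ef)
    if (!is.na(h$p_Q) && h$p_Q < 0.05 && h$p_Q > 0.02 && h$I2 < 50) {
      expect_identical(select_model(ef)$model, "random")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("Egger regression matches the classic form and holds its size", {
  ef <- random_effects_panel(12, seed = 42)
  e <- egger_test(ef)
  r <- metafor::rma(yi = ef$g, vi = ef$variance, method = "DL")
  rt <- metafor::regtest(r, model = "lm", predictor = "sei")
  expect_equal(e$p, rt$pval, tolerance = 1e-10)

  expect_error(egger_test(ef[1:2, ]), "at least 3")
  coll <- data.frame(study_id = letters[1:5], g = rnorm(5),
                     variance = rep(0.04, 5))
  expect_error(egger_test(coll), "constant")

  # null symmetric funnel: rejection rate close to the nominal 5%
  set.seed(7)
  rej <- 0; reps <- 300
  for (i in seq_len(reps)) {
    vv <- runif(15, 0.01, 0.25)
    ee <- data.frame(g = rnorm(15, 0, sqrt(vv)), variance = vv)
    if (egger_test(ee)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.01)
  expect_lt(rej / reps, 0.10)
})

test_that("Begg rank correlation detects a censored funnel and not a null one", {
  ef <- random_effects_panel(12, seed = 42)
  b <- begg_test(ef)
  rk <- metafor::ranktest(ef$g, vi = ef$variance)
  expect_equal(b$statistic, as.numeric(rk$tau), tolerance = 1e-10)
  expect_true(b$p >= 0 && b$p <= 1)

  expect_error(begg_test(ef[1:2, ]), "at least 3")

  # small-study selection: keep the 25 most negative-leaning of 50 studies
  set.seed(8)
  rej <- 0; reps <- 60
  for (i in seq_len(reps)) {
    vv <- runif(50, 0.005, 0.4)
    gg <- rnorm(50, 0, sqrt(vv))
    keep <- order(gg + 1.5 * sqrt(vv))[1:25]
    if (begg_test(data.frame(g = gg[keep], variance = vv[keep]))$p < 0.05)
      rej <- rej + 1
  }
  expect_gt(rej / reps, 0.5)
})

test_that("funnel coordinates and leave-one-out tables are well formed", {
  ef <- effect_sizes(table1_studies())
  fp <- funnel_points(ef)
  expect_equal(nrow(fp), 11)
  expect_true(!is.unsorted(fp$se))
  expect_equal(attr(fp, "pooled"), pool_fixed(ef)$pooled)
  expect_equal(nrow(funnel_points(ef[1, ])), 1)

  loo <- leave_one_out(ef)
  expect_equal(nrow(loo), 11)
  expect_setequal(loo$omitted, ef$study_id)
  # omitting a study re-pools the remaining ten
  m10 <- pool_random(ef[-1, ])
  expect_equal(loo$pooled[1], m10$pooled)
})
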