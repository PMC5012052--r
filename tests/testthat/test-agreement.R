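test_that("Lin's concordance coefficient matches its formula", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  # hand-evaluable: x=(1,2,3), y=(1,2,4): population moments give 6/7
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 4)), 6 / 7, tolerance = 1e-12)
  expect_error(lin_ccc(c(1, 1), c(2, 2)), class = "osic_undefined_statistic")
  expect_error(lin_ccc(1, 1:2), class = "osic_validation_error")
  # |rho_c| <= |r|, equality only without location/scale shift
  set.seed(51)
  for (i in 1:50) {
    x <- rnorm(20); y <- 0.8 * x + rnorm(20, sd = 0.3) + 0.5
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
  # sample-moment variant differs only via the bias term
  x <- rnorm(10); y <- x + 1
  expect_equal(lin_ccc(x, y, "sample") *
                 (var(x) + var(y) + 1) / (2 * cov(x, y)), 1, tolerance = 1e-12)
})

test_that("tolerance limits: variants, closed forms, and width shrinks with n", {
  d <- c(-1, 0, 1)
  expect_equal(unname(tolerance_limits(d, variant = "plain")),
               c(-1.96, 1.96), tolerance = 1e-4)
  expect_equal(unname(tolerance_limits(d, variant = "future_obs")),
               c(-1, 1) * qt(0.975, 2) * sd(d) * sqrt(1 + 1 / 3), tolerance = 1e-12)
  k_expected <- sqrt(2 * (1 + 1 / 3) * qnorm(0.975)^2 / qchisq(0.05, 2))
  expect_equal(unname(tolerance_limits(d, variant = "kfactor")),
               c(-1, 1) * k_expected * sd(d), tolerance = 1e-12)
  # width non-increasing in n at fixed SD
  widths <- vapply(c(5, 10, 50, 200, 1000), function(n) {
    d <- scale(seq_len(n))[, 1]  # sd exactly 1
    diff(tolerance_limits(d, variant = "kfactor"))
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("bland_altman assembles bias, CI, p and tolerance limits", {
  set.seed(52)
  ref <- rnorm(30, 20, 5)
  test <- ref + rnorm(30, 0.2, 0.5)
  res <- bland_altman(ref, test, variant = "plain")
  d <- test - ref
  expect_equal(res$bias, mean(d))
  expect_equal(res$p_value, t.test(d)$p.value)
  expect_equal(res$tl_low, mean(d) - qnorm(0.975) * sd(d))
  expect_equal(res$r_squared, cor(ref, test)^2)
  expect_true(res$tl_low <= res$bias && res$bias <= res$tl_high)
  # identical pairs: collapse and undefined p
  expect_warning(res0 <- bland_altman(ref, ref), class = "osic_degenerate_differences")
  expect_equal(res0$bias, 0)
  expect_equal(c(res0$tl_low, res0$tl_high), c(0, 0))
  expect_true(is.na(res0$p_value))
})

test_that("absolute error summaries aggregate consistently", {
  expect_equal(absolute_error_summary(c(1, 2, 3), c(1, 2, 3))$mean_abs, 0)
  set.seed(53)
  ref <- rnorm(40); test <- ref + rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  per <- absolute_error_summary(ref, test, g)
  pooled <- absolute_error_summary(ref, test)
  expect_equal(pooled$mean_abs, weighted.mean(per$mean_abs, per$n))
})

test_that("validation_report reproduces structure and counts", {
  rep <- validation_report(load_validation_table())
  cc <- rep$concordance
  expect_identical(nrow(cc), 6L)
  expect_equal(cc$n[cc$family == "ProjA" & cc$value1 == "GS"], 96)
  expect_equal(cc$n[cc$family == "SafA" & cc$value1 == "GS"], 192)
  expect_equal(cc$n[cc$family == "ProjA" & cc$value1 == "Rep1"], 48)
  expect_equal(cc$n[cc$family == "SafA" & cc$value1 == "Obs1"], 96)
  ae <- rep$absolute_errors
  expect_identical(nrow(ae), 12L)  # 2 families x 2 observers x (rep1, rep2, both)
  expect_true(all(ae$mean_abs >= 0 & ae$sd_abs >= 0))
  # pooled "both" rows aggregate the repeat rows
  for (fam in c("ProjA", "SafA")) for (o in 1:2) {
    sub <- ae[ae$family == fam & ae$observer == o, ]
    expect_equal(sub$mean_abs[sub$repeat_ == "both"],
                 weighted.mean(sub$mean_abs[sub$repeat_ != "both"],
                               sub$n[sub$repeat_ != "both"]))
  }
})

test_that("landmark quadruple analysis handles exact and arithmetic cases", {
  quads <- expand.grid(item = c("i1", "i2"), observer = 1:2, rep = 1:2)
  quads$value <- ifelse(quads$item == "i1", 10, 20)
  res <- suppressWarnings(landmark_proja_analysis(quads))
  expect_true(all(res$concordance$tl_low == res$concordance$bias &
                    res$concordance$tl_high == res$concordance$bias))
  expect_true(all(res$absolute_errors$mean_abs == 0))

  # values (10, 10, 12, 12): GS = 11, single absolute errors all 1
  q2 <- data.frame(item = "i", observer = c(1, 1, 2, 2), rep = c(1, 2, 1, 2),
                   value = c(10, 10, 12, 12))
  q2 <- rbind(q2, transform(q2, item = "j", value = value + 5))
  res2 <- suppressWarnings(landmark_proja_analysis(q2))
  expect_equal(res2$gold_standard$gs, c(11, 16))
  single <- res2$absolute_errors[res2$absolute_errors$comparison == "single", ]
  expect_equal(single$mean_abs, 1)
  # incomplete items are dropped with a warning
  q3 <- rbind(q2, data.frame(item = "k", observer = 1, rep = 1, value = 5))
  expect_warning(
    res3 <- suppressWarnings(landmark_proja_analysis(q3),
                             classes = "osic_degenerate_differences"),
    class = "osic_incomplete_item")
  expect_identical(nrow(res3$gold_standard), 2L)
})
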