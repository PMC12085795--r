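# Agreement metrics between predicted and reference bone ages.

rand_pairs <- function(n, seed, bias = 0, sd = 1) {
  withr::with_seed(seed, {
    ref <- runif(n, 1, 18)
    paired_ages(sprintf("s%03d", seq_len(n)), ref,
                ref + bias + rnorm(n, 0, sd))
  })
}

test_that("error metrics satisfy their closed forms and a loop oracle", {
  p0 <- paired_ages(c("a", "b"), c(5, 9), c(5, 9))
  expect_equal(ba_mse(p0), 0)
  expect_equal(ba_mae(p0), 0)
  p1 <- paired_ages(c("a", "b"), c(5, 9), c(6, 8)) # diffs +1, -1
  expect_equal(ba_mse(p1), 1)
  expect_equal(ba_mae(p1), 1)
  expect_equal(ba_rmse(p1), 1)
  p <- rand_pairs(50, 17)
  expect_equal(ba_mse(p), naive_mse(p$reference, p$predicted),
               tolerance = 1e-12)
  expect_equal(ba_mae(p), naive_mae(p$reference, p$predicted),
               tolerance = 1e-12)
  expect_error(ba_mse(p[0, ]), class = "skelage_domain_error")
})

test_that("Pearson r hits its boundary cases and the textbook formula", {
  x <- c(2, 5, 9, 13, 17)
  expect_equal(ba_pearson(paired_ages(letters[1:5], x, x))$r, 1)
  expect_equal(ba_pearson(paired_ages(letters[1:5], x, -x + 20))$r, -1)
  p <- rand_pairs(30, 23, sd = 2)
  got <- ba_pearson(p)
  expect_equal(got$r, naive_pearson(p$reference, p$predicted),
               tolerance = 1e-12)
  expect_lt(got$p_value, 0.01)
  flat <- paired_ages(letters[1:4], c(1, 2, 3, 4), rep(5, 4))
  expect_error(ba_pearson(flat), class = "skelage_domain_error")
})

test_that("ICC(2,1) matches the ANOVA decomposition and penalizes bias", {
  x <- c(3, 7, 11, 15)
  expect_equal(ba_icc(paired_ages(letters[1:4], x, x)), 1)
  p <- rand_pairs(20, 31, sd = 1.5)
  expect_equal(ba_icc(p), naive_icc_aov(p$reference, p$predicted),
               tolerance = 1e-9)
  # a large constant shift destroys absolute agreement but not correlation
  shifted <- rand_pairs(20, 31, bias = 8, sd = 1.5)
  expect_lt(ba_icc(shifted), ba_pearson(shifted)$r - 0.3)
  # consistency form equals Pearson r under equal means and variances
  y <- withr::with_seed(2, rnorm(15))
  pc <- paired_ages(sprintf("c%02d", 1:15), y, rev(y))
  expect_equal(ba_icc(pc, form = "icc3_1"), naive_pearson(y, rev(y)),
               tolerance = 1e-9)
  expect_error(ba_icc(p[1:2, ]), class = "skelage_domain_error")
})

test_that("limits of agreement bracket the mean difference", {
  p0 <- paired_ages(c("a", "b"), c(4, 6), c(4, 6))
  expect_equal(unlist(ba_loa(p0)), c(mean_diff = 0, loa_low = 0, loa_high = 0))
  p1 <- paired_ages(c("a", "b"), c(5, 5), c(4, 6)) # d = {-1, +1}
  loa <- ba_loa(p1)
  expect_equal(loa$mean_diff, 0)
  expect_equal(loa$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  p <- rand_pairs(30, 41, bias = 0.4)
  got <- ba_loa(p)
  ref <- naive_loa(p$reference, p$predicted)
  expect_equal(c(got$mean_diff, got$loa_low, got$loa_high), ref,
               tolerance = 1e-12)
  expect_true(got$loa_low <= got$mean_diff && got$mean_diff <= got$loa_high)
})

test_that("error range is the elementwise min/max of differences", {
  p <- paired_ages(letters[1:3], c(5, 5, 5), c(4.5, 5.2, 6.1))
  expect_equal(ba_error_range(p), c(min = -0.5, max = 1.1))
  pr <- rand_pairs(40, 43)
  d <- sort(pr$predicted - pr$reference)
  expect_equal(unname(ba_error_range(pr)), c(d[1], d[40]))
})

test_that("Jensen inequality holds between MAE and MSE on random data", {
  for (s in 1:10) {
    p <- rand_pairs(25, 100 + s, bias = runif(1, -1, 1))
    expect_lte(ba_mae(p)^2, ba_mse(p) + 1e-12)
  }
})

test_that("normal differences fall inside the 95% LoA about 95% of the time", {
  d <- withr::with_seed(71, rnorm(10000, 0.2, 0.8))
  p <- paired_ages(sprintf("n%05d", 1:10000), rep(10, 10000), 10 + d)
  loa <- ba_loa(p)
  cov <- mean(d >= loa$loa_low & d <= loa$loa_high)
  expect_gte(cov, 0.94)
  expect_lte(cov, 0.96)
})

test_that("evaluate_model builds per-sex reports and degrades gracefully", {
  # crafted features decoded exactly by the linear probe model
  k <- 3
  ids <- sprintf("s%02d", 1:12)
  sex <- rep(c("M", "F"), each = 6)
  age <- c(2, 5, 8, 11, 14, 17, 3, 6, 9, 12, 15, 18)
  ft <- data.frame(subject_id = rep(ids, each = k),
                   sex = rep(sex, each = k),
                   roi_index = rep(1:k, 12),
                   reference_age = rep(age, each = k))
  ft$f000 <- ft$reference_age + rep(c(-0.2, 0, 0.2), 12)
  ft$f001 <- 0; ft$f002 <- 0
  split <- data.frame(subject_id = ids,
                      partition = factor(rep("validation", 12),
                                         levels = c("train", "test", "validation")))
  models <- list(M = linear_probe_model(3, "M"), F = linear_probe_model(3, "F"))
  rep1 <- evaluate_model(models, ft, split)
  expect_equal(rep1$M$n, 6)
  expect_equal(rep1$M$mae, 0, tolerance = 1e-12) # ROI errors average out
  expect_equal(rep1$F$icc, 1, tolerance = 1e-12)
  # reports are byte-identical across repeated writes
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_eval_report(rep1, d1, figures = FALSE)
  write_eval_report(rep1, d2, figures = FALSE)
  for (f in c("report.json", "report.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # single-subject partition: r/ICC unavailable, error metrics still there
  one <- ft[ft$subject_id %in% c("s01", "s07"), ]
  split1 <- split[split$subject_id %in% c("s01", "s07"), ]
  rep2 <- evaluate_model(models, one, split1)
  expect_true(is.na(rep2$M$pearson_r))
  expect_true(is.na(rep2$M$icc))
  expect_match(paste(rep2$M$notes, collapse = " "), "pairs")
  expect_equal(rep2$M$mae, 0, tolerance = 1e-12)
  # a missing sex model is a hard error
  expect_error(evaluate_model(models["M"], ft, split),
               class = "skelage_domain_error")
})
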