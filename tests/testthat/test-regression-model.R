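# Subject-level splitting and the per-sex perceptron regressor.

# feature table with age encoded linearly in one feature (plus distractor
# noise columns), n subjects per sex, k rows per subject
encoded_features <- function(n_per_sex = 60, k = 3, seed = 5,
                             noise_sd = 0) {
  withr::with_seed(seed, {
    n <- 2 * n_per_sex
    ids <- sprintf("P%03d", seq_len(n))
    sex <- rep(c("M", "F"), each = n_per_sex)
    age <- runif(n, 1, 18)
    rows <- data.frame(
      subject_id = rep(ids, each = k),
      sex = rep(sex, each = k),
      roi_index = rep(seq_len(k), n),
      reference_age = rep(age, each = k))
    rows$f000 <- rows$reference_age + rnorm(nrow(rows), 0, noise_sd)
    rows$f001 <- rnorm(nrow(rows))
    rows$f002 <- rnorm(nrow(rows))
    structure(rows, class = c("feature_table", "data.frame"))
  })
}

manifest_of <- function(features) {
  u <- !duplicated(features$subject_id)
  data.frame(subject_id = features$subject_id[u], sex = features$sex[u],
             reference_age = features$reference_age[u],
             image_path = "", stringsAsFactors = FALSE)
}

test_that("split is subject-level, seeded, and hits 70/15/15 per sex", {
  ft <- encoded_features(n_per_sex = 100)
  man <- manifest_of(ft)
  sp <- split_cohort(man, seed = 3)
  expect_identical(sp, split_cohort(man, seed = 3))
  for (sx in c("M", "F")) {
    tab <- table(sp$partition[man$sex[match(sp$subject_id, man$subject_id)] == sx])
    expect_lte(abs(tab[["train"]] - 70), 1)
    expect_lte(abs(tab[["test"]] - 15), 1)
    expect_lte(abs(tab[["validation"]] - 15), 1)
  }
  expect_false(anyDuplicated(sp$subject_id) > 0)
})

test_that("largest-remainder rounding gives 14/3/3 for n = 20", {
  man <- data.frame(subject_id = sprintf("Q%02d", 1:20), sex = "F",
                    reference_age = 10, image_path = "")
  sp <- split_cohort(man, seed = 1)
  expect_equal(as.vector(table(sp$partition)), c(14L, 3L, 3L))
  expect_error(split_cohort(man[1:2, ]), class = "skelage_config_error")
})

test_that("perceptron recovers a noiseless linear age encoding", {
  ft <- encoded_features(n_per_sex = 60, noise_sd = 0)
  sp <- split_cohort(manifest_of(ft), seed = 2)
  m <- suppressWarnings(
    train_sex_model(ft, sp, "M",
                    mlp_spec(hidden_units = 8L, max_epochs = 2000L,
                             learning_rate = 2e-2, early_stop_patience = 100L,
                             seed = 4)))
  part <- sp$partition[match(ft$subject_id, sp$subject_id)]
  tr <- ft$sex == "M" & part == "train"
  preds <- apply(as.matrix(ft[tr, c("f000", "f001", "f002")]), 1,
                 function(v) predict_bone_age(m, v))
  expect_lte(mean(abs(preds - ft$reference_age[tr])), 0.25)
  # training loss decreased
  expect_lte(utils::tail(m$train_loss, 1), m$train_loss[1])
})

test_that("constant labels are regressed to the constant", {
  ft <- encoded_features(n_per_sex = 40)
  ft$reference_age <- 10
  ft$f000 <- withr::with_seed(1, rnorm(nrow(ft)))
  sp <- split_cohort(manifest_of(ft), seed = 9)
  m <- suppressWarnings(
    train_sex_model(ft, sp, "F", mlp_spec(hidden_units = 4L, seed = 8)))
  X <- as.matrix(ft[ft$sex == "F", c("f000", "f001", "f002")])[1:20, ]
  preds <- apply(X, 1, function(v) predict_bone_age(m, v))
  expect_true(all(abs(preds - 10) <= 0.1))
})

test_that("training is bitwise reproducible and leakage-free", {
  ft <- encoded_features(n_per_sex = 30, noise_sd = 0.5)
  sp <- split_cohort(manifest_of(ft), seed = 6)
  spec <- mlp_spec(hidden_units = 4L, max_epochs = 40L, seed = 12)
  m1 <- suppressWarnings(train_sex_model(ft, sp, "M", spec))
  m2 <- suppressWarnings(train_sex_model(ft, sp, "M", spec))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  # corrupting the validation partition must not change the weights
  part <- sp$partition[match(ft$subject_id, sp$subject_id)]
  ft_corrupt <- ft
  val <- part == "validation"
  ft_corrupt$f000[val] <- 999
  ft_corrupt$reference_age[val] <- 1
  m3 <- suppressWarnings(train_sex_model(ft_corrupt, sp, "M", spec))
  expect_identical(m1$W1, m3$W1)
  expect_identical(m1$W2, m3$W2)
})

test_that("prediction aggregates ROI-level estimates and clips to [1, 18]", {
  pm <- linear_probe_model(p = 3, aggregator = "mean")
  X <- cbind(rep(7.3, 13), 0, 0)
  expect_equal(predict_bone_age(pm, X), 7.3)
  pmed <- linear_probe_model(p = 3, aggregator = "median")
  Xr <- cbind(c(rep(5, 12), 18), 0, 0)
  expect_equal(predict_bone_age(pmed, Xr), 5)
  # mean equals an independently computed arithmetic mean
  vals <- withr::with_seed(3, runif(13, 2, 17))
  expect_equal(predict_bone_age(pm, cbind(vals, 0, 0)), sum(vals) / 13)
  # clipping
  expect_equal(predict_bone_age(pm, cbind(rep(40, 5), 0, 0)), 18)
  expect_error(predict_bone_age(pm, matrix(1, 2, 5)),
               class = "skelage_domain_error")
  expect_error(predict_bone_age(pm, X, sex = "F"),
               class = "skelage_domain_error")
})

test_that("models survive a save/load round trip", {
  ft <- encoded_features(n_per_sex = 30, noise_sd = 0.3)
  sp <- split_cohort(manifest_of(ft), seed = 6)
  m <- suppressWarnings(
    train_sex_model(ft, sp, "F", mlp_spec(hidden_units = 4L,
                                          max_epochs = 30L, seed = 2)))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  X <- withr::with_seed(11, matrix(rnorm(100 * 3), 100, 3))
  for (i in 1:20)
    expect_equal(predict_bone_age(back, X[i, , drop = FALSE]),
                 predict_bone_age(m, X[i, , drop = FALSE]),
                 tolerance = 1e-9)
  # wrong magic is refused
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(magic = "other"), bad, auto_unbox = TRUE)
  expect_error(load_model(bad), class = "skelage_format_error")
  # loaded female model refuses male subjects
  expect_error(predict_bone_age(back, X[1, , drop = FALSE], sex = "M"),
               class = "skelage_domain_error")
})
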