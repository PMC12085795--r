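# Patch histograms, local Shannon entropy, and entropy-maximizing ROI
# placement (greedy reference and genetic algorithm).

test_that("patch histogram counts gray levels exactly", {
  img <- matrix(0L, 50, 50)
  h <- patch_histogram(img, c(1, 1), 40)
  expect_equal(h$counts[1], 1600L)
  expect_equal(sum(h$counts), h$total)

  img2 <- matrix(c(0L, 0L, 255L, 255L), 2, 2)
  h2 <- patch_histogram(img2, c(1, 1), 2)
  expect_equal(h2$counts[1], 2L)
  expect_equal(h2$counts[256], 2L)
  expect_equal(sum(h2$counts), 4L)

  img3 <- test_image(5)
  h3 <- patch_histogram(img3, c(7, 12), 40)
  expect_equal(h3$counts, naive_patch_hist(img3, c(7, 12), 40))

  expect_error(patch_histogram(img3, c(30, 30), 40),
               class = "skelage_domain_error")
})

test_that("patch entropy stays within [0, 8] bits and matches the oracle", {
  img <- test_image(8)
  for (tl in list(c(1, 1), c(13, 40), c(25, 25))) {
    h <- patch_histogram(img, tl, 8)
    expect_equal(shannon_entropy(h), naive_entropy(h$counts), tolerance = 1e-12)
    expect_gte(shannon_entropy(h), 0)
    expect_lte(shannon_entropy(h), 8)
  }
  # base option: natural-log entropy is bits * ln 2
  h <- patch_histogram(img, c(3, 3), 8)
  expect_equal(shannon_entropy(h, base = exp(1)),
               shannon_entropy(h) * log(2), tolerance = 1e-12)
  expect_error(shannon_entropy(integer(256)), class = "skelage_domain_error")
})

test_that("entropy map covers the stride grid and matches recomputation", {
  flat <- matrix(77L, 40, 40)
  expect_true(all(entropy_map(flat, 8) == 0))

  img <- test_image(3)
  em <- entropy_map(img, 8)
  expect_equal(dim(em), c(57, 57))
  for (cell in list(c(1, 1), c(10, 31), c(57, 57), c(23, 5))) {
    tl <- cell # stride 1: map cell == patch top-left
    expect_equal(em[cell[1], cell[2]],
                 shannon_entropy(patch_histogram(img, tl, 8)),
                 tolerance = 1e-12)
  }
  # strides, including stride > patch (disjoint windows)
  for (st in c(3L, 10L)) {
    ems <- entropy_map(img, 8, stride = st)
    expect_equal(dim(ems), c((64 - 8) %/% st + 1, (64 - 8) %/% st + 1))
    expect_equal(ems[2, 3],
                 shannon_entropy(patch_histogram(img, c(st + 1, 2 * st + 1), 8)),
                 tolerance = 1e-12)
  }
  expect_error(entropy_map(img, 100), class = "skelage_domain_error")
})

test_that("greedy selection finds an isolated textured block", {
  img <- matrix(40L, 64, 64)
  set.seed(1)
  img[20:27, 30:37] <- sample(0:255, 64, replace = TRUE)
  rs <- brute_force_rois(img, 8, k = 1)
  expect_equal(rs$rois[1, ], c(row = 20L, col = 30L))
  expect_error(brute_force_rois(img, 8, k = 500, min_separation = 40),
               class = "skelage_domain_error")
})

test_that("greedy selection agrees with an independent enumerator", {
  for (s in 1:3) {
    img <- test_image(s, hw = 32L)
    got <- brute_force_rois(img, 8, k = 3, min_separation = 4)
    ref <- naive_greedy_rois(img, 8, 3, 4)
    expect_identical(unname(got$rois), matrix(as.integer(ref$rois), ncol = 2))
    expect_equal(got$entropies, ref$entropies, tolerance = 1e-12)
  }
})

test_that("GA returns feasible, seeded-deterministic, near-greedy ROI sets", {
  img <- test_image(12)
  bf <- brute_force_rois(img, 8, k = 3)
  ga <- ga_select_rois(img, 8, k = 3, params = ga_params(seed = 2))
  ga2 <- ga_select_rois(img, 8, k = 3, params = ga_params(seed = 2))
  expect_identical(ga$rois, ga2$rois)
  expect_gte(sum(ga$entropies), 0.95 * sum(bf$entropies))
  expect_lte(sum(ga$entropies), sum(bf$entropies) + 1e-9)
  # feasibility under random instances: in-bounds + pairwise separation
  for (s in 14:17) {
    im <- test_image(s)
    k <- withr::with_seed(s, sample(2:6, 1))
    sep <- withr::with_seed(s + 50, sample(3:8, 1))
    rs <- ga_select_rois(im, 8, k = k, min_separation = sep,
                         params = ga_params(seed = s))
    expect_true(all(rs$rois >= 1 & rs$rois <= 64 - 8 + 1))
    if (k > 1)
      expect_true(all(stats::dist(rs$rois)^2 >= sep^2))
    expect_true(all(diff(rs$entropies) <= 0))
  }
})

test_that("GA handles a flat image (degenerate fitness) gracefully", {
  flat <- matrix(10L, 48, 48)
  rs <- ga_select_rois(flat, 8, k = 4, min_separation = 6,
                       params = ga_params(seed = 1))
  expect_equal(sum(rs$entropies), 0)
  expect_true(all(stats::dist(rs$rois)^2 >= 36))
})

test_that("ROI sets round-trip through the cohort CSV", {
  img <- test_image(9)
  rs <- list(A1 = brute_force_rois(img, 8, k = 3),
             B2 = ga_select_rois(img, 8, k = 3, params = ga_params(seed = 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_roisets(rs, path)
  back <- read_roisets(path)
  expect_equal(names(back), c("A1", "B2"))
  for (nm in names(rs)) {
    expect_identical(back[[nm]]$rois, rs[[nm]]$rois)
    expect_equal(back[[nm]]$entropies, rs[[nm]]$entropies, tolerance = 1e-9)
    expect_equal(back[[nm]]$patch_size, rs[[nm]]$patch_size)
  }
})
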