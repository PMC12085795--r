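# Independent, naively coded reference implementations used as oracles.
# These deliberately avoid the package's code paths (no entropy_map, no
# tabulate tricks, no vectorized convolution) so that agreement between
# the two routes is meaningful.

# per-pixel double-loop histogram
naive_patch_hist <- function(image, top_left, s) {
  counts <- integer(256)
  for (i in seq(top_left[1], top_left[1] + s - 1))
    for (j in seq(top_left[2], top_left[2] + s - 1))
      counts[image[i, j] + 1L] <- counts[image[i, j] + 1L] + 1L
  counts
}

naive_entropy <- function(counts, base = 2) {
  t <- sum(counts)
  h <- 0
  for (c in counts) if (c > 0) h <- h - (c / t) * log(c / t, base = base)
  h
}

# second, naively coded greedy enumerator (full scan each round)
naive_greedy_rois <- function(image, s, k, min_sep) {
  nr <- nrow(image) - s + 1L
  nc <- ncol(image) - s + 1L
  ent <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr))
    for (c in seq_len(nc))
      ent[r, c] <- naive_entropy(naive_patch_hist(image, c(r, c), s))
  sel <- matrix(numeric(0), 0, 2)
  for (round in seq_len(k)) {
    best <- NULL; best_h <- -Inf
    for (r in seq_len(nr))
      for (c in seq_len(nc)) {
        ok <- TRUE
        if (nrow(sel) > 0)
          for (q in seq_len(nrow(sel)))
            if ((sel[q, 1] - r)^2 + (sel[q, 2] - c)^2 < min_sep^2) {
              ok <- FALSE; break
            }
        if (ok && ent[r, c] > best_h) { best_h <- ent[r, c]; best <- c(r, c) }
      }
    if (is.null(best)) stop("infeasible")
    sel <- rbind(sel, best)
  }
  # order rows like the package does: entropy desc, then (row, col)
  h <- apply(sel, 1, function(p) ent[p[1], p[2]])
  o <- order(-h, sel[, 1], sel[, 2])
  list(rois = unname(sel[o, , drop = FALSE]), entropies = unname(h[o]))
}

# explicit-padding double-loop correlation (edge-replicating borders),
# kernel anchored at its center cell ceiling(dim/2)
naive_conv_reflect <- function(x, k) {
  n <- nrow(x); m <- ncol(x)
  kr <- nrow(k); kc <- ncol(k)
  ar <- ceiling(kr / 2); ac <- ceiling(kc / 2)
  out <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m)) {
      acc <- 0
      for (a in seq_len(kr))
        for (b in seq_len(kc)) {
          ii <- min(max(i + a - ar, 1), n)
          jj <- min(max(j + b - ac, 1), m)
          acc <- acc + k[a, b] * x[ii, jj]
        }
      out[i, j] <- acc
    }
  out
}

naive_mse <- function(ref, pred) {
  s <- 0
  for (i in seq_along(ref)) s <- s + (pred[i] - ref[i])^2
  s / length(ref)
}

naive_mae <- function(ref, pred) {
  s <- 0
  for (i in seq_along(ref)) s <- s + abs(pred[i] - ref[i])
  s / length(ref)
}

naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# ICC(2,1) from stats::aov mean squares on the long-format two-way layout
naive_icc_aov <- function(ref, pred) {
  n <- length(ref)
  d <- data.frame(y = c(ref, pred),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

naive_loa <- function(ref, pred, mult = 1.96) {
  d <- pred - ref
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  c(m, m - mult * s, m + mult * s)
}

# small textured test image (seeded), reused across ROI tests
test_image <- function(seed, age = NULL, hw = 64L, noise = 0.2) {
  spec <- cohort_spec(n_male = 1, n_female = 1, image_height = hw,
                      image_width = hw, noise_level = noise, seed = 1L)
  if (is.null(age)) age <- withr::with_seed(seed, runif(1, 1, 18))
  generate_radiograph(age, "female", spec, seed = seed)
}

# minimal fast pipeline config rooted at a temp dir
tiny_config <- function(out_dir, seed = 7L, n = 10L, noise = 0.2,
                        k = 3L, method = "brute_force") {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  cfg$data <- utils::modifyList(cfg$data, list(
    n_male = as.integer(n), n_female = as.integer(n),
    image_height = 64L, image_width = 64L, noise_level = noise))
  cfg$roi <- utils::modifyList(cfg$roi, list(
    patch_size = 8L, k = as.integer(k), min_separation = 4, method = method))
  cfg$model <- utils::modifyList(cfg$model, list(
    hidden_units = 4L, max_epochs = 60L, early_stop_patience = 15L))
  cfg
}

# an exactly linear "model" (relu pair trick): prediction == first feature
linear_probe_model <- function(p = 3, sex = "M", aggregator = "mean") {
  W1 <- matrix(0, p, 2); W1[1, 1] <- 1; W1[1, 2] <- -1
  structure(list(
    sex = sex, W1 = W1, b1 = c(0, 0),
    W2 = matrix(c(1, -1), 2, 1), b2 = 0,
    x_center = rep(0, p), x_scale = rep(1, p),
    y_center = 0, y_scale = 1,
    spec = mlp_spec(hidden_units = 2L, activation = "relu"),
    aggregator = aggregator,
    feature_names = sprintf("f%03d", seq_len(p) - 1),
    train_loss = 0, test_loss = 0, format_version = 1L
  ), class = "sex_model")
}
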