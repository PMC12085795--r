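# Sex-stratified two-layer perceptron regression on ROI detail vectors.
#
# "Two-layer" means two weight layers: input -> hidden (tanh by default)
# -> linear output. Training is plain seeded mini-batch gradient descent
# on the squared error of ROI-level age prediction, with early stopping
# monitored on the held-out test partition. Features and target are
# standardized with statistics computed from the training partition only;
# the validation partition is never touched during fitting.

#' Split a cohort into train / test / validation partitions
#'
#' Subject-level assignment (all 13 ROI rows of a subject share one
#' partition), stratified by sex and 3-year age band. Per sex, partition
#' quotas are computed by the largest-remainder rule on the target
#' fractions; subjects ordered by (band, seeded shuffle) are then assigned
#' by a greedy proportional filler so every band is spread across
#' partitions. Deterministic under a fixed seed.
#'
#' @param manifest Cohort manifest data.frame.
#' @param fractions Target (train, test, validation) fractions; default
#'   `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed.
#' @return Object of class `split_assignment`: data.frame `subject_id`,
#'   `partition` (factor train/test/validation), plus the fractions and
#'   seed as attributes.
#' @export
split_cohort <- function(manifest, fractions = c(0.70, 0.15, 0.15),
                         seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  parts <- c("train", "test", "validation")
  sexes <- unique(manifest$sex)
  for (s in sexes)
    if (sum(manifest$sex == s) < 3)
      skel_stop(sprintf("need >= 3 subjects per sex; sex '%s' has %d",
                        s, sum(manifest$sex == s)), "skelage_config_error")

  largest_remainder <- function(n, frac) {
    raw <- n * frac
    q <- floor(raw)
    rem <- n - sum(q)
    if (rem > 0) {
      # distribute leftovers by largest fractional part, ties favouring
      # earlier partitions (train > test > validation)
      o <- order(-(raw - q), seq_along(frac))
      q[o[seq_len(rem)]] <- q[o[seq_len(rem)]] + 1
    }
    q
  }

  out <- withr::with_seed(as.integer(seed), {
    blocks <- lapply(sexes, function(s) {
      sub <- manifest[manifest$sex == s, c("subject_id", "reference_age")]
      sub <- sub[order(sub$subject_id), ]
      band <- pmin(floor((sub$reference_age - 1) / 3), 5)
      ord <- order(band, sample.int(nrow(sub)))
      sub <- sub[ord, ]
      quota <- largest_remainder(nrow(sub), fractions)
      cnt <- c(0, 0, 0)
      assign <- character(nrow(sub))
      for (i in seq_len(nrow(sub))) {
        # fill the partition currently furthest below its quota share
        deficit <- ifelse(quota > 0, (quota - cnt) / quota, -Inf)
        p <- which.max(deficit)
        assign[i] <- parts[p]
        cnt[p] <- cnt[p] + 1
      }
      data.frame(subject_id = sub$subject_id, partition = assign,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
  out <- out[order(out$subject_id), ]
  rownames(out) <- NULL
  out$partition <- factor(out$partition, levels = parts)
  structure(out, fractions = fractions, seed = as.integer(seed),
            class = c("split_assignment", "data.frame"))
}

#' Perceptron hyperparameters
#'
#' @param hidden_units Hidden-layer width (>= 1); default 32.
#' @param activation `"tanh"` (default) or `"relu"`.
#' @param max_epochs Maximum training epochs; default 1000.
#' @param learning_rate Gradient-descent step size; default 5e-3.
#' @param batch_size Mini-batch size; default 32.
#' @param early_stop_patience Epochs without test-loss improvement before
#'   stopping; default 60.
#' @param seed Integer seed for weight init and batch shuffling.
#' @return Object of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden_units = 32L, activation = c("tanh", "relu"),
                     max_epochs = 1000L, learning_rate = 5e-3,
                     batch_size = 32L, early_stop_patience = 60L,
                     seed = 1L) {
  activation <- match.arg(activation)
  if (hidden_units < 1) skel_stop("hidden_units must be >= 1",
                                  "skelage_config_error")
  if (learning_rate <= 0) skel_stop("learning_rate must be positive",
                                    "skelage_config_error")
  structure(list(hidden_units = as.integer(hidden_units),
                 activation = activation,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "mlp_spec")
}

.act <- function(z, kind) if (kind == "tanh") tanh(z) else pmax(z, 0)
.act_grad <- function(a, z, kind) {
  if (kind == "tanh") 1 - a^2 else (z > 0) * 1
}

# feature columns of a feature table, as a numeric matrix
.feature_matrix <- function(features) {
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  as.matrix(features[, fcols, drop = FALSE])
}

#' Train the perceptron for one sex
#'
#' Selects the given sex's ROI rows, standardizes features and target with
#' train-partition statistics, and fits the two-layer perceptron by seeded
#' mini-batch gradient descent, early-stopped on the test partition's
#' loss (best-weights restore). The validation partition plays no role.
#'
#' @param features `feature_table` from [featurize_cohort()].
#' @param split `split_assignment` from [split_cohort()].
#' @param sex `"M"` or `"F"`.
#' @param spec An [mlp_spec()].
#' @param aggregator How [predict_bone_age()] combines a subject's k
#'   ROI-level estimates: `"mean"` (default) or `"median"`.
#' @return Object of class `sex_model`: weights, train-set
#'   standardization, spec, aggregator, per-epoch train/test loss history.
#' @export
train_sex_model <- function(features, split, sex, spec = mlp_spec(),
                            aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  sex <- match.arg(sex, c("M", "F"))
  part <- split$partition[match(features$subject_id, split$subject_id)]
  rows <- features$sex == sex & !is.na(part)
  if (!any(rows))
    skel_stop(sprintf("no feature rows for sex '%s'", sex),
              "skelage_domain_error")
  tr <- rows & part == "train"
  te <- rows & part == "test"
  X <- .feature_matrix(features)
  if (sum(tr) < 10 * spec$hidden_units)
    warning(sprintf(
      "only %d training rows for %d hidden units; >= %d recommended",
      sum(tr), spec$hidden_units, 10 * spec$hidden_units))

  x_center <- colMeans(X[tr, , drop = FALSE])
  x_scale <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  x_scale[x_scale < 1e-12] <- 1
  y_all <- features$reference_age
  y_center <- mean(y_all[tr])
  y_scale <- stats::sd(y_all[tr])
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1

  std <- function(M) sweep(sweep(M, 2, x_center), 2, x_scale, "/")
  Xtr <- std(X[tr, , drop = FALSE]); ytr <- (y_all[tr] - y_center) / y_scale
  Xte <- std(X[te, , drop = FALSE]); yte <- (y_all[te] - y_center) / y_scale
  n <- nrow(Xtr); p <- ncol(Xtr); h <- spec$hidden_units

  loss_of <- function(W1, b1, W2, b2, Xm, yv) {
    A <- .act(sweep(Xm %*% W1, 2, b1, "+"), spec$activation)
    mean((drop(A %*% W2) + b2 - yv)^2)
  }

  fit <- withr::with_seed(spec$seed, {
    a1 <- sqrt(6 / (p + h)); a2 <- sqrt(6 / (h + 1))
    W1 <- matrix(runif(p * h, -a1, a1), p, h); b1 <- numeric(h)
    W2 <- matrix(runif(h, -a2, a2), h, 1); b2 <- 0
    best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    best_te <- Inf; stall <- 0L
    tr_hist <- te_hist <- numeric(0)
    lr <- spec$learning_rate

    for (epoch in seq_len(spec$max_epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = spec$batch_size)) {
        b_idx <- idx[start:min(start + spec$batch_size - 1, n)]
        Xb <- Xtr[b_idx, , drop = FALSE]; yb <- ytr[b_idx]
        Z1 <- sweep(Xb %*% W1, 2, b1, "+")
        A1 <- .act(Z1, spec$activation)
        yhat <- drop(A1 %*% W2) + b2
        err <- yhat - yb                       # d loss / d yhat * (1/2)
        g <- 2 * err / length(yb)
        gW2 <- crossprod(A1, g); gb2 <- sum(g)
        dH <- (g %*% t(W2)) * .act_grad(A1, Z1, spec$activation)
        gW1 <- crossprod(Xb, dH); gb1 <- colSums(dH)
        W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
        W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
      }
      tr_loss <- loss_of(W1, b1, W2, b2, Xtr, ytr)
      if (!is.finite(tr_loss))
        skel_stop("training diverged: non-finite loss", "skelage_training_error")
      te_loss <- if (length(yte)) loss_of(W1, b1, W2, b2, Xte, yte) else tr_loss
      tr_hist <- c(tr_hist, tr_loss); te_hist <- c(te_hist, te_loss)
      if (te_loss < best_te - 1e-12) {
        best_te <- te_loss; stall <- 0L
        best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      } else {
        stall <- stall + 1L
        if (stall >= spec$early_stop_patience) break
      }
    }
    c(best, list(train_loss = tr_hist, test_loss = te_hist))
  })

  structure(list(sex = sex,
                 W1 = fit$W1, b1 = fit$b1, W2 = fit$W2, b2 = fit$b2,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 spec = spec, aggregator = aggregator,
                 feature_names = colnames(X),
                 train_loss = fit$train_loss, test_loss = fit$test_loss,
                 format_version = 1L),
            class = "sex_model")
}

#' @export
print.sex_model <- function(x, ...) {
  cat(sprintf(
    "sex_model (%s): %d -> %d -> 1 (%s), %d epochs, final train loss %.4g\n",
    x$sex, length(x$x_center), x$spec$hidden_units, x$spec$activation,
    length(x$train_loss), utils::tail(x$train_loss, 1)))
  invisible(x)
}

# ROI-level predictions in years (no aggregation, no clipping)
.predict_rows <- function(model, X) {
  if (ncol(X) != length(model$x_center))
    skel_stop(sprintf("feature length %d does not match model's %d",
                      ncol(X), length(model$x_center)),
              "skelage_domain_error")
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  A <- .act(sweep(Xs %*% model$W1, 2, model$b1, "+"), model$spec$activation)
  drop(A %*% model$W2) + model$b2
}

#' Predict a subject's bone age
#'
#' Runs the model on the subject's k ROI detail vectors, aggregates the k
#' ROI-level estimates by the model's aggregator (mean or median), and
#' clips the result to the cohort age support \[1, 18\] years.
#'
#' @param model A `sex_model`.
#' @param subject_features Numeric matrix (k x feature length) of the
#'   subject's detail vectors, or a single vector.
#' @param sex Optional `"M"`/`"F"` of the subject; if given it must match
#'   the model's sex.
#' @return Bone age estimate in years (scalar).
#' @export
predict_bone_age <- function(model, subject_features, sex = NULL) {
  if (!is.null(sex) && sex != model$sex)
    skel_stop(sprintf("subject sex '%s' does not match model sex '%s'",
                      sex, model$sex), "skelage_domain_error")
  X <- if (is.matrix(subject_features)) subject_features
       else matrix(subject_features, nrow = 1)
  preds <- (.predict_rows(model, X)) * model$y_scale + model$y_center
  agg <- if (model$aggregator == "mean") mean(preds) else median(preds)
  min(max(agg, 1), 18)
}

#' Save / load a trained sex model
#'
#' JSON container with a magic tag and format version; numbers are written
#' at full precision so a round trip preserves predictions to < 1e-9 y.
#'
#' @param model A `sex_model`.
#' @param path File path (`.json`).
#' @export
save_model <- function(model, path) {
  payload <- list(
    magic = "skelage-model",
    format_version = model$format_version,
    sex = model$sex,
    spec = unclass(model$spec),
    aggregator = model$aggregator,
    feature_names = model$feature_names,
    x_center = model$x_center, x_scale = model$x_scale,
    y_center = model$y_center, y_scale = model$y_scale,
    W1_dim = dim(model$W1), W1 = as.vector(model$W1),
    b1 = model$b1, W2 = as.vector(model$W2), b2 = model$b2,
    train_loss = model$train_loss, test_loss = model$test_loss
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e)
                  skel_stop(sprintf("cannot parse model file '%s'", path),
                            "skelage_format_error"))
  if (!identical(x$magic, "skelage-model") ||
      !identical(as.integer(x$format_version), 1L))
    skel_stop(sprintf(
      "'%s' is not a skelage model file (magic '%s', version '%s')",
      path, x$magic %||% "?", x$format_version %||% "?"),
      "skelage_format_error")
  spec <- do.call(mlp_spec, as.list(x$spec))
  structure(list(sex = x$sex,
                 W1 = matrix(as.numeric(x$W1), x$W1_dim[1], x$W1_dim[2]),
                 b1 = as.numeric(x$b1),
                 W2 = matrix(as.numeric(x$W2), ncol = 1),
                 b2 = as.numeric(x$b2),
                 x_center = stats::setNames(as.numeric(x$x_center), x$feature_names),
                 x_scale = stats::setNames(as.numeric(x$x_scale), x$feature_names),
                 y_center = as.numeric(x$y_center),
                 y_scale = as.numeric(x$y_scale),
                 spec = spec, aggregator = x$aggregator,
                 feature_names = x$feature_names,
                 train_loss = as.numeric(x$train_loss),
                 test_loss = as.numeric(x$test_loss),
                 format_version = 1L),
            class = "sex_model")
}
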