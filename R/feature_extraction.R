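# Fixed filter bank turning each ROI into one "detail vector".
#
# The original study's filters are undisclosed; the default bank here is a
# versioned, documented choice of standard edge/texture descriptors:
# horizontal and vertical first differences, a 4-neighbour Laplacian, and
# four orientation-selective (Sobel-type) edge kernels. Each response is
# summarized by mean absolute value, standard deviation, and energy (mean
# square), and the vector is completed by the patch mean gray level and
# the patch Shannon entropy: 7 kernels x 3 stats + 2 = 23 features.

#' Default fixed filter bank
#'
#' @return Object of class `filter_bank`: `kernels` (named list of small
#'   real matrices), `stats` (names of per-response summaries),
#'   `version_tag`. Feature length is
#'   `length(kernels) * length(stats) + 2`.
#' @export
default_filter_bank <- function() {
  k <- list(
    dx = matrix(c(-1, 1), 1, 2),
    dy = matrix(c(-1, 1), 2, 1),
    laplacian = matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3),
    edge_0 = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE),
    edge_45 = matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3, 3, byrow = TRUE),
    edge_90 = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE),
    edge_135 = matrix(c(0, 1, 2, -1, 0, 1, -2, -1, 0), 3, 3, byrow = TRUE)
  )
  structure(list(kernels = k,
                 stats = c("mean_abs", "sd", "energy"),
                 version_tag = "skelage-bank-v1"),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("filter_bank '%s': %d kernels x %d stats + 2 = %d features\n",
              x$version_tag, length(x$kernels), length(x$stats),
              feature_length(x)))
  invisible(x)
}

#' @rdname default_filter_bank
#' @param bank A `filter_bank`.
#' @export
feature_length <- function(bank) {
  length(bank$kernels) * length(bank$stats) + 2L
}

#' Feature names of a bank, in extraction order
#' @rdname default_filter_bank
#' @export
feature_names <- function(bank) {
  c(as.vector(outer(bank$stats, names(bank$kernels),
                    function(s, k) paste(k, s, sep = "_"))),
    "patch_mean", "patch_entropy")
}

# 2-D correlation of `x` with kernel `k`, same-size output, edge-replicating
# reflection padding. Kernel anchor is its center cell, ceiling(dim/2).
.conv2_reflect <- function(x, k) {
  n <- nrow(x); m <- ncol(x)
  kr <- nrow(k); kc <- ncol(k)
  ar <- ceiling(kr / 2); ac <- ceiling(kc / 2)
  out <- matrix(0, n, m)
  for (i in seq_len(kr)) {
    ri <- pmin(pmax(seq_len(n) + (i - ar), 1L), n)
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      cj <- pmin(pmax(seq_len(m) + (j - ac), 1L), m)
      out <- out + k[i, j] * x[ri, cj, drop = FALSE]
    }
  }
  out
}

#' Extract the detail vector of one ROI
#'
#' Applies every kernel of the bank to the patch (same-size correlation
#' with edge-replicating padding), summarizes each response by the bank's
#' statistics in kernel-major, stat-minor order, then appends the patch
#' mean gray level and the patch Shannon entropy (bits).
#'
#' @inheritParams patch_histogram
#' @param roi Length-2 `(row, col)` 1-based top-left corner.
#' @param bank A [default_filter_bank()]-style bank.
#' @return Named numeric vector of length [feature_length()].
#' @export
extract_features <- function(image, roi, patch_size,
                             bank = default_filter_bank()) {
  r <- roi[1]; c <- roi[2]; s <- patch_size
  if (r < 1 || c < 1 || r + s - 1 > nrow(image) || c + s - 1 > ncol(image))
    skel_stop(sprintf("ROI at (%d, %d) out of bounds", r, c),
              "skelage_domain_error")
  patch <- matrix(as.numeric(image[r:(r + s - 1), c:(c + s - 1)]), s, s)
  stat_fun <- list(
    mean_abs = function(v) mean(abs(v)),
    sd = function(v) stats::sd(v),
    energy = function(v) mean(v^2)
  )
  vals <- unlist(lapply(bank$kernels, function(k) {
    resp <- as.vector(.conv2_reflect(patch, k))
    vapply(bank$stats, function(s) stat_fun[[s]](resp), numeric(1))
  }), use.names = FALSE)
  out <- c(vals, mean(patch),
           shannon_entropy(patch_histogram(image, roi, patch_size)))
  names(out) <- feature_names(bank)
  out
}

#' Featurize a whole cohort
#'
#' One row per (subject, ROI): subject id, sex, ROI index, the subject's
#' reference age (constant across that subject's rows), and the detail
#' vector in columns `f000...`. Rows are ordered by (subject, roi_index).
#'
#' @param manifest Manifest data.frame from [read_manifest()] or
#'   [generate_cohort()].
#' @param roisets Named list of `roi_set` objects (names = subject ids).
#' @param bank Filter bank.
#' @param image_dir Base directory for relative `image_path`s; defaults to
#'   the manifest's own `base_dir` attribute.
#' @return data.frame of class `feature_table` with
#'   `k x nrow(manifest)` rows.
#' @export
featurize_cohort <- function(manifest, roisets,
                             bank = default_filter_bank(),
                             image_dir = attr(manifest, "base_dir")) {
  fn <- feature_names(bank)
  fcols <- sprintf("f%03d", seq_along(fn) - 1L)
  empty <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = 4 + length(fn))),
    c("subject_id", "sex", "roi_index", "reference_age", fcols))
  if (nrow(manifest) == 0) return(structure(empty, class = c("feature_table", "data.frame")))

  blocks <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    rs <- roisets[[id]]
    if (is.null(rs))
      skel_stop(sprintf("no ROI set for subject '%s'", id), "skelage_io_error")
    p <- manifest$image_path[i]
    if (!is.null(image_dir) && !file.exists(p)) p <- file.path(image_dir, p)
    if (!file.exists(p))
      skel_stop(sprintf("image for subject '%s' not found: '%s'", id, p),
                "skelage_io_error")
    img <- read_radiograph(p)
    k <- nrow(rs$rois)
    feats <- t(vapply(seq_len(k), function(j)
      extract_features(img, rs$rois[j, ], rs$patch_size, bank),
      numeric(length(fn))))
    colnames(feats) <- fcols
    blocks[[i]] <- cbind(
      data.frame(subject_id = id, sex = manifest$sex[i],
                 roi_index = seq_len(k),
                 reference_age = manifest$reference_age[i],
                 stringsAsFactors = FALSE),
      as.data.frame(feats))
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out, feature_names = fn,
            class = c("feature_table", "data.frame"))
}

#' Write / read a feature table
#'
#' CSV schema: `subject_id,sex,roi_index,reference_age,f000..fNNN`.
#'
#' @param features A `feature_table` from [featurize_cohort()].
#' @param path CSV file path.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  for (cn in fcols) df[[cn]] <- sprintf("%.12g", df[[cn]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(sex = "character"))
  structure(df, class = c("feature_table", "data.frame"))
}
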