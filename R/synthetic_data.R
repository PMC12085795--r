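# Synthetic radiograph-like cohort generator.
#
# The clinical images behind the method are not deposited, so downstream
# stages are exercised on generated images whose texture encodes a known
# bone age. An effective maturity m = age - sex_lag * [sex == male] drives
# three monotone texture channels: the number of bright elliptical
# "ossification" blobs, the sharpness of their edges, and the amplitude of
# a sinusoidal high-frequency texture inside them. The background is dark
# and nearly featureless (low entropy), so entropy-maximizing ROI selection
# lands on the blobs that carry the age signal.

# Age-band counts of the emulated cohort (ages in years, counts per sex).
# The final band is clipped to the cohort support [1, 18].
.age_bands <- data.frame(
  lower = c(0, 2:18),
  upper = c(2, 3:19),
  male  = c(1, 8, 13, 12, 4, 17, 2, 12, 3, 6, 23, 8, 31, 16, 15, 13, 10, 14),
  female = c(2, 10, 20, 8, 18, 16, 34, 35, 12, 24, 43, 41, 11, 20, 15, 8, 13, 17)
)

#' Age-band sampling weights of the emulated study cohort
#'
#' Per-sex counts of subjects per one-year age band (first band spans two
#' years) used by the table-weighted age sampler. Band edges are clipped to
#' the cohort age support \[1, 18\] at sampling time.
#'
#' @return A data.frame with columns `lower`, `upper`, `male`, `female`.
#' @export
age_band_weights <- function() .age_bands

#' Cohort specification
#'
#' Bundles everything [generate_cohort()] needs: demographic structure,
#' image geometry, the maturation offset between the sexes, the noise
#' level, and the master seed.
#'
#' @param n_male,n_female Number of subjects per sex. Defaults are the
#'   emulated cohort's printed totals (220 boys, 335 girls).
#' @param age_sampler `"table"` (band-weighted by [age_band_weights()],
#'   the default) or `"uniform"` over \[1, 18\].
#' @param image_height,image_width Image size in pixels. The default
#'   512 x 512 = 262,144 pixels matches the source images' ">240,000
#'   pixels" scale.
#' @param sex_lag Maturation offset in years subtracted from boys'
#'   effective maturity; default 1.25 (midpoint of the reported 12-18
#'   month lag).
#' @param noise_level Dimensionless in \[0, 1\]. Drives both additive pixel
#'   noise (sd `25 * noise_level` gray levels) and a per-subject maturity
#'   rendering jitter (sd `1.5 * noise_level` years) that decouples texture
#'   from the recorded label the way biological variation does.
#' @param seed Master integer seed; per-subject seeds are derived as
#'   `seed + subject index`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 220, n_female = 335,
                        age_sampler = c("table", "uniform"),
                        image_height = 512, image_width = 512,
                        sex_lag = 1.25, noise_level = 0.2, seed = 1L) {
  age_sampler <- match.arg(age_sampler)
  if (n_male < 0 || n_female < 0 || n_male + n_female < 1)
    skel_stop("n_male + n_female must be >= 1 and counts nonnegative",
              "skelage_config_error")
  if (image_height <= 0 || image_width <= 0)
    skel_stop("image dimensions must be positive", "skelage_config_error")
  if (sex_lag < 0)
    skel_stop("sex_lag must be >= 0", "skelage_config_error")
  if (noise_level < 0 || noise_level > 1)
    skel_stop("noise_level must lie in [0, 1]", "skelage_config_error")
  structure(list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    age_sampler = age_sampler,
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    sex_lag = sex_lag, noise_level = noise_level, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: %d male + %d female, %dx%d px, sampler=%s, sex_lag=%.2f y, noise=%.2f, seed=%d\n",
    x$n_male, x$n_female, x$image_height, x$image_width,
    x$age_sampler, x$sex_lag, x$noise_level, x$seed))
  invisible(x)
}

# effective maturity in years; may go slightly negative for lagged young
# boys (the texture mapping stays valid down to m = -2, where the blob
# texture amplitude is still positive)
.maturity <- function(age, sex, sex_lag) {
  age - sex_lag * (sex == "male")
}

#' Generate one synthetic radiograph
#'
#' Renders an 8-bit grayscale image whose texture is controlled by the
#' effective maturity `m = age - sex_lag * [sex == male]`: blob count,
#' blob edge sharpness and in-blob texture amplitude are all nondecreasing
#' in `m`. All randomness (blob geometry, texture phase, pixel noise) flows
#' from `seed` through draws whose number does not depend on `m`, so two
#' calls with equal effective maturity and equal seed produce identical
#' pixel arrays.
#'
#' @param age Reference age in years, in \[1, 18\].
#' @param sex `"male"` or `"female"`.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for this image.
#' @return Integer matrix (`image_height` x `image_width`) of gray levels
#'   in 0..255, with attributes `n_blobs` (rendered blob count) and
#'   `maturity` (the rendered effective maturity in years).
#' @export
generate_radiograph <- function(age, sex, spec, seed = spec$seed) {
  if (!is.numeric(age) || length(age) != 1 || is.na(age) || age < 1 || age > 18)
    skel_stop("age must be a single value in [1, 18]", "skelage_domain_error")
  sex <- match.arg(sex, c("male", "female"))
  if (spec$image_height <= 0 || spec$image_width <= 0)
    skel_stop("image dimensions must be positive", "skelage_config_error")
  H <- spec$image_height; W <- spec$image_width
  S <- min(H, W)
  max_blobs <- 20L
  m_eff <- .maturity(age, sex, spec$sex_lag)

  withr::with_seed(as.integer(seed), {
    # fixed-size parameter draws, independent of maturity
    cy   <- runif(max_blobs, 0.10, 0.90) * H
    cx   <- runif(max_blobs, 0.10, 0.90) * W
    rad  <- runif(max_blobs, 0.07, 0.13) * S
    ax1  <- rad * runif(max_blobs, 0.75, 1.30)
    ax2  <- rad * runif(max_blobs, 0.75, 1.30)
    psi  <- runif(max_blobs, 0, pi)      # ellipse orientation
    thg  <- runif(max_blobs, 0, pi)      # grating orientation
    phg  <- runif(max_blobs, 0, 2 * pi)  # grating phase
    frq  <- runif(max_blobs, 0.22, 0.42) # grating frequency, cycles/px
    speckle <- matrix(runif(H * W, -1, 1), H, W)
    m_jit <- rnorm(1, 0, 1.5 * spec$noise_level)
    pix_noise <- rnorm(H * W, 0, 25 * spec$noise_level)

    m <- min(max(m_eff + m_jit, -2), 18)
    n_blobs <- min(3L + as.integer(floor(0.8 * m)), max_blobs)
    amp   <- 6 + 2.2 * m                  # texture amplitude, gray levels
    base  <- 90 + 6.5 * m                 # blob interior brightness
    # edge softness shrinks gently with maturity (edges sharpen) but
    # mildly enough that the texture amplitude dominates local entropy
    softw <- 0.05 / (1 + exp(0.2 * (m - 9))) + 0.08

    Y <- matrix(seq_len(H), H, W)
    X <- matrix(seq_len(W), H, W, byrow = TRUE)
    img <- 28 + 8 * (Y / H)               # dark, nearly flat background
    for (b in seq_len(n_blobs)) {
      dx <- X - cx[b]; dy <- Y - cy[b]
      u <- (dx * cos(psi[b]) + dy * sin(psi[b])) / ax1[b]
      v <- (-dx * sin(psi[b]) + dy * cos(psi[b])) / ax2[b]
      dn <- sqrt(u * u + v * v)
      mask <- stats::plogis((1 - dn) / softw)
      tex <- amp * (0.6 * speckle +
                    0.4 * sin(2 * pi * frq[b] * (X * cos(thg[b]) + Y * sin(thg[b])) + phg[b]))
      img <- pmax(img, mask * (base + tex))
    }
    img <- img + pix_noise
    out <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), H, W)
    attr(out, "n_blobs") <- n_blobs
    attr(out, "maturity") <- m
    out
  })
}

# sample n ages for one sex; band-weighted ("table") or uniform over [1,18];
# consumes the caller's RNG stream
.sample_ages <- function(n, sex, sampler) {
  if (n == 0) return(numeric(0))
  if (sampler == "uniform") return(runif(n, 1, 18))
  w <- .age_bands[[sex]]
  lo <- pmax(.age_bands$lower, 1)
  hi <- pmin(.age_bands$upper, 18)
  band <- sample.int(nrow(.age_bands), n, replace = TRUE, prob = w / sum(w))
  lo[band] + runif(n) * (hi[band] - lo[band])
}

#' Generate a synthetic cohort on disk
#'
#' Samples ages per sex, renders one radiograph per subject, writes the
#' images and a manifest CSV (`subject_id,sex,reference_age,image_path`;
#' sex coded `M`/`F`, ages in decimal years with 2 decimals, paths relative
#' to `out_dir`). Per-subject image seeds are `spec$seed + subject index`,
#' so generation is reproducible and each image independently so.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed); images go to
#'   `out_dir/images/`.
#' @param format `"png"` (default) or `"tiff"`.
#' @return The manifest as a data.frame, invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(spec, out_dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "cohort_spec"))
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || file.access(img_dir, 2) != 0)
    skel_stop(sprintf("cannot write to output directory '%s'", out_dir),
              "skelage_io_error")
  if (format == "tiff" && !requireNamespace("tiff", quietly = TRUE))
    skel_stop("the 'tiff' package is required for format = 'tiff'",
              "skelage_config_error")

  n <- spec$n_male + spec$n_female
  ages <- withr::with_seed(spec$seed, {
    c(.sample_ages(spec$n_male, "male", spec$age_sampler),
      .sample_ages(spec$n_female, "female", spec$age_sampler))
  })
  ages <- round(ages, 2)
  sexes <- rep(c("male", "female"), c(spec$n_male, spec$n_female))
  ids <- sprintf("S%04d", seq_len(n))
  rel <- file.path("images", paste0(ids, ".", format))

  for (i in seq_len(n)) {
    img <- generate_radiograph(ages[i], sexes[i], spec, seed = spec$seed + i)
    p <- file.path(out_dir, rel[i])
    if (format == "png") png::writePNG(img / 255, p)
    else tiff::writeTIFF(img / 255, p, bits.per.sample = 8L)
  }
  manifest <- data.frame(
    subject_id = ids,
    sex = ifelse(sexes == "male", "M", "F"),
    reference_age = sprintf("%.2f", ages),
    image_path = rel,
    stringsAsFactors = FALSE
  )
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(read_manifest(file.path(out_dir, "manifest.csv")))
}

#' Read a cohort manifest
#'
#' @param path Path to a `manifest.csv` with columns
#'   `subject_id,sex,reference_age,image_path`.
#' @return data.frame with `reference_age` numeric, `sex` in `{"M","F"}`,
#'   and an attribute `base_dir` for resolving relative image paths.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = "character") # "F" must not become FALSE
  need <- c("subject_id", "sex", "reference_age", "image_path")
  if (!all(need %in% names(m)))
    skel_stop(sprintf("manifest misses column(s): %s",
                      paste(setdiff(need, names(m)), collapse = ", ")),
              "skelage_io_error")
  if (anyDuplicated(m$subject_id))
    skel_stop("duplicate subject_id in manifest", "skelage_io_error")
  if (!all(m$sex %in% c("M", "F")))
    skel_stop("manifest sex must be coded M/F", "skelage_io_error")
  m$reference_age <- as.numeric(m$reference_age)
  attr(m, "base_dir") <- dirname(normalizePath(path, mustWork = FALSE))
  m
}

#' Read an 8-bit grayscale radiograph image
#'
#' @param path PNG or TIFF file. Multi-channel images are reduced to their
#'   first channel.
#' @return Integer matrix of gray levels 0..255.
#' @export
read_radiograph <- function(path) {
  if (!file.exists(path))
    skel_stop(sprintf("image file not found: '%s'", path), "skelage_io_error")
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      skel_stop("the 'tiff' package is required to read TIFF",
                "skelage_config_error")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}
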