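# ROI ("click") selection by local Shannon entropy maximization.
#
# Patches are s x s squares addressed by their 1-based (row, col) top-left
# corner, spanning rows r..r+s-1 and cols c..c+s-1. Spatial diversity is
# enforced by a minimum Euclidean center distance between selected patches
# (equal to the top-left distance since all patches share one size).

#' Gray-level histogram of one patch
#'
#' @param image Integer matrix of gray levels in 0..255.
#' @param top_left Length-2 vector `(row, col)`, 1-based top-left corner.
#' @param patch_size Side length in pixels.
#' @return Object of class `patch_histogram`: list with `counts` (256
#'   nonnegative integers, bins 0..255) and `total` (= `patch_size^2`).
#' @export
patch_histogram <- function(image, top_left, patch_size) {
  r <- top_left[1]; c <- top_left[2]; s <- patch_size
  if (s < 1 || r < 1 || c < 1 || r + s - 1 > nrow(image) || c + s - 1 > ncol(image))
    skel_stop(sprintf(
      "patch at (%d, %d) with size %d exceeds a %d x %d image",
      r, c, s, nrow(image), ncol(image)), "skelage_domain_error")
  patch <- image[r:(r + s - 1), c:(c + s - 1)]
  if (anyNA(patch) || min(patch) < 0 || max(patch) > 255)
    skel_stop("image values must lie in [0, 255]", "skelage_domain_error")
  structure(list(counts = tabulate(as.integer(patch) + 1L, 256L),
                 total = s * s),
            class = "patch_histogram")
}

#' Shannon entropy of a patch histogram
#'
#' `H = -sum_i p_i log_b(p_i)` over occupied bins, with `0 log 0 = 0`.
#' In base 2 (the default) `H` lies in \[0, 8\] bits for 8-bit images.
#'
#' @param hist A [patch_histogram()], or a bare vector of 256 counts.
#' @param base Logarithm base; default 2 (bits).
#' @return Entropy (scalar).
#' @export
shannon_entropy <- function(hist, base = 2) {
  counts <- if (inherits(hist, "patch_histogram")) hist$counts else hist
  total <- sum(counts)
  if (total <= 0)
    skel_stop("empty histogram", "skelage_domain_error")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Local-entropy map of an image
#'
#' Entropy of every `patch_size` square window whose top-left corner lies
#' on the stride grid. Cell `[i, j]` of the result is the entropy of the
#' patch at top-left `((i-1)*stride + 1, (j-1)*stride + 1)`.
#'
#' @inheritParams patch_histogram
#' @param stride Grid step in pixels (>= 1).
#' @param base Logarithm base; default 2.
#' @return Numeric matrix of entropies with attributes `patch_size` and
#'   `stride`.
#' @export
entropy_map <- function(image, patch_size, stride = 1L, base = 2) {
  if (stride < 1) skel_stop("stride must be >= 1", "skelage_domain_error")
  if (patch_size > nrow(image) || patch_size > ncol(image) || patch_size < 1)
    skel_stop("patch_size must be between 1 and the image dimensions",
              "skelage_domain_error")
  storage.mode(image) <- "integer"
  m <- entropy_map_cpp(image, as.integer(patch_size), as.integer(stride))
  if (base != 2) m <- m / log2(base)
  structure(m, patch_size = as.integer(patch_size), stride = as.integer(stride))
}

# assemble a roi_set: order by entropy nonincreasing, ties by (row, col)
.roi_set <- function(rois, entropies, patch_size, min_separation, method) {
  o <- order(-entropies, rois[, 1], rois[, 2])
  structure(list(
    patch_size = as.integer(patch_size),
    rois = matrix(as.integer(rois[o, , drop = FALSE]), ncol = 2,
                  dimnames = list(NULL, c("row", "col"))),
    entropies = entropies[o],
    min_separation = min_separation,
    method = method
  ), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set (%s): %d patches of %dx%d px, total entropy %.3f\n",
              x$method, nrow(x$rois), x$patch_size, x$patch_size,
              sum(x$entropies)))
  invisible(x)
}

# TRUE if candidate (r, c) keeps Euclidean distance >= min_sep
# from every row of `sel` (matrix with columns row, col)
.separated <- function(r, c, sel, min_sep) {
  if (nrow(sel) == 0) return(TRUE)
  all((sel[, 1] - r)^2 + (sel[, 2] - c)^2 >= min_sep^2)
}

#' Exhaustive greedy ROI selection (reference implementation)
#'
#' Deterministic oracle for [ga_select_rois()]: scans every valid top-left
#' position (stride 1), then repeatedly takes the highest-entropy position
#' that keeps at least `min_separation` center distance from the already
#' selected patches. Ties are broken by (row, col) lexicographic order.
#'
#' @inheritParams entropy_map
#' @param k Number of ROIs (default 13).
#' @param min_separation Minimum pairwise center distance in pixels;
#'   default `patch_size / 2`.
#' @return Object of class `roi_set`: `patch_size`, `rois` (k x 2 matrix
#'   of 1-based top-left corners), `entropies` (nonincreasing).
#' @export
brute_force_rois <- function(image, patch_size, k = 13L,
                             min_separation = patch_size / 2, base = 2) {
  em <- entropy_map(image, patch_size, stride = 1L, base = base)
  nr <- nrow(em); nc <- ncol(em)
  # candidate order: entropy desc, then row, then col (1-based top-lefts)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  o <- order(-as.vector(em), rows, cols)
  sel <- matrix(integer(0), 0, 2)
  ent <- numeric(0)
  for (idx in o) {
    r <- rows[idx]; c <- cols[idx]
    if (.separated(r, c, sel, min_separation)) {
      sel <- rbind(sel, c(r, c))
      ent <- c(ent, em[r, c])
      if (nrow(sel) == k) break
    }
  }
  if (nrow(sel) < k)
    skel_stop(sprintf(
      "only %d of %d requested ROIs are feasible at min_separation %.1f",
      nrow(sel), k, min_separation), "skelage_domain_error",
      feasible = nrow(sel))
  .roi_set(sel, ent, patch_size, min_separation, "brute_force")
}

#' Genetic-algorithm hyperparameters
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations (>= 1).
#' @param crossover_rate One-point crossover probability per pairing.
#' @param mutation_rate Mutation probability per coordinate.
#' @param mutation_step Max absolute coordinate jitter in pixels.
#' @param elitism Number of top individuals copied unchanged.
#' @param seed Integer seed making the run reproducible.
#' @return Object of class `ga_params`.
#' @export
ga_params <- function(population_size = 60L, generations = 80L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      mutation_step = 10L, elitism = 2L, seed = 1L) {
  if (population_size < 2) skel_stop("population_size must be >= 2",
                                     "skelage_config_error")
  if (generations < 1) skel_stop("generations must be >= 1",
                                 "skelage_config_error")
  for (p in c(crossover_rate, mutation_rate))
    if (p < 0 || p > 1) skel_stop("rates must lie in [0, 1]",
                                  "skelage_config_error")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_step = as.integer(mutation_step),
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_params")
}

# count of violated pairs (center distance < min_sep) in chromosome
# given as k x 2 matrix
.n_violations <- function(pos, min_sep) {
  if (nrow(pos) < 2) return(0L)
  d2 <- stats::dist(pos)^2
  sum(d2 < min_sep^2)
}

#' Genetic-algorithm ROI selection
#'
#' Places `k` patches jointly: a chromosome is the concatenation of k
#' (row, col) top-left corners; fitness is the sum of the k local
#' entropies minus a penalty per separation violation large enough that
#' any infeasible set scores below any feasible one of comparable
#' entropy. The best feasible individual seen across all generations is
#' returned. With a fixed `params$seed` the result is reproducible.
#'
#' The initial population is random except for one deterministic
#' evenly-spaced individual, which guarantees a feasible candidate exists
#' from generation 0 whenever the spacing grid admits one.
#'
#' @inheritParams brute_force_rois
#' @param params A [ga_params()].
#' @return A `roi_set` (see [brute_force_rois()]), `method = "ga"`.
#' @export
ga_select_rois <- function(image, patch_size, k = 13L,
                           min_separation = patch_size / 2,
                           params = ga_params(), base = 2) {
  em <- entropy_map(image, patch_size, stride = 1L, base = base)
  nr <- nrow(em); nc <- ncol(em)
  if (nr * nc < k)
    skel_stop("image admits fewer positions than k", "skelage_domain_error")
  penalty <- 2 * max(max(em), 1e-9)
  np <- params$population_size

  # chromosome: integer vector c(rows, cols), length 2k
  fitness <- function(chrom) {
    pos <- matrix(chrom, ncol = 2)
    sum(em[pos]) - penalty * .n_violations(pos, min_separation)
  }
  feasible <- function(chrom)
    .n_violations(matrix(chrom, ncol = 2), min_separation) == 0L

  # deterministic spread individual on an evenly spaced grid
  spread <- function() {
    g <- ceiling(sqrt(k))
    rs <- round(seq(1, nr, length.out = g))
    cs <- round(seq(1, nc, length.out = ceiling(k / g)))
    grid <- expand.grid(row = rs, col = cs)[seq_len(k), ]
    c(grid$row, grid$col)
  }

  withr::with_seed(params$seed, {
    pop <- replicate(np, c(sample.int(nr, k, replace = TRUE),
                           sample.int(nc, k, replace = TRUE)),
                     simplify = FALSE)
    pop[[1]] <- spread()
    best_feas <- NULL; best_feas_fit <- -Inf
    best_any <- pop[[1]]; best_any_fit <- -Inf

    for (gen in seq_len(params$generations)) {
      fit <- vapply(pop, fitness, numeric(1))
      o <- order(-fit)
      if (fit[o[1]] > best_any_fit) {
        best_any_fit <- fit[o[1]]; best_any <- pop[[o[1]]]
      }
      for (i in o) {
        if (fit[i] <= best_feas_fit) break
        if (feasible(pop[[i]])) {
          best_feas_fit <- fit[i]; best_feas <- pop[[i]]; break
        }
      }
      # tournament selection (size 3), elitism, one-point crossover,
      # per-coordinate jitter mutation
      elite <- pop[o[seq_len(min(params$elitism, np))]]
      tourn <- function() {
        cand <- sample.int(np, 3L, replace = TRUE)
        pop[[cand[which.max(fit[cand])]]]
      }
      children <- vector("list", np - length(elite))
      for (j in seq_along(children)) {
        a <- tourn(); b <- tourn()
        child <- a
        if (runif(1) < params$crossover_rate) {
          cut <- sample.int(2L * k - 1L, 1L)
          child <- c(a[seq_len(cut)], b[(cut + 1L):(2L * k)])
        }
        mut <- runif(2L * k) < params$mutation_rate
        if (any(mut)) {
          jit <- sample.int(2L * params$mutation_step + 1L, sum(mut),
                            replace = TRUE) - params$mutation_step - 1L
          child[mut] <- child[mut] + jit
          child[seq_len(k)] <- pmin(pmax(child[seq_len(k)], 1L), nr)
          child[k + seq_len(k)] <- pmin(pmax(child[k + seq_len(k)], 1L), nc)
        }
        children[[j]] <- child
      }
      pop <- c(elite, children)
    }
    fit <- vapply(pop, fitness, numeric(1))
    o <- order(-fit)
    for (i in o) {
      if (fit[i] <= best_feas_fit) break
      if (feasible(pop[[i]])) {
        best_feas_fit <- fit[i]; best_feas <- pop[[i]]; break
      }
    }
    if (fit[o[1]] > best_any_fit) {
      best_any_fit <- fit[o[1]]; best_any <- pop[[o[1]]]
    }
  })

  if (is.null(best_feas))
    skel_stop(sprintf(
      "no separation-feasible ROI set found in %d generations",
      params$generations), "skelage_ga_error",
      best_candidate = matrix(best_any, ncol = 2,
                              dimnames = list(NULL, c("row", "col"))))
  pos <- matrix(best_feas, ncol = 2)
  .roi_set(pos, em[pos], patch_size, min_separation, "ga")
}

#' Write / read per-cohort ROI sets
#'
#' CSV schema: `subject_id,roi_index,row,col,patch_size,entropy_bits`,
#' coordinates 1-based top-left, `roi_index` in entropy-descending order.
#'
#' @param roisets Named list of `roi_set` objects, names = subject ids.
#' @param path CSV file path.
#' @return `write_roisets`: the path, invisibly. `read_roisets`: named
#'   list of `roi_set` objects.
#' @export
write_roisets <- function(roisets, path) {
  rows <- lapply(names(roisets), function(id) {
    rs <- roisets[[id]]
    data.frame(subject_id = id,
               roi_index = seq_len(nrow(rs$rois)),
               row = rs$rois[, 1], col = rs$rois[, 2],
               patch_size = rs$patch_size,
               entropy_bits = rs$entropies)
  })
  df <- do.call(rbind, rows)
  df$entropy_bits <- sprintf("%.12g", df$entropy_bits)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roisets
#' @export
read_roisets <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$roi_index), ]
    structure(list(patch_size = d$patch_size[1],
                   rois = matrix(as.integer(c(d$row, d$col)), ncol = 2,
                                 dimnames = list(NULL, c("row", "col"))),
                   entropies = as.numeric(d$entropy_bits),
                   min_separation = NA_real_,
                   method = "file"),
              class = "roi_set")
  })
  out[unique(df$subject_id)]
}
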