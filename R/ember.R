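#' Build the excitation/emission scan-channel grid
#'
#' Enumerates the spectral acquisition protocol. The dual-sweep part steps
#' the excitation line from `ex_from` to `ex_to` by `ex_step`; for each
#' excitation, contiguous emission windows of width `em_window` start at
#' `ex + em_offset` (detection begins 10 nm above the excitation line by
#' default) and tile up to `em_stop`. An optional single-excitation sweep
#' appends windows from `em_from` to `em_stop` at a fixed excitation.
#' Ordering is deterministic: excitation-major, then emission. The default
#' protocol yields 110 dual-sweep channels plus 18 at 405 nm, 128 in total.
#'
#' @param lambda_spec list with `ex_from`, `ex_to`, `ex_step`, `em_offset`,
#'   `em_window`, `em_stop` (nm)
#' @param mono_spec optional list with `ex`, `em_from`, `em_stop`,
#'   `em_window` (nm)
#' @return data frame of scan channels: `ex_nm`, `em_start_nm`, `em_end_nm`,
#'   `em_mid_nm`, `mode` (`"lambda_lambda"` or `"mono"`)
#' @export
build_scan_grid <- function(lambda_spec = list(ex_from = 470, ex_to = 670,
                                               ex_step = 20, em_offset = 10,
                                               em_window = 20, em_stop = 780),
                            mono_spec = list(ex = 405, em_from = 420,
                                             em_stop = 780, em_window = 20)) {
  ls <- lambda_spec
  stopifnot(ls$ex_step > 0, ls$em_window > 0)
  rows <- list()
  for (ex in seq(ls$ex_from, ls$ex_to, by = ls$ex_step)) {
    em0 <- ex + ls$em_offset
    span <- ls$em_stop - em0
    if (span < ls$em_window) {
      stop_fmt("build_scan_grid: no %g nm emission window fits between %g and %g nm",
               ls$em_window, em0, ls$em_stop)
    }
    if (span %% ls$em_window != 0) {
      stop_fmt("build_scan_grid: emission span %g-%g nm leaves a %g nm remainder for %g nm windows",
               em0, ls$em_stop, span %% ls$em_window, ls$em_window)
    }
    starts <- seq(em0, ls$em_stop - ls$em_window, by = ls$em_window)
    rows[[length(rows) + 1L]] <- data.frame(
      ex_nm = ex, em_start_nm = starts, em_end_nm = starts + ls$em_window,
      mode = "lambda_lambda", stringsAsFactors = FALSE)
  }
  if (!is.null(mono_spec)) {
    ms <- mono_spec
    span <- ms$em_stop - ms$em_from
    if (span %% ms$em_window != 0) {
      stop_fmt("build_scan_grid: mono emission span %g-%g nm leaves a %g nm remainder",
               ms$em_from, ms$em_stop, span %% ms$em_window)
    }
    starts <- seq(ms$em_from, ms$em_stop - ms$em_window, by = ms$em_window)
    rows[[length(rows) + 1L]] <- data.frame(
      ex_nm = ms$ex, em_start_nm = starts, em_end_nm = starts + ms$em_window,
      mode = "mono", stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  grid$em_mid_nm <- (grid$em_start_nm + grid$em_end_nm) / 2
  rownames(grid) <- NULL
  grid[, c("ex_nm", "em_start_nm", "em_end_nm", "em_mid_nm", "mode")]
}

#' Multispectral image stack for one imaging condition
#'
#' @param channels scan-channel data frame from [build_scan_grid()]
#' @param images numeric array `height x width x n_channels`, or a list of
#'   equally sized matrices (one per channel)
#' @param condition list of condition metadata (`protein_variant`,
#'   `inducer_id`, `dye_id`)
#' @return an object of class `ember_stack`
#' @export
ember_stack <- function(channels, images, condition = list()) {
  if (is.list(images) && !is.array(images)) {
    dims <- unique(lapply(images, dim))
    if (length(dims) != 1L) stop("ember_stack: images differ in dimensions", call. = FALSE)
    images <- array(unlist(images), dim = c(dims[[1L]], length(images)))
  }
  if (length(dim(images)) != 3L) {
    stop("ember_stack: images must form a height x width x channel array", call. = FALSE)
  }
  if (dim(images)[3L] != nrow(channels)) {
    stop_fmt("ember_stack: %d images but %d scan channels",
             dim(images)[3L], nrow(channels))
  }
  structure(list(channels = channels, images = images, condition = condition),
            class = "ember_stack")
}

#' Maximum-intensity projection of a stack
#'
#' @param stack an [ember_stack()]
#' @return matrix of per-pixel maxima across channels
#' @export
max_projection <- function(stack) {
  apply(stack$images, c(1L, 2L), max)
}

#' Segment particles by adaptive local-mean thresholding
#'
#' Bradley-style segmentation on the maximum-intensity projection across the
#' full wavelength range: a pixel is foreground when its intensity exceeds
#' the local mean (square window of side `window_fraction` times the image
#' side, computed exactly via an integral image) scaled by
#' `1 + sensitivity`. Foreground pixels are grouped into 8-connected
#' components and components smaller than `min_area` pixels dropped.
#'
#' @param stack an [ember_stack()]
#' @param window_fraction local window side as a fraction of the image side
#' @param sensitivity relative threshold above the local mean (0 = the local
#'   mean itself); raise it on noisy images
#' @param min_area minimum particle area in pixels
#' @return list of particle masks, each a list with `pixels` (two-column
#'   row/col matrix), `area`, `centroid` (row, col)
#' @export
segment_particles <- function(stack, window_fraction = 0.125, sensitivity = 0,
                              min_area = 10L) {
  proj <- max_projection(stack)
  if (max(proj) == min(proj)) return(list())  # constant image: nothing to find
  side <- max(dim(proj))
  half <- max(1L, as.integer(round(window_fraction * side / 2)))
  lm <- local_mean(proj, half)
  # the epsilon guard absorbs integral-image round-off on flat regions; it
  # scales with the dynamic range so segmentation stays intensity-scale
  # invariant
  eps <- 1e-8 * diff(range(proj))
  fg <- proj > lm * (1 + sensitivity) + eps
  lab <- label_components(fg)
  k <- max(lab)
  if (k == 0L) return(list())
  masks <- lapply(seq_len(k), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) < min_area) return(NULL)
    list(pixels = unname(px), area = nrow(px),
         centroid = c(mean(px[, 1L]), mean(px[, 2L])))
  })
  Filter(Negate(is.null), masks)
}

#' Extract per-particle spectral profiles
#'
#' The profile value for channel c is the mean intensity of the particle's
#' pixels in image c; profile order matches mask order.
#'
#' @param stack an [ember_stack()]
#' @param masks particle masks from [segment_particles()]
#' @return numeric matrix, one row per particle, one column per channel
#' @export
extract_profiles <- function(stack, masks) {
  dims <- dim(stack$images)
  n_ch <- dims[3L]
  if (!length(masks)) return(matrix(numeric(0), 0L, n_ch))
  flat <- matrix(stack$images, nrow = dims[1L] * dims[2L], ncol = n_ch)
  profs <- t(vapply(masks, function(m) {
    if (is.null(m$pixels) || nrow(m$pixels) == 0L) {
      stop("extract_profiles: empty particle mask", call. = FALSE)
    }
    if (any(m$pixels[, 1L] < 1L) || any(m$pixels[, 1L] > dims[1L]) ||
        any(m$pixels[, 2L] < 1L) || any(m$pixels[, 2L] > dims[2L])) {
      stop("extract_profiles: mask pixels outside image bounds", call. = FALSE)
    }
    idx <- m$pixels[, 1L] + (m$pixels[, 2L] - 1L) * dims[1L]
    colMeans(flat[idx, , drop = FALSE])
  }, numeric(n_ch)))
  profs
}

#' Normalize spectral profiles to unit total intensity
#'
#' Each profile is divided by its own sum, making profiles comparable across
#' particle brightness; the result sums to one.
#'
#' @param profiles matrix of profiles (rows = particles)
#' @return matrix of the same shape with unit row sums
#' @export
normalize_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  totals <- rowSums(profiles)
  bad <- which(totals <= 0)
  if (length(bad)) {
    stop_fmt("normalize_profiles: particle %d has non-positive total intensity", bad[1L])
  }
  profiles / totals
}

#' PCA embedding of spectral profiles
#'
#' Mean-centered principal component analysis. The sign of each component is
#' fixed by making its largest-magnitude loading positive, so embeddings are
#' reproducible across runs and platforms.
#'
#' @param profiles matrix of (normalized) profiles, rows = particles
#' @param n_components number of components to retain (default 2)
#' @return list of class `ember_embedding`: `coordinates` (n x k score
#'   matrix), `loadings`, `explained_variance` (fractions, non-increasing),
#'   `center`
#' @export
pca_embed <- function(profiles, n_components = 2L) {
  profiles <- as.matrix(profiles)
  if (n_components < 1L) stop("pca_embed: n_components must be >= 1", call. = FALSE)
  if (nrow(profiles) < n_components + 1L) {
    stop_fmt("pca_embed: need at least %d profiles for %d components, got %d",
             n_components + 1L, n_components, nrow(profiles))
  }
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_big <- which.max(abs(rot[, j]))
    if (rot[i_big, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  ev <- if (total_var > 0) pc$sdev[seq_len(k)]^2 / total_var else rep(0, k)
  structure(list(coordinates = sco, loadings = rot,
                 explained_variance = ev, center = pc$center),
            class = "ember_embedding")
}

#' Quadratic-discriminant discrimination accuracy
#'
#' Fits a quadratic discriminant (per-class means and covariances, empirical
#' class priors) to the PCA coordinates and returns the resubstitution
#' accuracy -- the fraction of particles assigned back to their true class.
#' This accuracy is the polymorph discrimination score for one dye/inducer
#' pair. An optional k-fold cross-validated accuracy is available for
#' sensitivity analysis.
#'
#' @param embedding an [pca_embed()] result, or a coordinate matrix
#' @param labels factor/character class labels, one per particle (two classes)
#' @param cv_folds `NULL` for resubstitution (default); an integer >= 2 for
#'   seeded k-fold cross-validation
#' @param seed RNG seed for the cross-validation fold split
#' @return accuracy in [0, 1]; the fitted `MASS::qda` model is attached as
#'   attribute `"model"` for decision-boundary plotting
#' @export
qda_discrimination <- function(embedding, labels, cv_folds = NULL, seed = 1L) {
  x <- if (inherits(embedding, "ember_embedding")) embedding$coordinates else as.matrix(embedding)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) {
    stop("qda_discrimination: exactly two classes required", call. = FALSE)
  }
  k <- ncol(x)
  counts <- table(labels)
  if (any(counts < k + 2L)) {
    stop_fmt("qda_discrimination: each class needs >= %d particles to estimate its covariance (have %s)",
             k + 2L, paste(counts, collapse = ", "))
  }
  fit <- tryCatch(MASS::qda(x, grouping = labels),
                  error = function(e) {
                    stop_fmt("qda_discrimination: class covariance is singular (%s); add particles or regularize the profiles",
                             conditionMessage(e))
                  })
  if (is.null(cv_folds)) {
    pred <- stats::predict(fit, x)$class
    acc <- mean(pred == labels)
  } else {
    stopifnot(cv_folds >= 2L)
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    fold <- sample(rep_len(seq_len(cv_folds), nrow(x)))
    hits <- logical(nrow(x))
    for (f in seq_len(cv_folds)) {
      te <- fold == f
      m <- MASS::qda(x[!te, , drop = FALSE], grouping = labels[!te])
      hits[te] <- stats::predict(m, x[te, , drop = FALSE])$class == labels[te]
    }
    acc <- mean(hits)
  }
  structure(acc, model = fit)
}

#' Average per-inducer accuracies into an overall discrimination score
#'
#' @param per_inducer named numeric vector or list mapping inducer id to
#'   accuracy in [0, 1]
#' @return list of class `discrimination_result`: `per_inducer_accuracy`,
#'   `overall` (their arithmetic mean)
#' @export
discrimination_score <- function(per_inducer) {
  acc <- unlist(per_inducer)
  if (!length(acc)) stop("discrimination_score: empty accuracy map", call. = FALSE)
  if (any(acc < 0 | acc > 1)) {
    stop("discrimination_score: accuracies must lie in [0, 1]", call. = FALSE)
  }
  structure(list(per_inducer_accuracy = acc, overall = mean(acc)),
            class = "discrimination_result")
}

#' Run the full spectral discrimination pipeline on two stacks
#'
#' Segments both stacks, extracts and normalizes particle profiles,
#' concatenates them, embeds with PCA, and scores class separation with a
#' quadratic discriminant.
#'
#' @param stack_a,stack_b [ember_stack()]s for the two fibril classes
#' @param labels length-2 character vector of class labels
#' @param n_components PCA components retained (default 2)
#' @param ... passed to [segment_particles()]
#' @return list: `accuracy`, `embedding`, `labels`, `n_particles`
#' @export
ember_pipeline <- function(stack_a, stack_b, labels = c("WT", "P301S"),
                           n_components = 2L, ...) {
  ma <- segment_particles(stack_a, ...)
  mb <- segment_particles(stack_b, ...)
  pa <- extract_profiles(stack_a, ma)
  pb <- extract_profiles(stack_b, mb)
  profs <- normalize_profiles(rbind(pa, pb))
  lab <- factor(rep(labels, c(nrow(pa), nrow(pb))), levels = labels)
  emb <- pca_embed(profs, n_components = n_components)
  acc <- qda_discrimination(emb, lab)
  list(accuracy = as.numeric(acc), embedding = emb, labels = lab,
       n_particles = c(nrow(pa), nrow(pb)))
}
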