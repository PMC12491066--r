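#' Derive a reproducible substream seed from a master seed and a key
#'
#' Generators draw noise from per-artifact substreams keyed by name, so
#' adding wells (or particles) to a design never perturbs the noise of the
#' existing ones.
#'
#' @param seed master integer seed
#' @param key character substream name
#' @return integer seed
#' @keywords internal
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Dye archetype parameter table
#'
#' The behavioural classes the generator plants: pan-fibril binders and
#' variant-selective binders (high initial fluorescence decaying through a
#' melt midpoint below 55 degC), monomer binders (react with unaggregated
#' protein), inert dyes (flat baseline), and bright artefacts (high flat
#' fluorescence in every well, including the no-protein control). RFU
#' magnitudes are parameterized around the scoring-rule thresholds so the
#' noise-free archetypes map onto known scores: binders earn 10 on their
#' targets, monomer binders earn 5 on the monomer control, inert and bright
#' dyes earn 0.
#'
#' @return data frame of archetype parameters
#' @export
dye_archetypes <- function() {
  data.frame(
    kind = c("pan_binder", "wt_selective", "p301s_selective",
             "monomer_binder", "inert", "bright_artifact"),
    amplitude = c(3000, 3000, 3000, 1200, 0, 0),
    melt_midpoint = c(45, 45, 45, 45, NA, NA),
    baseline = c(200, 200, 200, 200, 200, 5000),
    stringsAsFactors = FALSE
  )
}

# logistic melt decay: high plateau at low temperature, decaying through the
# midpoint; width in degrees C
melt_decay <- function(temps, baseline, amplitude, midpoint, width = 3) {
  baseline + amplitude / (1 + exp((temps - midpoint) / width))
}

#' Intended noise-free well score for an archetype/sample pairing
#'
#' The closed-form oracle counterpart of the generator: which score the
#' scoring rules assign to each archetype's noise-free curves.
#'
#' @param kind archetype kind
#' @param sample_type `"fibril"` or `"monomer"`
#' @param protein_variant fibril variant (`"WT"`/`"P301S"`)
#' @return integer intended well score
#' @export
intended_score <- function(kind, sample_type, protein_variant = NA_character_) {
  if (sample_type == "fibril") {
    switch(kind,
           pan_binder = 10L,
           wt_selective = if (identical(protein_variant, "WT")) 10L else 0L,
           p301s_selective = if (identical(protein_variant, "P301S")) 10L else 0L,
           0L)
  } else {
    if (kind == "monomer_binder") 5L else 0L
  }
}

#' Default fibril condition table for simulated screens
#'
#' WT and P301S protein variants crossed with `n_inducers` polyanion
#' inducers; the full design (13 inducers) gives the 26 fibril samples of
#' the screening campaign.
#'
#' @param n_inducers number of polyanion inducers per variant
#' @return data frame with `protein_variant` and `inducer_id`
#' @export
default_conditions <- function(n_inducers = 13L) {
  data.frame(protein_variant = rep(c("WT", "P301S"), each = n_inducers),
             inducer_id = rep(seq_len(n_inducers), 2L),
             stringsAsFactors = FALSE)
}

#' Simulate a two-replicate paDSF screen with controls and ground truth
#'
#' Emulates the screen design: `n_dyes` dyes against fibril samples formed
#' from each (variant, inducer) condition, plus the three control types
#' (no-protein, polyanion-only, tau monomer), read in six optical channels
#' over the 25-95 degC ramp, in two biological replicates. Archetypes are
#' fixed across replicates; only the noise stream differs. Binder dyes are
#' active in the FAM channel; all other curves are flat baselines. The same
#' seed reproduces the output bit for bit.
#'
#' @param n_dyes number of dyes (default 306, the library size)
#' @param conditions data frame with `protein_variant` and `inducer_id`
#'   columns (default: WT and P301S against 13 inducers, 26 samples)
#' @param archetype_mix named proportions over [dye_archetypes()] kinds;
#'   must sum to 1
#' @param noise_sd additive Gaussian noise on every curve (RFU)
#' @param seed master seed
#' @param ramp temperature grid
#' @return list: `replicates` (two [screen_run()]s), `controls` (matching
#'   control [screen_run()]s), `truth` (list with `dyes`, `intended`,
#'   `expected_hits`)
#' @export
gen_screen <- function(n_dyes = 306L,
                       conditions = default_conditions(),
                       archetype_mix = c(pan_binder = 0.02, wt_selective = 0.02,
                                         p301s_selective = 0.02,
                                         monomer_binder = 0.03,
                                         bright_artifact = 0.03, inert = 0.88),
                       noise_sd = 0, seed = 1L, ramp = default_ramp()) {
  if (!nrow(conditions)) stop("gen_screen: empty condition list", call. = FALSE)
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("gen_screen: archetype_mix must sum to 1", call. = FALSE)
  }
  kinds_avail <- dye_archetypes()$kind
  if (!all(names(archetype_mix) %in% kinds_avail)) {
    stop("gen_screen: unknown archetype in mix", call. = FALSE)
  }
  dye_ids <- sprintf("D%03d", seq_len(n_dyes))
  counts <- floor(archetype_mix * n_dyes)
  # distribute the remainder by largest fractional part, ties by name order
  rem <- n_dyes - sum(counts)
  frac <- archetype_mix * n_dyes - counts
  bump <- order(-frac, names(archetype_mix))[seq_len(rem)]
  counts[bump] <- counts[bump] + 1L
  kinds <- rep(names(archetype_mix), counts)
  kinds <- with_seed(derive_seed(seed, "archetypes"), sample(kinds))
  arch <- dye_archetypes()
  params <- arch[match(kinds, arch$kind), , drop = FALSE]

  channels <- names(padsf_channels())
  active_channel <- "FAM"

  curve_set <- function(dye_i, well_key, sample_type, variant) {
    kind <- kinds[dye_i]
    p <- params[dye_i, ]
    noise_seed <- derive_seed(seed, well_key)
    with_seed(noise_seed, {
      lapply(stats::setNames(channels, channels), function(ch) {
        active <- ch == active_channel && (
          (sample_type == "fibril" &&
             intended_score(kind, "fibril", variant) > 0L) ||
            (sample_type == "monomer" && kind == "monomer_binder"))
        y <- if (active) {
          melt_decay(ramp, p$baseline, p$amplitude, p$melt_midpoint)
        } else {
          rep(p$baseline, length(ramp))
        }
        if (noise_sd > 0) y <- y + stats::rnorm(length(ramp), 0, noise_sd)
        melt_curve(ramp, y, ch)
      })
    })
  }

  build_replicate <- function(rep_idx) {
    sample_wells <- list()
    control_wells <- list()
    for (i in seq_len(n_dyes)) {
      d <- dye_ids[i]
      for (j in seq_len(nrow(conditions))) {
        v <- conditions$protein_variant[j]; ind <- conditions$inducer_id[j]
        sid <- sprintf("%s_ind%02d", v, ind)
        key <- sprintf("r%d/%s/%s/fibril", rep_idx, d, sid)
        sample_wells[[length(sample_wells) + 1L]] <-
          screen_well(d, sid, "fibril", curve_set(i, key, "fibril", v),
                      protein_variant = v, inducer_id = ind)
      }
      key <- sprintf("r%d/%s/monomer", rep_idx, d)
      sample_wells[[length(sample_wells) + 1L]] <-
        screen_well(d, "tau_monomer", "monomer",
                    curve_set(i, key, "monomer", NA_character_))
      key <- sprintf("r%d/%s/no_protein", rep_idx, d)
      control_wells[[length(control_wells) + 1L]] <-
        screen_well(d, "no_protein", "no_protein",
                    curve_set(i, key, "no_protein", NA_character_))
      for (ind in unique(conditions$inducer_id)) {
        key <- sprintf("r%d/%s/polyanion%02d", rep_idx, d, ind)
        control_wells[[length(control_wells) + 1L]] <-
          screen_well(d, sprintf("polyanion_%02d", ind), "polyanion_only",
                      curve_set(i, key, "polyanion_only", NA_character_),
                      inducer_id = ind)
      }
    }
    list(run = screen_run(sprintf("sim_rep%d", rep_idx), rep_idx, sample_wells),
         controls = screen_run(sprintf("sim_rep%d_controls", rep_idx), rep_idx,
                               control_wells))
  }

  r1 <- build_replicate(1L)
  r2 <- build_replicate(2L)

  intended <- do.call(rbind, lapply(seq_len(n_dyes), function(i) {
    fib <- data.frame(
      dye_id = dye_ids[i],
      sample_id = sprintf("%s_ind%02d", conditions$protein_variant,
                          conditions$inducer_id),
      sample_type = "fibril",
      intended_score = vapply(seq_len(nrow(conditions)), function(j)
        intended_score(kinds[i], "fibril", conditions$protein_variant[j]),
        integer(1)),
      stringsAsFactors = FALSE)
    rbind(fib, data.frame(dye_id = dye_ids[i], sample_id = "tau_monomer",
                          sample_type = "monomer",
                          intended_score = intended_score(kinds[i], "monomer"),
                          stringsAsFactors = FALSE))
  }))
  rownames(intended) <- NULL
  truth <- list(
    dyes = data.frame(dye_id = dye_ids, archetype = kinds,
                      stringsAsFactors = FALSE),
    intended = intended,
    expected_hits = dye_ids[kinds %in% c("pan_binder", "wt_selective",
                                         "p301s_selective")]
  )
  list(replicates = list(r1$run, r2$run),
       controls = list(r1$controls, r2$controls),
       truth = truth)
}

#' Simulate a pair of multispectral particle stacks with a spectral shift
#'
#' Particles are Gaussian intensity blobs placed on a jittered cell grid (so
#' they never overlap). Each particle's per-channel intensity follows a
#' bivariate Gaussian response over (excitation, emission-midpoint)
#' wavelength, centred at `peak_ex_em` for class A and shifted by `shift_nm`
#' in both coordinates for class B, evaluated on the scan grid, on top of a
#' constant detector background, plus i.i.d. Gaussian noise. A shift of 0
#' makes the two classes spectrally identical; 60 nm separates them cleanly.
#'
#' @param n_particles_per_class particles per class (must fit the cell grid)
#' @param image_size image side in pixels
#' @param peak_ex_em length-2 numeric: spectral peak (ex, em) in nm, class A
#' @param shift_nm spectral shift of class B's peak (nm)
#' @param noise_sd additive Gaussian noise s.d. (intensity units)
#' @param amplitude peak particle intensity above background
#' @param blob_sigma_px Gaussian blob s.d. in pixels
#' @param background constant detector background level
#' @param response_sigma_nm s.d. of the spectral response Gaussian (nm)
#' @param grid scan-channel grid (default the 128-channel protocol)
#' @param labels class labels, length 2
#' @param seed master seed
#' @return list: `stacks` (named list of two [ember_stack()]s), `truth`
#'   (particle table with centres, class, per-class peaks, `shift_nm`)
#' @export
gen_ember <- function(n_particles_per_class = 40L, image_size = 96L,
                      peak_ex_em = c(520, 560), shift_nm = 0,
                      noise_sd = 0, amplitude = 1000, blob_sigma_px = 1.8,
                      background = 200, response_sigma_nm = 60,
                      grid = build_scan_grid(), labels = c("WT", "P301S"),
                      seed = 1L) {
  cell <- 12L
  per_side <- image_size %/% cell
  if (n_particles_per_class > per_side^2) {
    stop_fmt("gen_ember: %d particles per class do not fit a %dx%d image without overlap",
             n_particles_per_class, image_size, image_size)
  }
  ex_rng <- range(grid$ex_nm); em_rng <- range(grid$em_mid_nm)
  clamp_peak <- function(peak) {
    cl <- c(min(max(peak[1L], ex_rng[1L]), ex_rng[2L]),
            min(max(peak[2L], em_rng[1L]), em_rng[2L]))
    if (any(cl != peak)) {
      warning(sprintf("spectral peak (%g, %g) nm outside the scan grid; clamped to (%g, %g)",
                      peak[1L], peak[2L], cl[1L], cl[2L]), call. = FALSE)
    }
    cl
  }
  peaks <- list(clamp_peak(peak_ex_em), clamp_peak(peak_ex_em + shift_nm))

  one_stack <- function(class_i) {
    lbl <- labels[class_i]
    n <- n_particles_per_class
    pk <- peaks[[class_i]]
    with_seed(derive_seed(seed, paste0("ember/", lbl)), {
      if (n > 0L) {
        cells <- sample(per_side^2, n)
        cr <- (cells - 1L) %/% per_side
        cc <- (cells - 1L) %% per_side
        centers <- cbind(row = cr * cell + cell / 2 + stats::runif(n, -2, 2),
                         col = cc * cell + cell / 2 + stats::runif(n, -2, 2))
        amps <- amplitude * stats::runif(n, 0.8, 1.2)
      } else {
        centers <- matrix(numeric(0), 0L, 2L)
        amps <- numeric(0)
      }
      px_r <- matrix(seq_len(image_size), image_size, image_size)
      px_c <- t(px_r)
      blobs <- vapply(seq_len(n), function(p) {
        as.vector(amps[p] * exp(-((px_r - centers[p, 1L])^2 +
                                    (px_c - centers[p, 2L])^2) /
                                  (2 * blob_sigma_px^2)))
      }, numeric(image_size^2))
      resp <- exp(-((grid$ex_nm - pk[1L])^2 + (grid$em_mid_nm - pk[2L])^2) /
                    (2 * response_sigma_nm^2))
      flat <- matrix(background, image_size^2, nrow(grid))
      # every particle in a class shares the spectral response, so the stack
      # is background + (summed blob image) outer (response vector)
      if (n > 0L) flat <- flat + rowSums(matrix(blobs, ncol = n)) %o% resp
      if (noise_sd > 0) {
        flat <- flat + stats::rnorm(length(flat), 0, noise_sd)
      }
      list(stack = ember_stack(grid,
                               array(flat, dim = c(image_size, image_size, nrow(grid))),
                               condition = list(protein_variant = lbl)),
           centers = centers, amps = amps)
    })
  }

  a <- one_stack(1L); b <- one_stack(2L)
  truth_particles <- rbind(
    if (nrow(a$centers)) data.frame(class = labels[1L], row = a$centers[, 1L],
                                    col = a$centers[, 2L], amplitude = a$amps),
    if (nrow(b$centers)) data.frame(class = labels[2L], row = b$centers[, 1L],
                                    col = b$centers[, 2L], amplitude = b$amps))
  list(stacks = stats::setNames(list(a$stack, b$stack), labels),
       truth = list(particles = truth_particles, shift_nm = shift_nm,
                    peaks = peaks, blob_sigma_px = blob_sigma_px,
                    background = background))
}

#' Simulate a logistic aggregation curve
#'
#' `baseline + plateau / (1 + exp(-(t - t_mid) / rate))` with additive
#' Gaussian noise, sampled on a regular grid: the canonical
#' lag/growth/plateau shape of an amyloid aggregation trace.
#'
#' @param t_mid_h true half-time (hours)
#' @param rate_h growth time constant (hours)
#' @param plateau signal amplitude above baseline (RFU); 0 gives a
#'   degenerate constant curve
#' @param baseline starting signal (RFU)
#' @param noise_sd additive Gaussian noise s.d. (RFU)
#' @param sampling_dt_h sampling interval (hours)
#' @param t_max_h last timepoint (hours; default 48, the assay duration)
#' @param channel,dye_id,condition_id metadata for the generated read
#' @param seed seed for the noise stream
#' @return list: `read` (a [kinetic_read()]), `truth` (the curve parameters)
#' @export
gen_kinetics <- function(t_mid_h = 12, rate_h = 1.5, plateau = 3000,
                         baseline = 200, noise_sd = 0, sampling_dt_h = 0.5,
                         t_max_h = 48, channel = "ex444",
                         dye_id = "simdye", condition_id = "simcond",
                         seed = 1L) {
  stopifnot(sampling_dt_h > 0)
  times <- seq(0, t_max_h, by = sampling_dt_h)
  y <- baseline + plateau / (1 + exp(-(times - t_mid_h) / rate_h))
  if (noise_sd > 0) {
    y <- y + with_seed(derive_seed(seed, "kinetics"),
                       stats::rnorm(length(times), 0, noise_sd))
  }
  list(read = kinetic_read(times, y, channel, dye_id, condition_id),
       truth = list(t_mid_h = t_mid_h, rate_h = rate_h, plateau = plateau,
                    baseline = baseline))
}
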