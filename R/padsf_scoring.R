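#' Curve summary statistics consumed by the scoring rules
#'
#' The four statistics the threshold scoring rules test: the raw curve's
#' maximum and minimum fluorescence, the temperature at which the maximum
#' occurs, and the amplitude (max minus min) of the buffer-subtracted curve.
#'
#' @param f_max maximum raw fluorescence (RFU)
#' @param f_min minimum raw fluorescence (RFU)
#' @param t_at_max temperature of the maximum (degrees C)
#' @param delta_f buffer-subtracted fluorescence amplitude (RFU)
#' @return an object of class `curve_summary`
#' @export
curve_summary <- function(f_max, f_min, t_at_max, delta_f) {
  vals <- c(f_max = f_max, f_min = f_min, t_at_max = t_at_max, delta_f = delta_f)
  if (any(!is.finite(vals))) {
    stop("curve_summary: all statistics must be finite", call. = FALSE)
  }
  if (f_max < f_min) stop("curve_summary: f_max < f_min", call. = FALSE)
  structure(as.list(vals), class = "curve_summary")
}

#' Subtract a matched control curve from a sample curve
#'
#' Pointwise sample minus control on the shared temperature grid. Used for
#' buffer subtraction: fibril wells subtract the matched polyanion-only
#' control, monomer wells the no-protein control.
#'
#' @param sample,control [melt_curve()]s on identical grids and channel
#' @param tol temperature grid comparison tolerance (degrees C)
#' @return a [melt_curve()] of the differences
#' @export
subtract_control <- function(sample, control, tol = 1e-6) {
  if (!identical(sample$channel, control$channel)) {
    stop_fmt("subtract_control: channel mismatch (%s vs %s)",
             sample$channel, control$channel)
  }
  if (length(sample$temperatures_c) != length(control$temperatures_c) ||
      max(abs(sample$temperatures_c - control$temperatures_c)) > tol) {
    stop_fmt("subtract_control: temperature grids differ (sample %g-%g vs control %g-%g)",
             min(sample$temperatures_c), max(sample$temperatures_c),
             min(control$temperatures_c), max(control$temperatures_c))
  }
  melt_curve(sample$temperatures_c, sample$rfu - control$rfu, sample$channel)
}

#' Summarize a melt curve for scoring
#'
#' `f_max`, `f_min` and `t_at_max` are read from the raw sample curve (the
#' rules mention subtraction only for the amplitude); `delta_f` is the
#' max-minus-min amplitude of the control-subtracted curve. Ties in the
#' maximum resolve to the lowest temperature.
#'
#' @param sample raw sample [melt_curve()]
#' @param control matched control [melt_curve()] on the same grid/channel
#' @param delta_mode `"amplitude"` (max - min of the subtracted curve, the
#'   default) or `"max"` (its maximum alone)
#' @return a [curve_summary()]
#' @export
summarize_curve <- function(sample, control, delta_mode = c("amplitude", "max")) {
  delta_mode <- match.arg(delta_mode)
  if (any(!is.finite(sample$rfu)) || any(!is.finite(control$rfu))) {
    bad <- which(!is.finite(sample$rfu) | !is.finite(control$rfu))[1L]
    stop_fmt("summarize_curve: non-finite fluorescence at %g degC (channel %s)",
             sample$temperatures_c[bad], sample$channel)
  }
  diff_curve <- subtract_control(sample, control)
  i_max <- which.max(sample$rfu)  # which.max takes the first: lowest temperature
  delta_f <- if (delta_mode == "amplitude") {
    max(diff_curve$rfu) - min(diff_curve$rfu)
  } else {
    max(diff_curve$rfu)
  }
  curve_summary(f_max = max(sample$rfu), f_min = min(sample$rfu),
                t_at_max = sample$temperatures_c[i_max], delta_f = delta_f)
}

#' Score a curve summary with the threshold rule table
#'
#' Assigns one of \{10, 8, 5, 3, 1, 0\}, evaluating the rules in descending
#' score order with first match winning:
#'
#' * 10: f_max > 1000, f_min > -1000, delta_f > 2500, t_at_max < 55
#' * 8:  f_max > 1000, f_min > -2000, 1500 <= delta_f <= 2500, t_at_max < 55
#' * 5:  f_max > 1000, f_min > -2000, 1000 <= delta_f < 1500, t_at_max < 55
#' * 3:  f_max > 2000, f_min > -2000, delta_f > 2000, 55 <= t_at_max <= 70
#' * 1:  f_max > 2000, f_min > -2000, delta_f > 2000, t_at_max > 70
#' * otherwise 0
#'
#' "Between" bands are closed against the strict inequality of the
#' neighbouring rule, so the amplitude axis tiles without gaps: exactly
#' 2500 RFU belongs to the 8 band (the 10 rule needs > 2500) and exactly
#' 70 degC belongs to rule 3 (rule 1 needs > 70). The 8/5 boundary at
#' 1500 RFU is half-open, owned by the higher band.
#'
#' @param s a [curve_summary()]
#' @return integer score in \{0, 1, 3, 5, 8, 10\}
#' @export
score_summary <- function(s) {
  stopifnot(inherits(s, "curve_summary"))
  with(s, {
    if (f_max > 1000 && f_min > -1000 && delta_f > 2500 && t_at_max < 55) return(10L)
    if (f_max > 1000 && f_min > -2000 && delta_f >= 1500 && delta_f <= 2500 &&
        t_at_max < 55) return(8L)
    if (f_max > 1000 && f_min > -2000 && delta_f >= 1000 && delta_f < 1500 &&
        t_at_max < 55) return(5L)
    if (f_max > 2000 && f_min > -2000 && delta_f > 2000 &&
        t_at_max >= 55 && t_at_max <= 70) return(3L)
    if (f_max > 2000 && f_min > -2000 && delta_f > 2000 && t_at_max > 70) return(1L)
    0L
  })
}

#' Find the matched subtraction control for a well
#'
#' Fibril wells pair with the polyanion-only control for the same dye and
#' inducer; monomer wells pair with the no-protein control for the same dye.
#'
#' @param well a [screen_well()]
#' @param controls a [screen_run()] of control wells
#' @return the control [screen_well()]
#' @keywords internal
find_control <- function(well, controls) {
  ctrl <- switch(well$sample_type,
    fibril = {
      hit <- NULL
      for (w in controls$wells) {
        if (w$sample_type == "polyanion_only" && w$dye_id == well$dye_id &&
            identical(w$inducer_id, well$inducer_id)) { hit <- w; break }
      }
      hit
    },
    monomer = {
      hit <- NULL
      for (w in controls$wells) {
        if (w$sample_type == "no_protein" && w$dye_id == well$dye_id) { hit <- w; break }
      }
      hit
    },
    stop_fmt("score_well: no control pairing defined for sample_type '%s'",
             well$sample_type)
  )
  if (is.null(ctrl)) {
    stop_fmt("missing matched control for (dye %s, sample %s, type %s)",
             well$dye_id, well$sample_id, well$sample_type)
  }
  ctrl
}

#' Score one well across its optical channels
#'
#' Each channel is summarized and scored independently; the well score is the
#' maximum across channels (hits appear in different channels for different
#' dyes), and the first channel attaining that maximum is recorded.
#'
#' @param well a [screen_well()] of type fibril or monomer
#' @param controls a [screen_run()] holding the matched control wells
#' @return list with `channel_scores` (named integer vector), `well_score`,
#'   and `best_channel`
#' @export
score_well <- function(well, controls) {
  ctrl <- find_control(well, controls)
  ch <- names(well$curves)
  scores <- vapply(ch, function(nm) {
    if (is.null(ctrl$curves[[nm]])) {
      stop_fmt("missing control curve for (dye %s, sample %s, channel %s)",
               well$dye_id, well$sample_id, nm)
    }
    score_summary(summarize_curve(well$curves[[nm]], ctrl$curves[[nm]]))
  }, integer(1))
  best <- which.max(scores)
  list(channel_scores = scores, well_score = max(scores),
       best_channel = ch[best])
}

#' Score every scorable well of a replicate run
#'
#' Fibril and monomer wells are scored ([score_well()]); control wells supply
#' the subtraction baselines. Wells whose no-protein control already exceeds
#' `bright_rfu` at the ramp start are flagged (not removed): such bright dyes
#' are the most common source of misleading apparent RFU differences.
#'
#' @param run a [screen_run()]
#' @param controls a [screen_run()] of control wells (`no_protein` and
#'   `polyanion_only` types)
#' @param bright_rfu RFU threshold for the bright-dye flag (default 1000)
#' @return a `score_table`: data frame with one row per (dye, sample,
#'   channel) plus columns `well_score` and `best_channel` repeated within a
#'   well; attributes `replicate_index` and `bright_dyes`
#' @export
score_screen <- function(run, controls, bright_rfu = 1000) {
  scorable <- Filter(function(w) w$sample_type %in% c("fibril", "monomer"),
                     run$wells)
  if (!length(scorable)) stop("score_screen: no fibril or monomer wells", call. = FALSE)
  rows <- lapply(scorable, function(w) {
    sc <- score_well(w, controls)
    data.frame(dye_id = w$dye_id, sample_id = w$sample_id,
               sample_type = w$sample_type,
               channel = names(sc$channel_scores), score = sc$channel_scores,
               well_score = sc$well_score, best_channel = sc$best_channel,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab <- tab[order(tab$dye_id, tab$sample_id, tab$channel), , drop = FALSE]
  rownames(tab) <- NULL
  bright <- character(0)
  for (w in controls$wells) {
    if (w$sample_type == "no_protein" &&
        any(vapply(w$curves, function(cv) cv$rfu[1L] > bright_rfu, logical(1)))) {
      bright <- c(bright, w$dye_id)
    }
  }
  structure(tab, class = c("score_table", "data.frame"),
            replicate_index = run$replicate_index,
            bright_dyes = sort(unique(bright)))
}

#' Per-well scores of a score table
#'
#' @param st a `score_table` from [score_screen()]
#' @param sample_type optional filter (`"fibril"` or `"monomer"`)
#' @return data frame with one row per (dye, sample): `well_score`,
#'   `best_channel`
#' @export
well_scores <- function(st, sample_type = NULL) {
  if (!is.null(sample_type)) st <- st[st$sample_type == sample_type, , drop = FALSE]
  ws <- st[!duplicated(paste(st$dye_id, st$sample_id, st$sample_type, sep = "\r")),
           c("dye_id", "sample_id", "sample_type", "well_score", "best_channel"),
           drop = FALSE]
  rownames(ws) <- NULL
  ws
}

#' Sum well scores across two biological replicates
#'
#' Entrywise sum of per-well scores over the shared (dye, sample) keys,
#' giving the cumulative 0-20 score whose maximum (two top-scoring
#' replicates) is the hit bar.
#'
#' @param r1,r2 `score_table`s for replicates 1 and 2 (fibril wells used)
#' @return an `additive_score_table`: data frame (`dye_id`, `sample_id`,
#'   `additive_score`)
#' @export
aggregate_replicates <- function(r1, r2) {
  w1 <- well_scores(r1, "fibril"); w2 <- well_scores(r2, "fibril")
  k1 <- paste(w1$dye_id, w1$sample_id, sep = "\r")
  k2 <- paste(w2$dye_id, w2$sample_id, sep = "\r")
  only1 <- setdiff(k1, k2); only2 <- setdiff(k2, k1)
  if (length(only1) || length(only2)) {
    stop_fmt("aggregate_replicates: (dye, sample) keys not shared by both replicates: %s",
             paste(gsub("\r", ":", c(only1, only2)), collapse = ", "))
  }
  w1 <- w1[order(k1), , drop = FALSE]
  w2 <- w2[order(k2), , drop = FALSE]
  out <- data.frame(dye_id = w1$dye_id, sample_id = w1$sample_id,
                    additive_score = as.integer(w1$well_score + w2$well_score),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("additive_score_table", "data.frame"))
}

#' Triage additive scores into hit records
#'
#' A dye qualifies when its best additive score over samples reaches
#' `hit_cutoff` (default 20: top score in both replicates). Qualified dyes
#' whose monomer-control well scored at least `monomer_cutoff` in either
#' replicate are excluded (`monomer_flag = TRUE`): they also react with the
#' unaggregated protein. Manually curated dyes are appended with
#' `curated = TRUE` and pass through the same monomer filter.
#'
#' @param additive an [aggregate_replicates()] table
#' @param monomer_scores a `score_table` containing monomer wells, or a list
#'   of them (one per replicate)
#' @param hit_cutoff additive-score bar for automatic qualification
#' @param monomer_cutoff well score at/above which monomer reactivity excludes
#' @param curated_additions character vector of dye ids to append manually
#' @return data frame of hit records: `dye_id`, `supporting_samples`,
#'   `additive_score`, `monomer_flag`, `curated`, `hit`. The final hit list
#'   is the subset with `hit == TRUE` (never a flagged record).
#' @export
triage_hits <- function(additive, monomer_scores, hit_cutoff = 20L,
                        monomer_cutoff = 5L, curated_additions = character(0)) {
  if (inherits(monomer_scores, "score_table")) monomer_scores <- list(monomer_scores)
  mono <- do.call(rbind, lapply(monomer_scores, function(st) {
    ws <- well_scores(st, "monomer")
    ws$replicate <- attr(st, "replicate_index") %||% NA_integer_
    ws
  }))
  best <- tapply(additive$additive_score, additive$dye_id, max)
  qualified <- names(best)[best >= hit_cutoff]
  dyes <- unique(c(qualified, curated_additions))
  missing_mono <- setdiff(dyes, mono$dye_id)
  if (length(missing_mono)) {
    stop_fmt("triage_hits: no monomer-control score for dye(s) %s",
             paste(missing_mono, collapse = ", "))
  }
  recs <- lapply(dyes, function(d) {
    rows <- additive[additive$dye_id == d, , drop = FALSE]
    top <- max(rows$additive_score)
    supp <- rows$sample_id[rows$additive_score == top]
    mflag <- any(mono$well_score[mono$dye_id == d] >= monomer_cutoff)
    data.frame(dye_id = d,
               supporting_samples = paste(sort(supp), collapse = ";"),
               additive_score = as.integer(top),
               monomer_flag = mflag,
               curated = !(d %in% qualified),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(dye_id = character(0), supporting_samples = character(0),
                      additive_score = integer(0), monomer_flag = logical(0),
                      curated = logical(0), stringsAsFactors = FALSE)
  }
  out$hit <- !out$monomer_flag
  out <- out[order(out$dye_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hit rate as a percentage of the library
#'
#' `100 * n_hits / n_library`, rounded half-up to one decimal, the precision
#' used when reporting screen yields (e.g. 30 of 306 dyes -> 9.8).
#'
#' @param n_hits number of hits (vectorized)
#' @param n_library library size (> 0)
#' @return percentage with one decimal
#' @export
hit_rate <- function(n_hits, n_library) {
  if (any(n_library <= 0)) stop("hit_rate: library size must be positive", call. = FALSE)
  if (any(n_hits < 0 | n_hits > n_library)) {
    stop("hit_rate: n_hits must lie in [0, n_library]", call. = FALSE)
  }
  round_half_up(100 * n_hits / n_library, 1L)
}

#' Standard-deviation activity call for intensity-based screens
#'
#' A dye is called active against fibrils when its mean fibril signal rises
#' above the monomer-control mean by at least `k` monomer standard
#' deviations (inclusive: "at least k s.d."). Used for screens read at a
#' single emission maximum rather than over a melt ramp.
#'
#' @param fibril_signals replicate fluorescence values with fibrils
#' @param monomer_signals replicate fluorescence values with monomer only
#' @param k s.d. multiplier (default 3)
#' @return logical: active or not
#' @export
sd_activity_call <- function(fibril_signals, monomer_signals, k = 3) {
  if (length(monomer_signals) < 2L) {
    stop("sd_activity_call: need >= 2 monomer replicates", call. = FALSE)
  }
  s <- stats::sd(monomer_signals)
  if (!is.finite(s) || s <= 0) {
    stop("sd_activity_call: monomer replicates have zero variance; supply an explicit tolerance",
         call. = FALSE)
  }
  mean(fibril_signals) >= mean(monomer_signals) + k * s
}

#' Row/column ordering for a clustered additive-score heatmap
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' dye-by-sample additive score matrix, applied to rows and columns
#' independently. Rows and columns are pre-sorted by identifier so the
#' ordering is a deterministic function of the table contents.
#'
#' @param additive an [aggregate_replicates()] table
#' @return list with `row_order` (dye ids), `col_order` (sample ids), and
#'   the score `matrix` in that order
#' @export
cluster_order <- function(additive) {
  if (!nrow(additive)) stop("cluster_order: empty score table", call. = FALSE)
  dyes <- sort(unique(additive$dye_id))
  samples <- sort(unique(additive$sample_id))
  m <- matrix(0, length(dyes), length(samples), dimnames = list(dyes, samples))
  m[cbind(match(additive$dye_id, dyes), match(additive$sample_id, samples))] <-
    additive$additive_score
  ord1 <- function(mm) {
    if (nrow(mm) < 3L) return(seq_len(nrow(mm)))
    stats::hclust(stats::dist(mm), method = "average")$order
  }
  ro <- ord1(m); co <- ord1(t(m))
  list(row_order = dyes[ro], col_order = samples[co],
       matrix = m[ro, co, drop = FALSE])
}
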