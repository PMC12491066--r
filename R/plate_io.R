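#' Optical channel specification
#'
#' An excitation/emission wavelength pair, optionally with the plate reader's
#' emission cutoff filter.
#'
#' @param name channel label (e.g. `"FAM"`)
#' @param ex_nm excitation wavelength, nm
#' @param em_nm emission wavelength, nm
#' @param cutoff_nm optional emission cutoff wavelength, nm
#' @return an object of class `channel_spec`
#' @export
channel_spec <- function(name, ex_nm, em_nm, cutoff_nm = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(em_nm > ex_nm)) {
    stop_fmt("channel '%s': emission (%g nm) must exceed excitation (%g nm)",
             name, em_nm, ex_nm)
  }
  structure(list(name = name, ex_nm = as.numeric(ex_nm),
                 em_nm = as.numeric(em_nm), cutoff_nm = as.numeric(cutoff_nm)),
            class = "channel_spec")
}

#' Default optical channel tables
#'
#' `padsf_channels()` returns the six qPCR channels used for melt-curve
#' screening (FAM, JOE, TAMRA, ROX, Cy5, Cy5.5). `kinetic_channels()` returns
#' the four plate-reader channels used for real-time aggregation assays,
#' each with its emission cutoff.
#'
#' @return a named list of [channel_spec()] objects
#' @export
padsf_channels <- function() {
  specs <- list(
    channel_spec("FAM",   470, 520),
    channel_spec("JOE",   515, 545),
    channel_spec("TAMRA", 535, 580),
    channel_spec("ROX",   565, 605),
    channel_spec("Cy5",   630, 670),
    channel_spec("Cy5.5", 660, 705)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' @rdname padsf_channels
#' @export
kinetic_channels <- function() {
  specs <- list(
    channel_spec("ex444", 444, 482, 475),
    channel_spec("ex470", 470, 520, 515),
    channel_spec("ex515", 515, 545, 530),
    channel_spec("ex565", 565, 605, 590)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Default melt-ramp temperature grid
#'
#' 25 to 95 degrees C inclusive at 1 degree per cycle: 71 read points.
#'
#' @return numeric vector of temperatures (degrees C)
#' @export
default_ramp <- function() seq(25, 95, by = 1)

#' Look up a channel by name, case-insensitively
#'
#' Unknown channel names are permitted (a bare `channel_spec` with the
#' midpoint convention cannot be invented, so the name alone is carried) but
#' reported via a message so typos surface.
#'
#' @param name channel name
#' @param table named list of channel specs to match against
#' @return a `channel_spec`, or `NULL` when unknown
#' @keywords internal
match_channel <- function(name, table = padsf_channels()) {
  hit <- which(tolower(names(table)) == tolower(name))
  if (length(hit) == 1L) table[[hit]] else NULL
}

#' Melt curve for one well and optical channel
#'
#' @param temperatures_c strictly increasing temperature grid (degrees C)
#' @param rfu fluorescence values (relative fluorescence units), one per
#'   temperature
#' @param channel channel name or [channel_spec()]
#' @return an object of class `melt_curve`
#' @export
melt_curve <- function(temperatures_c, rfu, channel = "FAM") {
  temperatures_c <- as.numeric(temperatures_c)
  rfu <- as.numeric(rfu)
  if (length(temperatures_c) != length(rfu)) {
    stop_fmt("melt_curve: %d temperatures but %d fluorescence values",
             length(temperatures_c), length(rfu))
  }
  if (length(temperatures_c) < 2L || any(diff(temperatures_c) <= 0)) {
    stop("melt_curve: temperatures must be strictly increasing", call. = FALSE)
  }
  ch_name <- if (inherits(channel, "channel_spec")) channel$name else as.character(channel)
  structure(list(temperatures_c = temperatures_c, rfu = rfu, channel = ch_name),
            class = "melt_curve")
}

#' A screened well: one dye against one sample, curves in every channel
#'
#' @param dye_id dye identifier
#' @param sample_id sample identifier
#' @param sample_type one of `"fibril"`, `"no_protein"`, `"polyanion_only"`,
#'   `"monomer"`
#' @param curves named list of [melt_curve()]s, one per channel
#' @param protein_variant optional protein variant (`"WT"`, `"P301S"`, ...)
#' @param inducer_id optional polyanion inducer identifier; required for
#'   fibril wells, whose conformation depends on the inducer
#' @return an object of class `screen_well`
#' @export
screen_well <- function(dye_id, sample_id, sample_type, curves,
                        protein_variant = NA_character_, inducer_id = NA) {
  sample_type <- match.arg(sample_type,
                           c("fibril", "no_protein", "polyanion_only", "monomer"))
  if (sample_type == "fibril" && is.na(inducer_id)) {
    stop_fmt("well (%s, %s): fibril wells require an inducer_id", dye_id, sample_id)
  }
  stopifnot(is.list(curves), length(curves) >= 1L)
  names(curves) <- vapply(curves, `[[`, "", "channel")
  structure(list(dye_id = as.character(dye_id), sample_id = as.character(sample_id),
                 sample_type = sample_type,
                 protein_variant = as.character(protein_variant),
                 inducer_id = inducer_id, curves = curves),
            class = "screen_well")
}

#' A screen run: one replicate plate's worth of wells
#'
#' @param run_id run identifier
#' @param replicate_index biological replicate number (>= 1)
#' @param wells list of [screen_well()]s; (dye, sample, type) must be unique
#' @return an object of class `screen_run`
#' @export
screen_run <- function(run_id, replicate_index, wells) {
  stopifnot(replicate_index >= 1L)
  keys <- vapply(wells, function(w)
    paste(w$dye_id, w$sample_id, w$sample_type, sep = "\r"), "")
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1L]
    stop_fmt("screen_run '%s': duplicate well for (dye, sample, type) = (%s)",
             run_id, gsub("\r", ", ", dup))
  }
  structure(list(run_id = as.character(run_id),
                 replicate_index = as.integer(replicate_index),
                 wells = stats::setNames(wells, keys)),
            class = "screen_run")
}

#' Retrieve a well from a run
#'
#' @param run a [screen_run()]
#' @param dye_id,sample_id,sample_type well key
#' @return the matching [screen_well()], or `NULL`
#' @export
get_well <- function(run, dye_id, sample_id = NULL, sample_type = NULL) {
  for (w in run$wells) {
    if (w$dye_id != dye_id) next
    if (!is.null(sample_id) && w$sample_id != sample_id) next
    if (!is.null(sample_type) && w$sample_type != sample_type) next
    return(w)
  }
  NULL
}

#' Real-time aggregation read for one dye/condition/channel
#'
#' @param times_h strictly increasing time grid (hours)
#' @param rfu fluorescence values
#' @param channel channel name or [channel_spec()]
#' @param dye_id dye identifier
#' @param condition_id condition identifier (protein + inducer)
#' @return an object of class `kinetic_read`
#' @export
kinetic_read <- function(times_h, rfu, channel = "ex444",
                         dye_id = NA_character_, condition_id = NA_character_) {
  times_h <- as.numeric(times_h); rfu <- as.numeric(rfu)
  if (length(times_h) != length(rfu)) {
    stop("kinetic_read: times and values differ in length", call. = FALSE)
  }
  if (length(times_h) >= 2L && any(diff(times_h) <= 0)) {
    stop("kinetic_read: times must be strictly increasing", call. = FALSE)
  }
  ch_name <- if (inherits(channel, "channel_spec")) channel$name else as.character(channel)
  structure(list(times_h = times_h, rfu = rfu, channel = ch_name,
                 dye_id = as.character(dye_id),
                 condition_id = as.character(condition_id)),
            class = "kinetic_read")
}

screen_csv_columns <- c("run_id", "replicate", "well", "dye_id", "sample_id",
                        "sample_type", "channel", "temperature_c", "rfu")

#' Read a screen run from long-format CSV
#'
#' One row per (well, channel, temperature). Required columns:
#' `run_id, replicate, well, dye_id, sample_id, sample_type, channel,
#' temperature_c, rfu`. The optional columns `protein_variant` and
#' `inducer_id` are carried onto the wells when present.
#'
#' @param path CSV file path
#' @return a [screen_run()]
#' @export
read_screen_csv <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(screen_csv_columns, names(df))
  if (length(missing)) {
    stop_fmt("screen CSV %s: missing column(s) %s", path,
             paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_fmt("screen CSV %s: no data rows", path)
  run_id <- df$run_id[1L]
  replicate <- as.integer(df$replicate[1L])
  key <- paste(df$dye_id, df$sample_id, df$sample_type, sep = "\r")
  wells <- lapply(split(df, key), function(d) {
    curves <- lapply(split(d, d$channel), function(dc) {
      if (is.unsorted(dc$temperature_c, strictly = TRUE)) {
        stop_fmt("well (%s, %s) channel %s: temperatures not strictly increasing",
                 dc$dye_id[1L], dc$sample_id[1L], dc$channel[1L])
      }
      melt_curve(dc$temperature_c, dc$rfu, dc$channel[1L])
    })
    screen_well(d$dye_id[1L], d$sample_id[1L], d$sample_type[1L],
                curves = curves,
                protein_variant = if ("protein_variant" %in% names(d))
                  d$protein_variant[1L] else NA_character_,
                inducer_id = if ("inducer_id" %in% names(d))
                  d$inducer_id[1L] else NA)
  })
  screen_run(run_id, replicate, unname(wells))
}

#' Write a screen run as long-format CSV
#'
#' Rows are ordered by (dye, sample, type, channel, temperature) and numeric
#' fields printed at fixed precision (temperatures to 0.001 degC, RFU to
#' 1e-4), so writing is a stable, deterministic function of the parsed
#' values: write -> read -> write reproduces the file byte for byte.
#'
#' @param run a [screen_run()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_screen_csv <- function(run, path) {
  rows <- lapply(run$wells, function(w) {
    do.call(rbind, lapply(w$curves, function(cv) {
      data.frame(run_id = run$run_id, replicate = run$replicate_index,
                 well = paste(w$dye_id, w$sample_id, sep = ":"),
                 dye_id = w$dye_id, sample_id = w$sample_id,
                 sample_type = w$sample_type,
                 protein_variant = w$protein_variant,
                 inducer_id = if (is.na(w$inducer_id)) NA else w$inducer_id,
                 channel = cv$channel,
                 temperature_c = cv$temperatures_c, rfu = cv$rfu,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  ord <- order(df$dye_id, df$sample_id, df$sample_type, df$channel, df$temperature_c)
  df <- df[ord, , drop = FALSE]
  df$temperature_c <- sprintf("%.3f", df$temperature_c)
  df$rfu <- sprintf("%.4f", df$rfu)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read kinetic aggregation reads from CSV
#'
#' Required columns: `dye_id, condition_id, channel, time_h, rfu`. Rows are
#' grouped per (dye, condition, channel) and sorted by time; duplicate
#' timepoints within a group are an error.
#'
#' @param path CSV file path
#' @return a list of [kinetic_read()]s (empty for a header-only file)
#' @export
read_kinetics_csv <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dye_id", "condition_id", "channel", "time_h", "rfu")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_fmt("kinetics CSV %s: missing column(s) %s", path,
             paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(list())
  full_key <- paste(df$dye_id, df$condition_id, df$channel, df$time_h, sep = "/")
  if (anyDuplicated(full_key)) {
    dups <- unique(full_key[duplicated(full_key)])
    stop_fmt("kinetics CSV %s: duplicate (dye, condition, channel, time) rows: %s",
             path, paste(dups, collapse = "; "))
  }
  key <- paste(df$dye_id, df$condition_id, df$channel, sep = "\r")
  reads <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    kinetic_read(d$time_h, d$rfu, d$channel[1L], d$dye_id[1L], d$condition_id[1L])
  })
  unname(reads)
}

#' Write kinetic reads as long-format CSV
#'
#' @param reads list of [kinetic_read()]s
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_kinetics_csv <- function(reads, path) {
  df <- do.call(rbind, lapply(reads, function(r) {
    data.frame(dye_id = r$dye_id, condition_id = r$condition_id,
               channel = r$channel, time_h = r$times_h, rfu = r$rfu,
               stringsAsFactors = FALSE)
  }))
  ord <- order(df$dye_id, df$condition_id, df$channel, df$time_h)
  df <- df[ord, , drop = FALSE]
  df$time_h <- sprintf("%.4f", df$time_h)
  df$rfu <- sprintf("%.4f", df$rfu)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a screen run against the default melt-ramp protocol
#'
#' Checks that every curve sits on the expected grid (within `tol` degrees C)
#' and has the expected number of read points (71 for the default 25-95 degC
#' ramp at 1 degC per cycle).
#'
#' @param run a [screen_run()]
#' @param ramp expected temperature grid
#' @param tol temperature comparison tolerance, degrees C
#' @return `TRUE` invisibly; errors describe the offending well
#' @export
validate_ramp <- function(run, ramp = default_ramp(), tol = 1e-6) {
  for (w in run$wells) {
    for (cv in w$curves) {
      if (length(cv$temperatures_c) != length(ramp) ||
          max(abs(cv$temperatures_c - ramp)) > tol) {
        stop_fmt("well (%s, %s) channel %s: temperature grid does not match the %g-%g ramp",
                 w$dye_id, w$sample_id, cv$channel, min(ramp), max(ramp))
      }
    }
  }
  invisible(TRUE)
}
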