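#' Molecular fingerprint as a set of set-bit indices
#'
#' The diversity summaries operate on precomputed binary fingerprints; bit
#' generation from structures is left to an external toolkit, so the
#' contract begins at bit sets over a fixed universe.
#'
#' @param molecule_id molecule identifier
#' @param bits integer vector of set-bit indices (1-based)
#' @param universe_size fingerprint length (default 2048)
#' @return an object of class `fingerprint`
#' @export
fingerprint <- function(molecule_id, bits, universe_size = 2048L) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 1L || max(bits) > universe_size)) {
    stop_fmt("fingerprint %s: bit indices must lie in [1, %d]",
             molecule_id, universe_size)
  }
  structure(list(molecule_id = as.character(molecule_id), bits = bits,
                 universe_size = as.integer(universe_size)),
            class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits; 1 for identical
#' non-empty fingerprints, 0 for disjoint ones. Undefined (error) when both
#' fingerprints are empty.
#'
#' @param a,b [fingerprint()]s over the same universe
#' @return similarity in [0, 1]
#' @export
tanimoto <- function(a, b) {
  if (a$universe_size != b$universe_size) {
    stop_fmt("tanimoto: fingerprints %s and %s use different universes (%d vs %d bits)",
             a$molecule_id, b$molecule_id, a$universe_size, b$universe_size)
  }
  n_union <- length(union(a$bits, b$bits))
  if (n_union == 0L) {
    stop_fmt("tanimoto: both fingerprints (%s, %s) are empty; similarity undefined",
             a$molecule_id, b$molecule_id)
  }
  length(intersect(a$bits, b$bits)) / n_union
}

#' Pairwise Tanimoto similarity matrix and histogram
#'
#' Without a reference, computes the symmetric all-versus-all similarity
#' matrix (unit diagonal) and a histogram over the n(n-1)/2 upper-triangle
#' values. With a reference fingerprint (e.g. ThT), the histogram is built
#' over the n comparisons against the reference instead.
#'
#' @param fps list of [fingerprint()]s
#' @param reference optional reference [fingerprint()]
#' @param bin_width histogram bin width on [0, 1] (default 0.1); the last
#'   bin is right-closed so identity pairs are counted once
#' @return list: `matrix` (all-vs-all similarities), `values` (the compared
#'   similarities), `histogram` (data frame `lower`, `upper`, `count`)
#' @export
pairwise_similarity <- function(fps, reference = NULL, bin_width = 0.1) {
  n <- length(fps)
  if (n == 0L) stop("pairwise_similarity: no fingerprints", call. = FALSE)
  if (is.null(reference) && n < 2L) {
    stop("pairwise_similarity: need >= 2 fingerprints (or a reference)", call. = FALSE)
  }
  ids <- vapply(fps, `[[`, "", "molecule_id")
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- tanimoto(fps[[i]], fps[[j]])
      }
    }
  }
  values <- if (is.null(reference)) {
    m[upper.tri(m)]
  } else {
    vapply(fps, tanimoto, numeric(1), b = reference)
  }
  edges <- seq(0, 1, by = bin_width)
  if (abs(edges[length(edges)] - 1) > 1e-12) edges <- c(edges, 1)
  counts <- integer(length(edges) - 1L)
  for (k in seq_along(counts)) {
    last <- k == length(counts)
    counts[k] <- sum(values >= edges[k] &
                       (values < edges[k + 1L] | (last & values <= edges[k + 1L])))
  }
  list(matrix = m, values = values,
       histogram = data.frame(lower = edges[-length(edges)], upper = edges[-1L],
                              count = counts))
}

#' Read fingerprints from CSV
#'
#' Columns: `molecule_id`, `universe_size`, `bits` (semicolon-joined set-bit
#' indices; empty string for an empty fingerprint). A `smiles` column, if
#' present, is passed through untouched as an attribute.
#'
#' @param path CSV file path
#' @return list of [fingerprint()]s
#' @export
read_fingerprints_csv <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bits = "character"))
  need <- c("molecule_id", "universe_size", "bits")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_fmt("fingerprint CSV %s: missing column(s) %s", path,
             paste(missing, collapse = ", "))
  }
  fps <- lapply(seq_len(nrow(df)), function(i) {
    bits <- if (nzchar(df$bits[i])) as.integer(strsplit(df$bits[i], ";")[[1L]])
    else integer(0)
    fp <- fingerprint(df$molecule_id[i], bits, df$universe_size[i])
    if (!length(bits)) message("fingerprint ", fp$molecule_id, " is empty")
    fp
  })
  if ("smiles" %in% names(df)) attr(fps, "smiles") <- df$smiles
  fps
}
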