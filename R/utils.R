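#' Round half away from zero
#'
#' Decimal rounding where ties go up (1.25 -> 1.3 at one decimal), the
#' convention used for reported hit-rate percentages. Base `round()` rounds
#' half to even, which would print 26.1% as 26.0% for some counts.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values like 9.7999999... representing
  # exact halves are not dragged down by floating-point error
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Summed-area table of a matrix
#'
#' @param m numeric matrix
#' @return matrix of cumulative sums over rows and columns
#' @keywords internal
integral_image <- function(m) {
  apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
}

#' Local mean filter via an integral image
#'
#' Mean over a `half * 2 + 1` square window centred on each pixel, with the
#' window clamped at the image borders (the mean is taken over the pixels
#' that actually fall inside the image).
#'
#' @param m numeric matrix
#' @param half window half-width in pixels
#' @return matrix of local means, same dimensions as `m`
#' @keywords internal
local_mean <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- integral_image(m)
  # pad with a leading row/column of zeros so rectangle sums index cleanly
  ii <- rbind(0, cbind(0, ii))
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums <- ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
    ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  sums / counts
}

#' Label connected components of a binary matrix
#'
#' 8-connected component labeling by iterative minimum-label propagation;
#' converges in O(component diameter) vectorized passes. Labels are
#' renumbered 1..k in order of first (column-major) occurrence.
#'
#' @param bw logical or 0/1 matrix
#' @return integer matrix; 0 is background
#' @keywords internal
label_components <- function(bw) {
  bw <- bw != 0
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  lab[bw] <- seq_along(lab)[bw]  # unique seed label = linear pixel index
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  big <- .Machine$integer.max
  repeat {
    cur <- lab
    m <- lab
    m[m == 0L] <- big
    for (i in seq_len(nrow(offs))) {
      s <- shift(lab, offs[i, 1L], offs[i, 2L])
      s[s == 0L] <- big
      m <- pmin(m, s)
    }
    m[!bw] <- 0L
    m[m == big] <- 0L
    lab <- m
    if (identical(lab, cur)) break
  }
  ids <- unique(lab[lab > 0L])
  lab[] <- match(lab, c(0L, ids), nomatch = 1L) - 1L
  lab
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
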