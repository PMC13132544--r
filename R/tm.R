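# ---- 2D template matching evaluation utilities -----------------------------
#
# Scoring utilities for quantifying correction quality with 2D template
# matching (2DTM): the SNR of a cross-correlation stack over orientations,
# the one-false-positive detection threshold, and pairing of detections
# between two processing variants. The template search itself (projection,
# CTF, orientation grids) is outside this package; these utilities consume
# correlation stacks or detection tables produced elsewhere.

#' 2DTM SNR of a cross-correlation stack
#'
#' Converts the correlation values over sampled orientations at one location
#' to z-scores using their mean and sample standard deviation, and returns
#' the maximum z-score.
#'
#' @param values Numeric vector of cross-correlation values over
#'   orientations (length >= 2).
#' @return The 2DTM SNR (maximum z-score).
#' @export
tm_snr <- function(values) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) stop("degenerate orientation stack: zero standard deviation")
  (max(values) - mean(values)) / s
}

#' Expected false positive rate above a z threshold
#'
#' \code{r_f = erfc(z / sqrt(2)) / 2}, the upper tail of the standard
#' normal.
#'
#' @param z_th Threshold z-score.
#' @return The false positive rate per correlation sample.
#' @export
false_positive_rate <- function(z_th) {
  stats::pnorm(z_th, lower.tail = FALSE)
}

#' One-false-positive detection threshold
#'
#' Solves \code{n * erfc(z_th / sqrt(2)) / 2 = 1} for \code{z_th}: the
#' z-score at which a search over \code{n} correlation values expects
#' exactly one Gaussian-noise false positive.
#'
#' @param n_correlations Total number of correlation values searched
#'   (locations times orientations), >= 2.
#' @return The threshold \code{z_th}.
#' @export
one_fp_threshold <- function(n_correlations) {
  if (n_correlations < 2) stop("n_correlations must be >= 2")
  stats::qnorm(1 - 1 / n_correlations)
}

#' Pair detections between two processing variants
#'
#' Greedy nearest-neighbor pairing: the globally closest remaining pair
#' within \code{radius} is matched first; each detection is used at most
#' once. Per pair \code{dsnr = snr_a - snr_b}; the pair table is sorted by
#' \code{dsnr}. Unpaired detections are reported separately.
#'
#' @param a,b Data frames with columns \code{x}, \code{y}, \code{snr}.
#' @param radius Pairing radius in pixels (> 0).
#' @return List with \code{pairs} (data frame: locations, both SNRs,
#'   \code{dsnr}, sorted ascending), \code{unpaired_a}, \code{unpaired_b}.
#' @export
match_detections <- function(a, b, radius = 10) {
  stopifnot(radius > 0)
  need <- c("x", "y", "snr")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  na <- nrow(a); nb <- nrow(b)
  pairs <- NULL
  if (na > 0 && nb > 0) {
    d <- outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2
    d[d > radius^2] <- Inf
    used_a <- rep(FALSE, na); used_b <- rep(FALSE, nb)
    ia <- integer(0); ib <- integer(0)
    repeat {
      m <- which.min(d)
      if (length(m) == 0 || !is.finite(d[m])) break
      i <- (m - 1) %% na + 1
      j <- (m - 1) %/% na + 1
      ia <- c(ia, i); ib <- c(ib, j)
      used_a[i] <- TRUE; used_b[j] <- TRUE
      d[i, ] <- Inf; d[, j] <- Inf
    }
    if (length(ia)) {
      pairs <- data.frame(x_a = a$x[ia], y_a = a$y[ia],
                          x_b = b$x[ib], y_b = b$y[ib],
                          snr_a = a$snr[ia], snr_b = b$snr[ib],
                          dsnr = a$snr[ia] - b$snr[ib])
      pairs <- pairs[order(pairs$dsnr), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  } else {
    used_a <- rep(FALSE, na); used_b <- rep(FALSE, nb)
  }
  if (is.null(pairs)) {
    pairs <- data.frame(x_a = numeric(0), y_a = numeric(0),
                        x_b = numeric(0), y_b = numeric(0),
                        snr_a = numeric(0), snr_b = numeric(0),
                        dsnr = numeric(0))
  }
  list(pairs = pairs,
       unpaired_a = a[!used_a, , drop = FALSE],
       unpaired_b = b[!used_b, , drop = FALSE])
}

# ---- Detection tables in STAR format ---------------------------------------

#' Write a detection table as a single-block STAR file
#'
#' Columns written: coordinates in pixels and the 2DTM SNR (plus any Euler
#' angle columns present).
#'
#' @param det Data frame with columns \code{x}, \code{y}, \code{snr}.
#' @param path Output path.
#' @export
write_star_detections <- function(det, path) {
  cols <- intersect(c("x", "y", "snr", "phi", "theta", "psi"), names(det))
  labels <- c(x = "_unbendrCoordinateX", y = "_unbendrCoordinateY",
              snr = "_unbendrSNR", phi = "_unbendrAnglePhi",
              theta = "_unbendrAngleTheta", psi = "_unbendrAnglePsi")
  lines <- c("data_detections", "", "loop_",
             paste0(labels[cols], " #", seq_along(cols)),
             apply(det[cols], 1, function(r)
               paste(format(r, trim = TRUE, digits = 10), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a detection table written by [write_star_detections()]
#'
#' @param path STAR file path.
#' @return Data frame with the stored columns.
#' @export
read_star_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  loop_at <- which(trimws(lines) == "loop_")
  if (!length(loop_at)) stop("not a STAR loop file: ", path)
  body <- lines[(loop_at[1] + 1):length(lines)]
  is_label <- grepl("^_", trimws(body))
  labels <- sub(" .*$", "", trimws(body[is_label]))
  rows <- trimws(body[!is_label])
  rows <- rows[nzchar(rows)]
  rev_map <- c(`_unbendrCoordinateX` = "x", `_unbendrCoordinateY` = "y",
               `_unbendrSNR` = "snr", `_unbendrAnglePhi` = "phi",
               `_unbendrAngleTheta` = "theta", `_unbendrAnglePsi` = "psi")
  df <- utils::read.table(text = rows, col.names = rev_map[labels])
  df
}
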