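#' SPO11-oligo coverage map
#'
#' Container for per-base SPO11-oligo read counts over a reference window.
#' SPO11-oligo sequencing yields nucleotide-resolution maps of meiotic DSB
#' activity; these maps drive both the double-cut simulator (cut sites are
#' sampled in proportion to oligo counts) and the breakpoint-profile
#' statistics. Coordinates are 0-based, half-open throughout the package.
#'
#' @param chrom Chromosome name.
#' @param start 0-based start of the window covered by `counts`.
#' @param counts Numeric vector of per-base non-negative signal (raw reads or
#'   RPM), one value per base pair.
#' @param total_reads Optional library size; when supplied, [rpm()] converts
#'   counts to reads per million.
#' @return An object of class `spo_map` with fields `chrom`, `start`,
#'   `counts`, `total_reads`.
#' @examples
#' m <- spo_map("chr1", 1000L, c(0, 2, 5, 3, 0))
#' rpm(spo_map("chr1", 0L, c(1, 1), total_reads = 2e6))
#' @export
spo_map <- function(chrom, start, counts, total_reads = NULL) {
  stopifnot(length(chrom) == 1L, length(start) == 1L)
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("counts must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  structure(
    list(chrom = as.character(chrom), start = as.integer(start),
         counts = counts, total_reads = total_reads),
    class = "spo_map")
}

#' @export
print.spo_map <- function(x, ...) {
  cat(sprintf("<spo_map> %s:%d-%d  total signal %.4g\n",
              x$chrom, x$start, x$start + length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Convert a map to reads per million
#'
#' @param map A [spo_map()].
#' @return A `spo_map` whose counts are scaled by `1e6 / total_reads`; when
#'   `total_reads` is absent the counts are returned unchanged.
#' @export
rpm <- function(map) {
  stopifnot(inherits(map, "spo_map"))
  if (is.null(map$total_reads)) return(map)
  map$counts <- map$counts * 1e6 / map$total_reads
  map$total_reads <- NULL
  map
}

#' Hann-window smoothing
#'
#' Smooths a signal by convolution with a Hann kernel
#' `w[n] = sin^2(pi * n / (width - 1))`, `n = 0..width-1` (endpoints zero),
#' normalized to sum 1. At the edges the kernel is truncated and
#' renormalized, so the output has the same length as the input. Profile
#' figures in this field conventionally use 21-bp (fine structure) or 151-bp
#' (broad shape) windows.
#'
#' @param values Numeric vector.
#' @param width Odd positive integer window width in bp, at most
#'   `length(values)`.
#' @return Numeric vector of the same length as `values`.
#' @examples
#' smooth_hann(c(0, 0, 1, 0, 0), 3L)
#' @export
smooth_hann <- function(values, width) {
  values <- as.numeric(values)
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L || width %% 2L == 0L) {
    stop("width must be a positive odd integer")
  }
  if (width > length(values)) stop("width exceeds signal length")
  if (width == 1L) return(values)
  n <- seq_len(width) - 1L
  w <- sin(pi * n / (width - 1L))^2
  w <- w / sum(w)
  h <- (width - 1L) %/% 2L
  L <- length(values)
  # centered FIR for the interior (kernel is symmetric), then
  # truncate-and-renormalize at the edges
  out <- as.numeric(stats::filter(values, w, method = "convolution", sides = 2))
  for (i in seq_len(min(h, L))) {
    lo <- max(1L, i - h); hi <- min(L, i + h)
    ww <- w[(lo - i + h + 1L):(hi - i + h + 1L)]
    out[i] <- sum(values[lo:hi] * ww) / sum(ww)
    ir <- L - i + 1L
    lo <- max(1L, ir - h); hi <- min(L, ir + h)
    ww <- w[(lo - ir + h + 1L):(hi - ir + h + 1L)]
    out[ir] <- sum(values[lo:hi] * ww) / sum(ww)
  }
  out
}

#' Local normalization by windowed mean
#'
#' Divides the signal at each base pair by the mean signal within an odd
#' window centered on it (truncated at the edges). Used to place hotspots of
#' different strength on a common scale before averaging profiles across
#' hotspots. Windows whose mean is zero yield 0 with a warning.
#'
#' @param values Numeric vector.
#' @param window Odd positive integer window in bp (default 3001).
#' @return Numeric vector of the same length.
#' @export
local_normalize <- function(values, window = 3001L) {
  values <- as.numeric(values)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer")
  }
  L <- length(values)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(0L, seq_len(L) - 1L - h)
  hi <- pmin(L, seq_len(L) + h)
  means <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  out <- numeric(L)
  pos <- means > 0
  out[pos] <- values[pos] / means[pos]
  if (any(!pos)) warning(sum(!pos), " positions with zero-mean window set to 0")
  out
}

#' Anchor-relative signal profile
#'
#' A signal expressed relative to an anchor (a hotspot center at relative
#' position 0), the unit that [flip_and_average()] consumes.
#'
#' @param positions Integer positions relative to the anchor.
#' @param values Numeric signal values, same length as `positions`.
#' @return An object of class `signal_profile`.
#' @export
signal_profile <- function(positions, values) {
  positions <- as.integer(positions)
  values <- as.numeric(values)
  stopifnot(length(positions) == length(values))
  structure(list(positions = positions, values = values),
            class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, ...) {
  cat(sprintf("<signal_profile> %d positions [%d, %d]\n",
              length(x$positions), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Flip-and-average profiles
#'
#' Mirrors flagged profiles about relative position 0, then returns the
#' pointwise mean across profiles. Left-hotspot profiles in a hotspot pair
#' are flipped before cross-pair averaging so that "toward the partner
#' hotspot" points the same way in every profile.
#'
#' @param profiles List of [signal_profile()] objects sharing one
#'   anchor-relative grid.
#' @param flip_flags Logical vector, one per profile; `TRUE` mirrors that
#'   profile about 0 before averaging.
#' @return A [signal_profile()] on the shared grid.
#' @export
flip_and_average <- function(profiles, flip_flags) {
  stopifnot(length(profiles) >= 1L, length(flip_flags) == length(profiles))
  grid <- profiles[[1L]]$positions
  for (p in profiles) {
    if (!identical(p$positions, grid)) stop("profiles must share one grid")
  }
  vals <- vapply(seq_along(profiles), function(i) {
    v <- profiles[[i]]$values
    if (!flip_flags[i]) return(v)
    # mirror: value at position x becomes value at -x
    idx <- match(-grid, grid)
    if (anyNA(idx)) stop("grid is not symmetric; cannot flip")
    v[idx]
  }, numeric(length(grid)))
  signal_profile(grid, rowMeans(vals))
}

#' Hotspot call from a SPO11-oligo map
#'
#' Defines a hotspot within given bounds: the center is the argmax of the
#' 151-bp Hann-smoothed signal inside the bounds (leftmost on ties), and the
#' strength is the raw count sum inside the bounds, so strength does not
#' depend on the smoothing width.
#'
#' @param map A [spo_map()].
#' @param left,right Genomic bounds (0-based, half-open) within the map.
#' @param smooth_width Hann width used only to place the center (default 151;
#'   clipped to the bound span if necessary).
#' @return An object of class `hotspot` with fields `chrom`, `center`,
#'   `left`, `right`, `strength`.
#' @export
call_hotspot <- function(map, left, right, smooth_width = 151L) {
  stopifnot(inherits(map, "spo_map"))
  left <- as.integer(left); right <- as.integer(right)
  i0 <- left - map$start + 1L
  i1 <- right - map$start
  if (left >= right || i0 < 1L || i1 > length(map$counts)) {
    stop("bounds outside map")
  }
  seg <- map$counts[i0:i1]
  if (all(seg == 0)) stop("empty signal in bounds")
  w <- min(as.integer(smooth_width), length(seg))
  if (w %% 2L == 0L) w <- w - 1L
  sm <- smooth_hann(seg, w)
  center <- left + which.max(sm) - 1L  # which.max takes the leftmost maximum
  hotspot(map$chrom, center, left, right, strength = sum(seg))
}

#' Hotspot record
#'
#' @param chrom Chromosome name.
#' @param center Center position (bp).
#' @param left,right Bounds (0-based, half-open); `left < center < right`.
#' @param strength Total SPO11-oligo signal within the bounds.
#' @return An object of class `hotspot`.
#' @export
hotspot <- function(chrom, center, left, right, strength) {
  stopifnot(left < center, center < right, strength >= 0)
  structure(list(chrom = as.character(chrom), center = as.integer(center),
                 left = as.integer(left), right = as.integer(right),
                 strength = as.numeric(strength)),
            class = "hotspot")
}

#' @export
print.hotspot <- function(x, ...) {
  cat(sprintf("<hotspot> %s:%d-%d center %d strength %.4g\n",
              x$chrom, x$left, x$right, x$center, x$strength))
  invisible(x)
}
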