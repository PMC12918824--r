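#' Microhomology expected by chance
#'
#' Probability that a junction in random DNA exhibits exactly `x` bp of
#' maximal microhomology: `P(x) = (x + 1) (1/4)^x (3/4)^2`. The junction can
#' extend its shared sequence independently to the left and to the right,
#' each extension geometric with per-base match probability 1/4; `x + 1` is
#' the number of left/right splits summing to `x`. At `x = 0` this gives
#' 0.5625, i.e. 56 percent of junctions between random flanks are expected
#' to show no microhomology at all.
#'
#' @param x Integer (vector) of microhomology lengths, `>= 0`.
#' @return Probabilities, one per element of `x`.
#' @examples
#' microhomology_chance(0)   # 0.5625
#' sum(microhomology_chance(0:100))  # ~1
#' @export
microhomology_chance <- function(x) {
  if (any(x < 0) || any(x != floor(x))) stop("x must be a non-negative integer")
  (x + 1) * (1 / 4)^x * (3 / 4)^2
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by enumeration: with margins fixed, the
#' probabilities of all tables are hypergeometric, and the p-value is the
#' sum of probabilities of tables no more probable than the observed one
#' (within a 1e-12 relative slack for floating-point ties) — the
#' conventional two-sided rule.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p.value`, `odds_ratio` (sample OR), and the observed
#'   table.
#' @examples
#' fisher_exact(matrix(c(234, 570, 66, 243), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != floor(table))) {
    stop("cells must be non-negative integers")
  }
  if (sum(table) == 0) stop("empty table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  list(p.value = min(1, p),
       odds_ratio = (a * d) / (b * c),
       table = table)
}

#' Spread (dispersion) test for breakpoint distributions
#'
#' Brown-Forsythe variant of Levene's test: a one-way ANOVA on the absolute
#' deviations of each observation from its group median. Used to ask whether
#' one genotype's breakpoints are more spread around the hotspot center than
#' another's. Degenerate input (all groups constant) returns p = 1 with a
#' warning.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 3).
#' @return List with `statistic` (F), `df`, `p.value`, `method`.
#' @export
spread_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 0L) < 3L)) stop("each group needs n >= 3")
  z <- unlist(lapply(groups, function(g) abs(g - stats::median(g))))
  f <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (all(z == z[1L])) {
    warning("degenerate groups (no within-group deviation); p = 1")
    return(list(statistic = 0, df = c(length(groups) - 1L,
                                      length(z) - length(groups)),
                p.value = 1, method = "Brown-Forsythe Levene test"))
  }
  fit <- stats::oneway.test(z ~ f, var.equal = TRUE)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p.value = fit$p.value, method = "Brown-Forsythe Levene test")
}

#' Shift test for breakpoint distributions
#'
#' Wilcoxon rank-sum test (normal approximation with tie correction)
#' comparing two sets of relative breakpoint positions, reported with the
#' difference of medians — e.g. the rightward shift of end-joining
#' breakpoints relative to SPO11-oligo positions expected from double
#' cutting within a hotspot.
#'
#' @param a,b Numeric vectors (n >= 3 each).
#' @return List with `shift` (`median(b) - median(a)`), `statistic` (W),
#'   `p.value`, `method`.
#' @export
shift_test <- function(a, b) {
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(shift = stats::median(b) - stats::median(a),
       statistic = unname(wt$statistic), p.value = wt$p.value,
       method = "Wilcoxon rank-sum test (normal approximation)")
}

#' Fraction of breakpoints near the hotspot center
#'
#' @param positions Relative breakpoint positions (bp from center).
#' @param half_width Window half-width in bp (default 100, i.e. a 200-bp
#'   window around the center).
#' @return Fraction of positions with `|position| <= half_width`.
#' @export
center_window_fraction <- function(positions, half_width = 100) {
  if (length(positions) == 0L) stop("empty breakpoint set")
  mean(abs(positions) <= half_width)
}

#' Stratify deletion events by size
#'
#' Bins events by net deletion size and emits, per stratum, the event rows,
#' a smoothed breakpoint profile (both breakpoints pooled) and a Gaussian
#' kernel density of sizes (bandwidth 2 bp). The default edges bracket the
#' empirically recurring classes: ~13 bp (11-17), ~21 bp (18-24), ~30 bp
#' (25-45), ~60 bp (46-75), intermediate (76-199) and large (>= 200)
#' microdeletions.
#'
#' @param events `data.frame` with `size`, `left_bp`, `right_bp` (or
#'   relative positions in `left_rel`/`right_rel`).
#' @param edges Strictly increasing lower bin edges; a final `Inf` is
#'   appended if missing. Default `c(11, 18, 25, 46, 76, 200)`.
#' @param center Hotspot center used to express breakpoints relative to it
#'   (ignored when `left_rel` is present).
#' @param profile_width Hann width for the per-stratum breakpoint profile.
#' @param density_bw Kernel density bandwidth in bp (default 2).
#' @return An object of class `size_strata`: list with `bins`
#'   (`data.frame(label, lower, upper, n)`), `events` (list of per-bin
#'   `data.frame`s), `profiles` (list of [signal_profile()] or NULL),
#'   `densities` (list of `stats::density` or NULL).
#' @export
stratify_sizes <- function(events, edges = c(11, 18, 25, 46, 76, 200),
                           center = NULL, profile_width = 21L,
                           density_bw = 2) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (any(events$size < 1)) stop("sizes must be >= 1")
  breaks <- c(edges, Inf)
  if (min(events$size, na.rm = TRUE) < edges[1L]) {
    breaks <- c(-Inf, breaks)
  }
  lab <- function(lo, hi) {
    if (!is.finite(lo)) sprintf("<%g", hi)
    else if (!is.finite(hi)) sprintf(">=%g", lo)
    else sprintf("%g-%g", lo, hi - 1)
  }
  labels <- mapply(lab, breaks[-length(breaks)], breaks[-1L])
  bin <- cut(events$size, breaks = breaks, labels = labels, right = FALSE)
  if (!is.null(center)) {
    events$left_rel <- events$left_bp - center
    events$right_rel <- events$right_bp - center
  }
  per <- lapply(labels, function(lb) events[which(bin == lb), , drop = FALSE])
  names(per) <- labels
  profiles <- lapply(per, function(e) {
    if (nrow(e) == 0L || is.null(e$left_rel)) return(NULL)
    pos <- c(e$left_rel, e$right_rel)
    grid <- seq(min(pos) - 50L, max(pos) + 50L)
    counts <- tabulate(match(pos, grid), nbins = length(grid))
    w <- min(profile_width, length(grid))
    if (w %% 2L == 0L) w <- w - 1L
    signal_profile(grid, smooth_hann(counts, w))
  })
  densities <- lapply(per, function(e) {
    if (nrow(e) < 2L) return(NULL)
    stats::density(e$size, bw = density_bw)
  })
  structure(list(
    bins = data.frame(label = labels,
                      lower = breaks[-length(breaks)], upper = breaks[-1L],
                      n = vapply(per, nrow, 0L)),
    events = per, profiles = profiles, densities = densities),
    class = "size_strata")
}

#' @export
print.size_strata <- function(x, ...) {
  cat("<size_strata>\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Hotspot-strength-adjusted assay frequency
#'
#' The expected double-cutting weight of a hotspot pair is the product of
#' its two hotspot strengths (independent cutting). Observed frequencies are
#' adjusted onto the scale of a reference pair by multiplying with
#' `weight(reference) / weight(pair)`, so pairs of different strength become
#' comparable; the reference pair's adjusted frequency equals its observed
#' one, and the adjustment is invariant to rescaling all strengths by a
#' common factor.
#'
#' @param assay An [simulate_well_assay()] result (or any list with a
#'   `frequency` field), or a bare numeric frequency.
#' @param pair List/vector of the two [hotspot()]s (or numeric strengths) of
#'   the assayed pair.
#' @param reference_pair Same, for the reference pair.
#' @return Adjusted frequency (numeric).
#' @export
adjusted_frequency <- function(assay, pair, reference_pair) {
  freq <- if (is.numeric(assay)) assay else assay$frequency
  strength <- function(p) {
    vapply(p, function(h) if (inherits(h, "hotspot")) h$strength else
      as.numeric(h), numeric(1))
  }
  s <- strength(pair); sr <- strength(reference_pair)
  stopifnot(length(s) == 2L, length(sr) == 2L)
  if (any(s <= 0) || any(sr <= 0)) stop("hotspot strengths must be positive")
  freq * prod(sr) / prod(s)
}

#' Classify insertions at deletion junctions
#'
#' Inserted sequences of at least `min_len` bp are searched (exact match,
#' both orientations) against the supplied hotspot reference windows; hits
#' are annotated with the source hotspot and the distance of the insert
#' midpoint from the source hotspot center. Inserts matching the
#' reverse-complement of sequence flanking (or inside) their own deletion
#' are classified as local inverted insertions. Unmappable inserts are
#' reported as `unclassified` and excluded from source statistics.
#'
#' @param events `data.frame` with `ins_seq`, `left_bp`, `right_bp`.
#' @param sources Named list of source windows, each a list with `seq`
#'   (reference sequence), `start` (genomic offset) and `center`.
#' @param own_ref Reference sequence of the assayed locus (for inverted
#'   detection); `own_start` its genomic offset.
#' @param min_len Minimum insert length searched (default 15).
#' @param local_flank Bases around the deletion searched for inverted
#'   matches (default 500).
#' @return `data.frame` per event: `ins_class` (`none`, `ectopic`,
#'   `inverted`, `unclassified`), `source`, `source_dist` (insert midpoint to
#'   source center), `orientation`.
#' @export
classify_insertions <- function(events, sources = list(), own_ref = NULL,
                                own_start = 0L, min_len = 15L,
                                local_flank = 500L) {
  n <- nrow(events)
  out <- data.frame(ins_class = rep("none", n),
                    source = NA_character_, source_dist = NA_real_,
                    orientation = NA_character_)
  for (i in seq_len(n)) {
    ins <- events$ins_seq[i]
    if (is.na(ins) || !nzchar(ins)) next
    if (nchar(ins) < min_len) { out$ins_class[i] <- "unclassified"; next }
    # local inverted: reverse-complement match near / inside the deletion
    if (!is.null(own_ref)) {
      w0 <- max(0L, events$left_bp[i] - own_start - local_flank)
      w1 <- min(nchar(own_ref), events$right_bp[i] - own_start + local_flank)
      window <- substr0(own_ref, w0, w1)
      if (grepl(revcomp(ins), window, fixed = TRUE)) {
        out$ins_class[i] <- "inverted"
        out$orientation[i] <- "rev"
        next
      }
    }
    hit <- NULL
    for (nm in names(sources)) {
      src <- sources[[nm]]
      for (orient in c("fwd", "rev")) {
        pat <- if (orient == "fwd") ins else revcomp(ins)
        m <- regexpr(pat, src$seq, fixed = TRUE)
        if (m[1L] != -1L) {
          mid <- src$start + (m[1L] - 1L) + nchar(ins) / 2
          hit <- list(nm = nm, dist = mid - src$center, orient = orient)
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      out$ins_class[i] <- "unclassified"
    } else {
      out$ins_class[i] <- "ectopic"
      out$source[i] <- hit$nm
      out$source_dist[i] <- hit$dist
      out$orientation[i] <- hit$orient
    }
  }
  out
}
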