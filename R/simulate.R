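#' Simulate a hotspot-shaped SPO11-oligo map
#'
#' Emulates the shape of SPO11-oligo coverage at a DSB hotspot: a dominant
#' major cleavage peak flanked by weaker secondary peaks at the ~34-bp and
#' ~55-bp offsets typical of strong hotspots, over a diffuse background.
#' Counts are a multinomial draw of `total_reads` reads over the per-base
#' intensity, so the map carries realistic sampling noise.
#'
#' @param chrom Chromosome name.
#' @param center Genomic position of the major peak.
#' @param window Half-width of the simulated window in bp.
#' @param peaks `data.frame(offset, weight, sd)` of Gaussian components
#'   relative to `center`. The default places the major peak at 0 and
#'   secondary peaks at +34 and +55 bp.
#' @param background Weight of a broad (sd 150 bp) background component.
#' @param total_reads Reads drawn over the window.
#' @param seed Integer seed.
#' @return A [spo_map()] spanning `[center - window, center + window)`.
#' @export
simulate_spo11_map <- function(chrom = "chrSim", center = 2000L,
                               window = 1000L,
                               peaks = data.frame(
                                 offset = c(0, 34, 55),
                                 weight = c(1, 0.35, 0.5),
                                 sd = c(6, 5, 6)),
                               background = 0.15, total_reads = 50000L,
                               seed = 1L) {
  set.seed(seed)
  pos <- seq.int(center - window, center + window - 1L)
  rel <- pos - center
  lambda <- numeric(length(pos))
  for (i in seq_len(nrow(peaks))) {
    lambda <- lambda + peaks$weight[i] *
      stats::dnorm(rel, peaks$offset[i], peaks$sd[i])
  }
  lambda <- lambda + background * stats::dnorm(rel, 0, 150)
  counts <- as.numeric(stats::rmultinom(1L, total_reads, lambda / sum(lambda)))
  spo_map(chrom, center - window, counts, total_reads = total_reads)
}

#' Sample SPO11 cut sites from a map
#'
#' Cut positions are drawn from the map's counts normalized to a probability
#' distribution: the working premise is that end-joining breakpoints mirror
#' SPO11-oligo maps.
#'
#' @param map A [spo_map()].
#' @param n Number of positions to draw (0 allowed).
#' @param seed Integer seed.
#' @return Integer vector of genomic positions (0-based).
#' @export
sample_cut_sites <- function(map, n, seed = 1L) {
  stopifnot(inherits(map, "spo_map"), n >= 0)
  if (all(map$counts == 0)) stop("map has no signal")
  if (n == 0L) return(integer(0))
  set.seed(seed)
  pos <- map$start + seq_along(map$counts) - 1L
  sample(pos, n, replace = TRUE, prob = map$counts)
}

#' Double-cut spacing model
#'
#' Mixture over a 10-bp lattice of spacings, reflecting the helical-turn
#' periodicity of distances between the two DSBs of a double cut, with
#' per-component integer jitter (truncated normal) and a hard minimum
#' spacing. The default lattice starts at 21 bp — about two helical turns,
#' the smallest double cut supported by the data — with weights that make the
#' ~30-bp and ~60-bp deletion classes prominent.
#'
#' @param lattice Integer spacings of the mixture components.
#' @param weights Mixture weights (normalized internally).
#' @param jitter_sd SD of the integer jitter around each lattice point.
#' @param jitter_max Truncation bound for the jitter (bp).
#' @param min_spacing Hard minimum spacing; draws below it are resampled.
#' @return An object of class `spacing_model`.
#' @export
spacing_model <- function(lattice = c(21L, 31L, 41L, 51L),
                          weights = c(0.25, 0.35, 0.25, 0.15),
                          jitter_sd = 1.5, jitter_max = 4L,
                          min_spacing = 21L) {
  stopifnot(length(lattice) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  structure(list(lattice = as.integer(lattice),
                 weights = weights / sum(weights),
                 jitter_sd = jitter_sd, jitter_max = as.integer(jitter_max),
                 min_spacing = as.integer(min_spacing)),
            class = "spacing_model")
}

# one spacing draw (seed managed by caller); the mixture component is drawn
# once and only the jitter is resampled when the result falls below the
# minimum, so component weights are reproduced exactly
draw_spacing <- function(model, max_tries = 100L) {
  comp <- sample.int(length(model$lattice), 1L, prob = model$weights)
  if (model$jitter_sd <= 0) {
    s <- model$lattice[comp]
    if (s < model$min_spacing) stop("lattice point below minimum spacing")
    return(as.integer(s))
  }
  for (t in seq_len(max_tries)) {
    jj <- round(stats::rnorm(1L, 0, model$jitter_sd))
    j <- max(-model$jitter_max, min(model$jitter_max, jj))
    s <- model$lattice[comp] + j
    if (s >= model$min_spacing) return(as.integer(s))
  }
  as.integer(max(model$lattice[comp], model$min_spacing))
}

#' Simulate SPO11 double cuts
#'
#' Draws the left cut of each double cut from the map and its spacing from
#' the spacing model; both cleavages are recorded with the 2-nt 5' overhangs
#' that SPO11 leaves.
#'
#' @param map A [spo_map()] for the hotspot.
#' @param n Number of double cuts.
#' @param model A [spacing_model()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `chromatid`, `left_cut`, `right_cut`,
#'   `spacing` (all cut positions 0-based; the released fragment is
#'   `[left_cut, right_cut)`).
#' @export
make_double_cuts <- function(map, n, model = spacing_model(), seed = 1L) {
  left <- sample_cut_sites(map, n, seed = seed)
  set.seed(derive_seed(seed, "spacing"))
  spacing <- vapply(seq_len(n), function(i) draw_spacing(model), integer(1))
  data.frame(chromatid = seq_len(n), left_cut = left,
             right_cut = left + spacing, spacing = spacing)
}

#' End-joining repair model
#'
#' Two modes capture the genotype contrast at the heart of breakpoint-profile
#' comparisons:
#' * `"unresected"` — joining of SPO11 ends that were never resected
#'   (NHEJ-like): the junction stays at the cut positions up to 0-2 bp of
#'   microhomology from overhang complementarity, the 2-nt 5' overhangs being
#'   filled in before ligation.
#' * `"resected"` — ends resected before joining (MMEJ-like): resection
#'   lengths are gamma-distributed (mean ~1100 nt in mouse meiosis) and the
#'   junction is placed at a microhomology of at least `min_mh` bp found
#'   within the resected flanks, widening the deletion.
#'
#' @param mode `"unresected"` or `"resected"`.
#' @param mh_probs For unresected mode: probabilities of 0, 1, 2 bp of
#'   junction microhomology (normalized internally). The default follows the
#'   chance expectation for random flanks truncated at 2 bp.
#' @param resection_mean,resection_shape Gamma parameters for the per-end
#'   resection length (bp).
#' @param min_mh Minimum microhomology used to place a resected-mode
#'   junction.
#' @param max_search Cap on how far into the resected flanks the
#'   microhomology search extends (keeps events within an amplicon-sized
#'   window; resection can exceed the assayable window).
#' @return An object of class `repair_model`.
#' @export
repair_model <- function(mode = c("unresected", "resected"),
                         mh_probs = c(0.5625, 0.28125, 0.10546875),
                         resection_mean = 1100, resection_shape = 4,
                         min_mh = 3L, max_search = 250L) {
  mode <- match.arg(mode)
  stopifnot(length(mh_probs) == 3L, all(mh_probs >= 0), sum(mh_probs) > 0)
  structure(list(mode = mode, mh_probs = mh_probs / sum(mh_probs),
                 resection_mean = resection_mean,
                 resection_shape = resection_shape,
                 min_mh = as.integer(min_mh),
                 max_search = as.integer(max_search)),
            class = "repair_model")
}

#' Join the ends of double cuts into deletion events
#'
#' Applies a [repair_model()] to each double cut on a reference sequence and
#' returns ground-truth deletion events, canonicalized (leftmost junction
#' placement, maximal microhomology) with the same convention the caller
#' uses, so recovery can be asserted exactly.
#'
#' In unresected mode a microhomology offset `m` in 0-2 bp is drawn and the
#' deletion becomes `[left_cut, right_cut - m)` before canonicalization
#' (size `spacing - m`). In resected mode per-end resection lengths are
#' drawn, exact repeats of at least `min_mh` bp shared between the resected
#' left flank (left of the left cut) and right flank (right of the right cut)
#' are enumerated, and one is chosen at random as the junction, widening the
#' deletion; if none exists the junction falls back to a 0-bp joint at the
#' cuts and is tagged `fallback`.
#'
#' @param cuts `data.frame` from [make_double_cuts()].
#' @param ref Reference sequence (single string; cut coordinates index it,
#'   0-based).
#' @param repair A [repair_model()].
#' @param genotype Label stored on the events.
#' @param seed Integer seed.
#' @return A `data.frame` of events: `left_bp`, `right_bp` (canonical deleted
#'   interval), `size`, `mh_len`, `mh_seq`, `ins_seq`, `ins_class`
#'   (`"none"`), `genotype`, `fallback`.
#' @export
join_ends <- function(cuts, ref, repair = repair_model(), genotype = "sim",
                      seed = 1L) {
  set.seed(derive_seed(seed, paste0("join-", repair$mode)))
  n <- nrow(cuts)
  if (n == 0L) {
    return(data.frame(event_id = integer(0), left_bp = integer(0),
                      right_bp = integer(0), size = integer(0),
                      mh_len = integer(0), mh_seq = character(0),
                      ins_seq = character(0), ins_class = character(0),
                      genotype = character(0), fallback = logical(0)))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lc <- cuts$left_cut[i]; rc <- cuts$right_cut[i]
    fallback <- FALSE
    if (repair$mode == "unresected") {
      m <- sample(0:2, 1L, prob = repair$mh_probs)
      m <- min(m, rc - lc - 1L)  # keep the deletion non-empty
      left <- lc; right <- rc - m
    } else {
      rl <- pmin(round(stats::rgamma(2L, shape = repair$resection_shape,
                                     scale = repair$resection_mean /
                                       repair$resection_shape)),
                 repair$max_search)
      hit <- find_flank_microhomology(ref, lc, rc, rl[1L], rl[2L],
                                      repair$min_mh)
      if (is.null(hit)) {
        left <- lc; right <- rc; fallback <- TRUE
      } else {
        # repeat occupies [i, i+m) left and [j, j+m) right; retaining the
        # left copy and resuming after the right copy deletes [i+m, j+m)
        left <- hit$i + hit$m; right <- hit$j + hit$m
      }
    }
    cj <- canonicalize_junction(ref, left, right)
    out[[i]] <- data.frame(left_bp = cj$left, right_bp = cj$right,
                           size = cj$size, mh_len = cj$mh_len,
                           mh_seq = cj$mh_seq, ins_seq = "",
                           ins_class = "none", genotype = genotype,
                           fallback = fallback)
  }
  cbind(event_id = seq_len(n), do.call(rbind, out))
}

# enumerate exact shared k-mers (k >= min_mh) between the resected windows
# [lc - rl_l, lc) and [rc, rc + rl_r); returns one hit chosen at random
# (i, j = 0-based starts of the left/right copies, m = length) or NULL
find_flank_microhomology <- function(ref, lc, rc, rl_l, rl_r, min_mh) {
  win_l <- c(max(0L, lc - rl_l), lc)
  win_r <- c(rc, min(nchar(ref), rc + rl_r))
  if (diff(win_l) < min_mh || diff(win_r) < min_mh) return(NULL)
  left_seq <- substr0(ref, win_l[1L], win_l[2L])
  right_seq <- substr0(ref, win_r[1L], win_r[2L])
  k <- min_mh
  kmers_l <- substring(left_seq, seq_len(nchar(left_seq) - k + 1L),
                       seq_len(nchar(left_seq) - k + 1L) + k - 1L)
  kmers_r <- substring(right_seq, seq_len(nchar(right_seq) - k + 1L),
                       seq_len(nchar(right_seq) - k + 1L) + k - 1L)
  shared <- intersect(kmers_l, kmers_r)
  if (length(shared) == 0L) return(NULL)
  hits <- do.call(rbind, lapply(shared, function(km) {
    expand.grid(i = win_l[1L] + which(kmers_l == km) - 1L,
                j = win_r[1L] + which(kmers_r == km) - 1L)
  }))
  pick <- hits[sample.int(nrow(hits), 1L), ]
  i <- pick$i; j <- pick$j
  # extend the exact match as far as it goes
  m <- k
  while (i + m < lc && j + m < win_r[2L] &&
         substr(ref, i + m + 1L, i + m + 1L) ==
         substr(ref, j + m + 1L, j + m + 1L)) {
    m <- m + 1L
  }
  list(i = as.integer(i), j = as.integer(j), m = as.integer(m))
}

#' Add an ectopic or inverted insertion to a deletion event
#'
#' Two insertion classes are modeled:
#' * `"ectopic"` — a double-cut fragment released at another hotspot is
#'   captured at the junction, in either orientation; the source interval is
#'   recorded. Donors overlapping the deletion are rejected.
#' * `"inverted"` — a local segment (from inside the deleted interval) is
#'   reinserted in inverted orientation; candidate segments are scanned so
#'   that the junction carries at least 1 bp of microhomology at exactly one
#'   side, the signature of foldback-mediated reinsertion.
#'
#' @param event One-row event `data.frame` (see [join_ends()]).
#' @param ref Reference sequence the event lives on.
#' @param class `"ectopic"` or `"inverted"`.
#' @param donor_seq For ectopic mode: the donor fragment sequence (e.g. the
#'   released fragment of a double cut at another hotspot).
#' @param donor_source Label recorded as the donor's source.
#' @param orientation `"fwd"`, `"rev"`, or `"random"` (ectopic mode).
#' @param seed Integer seed.
#' @return The event row with `ins_seq`, `ins_class`, `ins_source`,
#'   `ins_orient` filled in (`mh_len` reset to 0: microhomology and inserted
#'   bases are mutually exclusive at a junction).
#' @export
make_insertion_event <- function(event, ref, class = c("ectopic", "inverted"),
                                 donor_seq = NULL, donor_source = NA_character_,
                                 orientation = "random", seed = 1L) {
  class <- match.arg(class)
  set.seed(derive_seed(seed, paste0("ins-", class)))
  ev <- event
  if (class == "ectopic") {
    if (is.null(donor_seq)) stop("ectopic mode needs a donor fragment")
    orient <- if (orientation == "random") {
      sample(c("fwd", "rev"), 1L)
    } else orientation
    ins <- if (orient == "rev") revcomp(donor_seq) else donor_seq
    ev$ins_orient <- orient
  } else {
    # inverted: local segment from inside the deletion, reverse-complemented;
    # scan candidate segments for >= 1 bp microhomology at exactly one side
    del_seq <- substr0(ref, ev$left_bp, ev$right_bp)
    L <- nchar(del_seq)
    if (L < 4L) stop("deletion too small to host an inverted insertion")
    lflank <- substr(ref, ev$left_bp, ev$left_bp)            # last retained base
    rflank <- substr(ref, ev$right_bp + 1L, ev$right_bp + 1L) # first resumed base
    found <- NULL
    for (t in seq_len(200L)) {
      len <- sample(3:max(3L, L - 1L), 1L)
      s0 <- sample.int(L - len + 1L, 1L) - 1L
      cand <- revcomp(substr0(del_seq, s0, s0 + len))
      mh_left <- substr(cand, 1L, 1L) == lflank
      mh_right <- substr(cand, len, len) == rflank
      if (xor(mh_left, mh_right)) {
        found <- list(ins = cand, src = c(s0, s0 + len),
                      side = if (mh_left) "left" else "right")
        break
      }
    }
    if (is.null(found)) stop("no inverted candidate with one-sided microhomology")
    ins <- found$ins
    donor_source <- sprintf("local:%d-%d",
                            ev$left_bp + found$src[1L],
                            ev$left_bp + found$src[2L])
    ev$ins_orient <- "rev"
  }
  ev$ins_seq <- ins
  ev$ins_class <- class
  ev$ins_source <- donor_source
  ev$mh_len <- 0L
  ev$mh_seq <- ""
  ev
}

#' Simulate a nested-PCR well assay
#'
#' Limiting-input screen: each well is seeded with a fixed number of haploid
#' genome equivalents and scored for deletion products; the per-genome
#' frequency estimator is total events / total genomes. Per-well event counts
#' are Poisson with mean `rate * genomes_per_well`. A fixed number of events
#' can be planted instead of drawn, which is how detection-limit arithmetic
#' (one positive among N wells) is expressed.
#'
#' @param rate Per-haploid-genome event frequency (>= 0).
#' @param wells Number of wells (default one 96-well plate; a full screen of
#'   ~4.8 million genomes uses 300 wells).
#' @param genomes_per_well Haploid genome equivalents per well (default
#'   16000).
#' @param planted Optional integer: plant exactly this many events (one per
#'   well from well 1 up), bypassing the Poisson draw.
#' @param seed Integer seed.
#' @return An object of class `assay_result`: `wells`, `genomes_per_well`,
#'   `positives` (data.frame well/events), `total_events`, `frequency`.
#' @export
simulate_well_assay <- function(rate, wells = 96L, genomes_per_well = 16000L,
                                planted = NULL, seed = 1L) {
  stopifnot(rate >= 0, wells >= 1, genomes_per_well >= 1)
  if (is.null(planted)) {
    set.seed(derive_seed(seed, "wells"))
    ev <- stats::rpois(wells, rate * genomes_per_well)
  } else {
    stopifnot(planted <= wells * genomes_per_well)
    ev <- integer(wells)
    full <- min(planted, wells)
    ev[seq_len(full)] <- 1L
    if (planted > wells) ev[1L] <- ev[1L] + (planted - wells)
  }
  total <- sum(ev)
  structure(list(
    wells = as.integer(wells),
    genomes_per_well = as.integer(genomes_per_well),
    positives = data.frame(well = which(ev > 0), events = ev[ev > 0]),
    total_events = total,
    frequency = total / (as.numeric(wells) * genomes_per_well)),
    class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("<assay_result> %d wells x %d genomes: %d events, frequency %.3g per haploid genome\n",
              x$wells, x$genomes_per_well, x$total_events, x$frequency))
  invisible(x)
}
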