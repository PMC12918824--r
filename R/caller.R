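#' Amplicon definition
#'
#' An amplicon is the unit of read grouping: a reference interval whose ends
#' are the PCR primer endpoints. The reference sequence of the interval is
#' stored so that alignment and junction parsing never need the full genome.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open amplicon interval.
#' @param seq Reference sequence of the interval (length `end - start`).
#' @param primer_len Primer length at each end (default 20).
#' @param name Amplicon id.
#' @return An object of class `amplicon_def`.
#' @export
amplicon_def <- function(chrom, start, end, seq, primer_len = 20L,
                         name = "amp1") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(end - start == nchar(seq), end - start >= 2L * primer_len)
  structure(list(chrom = chrom, start = start, end = end, seq = seq,
                 primer_len = as.integer(primer_len), name = name),
            class = "amplicon_def")
}

#' @export
print.amplicon_def <- function(x, ...) {
  cat(sprintf("<amplicon_def> %s %s:%d-%d (%d bp)\n",
              x$name, x$chrom, x$start, x$end, x$end - x$start))
  invisible(x)
}

#' Merge overlapping read pairs
#'
#' Finds the best ungapped overlap (at least `min_overlap` bp, at most
#' `max_mm_frac` mismatches) between R1 and the reverse complement of R2 and
#' builds a single consensus read, taking the higher-quality base at each
#' disagreement and the maximum quality at each overlap position. Pairs with
#' no acceptable overlap are passed through unmerged and excluded from
#' calling.
#'
#' @param pairs List from [read_fastq_pairs()] (or the simulator): `seq1`,
#'   `qual1`, `seq2`, `qual2`, `id`.
#' @param min_overlap Minimum overlap in bp (default 20).
#' @param max_mm_frac Maximum mismatch fraction in the overlap (default 0.10).
#' @return List with `merged` (`data.frame(id, seq, qual)`), `unmerged_ids`,
#'   and `n_input`.
#' @export
merge_pairs <- function(pairs, min_overlap = 20L, max_mm_frac = 0.10) {
  n <- length(pairs$seq1)
  stopifnot(length(pairs$seq2) == n,
            all(nchar(pairs$seq1) == nchar(pairs$qual1)),
            all(nchar(pairs$seq2) == nchar(pairs$qual2)))
  s2rc <- revcomp(pairs$seq2)
  q2rc <- vapply(pairs$qual2, function(q) {
    intToUtf8(rev(utf8ToInt(q)))
  }, "", USE.NAMES = FALSE)
  out_id <- character(n); out_seq <- character(n); out_qual <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    ov <- cpp_best_overlap(pairs$seq1[i], s2rc[i], min_overlap, max_mm_frac)
    if (ov$overlap == 0L) next
    o <- ov$overlap
    n1 <- nchar(pairs$seq1[i]); n2 <- nchar(s2rc[i])
    a_seq <- utf8ToInt(substr(pairs$seq1[i], n1 - o + 1L, n1))
    b_seq <- utf8ToInt(substr(s2rc[i], 1L, o))
    a_q <- utf8ToInt(substr(pairs$qual1[i], n1 - o + 1L, n1))
    b_q <- utf8ToInt(substr(q2rc[i], 1L, o))
    cons <- ifelse(a_seq == b_seq | a_q >= b_q, a_seq, b_seq)
    consq <- pmax(a_q, b_q)
    out_seq[i] <- paste0(substr(pairs$seq1[i], 1L, n1 - o),
                         intToUtf8(cons),
                         substr(s2rc[i], o + 1L, n2))
    out_qual[i] <- paste0(substr(pairs$qual1[i], 1L, n1 - o),
                          intToUtf8(consq),
                          substr(q2rc[i], o + 1L, n2))
    out_id[i] <- pairs$id[i]
    ok[i] <- TRUE
  }
  list(merged = data.frame(id = out_id[ok], seq = out_seq[ok],
                           qual = out_qual[ok]),
       unmerged_ids = pairs$id[!ok],
       n_input = n)
}

# Locate the outer endpoints of merged reads on the reference by exact
# terminal k-mer seeding (offsets 0 and k are tried, so a single sequencing
# error in the terminal seed does not lose the read). Returns 0-based
# half-open (start, end); NA when no seed places.
read_endpoints <- function(seqs, ref_seq, k = 20L) {
  locate <- function(patterns) {
    # first exact match position (1-based) of each pattern, NA if absent
    vapply(patterns, function(p) {
      m <- regexpr(p, ref_seq, fixed = TRUE)
      if (m[1L] == -1L) NA_integer_ else as.integer(m[1L])
    }, integer(1), USE.NAMES = FALSE)
  }
  L <- nchar(seqs)
  s <- locate(substr(seqs, 1L, k))
  retry <- is.na(s) & L >= 2L * k
  s[retry] <- locate(substr(seqs[retry], k + 1L, 2L * k)) - k
  e <- locate(substr(seqs, L - k + 1L, L))
  retry <- is.na(e) & L >= 2L * k
  e[retry] <- locate(substr(seqs[retry], L - 2L * k + 1L, L - k)) + k
  data.frame(start = s - 1L, end = e + k - 1L)  # to 0-based half-open
}

#' Ab initio amplicon inference from merged reads
#'
#' Clusters the outer endpoints of merged reads on the reference (tolerance
#' `tol` bp); endpoint clusters supported by at least `min_reads` reads
#' become amplicons, with coordinates at the modal endpoints. Reads whose
#' terminal seeds fail to place on the reference (e.g. shuffled sequence)
#' are excluded from clustering.
#'
#' @param merged `data.frame(id, seq, qual)` from [merge_pairs()].
#' @param ref_seq Reference sequence (single string).
#' @param ref_start Genomic position of `ref_seq`'s first base (0-based).
#' @param chrom Chromosome name for the resulting definitions.
#' @param tol Endpoint clustering tolerance in bp (default 5).
#' @param min_reads Minimum reads per cluster (default 10).
#' @param primer_len Primer length recorded on the definitions.
#' @return List of [amplicon_def()] objects (possibly empty, with a warning).
#' @export
infer_amplicons <- function(merged, ref_seq, ref_start = 0L, chrom = "chr1",
                            tol = 5L, min_reads = 10L, primer_len = 20L) {
  ep <- read_endpoints(merged$seq, ref_seq)
  keep <- !is.na(ep$start) & !is.na(ep$end)
  ep <- ep[keep, , drop = FALSE]
  if (nrow(ep) == 0L) {
    warning("no reads with placeable endpoints; no amplicons inferred")
    return(list())
  }
  # single-linkage 1-D clustering on start, then on end within start groups
  cluster1d <- function(x, tol) {
    o <- order(x)
    brk <- c(0L, which(diff(x[o]) > tol), length(x))
    g <- integer(length(x))
    for (i in seq_len(length(brk) - 1L)) {
      g[o[(brk[i] + 1L):brk[i + 1L]]] <- i
    }
    g
  }
  gs <- cluster1d(ep$start, tol)
  key <- paste(gs, stats::ave(ep$end, gs, FUN = function(e) cluster1d(e, tol)))
  tab <- table(key)
  out <- list()
  mode1 <- function(v) as.integer(names(sort(table(v), decreasing = TRUE))[1L])
  idx <- 0L
  for (kk in names(tab)[order(names(tab))]) {
    if (tab[[kk]] < min_reads) next
    sel <- key == kk
    s <- mode1(ep$start[sel]); e <- mode1(ep$end[sel])
    idx <- idx + 1L
    out[[idx]] <- amplicon_def(chrom, ref_start + s, ref_start + e,
                               substr0(ref_seq, s, e),
                               primer_len = primer_len,
                               name = sprintf("amp%d", idx))
  }
  if (length(out) == 0L) warning("no endpoint cluster met min_reads")
  out
}

#' Assign merged reads to amplicons by outer endpoints
#'
#' @param merged `data.frame(id, seq, qual)`.
#' @param amplicons List of [amplicon_def()].
#' @param ref_seq,ref_start Reference the amplicons live on.
#' @param tol Endpoint tolerance in bp.
#' @return Character vector of amplicon names (NA = unassigned).
#' @export
assign_amplicons <- function(merged, amplicons, ref_seq, ref_start = 0L,
                             tol = 5L) {
  ep <- read_endpoints(merged$seq, ref_seq)
  s <- ref_start + ep$start; e <- ref_start + ep$end
  out <- rep(NA_character_, nrow(merged))
  for (a in amplicons) {
    hit <- !is.na(s) & !is.na(e) &
      abs(s - a$start) <= tol & abs(e - a$end) <= tol
    out[hit & is.na(out)] <- a$name
  }
  out
}

#' Collapse reads to unique sequences per amplicon
#'
#' Exact-sequence grouping with per-position maximum base quality across the
#' group and the group size retained — identical reads are potential PCR
#' duplicates of one input molecule.
#'
#' @param merged `data.frame(id, seq, qual)`.
#' @param amplicon_ids Character vector assigning each read to an amplicon
#'   (NA rows are dropped).
#' @return `data.frame(amplicon, seq, qual, reads, rep_id)`, one row per
#'   unique (amplicon, sequence).
#' @export
collapse_unique <- function(merged, amplicon_ids) {
  keep <- !is.na(amplicon_ids)
  merged <- merged[keep, , drop = FALSE]
  amplicon_ids <- amplicon_ids[keep]
  if (nrow(merged) == 0L) {
    return(data.frame(amplicon = character(0), seq = character(0),
                      qual = character(0), reads = integer(0),
                      rep_id = character(0)))
  }
  key <- paste(amplicon_ids, merged$seq, sep = "\r")
  groups <- split(seq_len(nrow(merged)), key)
  rows <- lapply(groups, function(ix) {
    q <- merged$qual[ix]
    best <- q[1L]
    if (length(ix) > 1L) {
      bi <- utf8ToInt(best)
      for (j in 2L:length(ix)) bi <- pmax(bi, utf8ToInt(q[j]))
      best <- intToUtf8(bi)
    }
    data.frame(amplicon = amplicon_ids[ix[1L]], seq = merged$seq[ix[1L]],
               qual = best, reads = length(ix), rep_id = merged$id[ix[1L]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Align a read to its amplicon reference
#'
#' Affine-gap alignment, global in the read and local in the reference (free
#' reference end gaps), with gap lengths unbounded up to the amplicon span so
#' that a large deletion appears as a single deletion operation. Scores:
#' match +1, mismatch -4, gap open -6, gap extend -1. Both strands are tried.
#'
#' A read is reported unaligned when its identity (matches / read length)
#' falls below `min_identity`; with these scores a legitimate several-hundred
#' bp deletion drives the raw score negative, so identity — not raw score —
#' separates real molecules from foreign sequence.
#'
#' Mapping confidence is a 0-60 margin score: `min(60, S1 - S2)` where S1 is
#' the best alignment score and S2 the best score over alignment end columns
#' more than half a read length away from the best end. A unique full-length
#' alignment scores 60; two equal placements score 0.
#'
#' @param seq Read sequence.
#' @param amplicon An [amplicon_def()].
#' @param match,mismatch,gap_open,gap_ext Alignment scores.
#' @param min_identity Identity floor below which the read is unaligned.
#' @return An object of class `alignment_path`: `aligned`, `strand`,
#'   `score`, `map_conf`, `identity`, and `ops`
#'   (`data.frame(op, len, read0, ref0)`; `ref0` is genomic, 0-based).
#' @export
align_to_amplicon <- function(seq, amplicon, match = 1, mismatch = -4,
                              gap_open = -6, gap_ext = -1,
                              min_identity = 0.8) {
  best <- cpp_align_glocal(seq, amplicon$seq, match, mismatch, gap_open,
                           gap_ext)
  best_strand <- "+"
  if (best$nmatch / nchar(seq) < 0.95) {  # only then can "-" plausibly win
    al <- cpp_align_glocal(revcomp(seq), amplicon$seq, match, mismatch,
                           gap_open, gap_ext)
    if (al$score > best$score) { best <- al; best_strand <- "-" }
  }
  L <- nchar(seq)
  identity <- best$nmatch / L
  if (identity < min_identity) {
    return(structure(list(aligned = FALSE, strand = best_strand,
                          score = best$score, map_conf = 0,
                          identity = identity, ops = NULL),
                     class = "alignment_path"))
  }
  # margin-based mapping confidence from the end-column score vector
  es <- best$end_scores
  j1 <- best$ref_end
  far <- abs(seq_along(es) - 1L - j1) > L / 2
  s2 <- if (any(far)) max(es[far]) else best$score - 60
  map_conf <- max(0, min(60, best$score - s2))
  ops <- data.frame(op = as.character(best$op), len = best$len,
                    read0 = best$read0,
                    ref0 = best$ref0 + amplicon$start)
  structure(list(aligned = TRUE, strand = best_strand, score = best$score,
                 map_conf = map_conf, identity = identity, ops = ops),
            class = "alignment_path")
}

#' @export
print.alignment_path <- function(x, ...) {
  if (!x$aligned) {
    cat("<alignment_path> unaligned\n")
  } else {
    cat(sprintf("<alignment_path> %s score %.0f conf %.0f  %s\n",
                x$strand, x$score, x$map_conf,
                paste0(x$ops$len, x$ops$op, collapse = "")))
  }
  invisible(x)
}

#' Extract deletion candidates from an alignment path
#'
#' Indel operations whose read positions fall within `pair_window` bp of
#' each other are clustered — together with any short aligned segments
#' between them — into one composite junction, because inserted or
#' low-quality bases frequently re-align piecewise against the deleted
#' reference and fragment what is really a single event. A cluster's
#' deletion length is the reference span it consumes and its insertion
#' length the read span, so the net size is invariant to how the aligner
#' fragmented the junction; this is also what pairs a deletion with a nearby
#' insertion in the balanced-indel artifact class. Clusters with a deletion
#' span of at least `min_del` bp become candidates; a read may carry several.
#'
#' @param path An [align_to_amplicon()] result.
#' @param read_seq The read sequence (for inserted bases).
#' @param min_del Minimum deletion span (default 10).
#' @param pair_window Read-distance window for clustering indel operations
#'   (default 30).
#' @return `data.frame(left_bp, right_bp, del_len, ins_len, ins_seq,
#'   read_pos)`; zero rows when the path has no qualifying deletion.
#'   `del_len - ins_len` is the candidate's net deletion.
#' @export
extract_deletions <- function(path, read_seq, min_del = 10L,
                              pair_window = 30L) {
  empty <- data.frame(left_bp = integer(0), right_bp = integer(0),
                      del_len = integer(0), ins_len = integer(0),
                      ins_seq = character(0), read_pos = integer(0))
  if (!isTRUE(path$aligned) || is.null(path$ops)) return(empty)
  ops <- path$ops
  idx <- which(ops$op != "M")
  if (length(idx) == 0L) return(empty)
  read_len_of <- function(i) ifelse(ops$op[i] == "D", 0L, ops$len[i])
  ref_len_of <- function(i) ifelse(ops$op[i] == "I", 0L, ops$len[i])
  # cluster indel ops by read distance
  cl <- cumsum(c(1L, diff(ops$read0[idx]) -
                   read_len_of(idx[-length(idx)]) > pair_window))
  rows <- lapply(split(idx, cl), function(ix) {
    first <- ix[1L]; last <- ix[length(ix)]
    span <- first:last  # includes any interior aligned segments
    del_len <- sum(ref_len_of(span))
    ins_len <- sum(read_len_of(span))
    if (del_len < min_del) return(NULL)
    ins_seq <- if (ins_len > 0L) {
      substr(read_seq, ops$read0[first] + 1L, ops$read0[first] + ins_len)
    } else ""
    data.frame(left_bp = ops$ref0[first], right_bp = ops$ref0[first] + del_len,
               del_len = del_len, ins_len = ins_len, ins_seq = ins_seq,
               read_pos = ops$read0[first])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter balanced-indel artifacts
#'
#' Retains candidates whose net deletion (deletion length minus paired
#' insertion length) is at least `min_net` bp; candidates with an insertion
#' and deletion of roughly equal length are artifacts of local alignment
#' failure, not structural variants.
#'
#' @param cands Candidate `data.frame` from [extract_deletions()].
#' @param min_net Minimum net deletion (default 10).
#' @return The retained rows, with a `net` column added; discarded rows are
#'   reported in the `"discarded"` attribute.
#' @export
filter_artifact_indels <- function(cands, min_net = 10L) {
  if (nrow(cands) == 0L) {
    out <- cbind(cands, net = integer(0))
    attr(out, "discarded") <- out
    return(out)
  }
  cands$net <- cands$del_len - cands$ins_len
  keep <- cands$net >= min_net
  out <- cands[keep, , drop = FALSE]
  attr(out, "discarded") <- cands[!keep, , drop = FALSE]
  out
}

#' Infer microhomology or inserted bases at a junction
#'
#' For a pure deletion the junction is canonicalized to its leftmost
#' placement and the maximal microhomology (a suffix of the retained left
#' flank that is also a prefix of the resumed right flank) is reported. When
#' the read carries bases at the junction that match neither flank they are
#' reported as inserted bases and the microhomology is 0 — the two are
#' mutually exclusive. Junctions whose flanks disagree with the read beyond
#' the junction are flagged invalid.
#'
#' @param cand One candidate row (after [filter_artifact_indels()]).
#' @param read_seq Read sequence.
#' @param amplicon The [amplicon_def()] the read aligned to.
#' @param flank_check Bases of flank compared on each side for validity
#'   (default 10); mismatches tolerated: 20 percent (sequencing error).
#' @return List: `left_bp`, `right_bp` (canonical, genomic), `size`,
#'   `mh_len`, `mh_seq`, `ins_seq`, `valid`.
#' @export
infer_junction_bases <- function(cand, read_seq, amplicon,
                                 flank_check = 10L) {
  l <- cand$left_bp - amplicon$start
  r <- cand$right_bp - amplicon$start
  stopifnot(l >= 0L, r <= nchar(amplicon$seq))
  cj <- canonicalize_junction(amplicon$seq, l, r, ins = cand$ins_seq)
  # validity: the read around the junction must match the joined flanks
  rp <- cand$read_pos
  nins <- nchar(cand$ins_seq)
  lf <- min(flank_check, rp)
  expect_left <- substr0(amplicon$seq, l - lf, l)
  got_left <- substr(read_seq, rp - lf + 1L, rp)
  rs <- rp + nins
  rf <- min(flank_check, nchar(read_seq) - rs)
  expect_right <- substr0(amplicon$seq, r, r + rf)
  got_right <- substr(read_seq, rs + 1L, rs + rf)
  mm <- function(a, b) {
    if (nchar(a) == 0L) return(0L)
    sum(utf8ToInt(a) != utf8ToInt(b))
  }
  valid <- (mm(expect_left, got_left) <= ceiling(0.2 * lf)) &&
    (mm(expect_right, got_right) <= ceiling(0.2 * rf))
  list(left_bp = amplicon$start + cj$left,
       right_bp = amplicon$start + cj$right,
       size = cj$size, mh_len = cj$mh_len, mh_seq = cj$mh_seq,
       ins_seq = cj$ins, valid = valid)
}

#' Collapse calls into unique molecular events by alignment path
#'
#' Calls whose reads have identical alignment paths — same amplicon, same
#' ordered junction list (canonical coordinates and inserted bases) — are
#' conservatively collapsed into one unique event, since identical paths may
#' be PCR duplicates of one input molecule. Counts are retained both as raw
#' reads and as unique events.
#'
#' @param calls Call `data.frame` in which each row is one junction and
#'   `path_key` identifies the read's full path (amplicon + ordered junction
#'   signature).
#' @return The calls with duplicates collapsed: `reads` summed over the
#'   group, `mean_baseq` and `map_conf` taken from the best read, and a
#'   `unique_events` attribute (number of distinct paths).
#' @export
dedup_paths <- function(calls) {
  if (nrow(calls) == 0L) {
    attr(calls, "unique_events") <- 0L
    return(calls)
  }
  grp <- split(seq_len(nrow(calls)), calls$path_key)
  rows <- lapply(grp, function(ix) {
    sub <- calls[ix, , drop = FALSE]
    # one path may contribute several junction rows (multi-junction molecule)
    # and several source reads; collapse per junction within the path
    jg <- split(seq_len(nrow(sub)), sub$junction_key)
    do.call(rbind, lapply(jg, function(jx) {
      s <- sub[jx, , drop = FALSE]
      best <- which.max(s$mean_baseq)
      out <- s[best, , drop = FALSE]
      out$reads <- sum(s$reads)
      out$map_conf <- max(s$map_conf)
      out
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unique_events") <- length(grp)
  out
}

#' Apply final quality filters
#'
#' Retains calls whose best representative read has a mean Phred base
#' quality of at least `min_mean_baseq` and a mapping confidence of at least
#' `min_map_conf` on the 0-60 margin scale.
#'
#' @param calls Call `data.frame` with `mean_baseq` and `map_conf` columns.
#' @param min_mean_baseq Minimum mean base quality (default 25).
#' @param min_map_conf Minimum mapping confidence (default 55).
#' @return Retained rows; rejected rows with their failing criterion are in
#'   the `"rejected"` attribute.
#' @export
apply_quality_filters <- function(calls, min_mean_baseq = 25,
                                  min_map_conf = 55) {
  if (nrow(calls) == 0L) {
    attr(calls, "rejected") <- calls
    return(calls)
  }
  bad_q <- calls$mean_baseq < min_mean_baseq
  bad_m <- calls$map_conf < min_map_conf
  keep <- !(bad_q | bad_m)
  rej <- calls[!keep, , drop = FALSE]
  if (nrow(rej) > 0L) {
    rej$reason <- ifelse(bad_q[!keep], "base_quality", "map_conf")
  }
  out <- calls[keep, , drop = FALSE]
  attr(out, "rejected") <- rej
  out
}

#' Call microdeletion junctions from paired FASTQ input
#'
#' End-to-end caller: merge read pairs, assign (or infer) amplicons,
#' collapse to unique sequences, align with the built-in affine-gap aligner,
#' extract deletion operations, discard balanced-indel artifacts, infer
#' junction microhomology / inserted bases, collapse PCR duplicates by
#' alignment path and apply the final quality filters.
#'
#' @param pairs List from [read_fastq_pairs()] or
#'   [simulate_amplicon_reads()].
#' @param amplicons List of [amplicon_def()]; when `NULL` they are inferred
#'   ab initio from the merged reads (requires `ref_seq`).
#' @param ref_seq,ref_start Reference sequence and its genomic offset; used
#'   for amplicon inference and read assignment. Defaults to the single
#'   supplied amplicon's sequence.
#' @param min_net Minimum net deletion size (default 10).
#' @param min_mean_baseq,min_map_conf Final quality thresholds (defaults 25
#'   and 55).
#' @param min_del Minimum deletion operation length (default equal to
#'   `min_net`).
#' @return List with `calls` (a `data.frame`: `amplicon`, `left_bp`,
#'   `right_bp`, `net`, `del_len`, `ins_len`, `mh_len`, `mh_seq`, `ins_seq`,
#'   `size`, `reads`, `mean_baseq`, `map_conf`, `rep_id`, `path_key`) and
#'   `log` (per-stage record counts).
#' @export
call_junctions <- function(pairs, amplicons = NULL, ref_seq = NULL,
                           ref_start = 0L, min_net = 10L,
                           min_mean_baseq = 25, min_map_conf = 55,
                           min_del = min_net) {
  log <- list(pairs_in = length(pairs$seq1))
  mg <- merge_pairs(pairs)
  log$merged <- nrow(mg$merged)
  log$unmerged <- length(mg$unmerged_ids)
  if (is.null(ref_seq)) {
    if (is.null(amplicons) || length(amplicons) != 1L) {
      stop("supply ref_seq, or exactly one amplicon to use as reference")
    }
    ref_seq <- amplicons[[1L]]$seq
    ref_start <- amplicons[[1L]]$start
  }
  if (is.null(amplicons)) {
    amplicons <- infer_amplicons(mg$merged, ref_seq, ref_start)
  }
  names(amplicons) <- vapply(amplicons, `[[`, "", "name")
  assign <- assign_amplicons(mg$merged, amplicons, ref_seq, ref_start)
  log$assigned <- sum(!is.na(assign))
  uniq <- collapse_unique(mg$merged, assign)
  log$unique_seqs <- nrow(uniq)

  rows <- list(); aligned <- 0L; candidates <- 0L; artifact <- 0L
  invalid <- 0L
  for (i in seq_len(nrow(uniq))) {
    amp <- amplicons[[uniq$amplicon[i]]]
    path <- align_to_amplicon(uniq$seq[i], amp)
    if (!path$aligned) next
    aligned <- aligned + 1L
    cands <- extract_deletions(path, uniq$seq[i], min_del = min_del)
    candidates <- candidates + nrow(cands)
    kept <- filter_artifact_indels(cands, min_net = min_net)
    artifact <- artifact + nrow(attr(kept, "discarded"))
    if (nrow(kept) == 0L) next
    jrows <- list()
    for (j in seq_len(nrow(kept))) {
      jb <- infer_junction_bases(kept[j, ], uniq$seq[i], amp)
      if (!jb$valid) { invalid <- invalid + 1L; next }
      jrows[[length(jrows) + 1L]] <- data.frame(
        amplicon = amp$name, left_bp = jb$left_bp, right_bp = jb$right_bp,
        net = kept$net[j], del_len = kept$del_len[j],
        ins_len = kept$ins_len[j], mh_len = jb$mh_len, mh_seq = jb$mh_seq,
        ins_seq = jb$ins_seq, size = jb$size)
    }
    if (length(jrows) == 0L) next
    jdf <- do.call(rbind, jrows)
    jdf$junction_key <- sprintf("%d:%d:%s", jdf$left_bp, jdf$right_bp,
                                jdf$ins_seq)
    jdf$path_key <- paste(amp$name,
                          paste(jdf$junction_key, collapse = "|"))
    jdf$reads <- uniq$reads[i]
    jdf$mean_baseq <- mean(phred_to_int(uniq$qual[i]))
    jdf$map_conf <- path$map_conf
    jdf$rep_id <- uniq$rep_id[i]
    rows[[length(rows) + 1L]] <- jdf
  }
  log$aligned <- aligned
  log$candidates <- candidates
  log$artifact_discards <- artifact
  log$invalid_junctions <- invalid
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(amplicon = character(0), left_bp = integer(0),
               right_bp = integer(0), net = integer(0), del_len = integer(0),
               ins_len = integer(0), mh_len = integer(0),
               mh_seq = character(0), ins_seq = character(0),
               size = integer(0), junction_key = character(0),
               path_key = character(0), reads = integer(0),
               mean_baseq = numeric(0), map_conf = numeric(0),
               rep_id = character(0))
  deduped <- dedup_paths(calls)
  log$unique_paths <- attr(deduped, "unique_events")
  final <- apply_quality_filters(deduped, min_mean_baseq, min_map_conf)
  log$quality_discards <- nrow(attr(final, "rejected"))
  log$final_junctions <- nrow(final)
  rownames(final) <- NULL
  list(calls = final, log = log, amplicons = amplicons)
}
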