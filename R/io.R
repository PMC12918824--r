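#' Read a SPO11-oligo signal track
#'
#' Accepts a bedGraph (`chrom start end value`, 0-based half-open) or a
#' two-column TSV (`position value`). The covered window is densified to one
#' value per base; uncovered bases are 0.
#'
#' @param path File path.
#' @param format `"bedGraph"` or `"tsv"`; guessed from the extension when
#'   `"auto"`.
#' @param total_reads Optional library size recorded on the returned map.
#' @return A [spo_map()].
#' @export
read_spo11_track <- function(path, format = c("auto", "bedGraph", "tsv"),
                             total_reads = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", tolower(path))) "bedGraph" else "tsv"
  }
  if (format == "bedGraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    chrom <- as.character(GenomicRanges::seqnames(gr)[1L])
    start0 <- min(GenomicRanges::start(gr)) - 1L           # GRanges is 1-based
    end0 <- max(GenomicRanges::end(gr))
    counts <- numeric(end0 - start0)
    for (i in seq_along(gr)) {
      s <- GenomicRanges::start(gr)[i] - 1L - start0
      e <- GenomicRanges::end(gr)[i] - start0
      counts[(s + 1L):e] <- gr$score[i]
    }
  } else {
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("pos", "value"))
    start0 <- min(tab$pos)
    counts <- numeric(max(tab$pos) - start0 + 1L)
    counts[tab$pos - start0 + 1L] <- tab$value
    chrom <- "unknown"
  }
  spo_map(chrom, start0, counts, total_reads = total_reads)
}

#' Write a map or profile as bedGraph
#'
#' Runs of equal signal are collapsed into intervals; zero runs are dropped.
#'
#' @param map A [spo_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spo11_track <- function(map, path) {
  stopifnot(inherits(map, "spo_map"))
  v <- map$counts
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = map$chrom, start = map$start + s[keep],
                   end = map$start + e[keep], value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write hotspot definitions as BED6
#'
#' BED6 columns: chrom, start, end, name (hotspot id), score (strength),
#' strand (`.`). The `thick` position, when present, is ignored; the center
#' is re-derived by [call_hotspot()] against a map, or taken as the interval
#' midpoint.
#'
#' @param path File path.
#' @return A list of [hotspot()] objects (named by the BED name column).
#' @export
read_hotspots_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("expected BED6")
  names(tab)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    hotspot(tab$chrom[i], (tab$start[i] + tab$end[i]) %/% 2L,
            tab$start[i], tab$end[i], tab$score[i])
  })
  names(out) <- tab$name
  out
}

#' @rdname read_hotspots_bed
#' @param hotspots List of [hotspot()] objects.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  nm <- names(hotspots)
  if (is.null(nm)) nm <- sprintf("hs%d", seq_along(hotspots))
  df <- data.frame(
    chrom = vapply(hotspots, `[[`, "", "chrom"),
    start = vapply(hotspots, `[[`, 0L, "left"),
    end = vapply(hotspots, `[[`, 0L, "right"),
    name = nm,
    score = vapply(hotspots, `[[`, 0, "strength"),
    strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read paired FASTQ files
#'
#' @param fq1,fq2 Paths to the R1 and R2 FASTQ files (gzip accepted).
#' @return A list with character vectors `seq1`, `qual1`, `seq2`, `qual2`,
#'   `id` (read names from R1, stripped of any `/1` suffix).
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) stop("R1/R2 record counts differ")
  list(seq1 = unname(as.character(r1)),
       qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
       seq2 = unname(as.character(r2)),
       qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)),
       id = sub("/[12]$", "", names(r1)))
}

#' Write paired FASTQ files
#'
#' @param reads List as produced by [simulate_amplicon_reads()]: character
#'   vectors `seq1`, `qual1`, `seq2`, `qual2`, `id`.
#' @param fq1,fq2 Output paths.
#' @return `c(fq1, fq2)`, invisibly.
#' @export
write_fastq_pairs <- function(reads, fq1, fq2) {
  s1 <- Biostrings::DNAStringSet(reads$seq1); names(s1) <- reads$id
  s2 <- Biostrings::DNAStringSet(reads$seq2); names(s2) <- reads$id
  Biostrings::writeXStringSet(s1, fq1, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual1))
  Biostrings::writeXStringSet(s2, fq2, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual2))
  invisible(c(fq1, fq2))
}

#' Write junction calls as TSV and BEDPE
#'
#' The TSV carries the full call table; the BEDPE gives one record per unique
#' junction with the two 1-bp breakpoint anchors.
#'
#' @param calls Junction-call `data.frame` from [call_junctions()].
#' @param path Output path.
#' @param chrom Chromosome used for BEDPE records.
#' @return `path`, invisibly.
#' @export
write_junctions_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junctions_tsv
#' @export
write_junctions_bedpe <- function(calls, path, chrom = "chr1") {
  df <- data.frame(chrom1 = chrom, start1 = calls$left_bp,
                   end1 = calls$left_bp + 1L,
                   chrom2 = chrom, start2 = calls$right_bp,
                   end2 = calls$right_bp + 1L,
                   name = sprintf("%s_j%d", calls$amplicon, seq_len(nrow(calls))),
                   score = calls$reads, strand1 = "+", strand2 = "+")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a junction-call or deletion-event TSV
#'
#' @param path TSV with a header row, as written by [write_junctions_tsv()]
#'   or the simulator's truth tables.
#' @return A `data.frame`.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
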