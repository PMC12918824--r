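#' Simulate PCR amplification and paired-end sequencing of an amplicon pool
#'
#' Each input molecule (an amplicon sequence, possibly carrying a deletion /
#' insertion event) is amplified by a branching process — per cycle every
#' copy duplicates independently with probability `efficiency` — and the
#' final pool is subsampled to `depth` read pairs, so PCR-duplicate
#' multiplicities have a realistic spread without modeling polymerase
#' chemistry. Read pairs are taken from the two molecule ends (R2 is the
#' reverse complement of the 3' end); substitution errors are added at
#' `error_rate` per base. Base qualities are a constant Q33 baseline with
#' error positions written as Q12, so the mean-base-quality filter is
#' exercisable. Read names encode the molecule and event ids
#' (`mol<id>;evt<id>;copy<k>`) for ground-truth tracking.
#'
#' @param molecules `data.frame` with columns `mol_id`, `seq`, `event_id`
#'   (use `NA` or `"ref"` for intact molecules).
#' @param depth Total read pairs to emit.
#' @param read_len Read length (default 300, paired 300-bp sequencing).
#' @param pcr_cycles Amplification cycles (default 22).
#' @param efficiency Per-cycle duplication probability (default 0.9).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return A list of parallel character vectors `seq1`, `qual1`, `seq2`,
#'   `qual2`, `id`, plus `mol_id` and `event_id` integer/character vectors.
#' @export
simulate_amplicon_reads <- function(molecules, depth, read_len = 300L,
                                    pcr_cycles = 22L, efficiency = 0.9,
                                    error_rate = 0.001, seed = 1L) {
  stopifnot(nrow(molecules) >= 1L, depth >= 1L)
  if (any(nchar(molecules$seq) < 2L * 20L)) {
    stop("amplicon molecules shorter than the primers")
  }
  set.seed(derive_seed(seed, "pcr"))
  n <- nrow(molecules)
  copies <- rep(1, n)
  for (cyc in seq_len(pcr_cycles)) {
    copies <- copies + stats::rbinom(n, size = round(copies), prob = efficiency)
  }
  pick <- sample.int(n, depth, replace = TRUE, prob = copies)
  pick <- sort(pick)
  seqs <- molecules$seq[pick]
  lens <- nchar(seqs)
  r1 <- substr(seqs, 1L, pmin(read_len, lens))
  r2 <- revcomp(substr(seqs, pmax(1L, lens - read_len + 1L), lens))
  add_errors <- function(reads, tag) {
    set.seed(derive_seed(seed, paste0("err", tag)))
    out_seq <- reads
    out_qual <- strrep(int_to_phred(33L), nchar(reads))
    if (error_rate > 0) {
      nerr <- stats::rbinom(length(reads), nchar(reads), error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(nchar(reads[i]), nerr[i])
        s <- strsplit(out_seq[i], "")[[1L]]
        q <- strsplit(out_qual[i], "")[[1L]]
        for (p in pos) {
          s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
          q[p] <- int_to_phred(12L)
        }
        out_seq[i] <- paste(s, collapse = "")
        out_qual[i] <- paste(q, collapse = "")
      }
    }
    list(seq = out_seq, qual = out_qual)
  }
  e1 <- add_errors(r1, "r1")
  e2 <- add_errors(r2, "r2")
  evt <- molecules$event_id[pick]
  evt[is.na(evt)] <- "ref"
  copy_idx <- stats::ave(seq_along(pick), pick, FUN = seq_along)
  list(seq1 = e1$seq, qual1 = e1$qual, seq2 = e2$seq, qual2 = e2$qual,
       id = sprintf("mol%d;evt%s;copy%d", molecules$mol_id[pick], evt,
                    copy_idx),
       mol_id = molecules$mol_id[pick], event_id = as.character(evt))
}

#' Parse simulator read names back to ground truth
#'
#' Inverse of the read-name codec used by [simulate_amplicon_reads()].
#'
#' @param ids Character vector of read names.
#' @return `data.frame` with `mol_id` (integer), `event_id` (character),
#'   `copy` (integer).
#' @export
parse_read_ids <- function(ids) {
  m <- regmatches(ids, regexec("^mol([0-9]+);evt([^;]+);copy([0-9]+)$", ids))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("unparseable read ids: ", ids[which(bad)[1L]])
  data.frame(mol_id = as.integer(vapply(m, `[[`, "", 2L)),
             event_id = vapply(m, `[[`, "", 3L),
             copy = as.integer(vapply(m, `[[`, "", 4L)))
}

#' Build an amplicon molecule pool from ground-truth events
#'
#' Applies each event (deletion plus optional insertion) to the amplicon
#' reference sequence; intact reference molecules can be mixed in to emulate
#' the dominant wild-type background of a real amplicon library.
#'
#' @param events Event `data.frame` with `event_id`, `left_bp`, `right_bp`,
#'   `ins_seq` (coordinates are genomic; the amplicon interval maps them into
#'   the sequence).
#' @param amplicon An [amplicon_def()].
#' @param n_ref Number of intact reference molecules to add.
#' @return `data.frame(mol_id, seq, event_id)`.
#' @export
molecules_from_events <- function(events, amplicon, n_ref = 0L) {
  ref <- amplicon$seq
  off <- amplicon$start
  seqs <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    l <- events$left_bp[i] - off
    r <- events$right_bp[i] - off
    if (l < 0L || r > nchar(ref)) stop("event outside amplicon")
    seqs[i] <- apply_event_to_seq(ref, l, r, events$ins_seq[i])
  }
  mol <- data.frame(mol_id = seq_len(nrow(events)), seq = seqs,
                    event_id = as.character(events$event_id))
  if (n_ref > 0L) {
    mol <- rbind(mol, data.frame(
      mol_id = nrow(events) + seq_len(n_ref), seq = ref, event_id = "ref"))
  }
  mol
}
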