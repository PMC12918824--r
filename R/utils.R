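DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a character sequence
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA reference sequence
#'
#' @param length Sequence length in bp.
#' @param seed Integer seed.
#' @return A single character string of uniform random bases.
#' @export
random_reference <- function(length, seed = 1L) {
  set.seed(seed)
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

# Deterministic per-stage seed derived from a master seed and a stage name.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 10007 + h * 97) %% 2147483629)
}

# substring by 0-based half-open interval
substr0 <- function(x, from0, to0) {
  if (to0 <= from0) return("")
  substr(x, from0 + 1L, to0)
}

phred_to_int <- function(q) utf8ToInt(q) - 33L
int_to_phred <- function(v) intToUtf8(v + 33L)

#' Canonicalize a deletion junction against a reference
#'
#' Slides a deletion `[left, right)` to its leftmost equivalent placement and
#' reports the maximal junction microhomology: the longest sequence that is
#' simultaneously a suffix of the retained left flank and a prefix of the
#' deleted-then-resumed right flank (equivalently, the size of the interval
#' over which the junction can slide without changing the joined sequence).
#' Junctions with inserted bases do not slide and have microhomology 0 by
#' convention (microhomology and insertion are mutually exclusive).
#'
#' The same convention is applied to simulated ground truth and to caller
#' output, so coordinates are directly comparable.
#'
#' @param ref Reference sequence (single string, coordinates 0-based into it).
#' @param left,right Deleted interval `[left, right)`, 0-based.
#' @param ins Inserted bases at the junction (default none).
#' @return List with `left`, `right` (canonical coordinates), `mh_len`,
#'   `mh_seq`, `ins` and `size` (`right - left`).
#' @export
canonicalize_junction <- function(ref, left, right, ins = "") {
  left <- as.integer(left); right <- as.integer(right)
  stopifnot(left < right, left >= 0L, right <= nchar(ref))
  if (nzchar(ins)) {
    return(list(left = left, right = right, mh_len = 0L, mh_seq = "",
                ins = ins, size = right - left))
  }
  # slide left while the base entering the deletion equals the base leaving it
  a <- 0L
  while (left - a - 1L >= 0L &&
         substr(ref, left - a, left - a) == substr(ref, right - a, right - a)) {
    a <- a + 1L
  }
  # extension to the right of the original placement
  b <- 0L
  while (right + b < nchar(ref) &&
         substr(ref, left + b + 1L, left + b + 1L) ==
         substr(ref, right + b + 1L, right + b + 1L)) {
    b <- b + 1L
  }
  l2 <- left - a; r2 <- right - a
  mh_len <- a + b
  list(left = l2, right = r2, mh_len = mh_len,
       mh_seq = substr0(ref, r2, r2 + mh_len), ins = "",
       size = right - left)
}

# apply a deletion event (with optional insertion) to a reference sequence
apply_event_to_seq <- function(ref, left, right, ins = "") {
  paste0(substr0(ref, 0L, left), ins, substr0(ref, right, nchar(ref)))
}
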