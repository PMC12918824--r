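# shared in-code fixtures for the caller tests

# a deterministic amplicon on a random reference
fixture_amplicon <- function(len = 580L, start = 1000L, seed = 42L,
                             name = "ampA") {
  amplicon_def("chrT", start, start + len, random_reference(len, seed),
               name = name)
}

# error-free "merged reads" directly from molecule sequences (bypasses
# pairing), n copies each, constant Q33
merged_from_molecules <- function(seqs, copies = 1L) {
  seqs <- rep(seqs, each = copies)
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = strrep("B", nchar(seqs)))
}

# exact read pairs (no errors) from a molecule sequence
pair_from_molecule <- function(seq, read_len = 300L, id = "p1") {
  L <- nchar(seq)
  r1 <- substr(seq, 1L, min(read_len, L))
  r2 <- revcomp(substr(seq, max(1L, L - read_len + 1L), L))
  list(seq1 = r1, qual1 = strrep("B", nchar(r1)),
       seq2 = r2, qual2 = strrep("B", nchar(r2)), id = id)
}

# brute-force junction placement oracle: enumerate every placement of a
# deletion of the observed size and find the contiguous run of placements
# whose joined sequence equals the observed joined sequence
oracle_junction <- function(ref, left, right) {
  s <- right - left
  L <- nchar(ref)
  joined <- function(p) paste0(substr(ref, 1, p), substr(ref, p + s + 1, L))
  target <- joined(left)
  equiv <- which(vapply(0:(L - s), function(p) joined(p) == target,
                        logical(1))) - 1L
  # contiguous run containing `left`
  run <- equiv
  if (length(equiv) > 1L) {
    grp <- cumsum(c(1L, diff(equiv) != 1L))
    run <- equiv[grp == grp[match(left, equiv)]]
  }
  list(left = min(run), mh_len = length(run) - 1L)
}
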