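test_that("merge_pairs builds a quality-aware consensus from overlapping pairs", {
  amp <- fixture_amplicon(seed = 61)
  molecule <- substr(amp$seq, 1, 450)
  pr <- pair_from_molecule(molecule)
  mg <- merge_pairs(pr)
  expect_equal(nrow(mg$merged), 1L)
  expect_equal(mg$merged$seq, molecule)
  expect_equal(nchar(mg$merged$qual), 450L)

  # disjoint reads (no overlap >= 20): unmerged
  far <- list(seq1 = substr(amp$seq, 1, 100),
              qual1 = strrep("B", 100),
              seq2 = revcomp(substr(amp$seq, 301, 400)),
              qual2 = strrep("B", 100), id = "far")
  mg2 <- merge_pairs(far)
  expect_equal(nrow(mg2$merged), 0L)
  expect_equal(mg2$unmerged_ids, "far")

  # one disagreement inside the overlap (molecule position 200 = R2 index
  # 450 - 200 + 1 = 251): the higher-quality base wins
  pr3 <- pair_from_molecule(molecule, id = "mm")
  truth_base <- substr(molecule, 200, 200)
  wrong <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  s2 <- strsplit(pr3$seq2, "")[[1]]; s2[251] <- revcomp(wrong)
  pr3$seq2 <- paste(s2, collapse = "")
  q2 <- strsplit(pr3$qual2, "")[[1]]; q2[251] <- "-"  # Q12 at the error
  pr3$qual2 <- paste(q2, collapse = "")
  mg3 <- merge_pairs(pr3)
  expect_equal(substr(mg3$merged$seq, 200, 200), truth_base)

  # now make the wrong base the high-quality one: it wins instead
  pr4 <- pr3
  q1 <- strsplit(pr4$qual1, "")[[1]]; q1[200] <- "-"
  pr4$qual1 <- paste(q1, collapse = "")
  pr4$qual2 <- strrep("I", 300)  # Q40 everywhere on R2
  mg4 <- merge_pairs(pr4)
  expect_equal(substr(mg4$merged$seq, 200, 200), wrong)
})

test_that("amplicons are inferred from read outer endpoints", {
  ref <- random_reference(3000, seed = 71)
  # one amplicon: reads all share its endpoints
  a1 <- substr0(ref, 500, 1080)
  merged <- merged_from_molecules(a1, copies = 15L)
  amps <- infer_amplicons(merged, ref, ref_start = 0L)
  expect_length(amps, 1L)
  expect_equal(amps[[1]]$start, 500L)
  expect_equal(amps[[1]]$end, 1080L)

  # four overlapping amplicons recovered from a mixed pool
  starts <- c(500L, 610L, 715L, 820L)
  seqs <- vapply(starts, function(s) substr0(ref, s, s + 580L), "")
  merged4 <- merged_from_molecules(seqs, copies = 12L)
  amps4 <- infer_amplicons(merged4, ref)
  expect_length(amps4, 4L)
  expect_setequal(vapply(amps4, `[[`, 0L, "start"), starts)

  # shuffled reads fail seeding and are excluded; alone they infer nothing
  shuffled <- merged_from_molecules(random_reference(580, 999), copies = 12L)
  expect_warning(none <- infer_amplicons(shuffled, ref), "no")
  expect_length(none, 0L)

  # below min_reads: no amplicon
  expect_warning(few <- infer_amplicons(merged_from_molecules(a1, 3L), ref),
                 "min_reads")
  expect_length(few, 0L)
})

test_that("collapse_unique groups exact sequences keeping best qualities", {
  reads <- merged_from_molecules("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
                                 copies = 50L)
  uq <- collapse_unique(reads, rep("amp1", 50L))
  expect_equal(nrow(uq), 1L)
  expect_equal(uq$reads, 50L)

  two <- merged_from_molecules(c("AAAACCCCGGGGTTTTAAAA",
                                 "AAAACCCCGGGGTTTTAAAC"))
  uq2 <- collapse_unique(two, rep("amp1", 2L))
  expect_equal(nrow(uq2), 2L)

  # per-position maximum quality across duplicates
  dup <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACGT"),
                    qual = c("5I5I", "I5I5"))  # Q20/Q40 alternating
  uq3 <- collapse_unique(dup, rep("amp1", 2L))
  expect_equal(uq3$qual, "IIII")
  expect_equal(uq3$reads, 2L)
})

test_that("alignment reports clean paths, planted deletions, and rejects noise", {
  amp <- fixture_amplicon(seed = 81)
  # read equal to reference: single M segment, full confidence
  p0 <- align_to_amplicon(amp$seq, amp)
  expect_true(p0$aligned)
  expect_equal(nrow(p0$ops), 1L)
  expect_equal(p0$ops$op, "M")
  expect_equal(p0$map_conf, 60)

  # planted 60-bp deletion appears as one deletion op at the planted
  # coordinates
  rd <- paste0(substr(amp$seq, 1, 250), substr(amp$seq, 311, 580))
  p1 <- align_to_amplicon(rd, amp)
  dels <- p1$ops[p1$ops$op == "D", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$len, 60L)
  cj <- canonicalize_junction(amp$seq, 250L, 310L)
  got <- canonicalize_junction(amp$seq, dels$ref0 - amp$start,
                               dels$ref0 - amp$start + 60L)
  expect_equal(got$left, cj$left)

  # random sequence: unaligned
  p2 <- align_to_amplicon(random_reference(400, 123), amp)
  expect_false(p2$aligned)
})

test_that("deletion candidates and the balanced-indel filter follow the net rule", {
  amp <- fixture_amplicon(seed = 91)
  mkread <- function(left, right, ins = "") {
    apply_event_to_seq(amp$seq, left, right, ins)
  }
  cand_of <- function(read) {
    extract_deletions(align_to_amplicon(read, amp), read)
  }
  # 9-bp deletion: below the candidate floor
  expect_equal(nrow(cand_of(mkread(250L, 259L))), 0L)
  # 15-bp deletion: one candidate, net 15
  c15 <- filter_artifact_indels(cand_of(mkread(250L, 265L)))
  expect_equal(nrow(c15), 1L)
  expect_equal(c15$net, 15L)
  # a mock low-quality segment: position-wise transformed copy of the
  # deleted reference bases, so it cannot re-align against them
  garble <- function(left, len) {
    chartr("ACGT", "CATG", substr0(amp$seq, left, left + len))
  }
  # 30-bp deletion with adjacent 28-bp insertion: net 2, discarded
  art <- cand_of(mkread(250L, 280L, garble(250L, 28L)))
  expect_equal(nrow(art), 1L)
  kept <- filter_artifact_indels(art)
  expect_equal(nrow(kept), 0L)
  expect_equal(attr(kept, "discarded")$net, 2L)
  # 45-bp deletion with 30-bp insertion: retained, net 15
  mix <- filter_artifact_indels(cand_of(mkread(250L, 295L, garble(250L, 30L))))
  expect_equal(nrow(mix), 1L)
  expect_equal(mix$net, 15L)
})

test_that("junction bases match a brute-force placement oracle", {
  amp <- fixture_amplicon(seed = 101)
  # blunt junction in random sequence: usually small or zero microhomology;
  # must agree with the oracle for every random instance
  set.seed(33)
  for (rep in 1:25) {
    L <- nchar(amp$seq)
    left <- sample(60:(L - 120), 1)
    size <- sample(10:60, 1)
    cj <- canonicalize_junction(amp$seq, left, left + size)
    orc <- oracle_junction(amp$seq, left, left + size)
    expect_equal(cj$left, orc$left)
    expect_equal(cj$mh_len, orc$mh_len)
  }

  # engineered flanks: ...TTAGC [AGCGGGGGGGGG] AGCAA... -> deleting the
  # bracketed segment leaves ...TTAGC|AGCAA..., microhomology AGC (the
  # junction slides over the shared AGC), leftmost placement
  ref <- paste0(random_reference(50, 3), "TTAGC", "AGCGGGGGGGGG", "AGCAA",
                random_reference(50, 4))
  cj <- canonicalize_junction(ref, 55L, 67L)
  expect_equal(cj$mh_len, 3L)
  expect_equal(cj$mh_seq, "AGC")
  expect_equal(cj$left, 55L)

  # inserted bases are mutually exclusive with microhomology
  cji <- canonicalize_junction(ref, 55L, 67L, ins = "TTTTT")
  expect_equal(cji$mh_len, 0L)
  expect_equal(cji$ins, "TTTTT")
})

test_that("infer_junction_bases reports planted ectopic inserts verbatim", {
  amp <- fixture_amplicon(seed = 111)
  # novel bases that cannot re-align against the deleted segment
  ins <- chartr("ACGT", "CATG", substr0(amp$seq, 250L, 275L))
  ins <- substr(ins, 1, 25)
  read <- apply_event_to_seq(amp$seq, 250L, 310L, ins)
  path <- align_to_amplicon(read, amp)
  cand <- filter_artifact_indels(extract_deletions(path, read))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$net, 35L)
  jb <- infer_junction_bases(cand[1, ], read, amp)
  expect_true(jb$valid)
  expect_equal(jb$ins_seq, ins)
  expect_equal(jb$mh_len, 0L)
})

test_that("path deduplication collapses PCR duplicates conservatively", {
  amp <- fixture_amplicon(seed = 121)
  read <- apply_event_to_seq(amp$seq, 250L, 290L)
  # 50 identical copies of one molecule and an amplicon-sharing twin
  merged <- merged_from_molecules(c(read, read), copies = 25L)
  cj <- call_junctions(
    list(seq1 = merged$seq, qual1 = merged$qual,
         seq2 = revcomp(merged$seq), qual2 = merged$qual,
         id = sprintf("p%d", seq_len(nrow(merged)))),
    amplicons = list(amp))
  expect_equal(nrow(cj$calls), 1L)
  expect_equal(cj$calls$reads, 50L)
  expect_equal(cj$log$unique_paths, 1L)

  # same junction observed in two different amplicons: two unique events
  amp2 <- amplicon_def(amp$chrom, amp$start, amp$end, amp$seq, name = "ampB")
  calls <- data.frame(amplicon = c("ampA", "ampB"),
                      left_bp = 1250L, right_bp = 1290L, net = 40L,
                      del_len = 40L, ins_len = 0L, mh_len = 0L, mh_seq = "",
                      ins_seq = "", size = 40L,
                      junction_key = "1250:1290:",
                      path_key = c("ampA 1250:1290:", "ampB 1250:1290:"),
                      reads = 1L, mean_baseq = 33, map_conf = 60,
                      rep_id = c("x", "y"))
  dd <- dedup_paths(calls)
  expect_equal(attr(dd, "unique_events"), 2L)
})

test_that("quality filters reject low base quality and ambiguous placements", {
  calls <- data.frame(amplicon = "a", left_bp = 1L, right_bp = 20L,
                      mean_baseq = c(33, 24.9, 33),
                      map_conf = c(60, 60, 0))
  out <- apply_quality_filters(calls)
  expect_equal(nrow(out), 1L)
  rej <- attr(out, "rejected")
  expect_setequal(rej$reason, c("base_quality", "map_conf"))

  # a read matching a duplicated segment has two equal placements:
  # mapping confidence 0
  block <- random_reference(290, 131)
  dup_amp <- amplicon_def("chrT", 0L, 580L, paste0(block, block),
                          name = "dup")
  p <- align_to_amplicon(block, dup_amp)
  expect_true(p$aligned)
  expect_equal(p$map_conf, 0)
})
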