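test_that("sample_cut_sites follows the map's probability distribution", {
  spike <- spo_map("c", 100L, c(0, 0, 7, 0))
  expect_true(all(sample_cut_sites(spike, 50L, seed = 1) == 102L))
  expect_identical(sample_cut_sites(spike, 0L), integer(0))
  expect_error(sample_cut_sites(spo_map("c", 0L, c(0, 0)), 5L), "no signal")

  # two spikes with 3:1 weights: empirical ratio within 3 binomial SE
  two <- spo_map("c", 0L, c(3, 0, 0, 1))
  x <- sample_cut_sites(two, 40000L, seed = 7)
  p_hat <- mean(x == 0L)
  se <- sqrt(0.75 * 0.25 / 40000)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("double-cut spacings follow the lattice mixture with a hard minimum", {
  # degenerate model: all mass on 21, no jitter
  m0 <- spacing_model(lattice = 21L, weights = 1, jitter_sd = 0)
  map <- spo_map("c", 0L, rep(1, 100))
  cuts <- make_double_cuts(map, 50L, m0, seed = 3)
  expect_true(all(cuts$spacing == 21L))
  expect_true(all(cuts$right_cut - cuts$left_cut == cuts$spacing))

  # default model: histogram modes at lattice points +/- 1 bp, minimum 21
  md <- spacing_model()
  set.seed(1)
  sp <- replicate(10000, meiodel:::draw_spacing(md))
  expect_true(all(sp >= 21L))
  tab <- table(sp)
  for (lat in c(21L, 31L, 41L, 51L)) {
    window <- as.character((lat - 4L):(lat + 4L))
    local_mode <- as.integer(names(which.max(tab[intersect(window, names(tab))])))
    expect_lte(abs(local_mode - lat), 1L)
  }

  # mixture weights recovered within 3 SE (component = nearest lattice point)
  comp <- vapply(sp, function(s) which.min(abs(c(21, 31, 41, 51) - s)), 0L)
  for (k in 1:4) {
    p <- md$weights[k]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(comp == k) - p), 3 * se + 0.01)
  }
})

test_that("unresected joining places the junction at the cuts minus drawn microhomology", {
  ref <- random_reference(400, seed = 21)
  cuts <- data.frame(chromatid = 1L, left_cut = 150L, right_cut = 181L,
                     spacing = 31L)
  # forced MH = 0: deletion exactly [left_cut, right_cut)
  ev0 <- join_ends(cuts, ref, repair_model(mh_probs = c(1, 0, 0)), seed = 5)
  expect_equal(ev0$size, 31L)
  cj <- canonicalize_junction(ref, 150L, 181L)
  expect_equal(ev0$left_bp, cj$left)
  expect_equal(ev0$right_bp, cj$right)

  # forced MH = 2: size = spacing - 2
  ev2 <- join_ends(cuts, ref, repair_model(mh_probs = c(0, 0, 1)), seed = 5)
  expect_equal(ev2$size, 29L)
})

test_that("resected joining uses a planted microhomology repeat", {
  set.seed(8)
  base <- strsplit(random_reference(400, seed = 31), "")[[1]]
  motif <- strsplit("ACGTACGGTT", "")[[1]]
  # plant the 10-bp motif left of the left cut and right of the right cut,
  # with mismatching bases on both sides of each copy to stop extension
  base[101:110] <- motif; base[100] <- "A"; base[111] <- "C"
  base[251:260] <- motif; base[250] <- "T"; base[261] <- "G"
  ref <- paste(base, collapse = "")
  cuts <- data.frame(chromatid = 1L, left_cut = 160L, right_cut = 200L,
                     spacing = 40L)
  rm <- repair_model("resected", min_mh = 10L, max_search = 120L)
  ev <- join_ends(cuts, ref, rm, seed = 2)
  expect_false(ev$fallback)
  expect_equal(ev$mh_len, 10L)
  expect_equal(ev$mh_seq, "ACGTACGGTT")
  # junction: keep left copy [100,110), resume at right copy [250,260):
  # deleted interval canonicalized to [100, 250)
  expect_equal(ev$left_bp, 100L)
  expect_equal(ev$right_bp, 250L)
  expect_equal(ev$size, 150L)
})

test_that("resection lengths recover the configured gamma mean", {
  rm <- repair_model("resected", resection_mean = 1100, resection_shape = 4)
  set.seed(1)
  draws <- stats::rgamma(20000, shape = rm$resection_shape,
                         scale = rm$resection_mean / rm$resection_shape)
  se <- sqrt(rm$resection_mean^2 / rm$resection_shape / 20000)
  expect_lt(abs(mean(draws) - 1100), 2 * se)
})

test_that("insertion events carry the donor sequence with source bookkeeping", {
  ref <- random_reference(500, seed = 41)
  cuts <- data.frame(chromatid = 1L, left_cut = 200L, right_cut = 260L,
                     spacing = 60L)
  ev <- join_ends(cuts, ref, repair_model(mh_probs = c(1, 0, 0)), seed = 9)

  donor_map <- simulate_spo11_map(chrom = "chrD", center = 3000L,
                                  window = 400L, seed = 17)
  donor_ref <- random_reference(6000, seed = 18)
  dc <- make_double_cuts(donor_map, 1L, seed = 4)
  frag <- substr(donor_ref, dc$left_cut + 1L, dc$right_cut)

  ins <- make_insertion_event(ev, ref, "ectopic", donor_seq = frag,
                              donor_source = "hsD", orientation = "fwd")
  expect_equal(ins$ins_seq, frag)
  expect_equal(ins$ins_class, "ectopic")
  expect_equal(ins$ins_source, "hsD")
  expect_equal(ins$mh_len, 0L)

  inv <- make_insertion_event(ev, ref, "inverted", seed = 6)
  expect_equal(inv$ins_class, "inverted")
  # the insert is the reverse complement of a local segment
  src <- as.integer(strsplit(sub("local:", "", inv$ins_source), "-")[[1]])
  expect_equal(inv$ins_seq, revcomp(substr(ref, src[1] + 1L, src[2])))
  # microhomology (1 shared base) at exactly one junction
  lflank <- substr(ref, inv$left_bp, inv$left_bp)
  rflank <- substr(ref, inv$right_bp + 1L, inv$right_bp + 1L)
  first <- substr(inv$ins_seq, 1, 1)
  last <- substr(inv$ins_seq, nchar(inv$ins_seq), nchar(inv$ins_seq))
  expect_true(xor(first == lflank, last == rflank))
})

test_that("ectopic donor midpoints follow the donor hotspot map", {
  donor_map <- simulate_spo11_map(chrom = "chrD", center = 3000L,
                                  window = 300L, seed = 23)
  dc <- make_double_cuts(donor_map, 1000L, seed = 13)
  mid <- (dc$left_cut + dc$right_cut) / 2
  # donor cut sites concentrate at the map's peaks: the mean absolute
  # distance of fragment midpoints from the hotspot center stays within the
  # peak region (major at 0, secondary at +34/+55), far below the window size
  expect_lt(abs(median(mid - 3000 - median(dc$spacing) / 2)), 60)
  expect_gt(mean(abs(mid - 3000) < 120), 0.9)
})

test_that("well assay frequencies follow the planted / Poisson arithmetic", {
  expect_equal(simulate_well_assay(0, wells = 300L)$frequency, 0)

  one <- simulate_well_assay(0, wells = 300L, genomes_per_well = 16000L,
                             planted = 1L)
  expect_equal(one$total_events, 1L)
  expect_equal(round(one$frequency * 1e6, 1), 0.2)

  # mean estimate over 500 replicates within 2 SE of the true rate
  rate <- 5e-6
  est <- vapply(1:500, function(s) {
    simulate_well_assay(rate, wells = 300L, seed = s)$frequency
  }, numeric(1))
  genomes <- 300 * 16000
  se_mean <- sqrt(rate / genomes / 500)
  expect_lt(abs(mean(est) - rate), 2 * se_mean)
})

test_that("amplicon read simulation tracks molecules and errors faithfully", {
  amp <- fixture_amplicon(seed = 51)
  ev <- data.frame(event_id = "e1", left_bp = amp$start + 250L,
                   right_bp = amp$start + 310L, ins_seq = "")
  mol <- molecules_from_events(ev, amp)
  expect_equal(nchar(mol$seq), 520L)

  # zero error: every pair reconstructs the same junction sequence
  reads <- simulate_amplicon_reads(mol, depth = 50L, error_rate = 0, seed = 3)
  expect_true(all(reads$seq1 == reads$seq1[1]))
  expect_true(all(reads$seq2 == reads$seq2[1]))
  expect_equal(reads$seq1[1], substr(mol$seq[1], 1, 300))

  # duplication truth tracking: all 50 pairs name the same molecule
  ids <- parse_read_ids(reads$id)
  expect_true(all(ids$mol_id == 1L))
  expect_true(all(ids$event_id == "e1"))
  expect_equal(ids$copy, 1:50)

  # substitution rate recovered within 3 binomial SE
  reads2 <- simulate_amplicon_reads(mol, depth = 5000L, error_rate = 0.001,
                                    seed = 5)
  truth1 <- utf8ToInt(substr(mol$seq[1], 1, 300))
  mm <- vapply(reads2$seq1, function(s) sum(utf8ToInt(s) != truth1), 0,
               USE.NAMES = FALSE)
  p_hat <- sum(mm) / (5000 * 300)
  se <- sqrt(0.001 * 0.999 / (5000 * 300))
  expect_lt(abs(p_hat - 0.001), 3 * se)
  # error positions are flagged with low quality
  i <- which(mm > 0)[1]
  bad <- which(utf8ToInt(reads2$seq1[i]) != truth1)
  expect_true(all(utf8ToInt(reads2$qual1[i])[bad] - 33L == 12L))
})
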