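#' Pipeline run configuration
#'
#' A declarative description of a full simulate-call-profile run. All
#' stochastic stages derive their seeds deterministically from the master
#' seed and the stage name, so a configuration fully determines the output.
#'
#' @param seed Master seed (integer).
#' @param genotype Genotype label recorded on simulated events.
#' @param n_events Number of simulated deletion events.
#' @param n_ref Intact reference molecules mixed into the library.
#' @param depth Read pairs sequenced.
#' @param error_rate Per-base substitution error rate.
#' @param repair A [repair_model()].
#' @param spacing A [spacing_model()].
#' @param amplicon_len Amplicon length in bp (default 580).
#' @param read_len Read length (default 300).
#' @param min_net,min_mean_baseq,min_map_conf Caller thresholds.
#' @param out_dir Output directory (`NULL` = nothing written).
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(seed = 1L, genotype = "sim", n_events = 100L,
                       n_ref = 50L, depth = 2000L, error_rate = 0.001,
                       repair = repair_model(), spacing = spacing_model(),
                       amplicon_len = 580L, read_len = 300L,
                       min_net = 10L, min_mean_baseq = 25, min_map_conf = 55,
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), genotype = genotype,
              n_events = as.integer(n_events), n_ref = as.integer(n_ref),
              depth = as.integer(depth), error_rate = error_rate,
              repair = repair, spacing = spacing,
              amplicon_len = as.integer(amplicon_len),
              read_len = as.integer(read_len),
              min_net = as.integer(min_net),
              min_mean_baseq = min_mean_baseq, min_map_conf = min_map_conf,
              out_dir = out_dir)
  stopifnot(cfg$n_events >= 0L, cfg$depth >= 1L, cfg$amplicon_len >= 100L)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> seed %d, %d events (%s, %s repair), depth %d, error %.4g\n",
              x$seed, x$n_events, x$genotype, x$repair$mode, x$depth,
              x$error_rate))
  invisible(x)
}

#' Run the simulate - call - profile pipeline
#'
#' Executes any subset of the three stages on a self-contained synthetic
#' locus: a hotspot-shaped SPO11-oligo map on a random reference, double
#' cuts joined under the configured repair model, an amplicon library
#' sequenced to the configured depth, the junction caller, and the
#' breakpoint statistics. Output is a pure function of the configuration:
#' identical configurations give byte-identical output files.
#'
#' @param config A [run_config()].
#' @param stages Character subset of `c("simulate", "call", "stats")`.
#' @return List with `truth` (simulated events), `reads`, `calls`,
#'   `stats`, `map`, `amplicon`, and `log` (per-stage record counts and the
#'   effective configuration).
#' @export
run_pipeline <- function(config, stages = c("simulate", "call", "stats")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  log <- list(config = config[setdiff(names(config),
                                      c("repair", "spacing"))],
              repair_mode = config$repair$mode)
  res <- list(log = log)

  # locus: reference window with the amplicon centered on the hotspot
  ref_len <- config$amplicon_len + 400L
  ref <- random_reference(ref_len, seed = derive_seed(config$seed, "ref"))
  center <- ref_len %/% 2L
  map <- simulate_spo11_map(chrom = "chrSim", center = center,
                            window = min(center - 10L, 500L),
                            seed = derive_seed(config$seed, "map"))
  amp_start <- center - config$amplicon_len %/% 2L
  amplicon <- amplicon_def("chrSim", amp_start,
                           amp_start + config$amplicon_len,
                           substr0(ref, amp_start,
                                   amp_start + config$amplicon_len),
                           name = "amp1")
  res$map <- map
  res$amplicon <- amplicon
  res$center <- center

  if ("simulate" %in% stages) {
    guard <- config$amplicon_len %/% 2L - 60L
    cuts <- make_double_cuts(map, config$n_events, config$spacing,
                             seed = derive_seed(config$seed, "cuts"))
    # keep events inside the amplicon (resimulate out-of-bounds cuts by
    # clamping to the admissible window)
    cuts$left_cut <- pmin(pmax(cuts$left_cut, center - guard),
                          center + guard - cuts$spacing)
    cuts$right_cut <- cuts$left_cut + cuts$spacing
    # the amplicon bounds what is observable: cap the resected-mode
    # microhomology search so junctions stay within the amplicon
    rep_cfg <- config$repair
    rep_cfg$max_search <- min(rep_cfg$max_search,
                              config$amplicon_len %/% 2L - guard - 10L)
    truth <- join_ends(cuts, ref, rep_cfg, genotype = config$genotype,
                       seed = derive_seed(config$seed, "join"))
    res$truth <- truth
    mol <- molecules_from_events(truth, amplicon, n_ref = config$n_ref)
    res$reads <- simulate_amplicon_reads(
      mol, depth = config$depth, read_len = config$read_len,
      error_rate = config$error_rate,
      seed = derive_seed(config$seed, "reads"))
    res$log$molecules <- nrow(mol)
  }

  if ("call" %in% stages) {
    if (is.null(res$reads)) stop("call stage needs simulated (or loaded) reads")
    cj <- call_junctions(res$reads, amplicons = list(amplicon),
                         min_net = config$min_net,
                         min_mean_baseq = config$min_mean_baseq,
                         min_map_conf = config$min_map_conf)
    res$calls <- cj$calls
    res$log <- c(res$log, cj$log)
  }

  if ("stats" %in% stages && !is.null(res$calls) && nrow(res$calls) > 0L) {
    rel <- c(res$calls$left_bp, res$calls$right_bp) - center
    res$stats <- list(
      n_junctions = nrow(res$calls),
      center_fraction = center_window_fraction(rel),
      mh0_fraction = mean(res$calls$mh_len == 0 &
                            !nzchar(res$calls$ins_seq)),
      strata = stratify_sizes(res$calls, center = center))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(config$out_dir, f)
    if (!is.null(res$truth)) {
      utils::write.table(res$truth, pth("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$reads)) {
      write_fastq_pairs(res$reads, pth("reads_R1.fastq"), pth("reads_R2.fastq"))
    }
    if (!is.null(res$calls)) {
      write_junctions_tsv(res$calls, pth("junctions.tsv"))
      write_junctions_bedpe(res$calls, pth("junctions.bedpe"),
                            chrom = amplicon$chrom)
    }
    jsonlite::write_json(res$log, pth("run_log.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  res
}

#' Materialize a toy fixture dataset
#'
#' Writes a complete self-contained toy dataset to `dir`: a random
#' reference, two hotspot pairs with simulated SPO11-oligo maps (bedGraph),
#' hotspot definitions (BED6), four overlapping amplicon definitions (BED)
#' with the reference as FASTA, and a small paired-FASTQ amplicon library
#' with its ground-truth event table.
#'
#' @param dir Output directory.
#' @param ref_len Reference length (default 50 kb).
#' @param seed Master seed.
#' @param n_events,depth Library size knobs (kept small by default).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, ref_len = 50000L, seed = 1L,
                          n_events = 60L, depth = 1200L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- random_reference(ref_len, seed = derive_seed(seed, "fixref"))
  centers <- as.integer(ref_len * c(0.2, 0.3, 0.6, 0.72))
  maps <- lapply(seq_along(centers), function(i) {
    simulate_spo11_map(chrom = "chrFix", center = centers[i], window = 900L,
                       seed = derive_seed(seed, paste0("fixmap", i)))
  })
  hs <- lapply(maps, function(m) {
    call_hotspot(m, m$start + 400L, m$start + length(m$counts) - 400L)
  })
  names(hs) <- sprintf("hs%d", seq_along(hs))
  files <- c()
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(ref, "chrFix")), fa)
  files["reference"] <- fa
  for (i in seq_along(maps)) {
    f <- file.path(dir, sprintf("spo11_hs%d.bedgraph", i))
    write_spo11_track(maps[[i]], f)
    files[sprintf("map%d", i)] <- f
  }
  bed <- file.path(dir, "hotspots.bed")
  write_hotspots_bed(hs, bed)
  files["hotspots"] <- bed
  # four overlapping ~580-bp amplicons spanning ~900 bp of the first hotspot
  amp_starts <- centers[1L] - 450L + as.integer(c(0, 110, 215, 320))
  amps <- data.frame(chrom = "chrFix", start = amp_starts,
                     end = amp_starts + 580L,
                     name = sprintf("amp%d", 1:4), score = 0L, strand = "+")
  ampbed <- file.path(dir, "amplicons.bed")
  utils::write.table(amps, ampbed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files["amplicons"] <- ampbed
  # a small library on amplicon 2
  a2 <- amplicon_def("chrFix", amps$start[2L], amps$end[2L],
                     substr0(ref, amps$start[2L], amps$end[2L]),
                     name = "amp2")
  cuts <- make_double_cuts(maps[[1L]], n_events,
                           seed = derive_seed(seed, "fixcuts"))
  guard <- 230L
  cuts$left_cut <- pmin(pmax(cuts$left_cut, centers[1L] - guard),
                        centers[1L] + guard - cuts$spacing)
  cuts$right_cut <- cuts$left_cut + cuts$spacing
  truth <- join_ends(cuts, ref, repair_model("unresected"),
                     genotype = "fixture", seed = derive_seed(seed, "fixjoin"))
  mol <- molecules_from_events(truth, a2, n_ref = 40L)
  reads <- simulate_amplicon_reads(mol, depth = depth,
                                   seed = derive_seed(seed, "fixreads"))
  write_fastq_pairs(reads, file.path(dir, "reads_R1.fastq"),
                    file.path(dir, "reads_R2.fastq"))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["fastq1"] <- file.path(dir, "reads_R1.fastq")
  files["fastq2"] <- file.path(dir, "reads_R2.fastq")
  files["truth"] <- file.path(dir, "truth.tsv")
  invisible(files)
}
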