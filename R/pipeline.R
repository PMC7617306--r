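#' Thresholds of the clone-fate pipeline
#'
#' Collects every tunable threshold of the analysis: the library reference
#' rule, the detection filter, the significance and fold-change gates of
#' the decision tree, the variability gates and the high-well bar.
#'
#' @param min_total_reads Library-reference threshold: minimum summed reads
#'   across the viral-library samples (default 100).
#' @param min_detect_total Detection filter: minimum summed reads across
#'   the alone wells at the reference timepoint (default 9).
#' @param reference_timepoint Timepoint of the alone-arm detection samples.
#' @param padj_cut,lfc_cut Significance and log2 fold-change gates of rules
#'   i/ii (defaults 0.05 and 1).
#' @param v_alone_cut,v_nk_cut Variability gates of rules iii/iv (defaults
#'   0.5 and 1).
#' @param high_well_bar Doubling bar of the high-well rule (default 1).
#' @param sf_method Size-factor method used by the pipeline (default
#'   `"total"`; see [size_factors()]).
#' @param recenter Re-anchor fold changes on rule-static clones (default
#'   `TRUE`). Because sequencing measures relative abundance, wholesale
#'   elimination of clones in the NK arm shifts every clone's apparent fold
#'   change upward-compressed (a composition shift); after a first
#'   classification pass the NK-arm size factors are rescaled so that the
#'   median fold change of the clones the variability rules call static is
#'   zero, and statistics and calls are recomputed once. Skipped when
#'   fewer than `max(10, 2%)` of clones are called static in the first
#'   pass.
#' @return Named list of thresholds.
#' @export
pipeline_thresholds <- function(min_total_reads = 100,
                                min_detect_total = 9,
                                reference_timepoint = "TP1",
                                padj_cut = 0.05, lfc_cut = 1,
                                v_alone_cut = 0.5, v_nk_cut = 1,
                                high_well_bar = 1,
                                sf_method = "total",
                                recenter = TRUE) {
  list(min_total_reads = min_total_reads,
       min_detect_total = min_detect_total,
       reference_timepoint = reference_timepoint,
       padj_cut = padj_cut, lfc_cut = lfc_cut,
       v_alone_cut = v_alone_cut, v_nk_cut = v_nk_cut,
       high_well_bar = high_well_bar, sf_method = sf_method,
       recenter = recenter)
}

#' Run the full clone-fate pipeline on simulated data
#'
#' End-to-end driver: generates a barcode library and co-culture counts
#' from `config`, optionally synthesizes raw FASTQ reads and re-extracts
#' barcode counts from them, restricts counts to the library reference,
#' merges technical replicates, applies the detection filter, computes
#' per-sample Shannon diversity and per-clone statistics at each timepoint,
#' classifies clone fates, and summarizes category proportions. Ground
#' truth is retained for recovery checks. The run is deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @param thresholds A [pipeline_thresholds()] list.
#' @param read_level Synthesize FASTQ reads and recover counts through
#'   [count_sample()] (the faithful full pipeline). With `FALSE` the
#'   simulated count matrix is used directly, skipping read synthesis (no
#'   QC table; much faster for exploration).
#' @param dir Directory for FASTQ files when `read_level = TRUE`.
#' @param keep_fastq Keep the FASTQ files (default: delete after
#'   extraction).
#' @return Object of class `clone_run` with elements `config`,
#'   `thresholds`, `truth`, `reference`, `qc` (per-sample extraction QC,
#'   read-level runs only), `off_reference`, `retained` (barcodes passing
#'   the detection filter), `counts` (merged, filtered, normalized long
#'   tibble), `size_factors`, `diversity`, `stats` (per-timepoint
#'   [clone_stats()] tables), `calls`, `summary`, and a reproducibility
#'   `manifest`.
#' @examples
#' run <- run_pipeline(generator_config(n_clones = 60, seed = 4),
#'                     read_level = FALSE)
#' run$summary
#' @export
run_pipeline <- function(config = generator_config(),
                         thresholds = pipeline_thresholds(),
                         read_level = TRUE,
                         dir = tempfile("clonefate"),
                         keep_fastq = FALSE) {
  lib <- generate_library(config)
  sim_counts <- simulate_coculture(lib, config)
  qc <- NULL
  if (read_level) {
    files <- synthesize_reads(sim_counts, lib, config, dir = dir)
    per_sample <- purrr::map(seq_len(nrow(files)), function(i) {
      res <- count_sample(files$path[i], head = config$head,
                          tail = config$tail,
                          expected_length = config$barcode_length)
      list(counts = mutate(tidy(res), sample_id = files$sample_id[i]),
           qc = mutate(res$qc, sample_id = files$sample_id[i],
                       total = res$total,
                       discard_fraction = res$discard_fraction))
    })
    observed <- bind_rows(purrr::map(per_sample, "counts"))
    qc <- bind_rows(purrr::map(per_sample, "qc"))
    if (!keep_fastq) unlink(dir, recursive = TRUE)
    meta <- meta_from_counts(sim_counts)
    observed <- left_join(observed, meta, by = "sample_id")
  } else {
    observed <- sim_counts
  }
  reference <- build_reference(lib$library_counts,
                               min_total_reads = thresholds$min_total_reads)
  matched <- match_to_reference(observed, reference)
  off_ref <- off_reference(matched)
  # complete the barcode x sample grid so wells with zero reads are explicit
  meta <- meta_from_counts(if (read_level) observed else sim_counts)
  full <- tidyr::complete(
    matched[, c("barcode", "sample_id", "count")],
    barcode = reference$barcode,
    sample_id = meta$sample_id,
    fill = list(count = 0)) %>%
    left_join(meta, by = "sample_id")
  merged <- merge_technical_replicates(full)
  retained <- detection_filter(
    merged, reference_timepoint = thresholds$reference_timepoint,
    min_total = thresholds$min_detect_total)
  kept <- filter(merged, .data$barcode %in% retained)
  diversity <- sample_diversity(kept)
  timepoints <- sort(unique(kept$timepoint))
  staged <- purrr::map(timepoints, function(tp) {
    classify_at_timepoint(kept, tp, thresholds)
  })
  names(staged) <- timepoints
  stats_by_tp <- purrr::map(staged, "stats")
  calls <- bind_rows(purrr::map(staged, "calls"))
  recenter_delta <- purrr::map_dbl(staged, "delta")
  fate_summary <- summarize_fates(calls)
  norm <- shifted_log_normalize(
    kept, factors = NULL,
    method = if (thresholds$sf_method == "total") "total" else "median-ratio")
  manifest <- list(package = "clonefate",
                   version = as.character(packageVersion("clonefate")),
                   r_version = as.character(getRversion()),
                   seed = config$seed,
                   read_level = read_level,
                   config_hash = hash(unclass(config)),
                   recenter_delta = recenter_delta,
                   thresholds = thresholds)
  structure(list(config = config, thresholds = thresholds,
                 truth = lib$truth, reference = reference,
                 qc = qc, off_reference = off_ref,
                 retained = retained, counts = norm,
                 size_factors = distinct(norm[, c("sample_id", "size_factor")]),
                 diversity = diversity, stats = stats_by_tp,
                 calls = calls, summary = fate_summary,
                 manifest = manifest),
            class = "clone_run")
}

# one classification pass; with recentring, a second pass after rescaling
# the NK-arm size factors so rule-static clones sit at log2 fold change 0
classify_at_timepoint <- function(kept, tp, thresholds) {
  classify_with <- function(stats) {
    classify_clones(stats, padj_cut = thresholds$padj_cut,
                    lfc_cut = thresholds$lfc_cut,
                    v_alone_cut = thresholds$v_alone_cut,
                    v_nk_cut = thresholds$v_nk_cut)
  }
  sub <- filter(kept, .data$timepoint == tp)
  factors <- size_factors(
    sub, method = if (thresholds$sf_method == "total") "total"
                  else "median-ratio")
  s1 <- clone_stats(kept, timepoint = tp, factors = factors,
                    high_well_bar = thresholds$high_well_bar)
  c1 <- classify_with(s1)
  if (!isTRUE(thresholds$recenter)) {
    return(list(stats = s1, calls = c1, delta = 0))
  }
  static_bcs <- c1$barcode[c1$category == "static"]
  if (length(static_bcs) < max(10, 0.02 * nrow(s1))) {
    return(list(stats = s1, calls = c1, delta = 0))
  }
  delta <- median(s1$log2fc[s1$barcode %in% static_bcs])
  meta <- meta_from_counts(sub)
  is_nk <- meta$condition[match(factors$sample_id, meta$sample_id)] == "nk"
  factors$size_factor[is_nk] <- factors$size_factor[is_nk] * 2^delta
  # only the cross-arm test is recomputed: variability and the high-well
  # count are within-arm statistics and keep their first-pass normalization
  da2 <- diff_abundance(sub, timepoint = tp, factors = factors)
  s2 <- left_join(da2$result,
                  s1[, c("barcode", "v_alone", "v_nk", "n_high_wells")],
                  by = "barcode")
  attr(s2, "timepoint") <- tp
  list(stats = s2, calls = classify_with(s2), delta = delta)
}

#' @export
print.clone_run <- function(x, ...) {
  cat(sprintf("<clone_run> %d clones simulated, %d in reference, %d retained (seed %d)\n",
              nrow(x$truth), nrow(x$reference), length(x$retained),
              x$config$seed))
  if (!is.null(x$qc)) {
    cat(sprintf("  mean discard fraction: %.3f\n",
                mean(distinct(x$qc, .data$sample_id,
                              .data$discard_fraction)$discard_fraction)))
  }
  tp2 <- filter(x$summary, .data$timepoint == max(x$summary$timepoint))
  cat("  fate proportions at", as.character(max(x$summary$timepoint)), "\n")
  print(tp2)
  invisible(x)
}

#' Recovery of generating fates by the classifier
#'
#' Joins the pipeline's fate calls at one timepoint against the simulation
#' ground truth and tabulates, per generating fate, how many clones
#' received each category.
#'
#' @param run A [run_pipeline()] result.
#' @param timepoint Timepoint of the calls to score (default `"TP2"`, where
#'   the headline proportions are read).
#' @return Tibble `fate` (generating), `category` (called), `n`,
#'   `recovery` (share of the generating fate's clones).
#' @export
fate_recovery <- function(run, timepoint = "TP2") {
  calls <- filter(run$calls, .data$timepoint == !!timepoint)
  truth <- run$truth[, c("barcode", "fate")]
  calls %>%
    left_join(truth, by = "barcode") %>%
    count(.data$fate, .data$category, name = "n") %>%
    group_by(.data$fate) %>%
    mutate(recovery = .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Export the main result tables of a run as TSV
#'
#' Writes the fate calls, fate summary, per-sample diversity, QC and
#' reference tables, plus the run manifest as JSON.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_tables <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(run$calls, "fate_calls.tsv")
  tsv(run$summary, "fate_summary.tsv")
  tsv(run$diversity, "diversity.tsv")
  tsv(as_tibble(run$reference), "reference.tsv")
  if (!is.null(run$qc)) tsv(run$qc, "extraction_qc.tsv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
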