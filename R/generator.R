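#' Configuration for the synthetic co-culture generator
#'
#' Bundles every parameter of the synthetic-data generator: the barcode
#' library, the clone-fate model of the co-culture (tumour cells alone vs
#' tumour cells plus NK cells, two sampling timepoints, replicate wells
#' sequenced in technical duplicate), the negative-binomial count noise, and
#' the raw-read synthesis including a malformed-read fraction.
#'
#' Defaults mirror the experimental design the generator emulates: a 21-nt
#' random barcode insert flanked by the fixed anchors [BC_HEAD] and
#' [BC_TAIL] on 64-bp single-end reads, three replicate wells per condition
#' sequenced in technical duplicate at 50-100 reads per barcode (75 by
#' default), and a ~15% malformed-read rate. The default fate weights are
#' the observed per-category mean proportions on day 14 of NK co-culture:
#' 58.5% eliminated, 14.3% primary resistant, 23.9% static, 3.3% secondary
#' resistant.
#'
#' @param n_clones Number of barcoded founder clones (>= 0).
#' @param barcode_length Barcode insert length in nt (default 21).
#' @param fate_weights Named probabilities over
#'   `c("eliminated","primary_resistant","static","secondary_resistant","other")`;
#'   must sum to 1.
#' @param effect_sizes Named log2 fold changes applied in the NK arm:
#'   `eliminated` (negative), `primary_resistant` (positive),
#'   `secondary_resistant` (positive; applied in a single well at the late
#'   timepoint only, the remaining wells behave as eliminated), `static`
#'   (0), and `other` (standard deviation of i.i.d. per-well effects).
#' @param dispersion Negative-binomial overdispersion alpha (>= 0; variance
#'   `mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param depth_per_barcode Mean reads per barcode per technical replicate.
#' @param malformed_fraction Expected fraction of synthesized reads that are
#'   defective (default 0.15).
#' @param malformed_mix Named proportions over defect classes
#'   `c("short_insert","long_insert","uncalled_base","missing_head","missing_tail")`;
#'   must sum to 1.
#' @param n_wells Replicate wells per condition (default 3).
#' @param n_techreps Technical sequencing replicates per well (default 2).
#' @param n_library_samples Viral-library reference samples (default 4).
#' @param read_length Read length in nt (default 64).
#' @param founder_sigma Log-normal sigma of founder clone abundances.
#' @param library_sigma Log-normal sigma of barcode frequencies in the viral
#'   library samples.
#' @param head,tail Anchor sequences flanking the barcode.
#' @param cell_line Cell-line label recorded in sample metadata.
#' @param nk_genotype NK genotype label recorded for the NK arm.
#' @param seed Integer RNG seed; all generator stages are deterministic
#'   given the seed.
#'
#' @return A validated `generator_config` list.
#' @examples
#' cfg <- generator_config(n_clones = 100, seed = 1)
#' cfg$fate_weights
#' @export
generator_config <- function(n_clones = 1000,
                             barcode_length = 21,
                             fate_weights = c(eliminated = 0.585,
                                              primary_resistant = 0.143,
                                              static = 0.239,
                                              secondary_resistant = 0.033,
                                              other = 0),
                             effect_sizes = c(eliminated = -3,
                                              primary_resistant = 3,
                                              static = 0,
                                              secondary_resistant = 3,
                                              other = 1.5),
                             dispersion = 0.05,
                             depth_per_barcode = 75,
                             malformed_fraction = 0.15,
                             malformed_mix = c(short_insert = 0.2,
                                               long_insert = 0.2,
                                               uncalled_base = 0.2,
                                               missing_head = 0.2,
                                               missing_tail = 0.2),
                             n_wells = 3,
                             n_techreps = 2,
                             n_library_samples = 4,
                             read_length = 64,
                             founder_sigma = 0.5,
                             library_sigma = 0.5,
                             head = BC_HEAD,
                             tail = BC_TAIL,
                             cell_line = "A",
                             nk_genotype = "WT",
                             seed = 1L) {
  cfg <- list(n_clones = as.integer(n_clones),
              barcode_length = as.integer(barcode_length),
              fate_weights = fate_weights,
              effect_sizes = effect_sizes,
              dispersion = dispersion,
              depth_per_barcode = depth_per_barcode,
              malformed_fraction = malformed_fraction,
              malformed_mix = malformed_mix,
              n_wells = as.integer(n_wells),
              n_techreps = as.integer(n_techreps),
              n_library_samples = as.integer(n_library_samples),
              read_length = as.integer(read_length),
              founder_sigma = founder_sigma,
              library_sigma = library_sigma,
              head = head, tail = tail,
              cell_line = cell_line, nk_genotype = nk_genotype,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$n_clones) || cfg$n_clones < 0L) {
    abort("`n_clones` must be a non-negative integer")
  }
  if (cfg$barcode_length < 1L) abort("`barcode_length` must be >= 1")
  # uniqueness must be possible in the 4^L barcode space
  if (log(max(cfg$n_clones, 1)) > cfg$barcode_length * log(4)) {
    abort(sprintf(
      "cannot draw %d unique barcodes of length %d (4^%d possible)",
      cfg$n_clones, cfg$barcode_length, cfg$barcode_length))
  }
  fw <- cfg$fate_weights
  if (!setequal(names(fw), FATE_LEVELS)) {
    abort(sprintf("`fate_weights` must be named by: %s",
                  paste(FATE_LEVELS, collapse = ", ")))
  }
  if (any(fw < 0 | fw > 1) || abs(sum(fw) - 1) > 1e-9) {
    abort("`fate_weights` must be probabilities summing to 1 (within 1e-9)")
  }
  mm <- cfg$malformed_mix
  mm_classes <- c("short_insert", "long_insert", "uncalled_base",
                  "missing_head", "missing_tail")
  if (!setequal(names(mm), mm_classes)) {
    abort(sprintf("`malformed_mix` must be named by: %s",
                  paste(mm_classes, collapse = ", ")))
  }
  if (any(mm < 0 | mm > 1) || abs(sum(mm) - 1) > 1e-9) {
    abort("`malformed_mix` must be proportions summing to 1")
  }
  if (cfg$malformed_fraction < 0 || cfg$malformed_fraction >= 1) {
    abort("`malformed_fraction` must be in [0, 1)")
  }
  if (cfg$dispersion < 0) abort("`dispersion` must be >= 0")
  if (cfg$depth_per_barcode <= 0) abort("`depth_per_barcode` must be > 0")
  if (cfg$n_wells < 1L || cfg$n_techreps < 1L || cfg$n_library_samples < 1L) {
    abort("`n_wells`, `n_techreps` and `n_library_samples` must be >= 1")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d clones, %d-nt barcodes, seed %d\n",
              x$n_clones, x$barcode_length, x$seed))
  cat(sprintf("  %d wells x %d techreps/condition, depth %g reads/barcode, dispersion %g\n",
              x$n_wells, x$n_techreps, x$depth_per_barcode, x$dispersion))
  cat("  fate weights:",
      paste(sprintf("%s=%.3f", names(x$fate_weights), x$fate_weights),
            collapse = " "), "\n")
  cat(sprintf("  malformed fraction %.2f, read length %d\n",
              x$malformed_fraction, x$read_length))
  invisible(x)
}

#' Generate a barcode library with simulation ground truth
#'
#' Draws `n_clones` unique random barcodes, assigns each clone a fate i.i.d.
#' from `fate_weights`, draws founder abundances from a normalized
#' log-normal, fixes the per-well NK-arm log2 fold changes implied by the
#' fate, and simulates read counts for the viral-library reference samples.
#'
#' For `secondary_resistant` clones exactly one well (chosen at random)
#' carries the positive expansion effect; the remaining wells carry the
#' eliminated-class effect, so the clone behaves as eliminated except for a
#' single stochastic escape event.
#'
#' @param config A [generator_config()].
#' @return A list of class `clone_library` with elements
#'   * `truth`: tibble with one row per clone (`barcode`, `fate`,
#'     `founder_abundance`, list-column `lfc_by_well`);
#'   * `library_counts`: long tibble of viral-library sample counts
#'     (`barcode`, `sample_id`, `count`).
#' @examples
#' lib <- generate_library(generator_config(n_clones = 50, seed = 7))
#' lib$truth
#' @export
generate_library <- function(config) {
  validate_generator_config(config)
  n <- config$n_clones
  if (n == 0L) {
    return(structure(
      list(truth = tibble(barcode = character(0), fate = character(0),
                          founder_abundance = numeric(0),
                          lfc_by_well = list()),
           library_counts = tibble(barcode = character(0),
                                   sample_id = character(0),
                                   count = integer(0))),
      class = "clone_library"))
  }
  withr::with_seed(config$seed, {
    barcodes <- rand_dna(n, config$barcode_length)
    while (anyDuplicated(barcodes)) {
      dup <- which(duplicated(barcodes))
      barcodes[dup] <- rand_dna(length(dup), config$barcode_length)
    }
    fate <- sample(FATE_LEVELS, n, replace = TRUE, prob = config$fate_weights)
    founder <- rlnorm(n, meanlog = 0, sdlog = config$founder_sigma)
    founder <- founder / sum(founder)
    lfc_by_well <- draw_well_effects(fate, config)
    lib_freq <- rlnorm(n, meanlog = 0, sdlog = config$library_sigma)
    lib_freq <- lib_freq / sum(lib_freq)
    lib_mu <- lib_freq * n * config$depth_per_barcode
    lib <- purrr::map(seq_len(config$n_library_samples), function(j) {
      tibble(barcode = barcodes,
             sample_id = sprintf("library_s%d", j),
             count = draw_nb(lib_mu, config$dispersion))
    })
  })
  structure(
    list(truth = tibble(barcode = barcodes, fate = fate,
                        founder_abundance = founder,
                        lfc_by_well = lfc_by_well),
         library_counts = bind_rows(lib)),
    class = "clone_library")
}

# per-clone vector of NK-arm log2 fold changes, one entry per well
draw_well_effects <- function(fate, config) {
  es <- config$effect_sizes
  nw <- config$n_wells
  purrr::map(seq_along(fate), function(i) {
    switch(fate[i],
      eliminated = rep(es[["eliminated"]], nw),
      primary_resistant = rep(es[["primary_resistant"]], nw),
      static = rep(0, nw),
      secondary_resistant = {
        v <- rep(es[["eliminated"]], nw)
        v[sample.int(nw, 1L)] <- es[["secondary_resistant"]]
        v
      },
      other = rnorm(nw, mean = 0, sd = es[["other"]]))
  })
}

#' @export
print.clone_library <- function(x, ...) {
  cat(sprintf("<clone_library> %d clones, %d library samples\n",
              nrow(x$truth), length(unique(x$library_counts$sample_id))))
  if (nrow(x$truth) > 0) print(count(x$truth, .data$fate))
  invisible(x)
}

# NB draw that degrades to Poisson at dispersion 0
draw_nb <- function(mu, dispersion) {
  mu <- pmax(mu, 0)
  if (dispersion == 0) return(rpois(length(mu), lambda = mu))
  out <- integer(length(mu))
  pos <- mu > 0
  out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion)
  out
}

#' Simulate co-culture barcode counts
#'
#' Produces the full factorial count table of the co-culture experiment:
#' condition (`alone`, `nk`) x timepoint (`TP1`, `TP2`) x replicate well x
#' technical replicate. In the alone arm a clone's expected frequency is its
#' founder abundance at both timepoints. In the NK arm it is
#' `founder * 2^(lfc * timepoint_scale)` renormalized within the sample,
#' with `timepoint_scale` 0.5 at TP1 and 1 at TP2 so selection pressure
#' accumulates over time; the secondary-resistant expansion applies only at
#' TP2 (at TP1 those clones behave as eliminated in every well). Counts per
#' technical replicate are drawn NB with mean
#' `frequency * n_clones * depth_per_barcode` and the configured dispersion.
#'
#' @param truth The `truth` tibble from [generate_library()] (or a
#'   `clone_library`, from which `$truth` is taken).
#' @param config The matching [generator_config()].
#' @return Long tibble with columns `sample_id`, `barcode`, `cell_line`,
#'   `condition`, `nk_genotype`, `timepoint`, `well`, `techrep`, `count`,
#'   containing an explicit row for every clone x sample combination.
#' @examples
#' cfg <- generator_config(n_clones = 20, seed = 2)
#' counts <- simulate_coculture(generate_library(cfg), cfg)
#' dplyr::count(counts, sample_id)
#' @export
simulate_coculture <- function(truth, config) {
  if (inherits(truth, "clone_library")) truth <- truth$truth
  validate_generator_config(config)
  n <- nrow(truth)
  lfc <- do.call(rbind, c(truth$lfc_by_well, list(matrix(0, 0, config$n_wells))))
  if (n > 0 && ncol(lfc) != config$n_wells) {
    abort("`truth$lfc_by_well` entries must have length `n_wells`")
  }
  grid <- tidyr::expand_grid(condition = c("alone", "nk"),
                             timepoint = c("TP1", "TP2"),
                             well = seq_len(config$n_wells),
                             techrep = seq_len(config$n_techreps))
  # secondary-resistant clones act as eliminated before their escape at TP2
  lfc_tp1 <- lfc
  if (n > 0) {
    sec <- truth$fate == "secondary_resistant"
    lfc_tp1[sec, ] <- config$effect_sizes[["eliminated"]]
  }
  withr::with_seed(config$seed + 1L, {
    rows <- purrr::pmap(grid, function(condition, timepoint, well, techrep) {
      scale <- if (timepoint == "TP1") 0.5 else 1
      l <- if (timepoint == "TP1") lfc_tp1 else lfc
      freq <- if (condition == "alone" || n == 0) {
        truth$founder_abundance
      } else {
        f <- truth$founder_abundance * 2^(l[, well] * scale)
        if (sum(f) > 0) f / sum(f) else f
      }
      mu <- freq * n * config$depth_per_barcode
      genotype <- if (condition == "nk") config$nk_genotype else "none"
      tibble(sample_id = sprintf("%s_%s_w%d_t%d", condition, timepoint,
                                 well, techrep),
             barcode = truth$barcode,
             cell_line = config$cell_line,
             condition = condition,
             nk_genotype = genotype,
             timepoint = timepoint,
             well = well,
             techrep = techrep,
             count = draw_nb(mu, config$dispersion))
    })
  })
  bind_rows(rows)
}

#' Synthesize raw barcode-amplicon reads as FASTQ files
#'
#' Writes one single-end FASTQ file per sample. Each intact read is
#' `head + barcode + tail` right-padded with random bases to `read_length`,
#' with uniform high base qualities; exactly `count` intact reads are
#' emitted per (barcode, sample). Malformed reads are injected on top so
#' that their expected share of all reads equals `malformed_fraction`, with
#' defect classes drawn from `malformed_mix`: an insert one base short or
#' long, an uncalled base (N) inside the insert, or a destroyed head or
#' tail anchor. The generator seed is recorded in every read header.
#'
#' @param counts Long count tibble from [simulate_coculture()] (columns
#'   `sample_id`, `barcode`, `count`).
#' @param truth Truth tibble (or `clone_library`); every barcode in
#'   `counts` must appear in it.
#' @param config The matching [generator_config()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQ files.
#' @return Tibble with one row per sample: `sample_id`, `path`, `n_reads`,
#'   `n_intact`, `n_malformed`.
#' @examples
#' cfg <- generator_config(n_clones = 10, seed = 3)
#' lib <- generate_library(cfg)
#' counts <- simulate_coculture(lib, cfg)
#' files <- synthesize_reads(counts, lib, cfg, dir = tempfile("fq"))
#' files$n_reads[1:2]
#' @export
synthesize_reads <- function(counts, truth, config, dir = tempfile("reads"),
                             gzip = FALSE) {
  if (inherits(truth, "clone_library")) truth <- truth$truth
  validate_generator_config(config)
  stopifnot_cols(counts, c("sample_id", "barcode", "count"), "counts")
  if (!all(counts$barcode %in% truth$barcode)) {
    abort("every barcode in `counts` must exist in `truth`")
  }
  pad_len <- config$read_length - nchar(config$head) -
    config$barcode_length - nchar(config$tail)
  if (pad_len < 0) {
    abort(sprintf(
      "`read_length` (%d) is shorter than head + barcode + tail (%d nt)",
      config$read_length,
      nchar(config$head) + config$barcode_length + nchar(config$tail)))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sample_ids <- unique(counts$sample_id)
  withr::with_seed(config$seed + 2L, {
    out <- purrr::map(sample_ids, function(sid) {
      sub <- counts[counts$sample_id == sid & counts$count > 0, ]
      intact <- rep.int(sub$barcode, sub$count)
      reads <- paste0(config$head, intact, config$tail,
                      rand_dna(length(intact), pad_len))
      mal <- synth_malformed(length(intact), truth$barcode, config, pad_len)
      all_reads <- c(reads, mal)
      if (length(all_reads) > 1) all_reads <- all_reads[sample.int(length(all_reads))]
      path <- file.path(dir, paste0(sid, ".fastq", if (gzip) ".gz" else ""))
      write_fastq(all_reads, path, sid, config)
      tibble(sample_id = sid, path = path,
             n_reads = length(all_reads),
             n_intact = length(intact),
             n_malformed = length(mal))
    })
  })
  bind_rows(out)
}

# defective reads for one sample; expected share mf of the combined total
synth_malformed <- function(n_intact, barcodes, config, pad_len) {
  mf <- config$malformed_fraction
  if (mf == 0 || n_intact == 0) return(character(0))
  n_mal <- rpois(1, n_intact * mf / (1 - mf))
  if (n_mal == 0) return(character(0))
  bc <- barcodes[sample.int(length(barcodes), n_mal, replace = TRUE)]
  cls <- sample(names(config$malformed_mix), n_mal, replace = TRUE,
                prob = config$malformed_mix)
  L <- config$barcode_length
  out <- character(n_mal)
  i <- cls == "short_insert"   # insert one base short
  out[i] <- paste0(config$head, substr(bc[i], 1, L - 1L), config$tail,
                   rand_dna(sum(i), pad_len + 1L))
  i <- cls == "long_insert"    # insert one base long
  if (any(i)) {
    extra_pad <- max(pad_len - 1L, 0L)
    out[i] <- substr(paste0(config$head, bc[i], rand_dna(sum(i), 1L),
                            config$tail, rand_dna(sum(i), extra_pad)),
                     1, config$read_length)
  }
  i <- cls == "uncalled_base"  # N at a random insert position
  if (any(i)) {
    b <- bc[i]
    pos <- sample.int(L, sum(i), replace = TRUE)
    substr(b, pos, pos) <- rep("N", sum(i))
    out[i] <- paste0(config$head, b, config$tail, rand_dna(sum(i), pad_len))
  }
  i <- cls == "missing_head"   # head anchor replaced by random bases
  out[i] <- paste0(rand_dna(sum(i), nchar(config$head)), bc[i], config$tail,
                   rand_dna(sum(i), pad_len))
  i <- cls == "missing_tail"   # tail anchor replaced by random bases
  out[i] <- paste0(config$head, bc[i],
                   rand_dna(sum(i), nchar(config$tail) + pad_len))
  out
}

write_fastq <- function(reads, path, sample_id, config) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads) == 0) return(invisible(path))
  ids <- sprintf("@%s:%d seed=%d", sample_id, seq_along(reads), config$seed)
  qual <- strrep("I", nchar(reads))
  writeLines(c(rbind(ids, reads, "+", qual)), con)
  invisible(path)
}
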