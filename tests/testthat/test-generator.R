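test_that("generated barcodes are unique, correct length, ACGT only", {
  lib <- generate_library(generator_config(n_clones = 1000, seed = 1))
  expect_equal(nrow(lib$truth), 1000)
  expect_false(anyDuplicated(lib$truth$barcode) > 0)
  expect_true(all(nchar(lib$truth$barcode) == 21))
  expect_false(any(grepl("[^ACGT]", lib$truth$barcode)))
  expect_equal(sum(lib$truth$founder_abundance), 1, tolerance = 1e-12)
})

test_that("empty library and impossible-uniqueness cases are handled", {
  lib0 <- generate_library(generator_config(n_clones = 0))
  expect_equal(nrow(lib0$truth), 0)
  expect_equal(nrow(lib0$library_counts), 0)
  expect_error(generator_config(n_clones = 100, barcode_length = 3),
               "unique")
})

test_that("generation is deterministic given the seed", {
  cfg <- small_config(n_clones = 30, seed = 9)
  expect_identical(generate_library(cfg), generate_library(cfg))
  lib <- generate_library(cfg)
  c1 <- simulate_coculture(lib, cfg)
  c2 <- simulate_coculture(lib, cfg)
  expect_identical(c1, c2)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- synthesize_reads(c1, lib, cfg, dir = d1)
  f2 <- synthesize_reads(c2, lib, cfg, dir = d2)
  expect_identical(readLines(f1$path[1]), readLines(f2$path[1]))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("config invariants are enforced", {
  expect_error(generator_config(fate_weights = c(eliminated = 0.5,
    primary_resistant = 0.3, static = 0.1, secondary_resistant = 0.05,
    other = 0.01)), "summing to 1")
  expect_error(generator_config(dispersion = -1), "dispersion")
  expect_error(generator_config(malformed_fraction = 1.2), "malformed_fraction")
})

test_that("fate assignment frequencies converge to the weights", {
  lib <- generate_library(generator_config(n_clones = 10000, seed = 3))
  w <- generator_config()$fate_weights
  obs <- table(factor(lib$truth$fate, levels = names(w))) / 10000
  for (f in names(w)) {
    ci <- 3 * sqrt(w[[f]] * (1 - w[[f]]) / 10000)
    expect_lt(abs(obs[[f]] - w[[f]]), max(ci, 1e-12))
  }
})

test_that("secondary-resistant clones expand in exactly one well", {
  cfg <- generator_config(n_clones = 2000, seed = 5)
  lib <- generate_library(cfg)
  sec <- lib$truth[lib$truth$fate == "secondary_resistant", ]
  expect_gt(nrow(sec), 0)
  npos <- vapply(sec$lfc_by_well, function(v) sum(v > 0), integer(1))
  expect_true(all(npos == 1))
  rest <- vapply(sec$lfc_by_well,
                 function(v) all(v[v <= 0] == cfg$effect_sizes[["eliminated"]]),
                 logical(1))
  expect_true(all(rest))
})

test_that("all-static clones give equal expected counts in both arms", {
  cfg <- generator_config(n_clones = 40, seed = 6, dispersion = 0,
                          depth_per_barcode = 2000,
                          fate_weights = c(eliminated = 0, primary_resistant = 0,
                                           static = 1, secondary_resistant = 0,
                                           other = 0))
  counts <- simulate_coculture(generate_library(cfg), cfg)
  m <- counts |>
    dplyr::group_by(barcode, condition) |>
    dplyr::summarise(mean = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = mean)
  expect_equal(m$nk / m$alone, rep(1, nrow(m)), tolerance = 0.1)
})

test_that("a kill flag empties the NK arm", {
  cfg <- generator_config(n_clones = 25, seed = 7,
                          fate_weights = c(eliminated = 1, primary_resistant = 0,
                                           static = 0, secondary_resistant = 0,
                                           other = 0),
                          effect_sizes = c(eliminated = -Inf,
                                           primary_resistant = 3, static = 0,
                                           secondary_resistant = 3, other = 1.5))
  counts <- simulate_coculture(generate_library(cfg), cfg)
  expect_true(all(counts$count[counts$condition == "nk"] == 0))
  expect_gt(sum(counts$count[counts$condition == "alone"]), 0)
})

test_that("synthesized reads have the configured geometry and conserve counts", {
  cfg <- small_config(n_clones = 15, seed = 8)
  lib <- generate_library(cfg)
  counts <- simulate_coculture(lib, cfg)
  dir <- tempfile()
  files <- synthesize_reads(counts, lib, cfg, dir = dir)
  per_sample <- counts |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(count))
  joined <- dplyr::left_join(files, per_sample, by = "sample_id")
  expect_equal(joined$n_intact, joined$total)
  lines <- readLines(files$path[1])
  seqs <- lines[seq(2, length(lines), by = 4)]
  expect_equal(length(seqs), files$n_reads[1])
  expect_true(all(nchar(seqs) == 64))
  expect_error(
    synthesize_reads(counts, lib,
                     generator_config(n_clones = 15, seed = 8, read_length = 40)),
    "shorter")
  unlink(dir, recursive = TRUE)
})

test_that("extraction round-trips the count matrix when no reads are malformed", {
  cfg <- small_config(n_clones = 20, seed = 10, malformed_fraction = 0)
  lib <- generate_library(cfg)
  counts <- simulate_coculture(lib, cfg)
  dir <- tempfile()
  files <- synthesize_reads(counts, lib, cfg, dir = dir)
  for (i in c(1, 5, nrow(files))) {
    res <- count_sample(files$path[i])
    expect_equal(res$discard_fraction, 0)
    sim <- counts |>
      dplyr::filter(sample_id == files$sample_id[i], count > 0) |>
      dplyr::arrange(barcode)
    got <- dplyr::arrange(tidy(res), barcode)
    expect_equal(got$barcode, sim$barcode)
    expect_equal(got$count, sim$count)
  }
  unlink(dir, recursive = TRUE)
})
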