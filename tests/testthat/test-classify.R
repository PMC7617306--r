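stats_row <- function(log2fc = 0, padj = 1, v_alone = 0.2, v_nk = 0.4,
                      n_high_wells = 0, barcode = "bc1") {
  tibble::tibble(barcode = barcode, log2fc = log2fc, padj = padj,
                 v_alone = v_alone, v_nk = v_nk, n_high_wells = n_high_wells)
}

call_one <- function(...) {
  as.character(classify_clones(stats_row(...))$category)
}

test_that("decision-tree rules assign the five fates", {
  expect_equal(call_one(log2fc = 1.5, padj = 0.01), "primary_resistant")
  expect_equal(call_one(log2fc = -2, padj = 0.01), "eliminated")
  expect_equal(call_one(log2fc = 0.2, padj = 0.5, v_alone = 0.3, v_nk = 0.4),
               "static")
  hw <- high_well_count(c(40, 0, 0))
  expect_equal(call_one(padj = 0.5, v_alone = 0.3, v_nk = 2,
                        n_high_wells = hw), "secondary_resistant")
  expect_equal(call_one(padj = 0.5, v_alone = 0.8, v_nk = 2, n_high_wells = 1),
               "other")
  # boundary values sit inside the rules: lfc = 1, v_alone = 0.5, v_nk = 1
  expect_equal(call_one(log2fc = 1, padj = 0.01), "primary_resistant")
  expect_equal(call_one(padj = 0.5, v_alone = 0.5, v_nk = 1, n_high_wells = 1),
               "secondary_resistant")
})

test_that("rule precedence is total: the first matching rule wins", {
  set.seed(111)
  grid <- tidyr::expand_grid(log2fc = c(-2, -1, 0, 1, 2),
                             padj = c(0.01, 0.2),
                             v_alone = c(0.2, 0.7),
                             v_nk = c(0.5, 1.5),
                             n_high_wells = 0:2) |>
    dplyr::mutate(barcode = sprintf("bc%03d", dplyr::row_number()))
  calls <- classify_clones(grid)
  rule_match <- function(r) {
    c(primary_resistant = r$padj < 0.05 && r$log2fc >= 1,
      eliminated = r$padj < 0.05 && r$log2fc <= -1,
      static = r$v_alone <= 0.5 && r$v_nk < 1,
      secondary_resistant = r$v_alone <= 0.5 && r$v_nk >= 1 &&
        r$n_high_wells == 1,
      other = TRUE)
  }
  for (i in seq_len(nrow(grid))) {
    first <- names(which(rule_match(grid[i, ])))[1]
    expect_equal(as.character(calls$category[i]), first)
  }
})

test_that("classification errors on missing statistics", {
  bad <- stats_row(); bad$padj <- NA_real_
  expect_error(classify_clones(bad), "bc1")
})

test_that("high-well counting uses the doubling bar over the shifted minimum", {
  expect_equal(high_well_count(c(40, 0, 0)), 1)
  expect_equal(high_well_count(c(5, 5, 5)), 0)
  expect_equal(high_well_count(c(40, 40, 0)), 2)
  expect_equal(high_well_count(c(3, 1, 1)), 1)   # log2(4/2) = 1, at the bar
  expect_error(high_well_count(numeric(0)), "non-empty")
})

test_that("fate summaries are a partition with proportions summing to one", {
  set.seed(121)
  n <- 300
  st <- tibble::tibble(
    barcode = sprintf("bc%03d", 1:n),
    log2fc = rnorm(n, 0, 2),
    padj = runif(n),
    v_alone = runif(n, 0, 1),
    v_nk = runif(n, 0, 2),
    n_high_wells = sample(0:3, n, TRUE))
  calls <- classify_clones(st)
  expect_equal(nrow(calls), n)
  expect_false(any(is.na(calls$category)))
  s <- summarize_fates(calls)
  expect_equal(nrow(s), 5)
  expect_equal(sum(s$n), n)
  expect_equal(sum(s$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(s$proportion_excl_other, na.rm = TRUE), 1, tolerance = 1e-12)
  # degenerate all-eliminated input
  one <- summarize_fates(
    tibble::tibble(category = factor(rep("eliminated", 10),
                                     levels = FATE_LEVELS)))
  expect_equal(one$proportion, c(1, 0, 0, 0, 0))
})

test_that("fate summaries pool mean and SD across experiments", {
  calls <- dplyr::bind_rows(
    tibble::tibble(experiment = "e1",
                   category = factor(c("eliminated", "eliminated", "static",
                                       "primary_resistant"),
                                     levels = FATE_LEVELS)),
    tibble::tibble(experiment = "e2",
                   category = factor(c("eliminated", "static", "static",
                                       "primary_resistant"),
                                     levels = FATE_LEVELS)))
  pooled <- summarize_fates(calls)
  elim <- pooled[pooled$category == "eliminated", ]
  expect_equal(elim$n_experiments, 2)
  expect_equal(elim$mean_proportion, mean(c(0.5, 0.25)))
  expect_equal(elim$sd_proportion, stats::sd(c(0.5, 0.25)))
})

test_that("overlap of fate sets reports intersections and Jaccard indices", {
  mk <- function(bcs, cat) {
    tibble::tibble(barcode = bcs,
                   category = factor(cat, levels = FATE_LEVELS))
  }
  a <- dplyr::bind_rows(mk(c("b1", "b2"), "eliminated"),
                        mk("b3", "secondary_resistant"))
  expect_equal(overlap_fates(a, a)$jaccard[c(1, 4)], c(1, 1))
  b <- dplyr::bind_rows(mk(c("b1", "b2"), "eliminated"),
                        mk("b4", "secondary_resistant"))
  ov <- overlap_fates(a, b)
  expect_equal(ov$jaccard[ov$category == "eliminated"], 1)
  expect_equal(ov$jaccard[ov$category == "secondary_resistant"], 0)
  expect_equal(ov$n_only1[ov$category == "secondary_resistant"], 1)
  # empty categories have Jaccard 0 by convention
  expect_equal(ov$jaccard[ov$category == "static"], 0)
})

test_that("independent experiments share primary fates but not secondary ones", {
  cfg1 <- generator_config(n_clones = 600, seed = 131,
                           depth_per_barcode = 100)
  lib1 <- generate_library(cfg1)
  # second experiment: same clones and intrinsic fates, but secondary
  # resistance is re-acquired stochastically by different clones
  lib2 <- lib1
  sec <- which(lib1$truth$fate == "secondary_resistant")
  stat <- which(lib1$truth$fate == "static")
  set.seed(132)
  swap <- sample(stat, length(sec))
  lib2$truth$fate[sec] <- "static"
  lib2$truth$fate[swap] <- "secondary_resistant"
  lib2$truth$lfc_by_well[sec] <- list(rep(0, 3))
  lib2$truth$lfc_by_well[swap] <- lapply(seq_along(swap), function(i) {
    v <- rep(cfg1$effect_sizes[["eliminated"]], 3)
    v[sample.int(3, 1)] <- cfg1$effect_sizes[["secondary_resistant"]]
    v
  })
  cfg2 <- generator_config(n_clones = 600, seed = 133,
                           depth_per_barcode = 100)
  run_calls <- function(lib, cfg) {
    counts <- simulate_coculture(lib, cfg)
    merged <- merge_technical_replicates(counts)
    classify_clones(clone_stats(merged, timepoint = "TP2"))
  }
  ov <- overlap_fates(run_calls(lib1, cfg1), run_calls(lib2, cfg2))
  expect_gt(ov$jaccard[ov$category == "eliminated"], 0.9)
  expect_gt(ov$jaccard[ov$category == "primary_resistant"], 0.9)
  expect_lt(ov$jaccard[ov$category == "secondary_resistant"], 0.2)
})

test_that("barcode ordering clusters identical and block-structured profiles", {
  m <- matrix(c(1, 1, 1, 9, 9, 9, 1, 1, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  ord <- order_barcodes(m)
  expect_setequal(ord, c("a", "b", "c"))
  expect_equal(abs(diff(match(c("a", "c"), ord))), 1)  # identical rows adjacent
  # planted two-block structure stays contiguous in leaf order
  set.seed(141)
  blocks <- rbind(matrix(rnorm(25, 0), 5, 5), matrix(rnorm(25, 10), 5, 5))
  rownames(blocks) <- sprintf("bc%02d", 1:10)
  ord2 <- order_barcodes(blocks)
  pos <- match(sprintf("bc%02d", 1:5), ord2)
  expect_equal(max(pos) - min(pos), 4)
  # single barcode passes through
  expect_equal(order_barcodes(m[1, , drop = FALSE]), "a")
})
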