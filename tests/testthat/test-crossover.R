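mk_profile <- function(offset, correction, haplotype = 1L, L = 960L,
                       vaf_wt = 0.5, depth = 10000L) {
  df <- data.frame(offset = offset, pos = L - offset, haplotype = haplotype,
                   vaf_wt = vaf_wt, vaf_integrated = vaf_wt * (1 - correction),
                   depth_wt = depth, depth_integrated = depth,
                   correction = correction, clipped = FALSE)
  class(df) <- c("crossover_profile", "data.frame")
  attr(df, "arm_len") <- L
  df
}

test_that("correction frequency is the normalized depletion of the donor allele", {
  snps <- data.frame(arm = "left", offset = c(100L, 500L), ref = c("A", "C"),
                     alt = c("T", "G"), haplotype = c(1L, 2L))
  L <- 960L
  pos <- snp_arm_index(snps$offset, snps$arm, L)
  wt <- mk_variant_table(data.frame(pos = pos, frequency = c(0.50, 0.50),
                                    alt = snps$alt, ref = snps$ref,
                                    depth = 10000L,
                                    alt_count = c(5000L, 5000L)))
  int <- mk_variant_table(data.frame(pos = pos, frequency = c(0.10, 0.50),
                                     alt = snps$alt, ref = snps$ref,
                                     depth = 10000L,
                                     alt_count = c(1000L, 5000L)))
  prof <- correction_frequencies(wt, int, snps, L)
  expect_equal(prof$correction[prof$offset == 100L], 0.8)
  expect_equal(prof$correction[prof$offset == 500L], 0)
  # a SNP with low WT frequency is excluded with a warning
  wt2 <- wt; wt2$frequency[1] <- 0.05
  expect_warning(p2 <- correction_frequencies(wt2, int, snps, L),
                 "not heterozygous")
  expect_equal(nrow(p2), 1L)
  # absent from both tables is an error naming the position
  expect_error(correction_frequencies(wt[1, ], int[1, ], snps, L),
               as.character(pos[2]))
})

test_that("uniform crossovers give correction 1 - d/L at each SNP", {
  m <- test_model()
  pw <- short_read_params(1, per_base_error = 0.001, seed = 61)
  pi <- short_read_params(1, per_base_error = 0.001, seed = 62)
  vw <- variant_pipeline(simulate_arm_reads(m, "left", "wt", 6000, pw),
                         m$left_arm, "L")
  vi <- variant_pipeline(simulate_arm_reads(m, "left", "integrated", 6000, pi),
                         m$left_arm, "L")
  snps <- m$snps[m$snps$arm == "left", ]
  prof <- correction_frequencies(vw, vi, snps, nchar(m$left_arm))
  expected <- 1 - prof$offset / nchar(m$left_arm)
  expect_lt(max(abs(prof$correction - expected)), 0.06)
  # corrections decline with distance from the payload
  expect_true(all(diff(prof$correction[order(prof$offset)]) < 0.05))
})

test_that("correction recovers 1 - F(d) for assorted crossover distributions", {
  m <- test_model()
  L <- nchar(m$right_arm)
  cdfs <- list(
    uniform = list(sample = function(n, L) runif(n, 0, L),
                   F = function(d, L) d / L),
    sqrt = list(sample = function(n, L) L * runif(n)^2,
                F = function(d, L) sqrt(d / L)),
    squared = list(sample = function(n, L) L * sqrt(runif(n)),
                   F = function(d, L) (d / L)^2))
  snps <- m$snps[m$snps$arm == "right", ]
  for (nm in names(cdfs)) {
    cd <- cdfs[[nm]]
    pw <- short_read_params(1, per_base_error = 0.001, seed = 70)
    pi <- short_read_params(1, per_base_error = 0.001, seed = 71,
                            crossover_model = cd$sample)
    vw <- variant_pipeline(simulate_arm_reads(m, "right", "wt", 6000, pw),
                           m$right_arm, "R")
    vi <- variant_pipeline(simulate_arm_reads(m, "right", "integrated", 6000,
                                              pi), m$right_arm, "R")
    prof <- correction_frequencies(vw, vi, snps, L)
    expected <- 1 - cd$F(prof$offset, L)
    expect_lt(max(abs(prof$correction - expected)), 0.07)
  }
})

test_that("trend fitting is exact on noise-free profiles", {
  L <- 960L
  offs <- c(47, 214, 378, 521, 562, 703, 886)
  prof <- mk_profile(offs, (L - offs) / L, haplotype = c(2, 2, 2, 1, 2, 2, 2))
  fit <- fit_trend(prof)
  expect_equal(fit$slope, -1 / L, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$by_haplotype[["2"]]$slope, -1 / L, tolerance = 1e-9)
  flat <- mk_profile(offs, rep(0.4, 7))
  expect_equal(fit_trend(flat)$slope, 0, tolerance = 1e-9)
  expect_error(fit_trend(mk_profile(100, 0.5)), "at least 2")
})

test_that("simulated trend slope approximates -1/L", {
  m <- test_model()
  L <- nchar(m$left_arm)
  slopes <- vapply(1:5, function(i) {
    pw <- short_read_params(1, per_base_error = 0.001, seed = 200 + i)
    pi <- short_read_params(1, per_base_error = 0.001, seed = 300 + i)
    vw <- variant_pipeline(simulate_arm_reads(m, "left", "wt", 3000, pw),
                           m$left_arm, "L")
    vi <- variant_pipeline(simulate_arm_reads(m, "left", "integrated", 3000,
                                              pi), m$left_arm, "L")
    fit_trend(correction_frequencies(vw, vi,
                                     m$snps[m$snps$arm == "left", ], L))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-1 / L)) / (1 / L), 0.15)
})

test_that("allele specificity reads parity and one-sided integration correctly", {
  m <- test_model()
  L <- nchar(m$left_arm)
  snps <- m$snps[m$snps$arm == "left", ]
  run <- function(hap_frac_int) {
    pw <- short_read_params(1, per_base_error = 0.001, seed = 81)
    pi <- short_read_params(1, per_base_error = 0.001, seed = 82,
                            haplotype_fractions = hap_frac_int)
    vw <- variant_pipeline(simulate_arm_reads(m, "left", "wt", 8000, pw),
                           m$left_arm, "L")
    vi <- variant_pipeline(simulate_arm_reads(m, "left", "integrated", 8000,
                                              pi), m$left_arm, "L")
    correction_frequencies(vw, vi, snps, L)
  }
  # equal haplotype usage: ratio near 1, CI contains 1
  prof_eq <- run(NULL)
  as_eq <- allele_specificity(prof_eq, bootstrap = 300, seed = 5)
  expect_lt(abs(as_eq$ratio - 1), 0.2)
  expect_true(as_eq$no_detectable_specificity)
  # haplotype 1 never integrates: its variant vanishes, ratio near 0
  prof_one <- run(c("1" = 0, "2" = 1))
  as_one <- allele_specificity(prof_one, bootstrap = 300, seed = 6)
  expect_lt(as_one$ratio, 0.1)
  expect_false(as_one$no_detectable_specificity)
  # single-haplotype profiles cannot be tested
  expect_error(allele_specificity(mk_profile(c(100, 500), c(0.9, 0.5))),
               "two haplotypes")
})

test_that("hotspot diagnostic flags an abrupt jump but not a linear profile", {
  L <- 960L
  offs <- seq(100, 900, by = 100)
  linear <- mk_profile(offs, (L - offs) / L)
  ht_lin <- hotspot_test(linear, bootstrap = 300, seed = 7)
  expect_gt(ht_lin$p_value, 0.05)
  jumpy <- mk_profile(offs, ifelse(offs < 500, 0.95, 0.15))
  ht_jump <- hotspot_test(jumpy, bootstrap = 300, seed = 8)
  expect_lt(ht_jump$p_value, 0.05)
  expect_equal(ht_jump$between_offsets, c(400, 500))
})
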