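test_that("short-read simulation is deterministic and emits valid FASTQ", {
  m <- toy_locus()
  p <- short_read_params(60, read_len = 40, integrated_fraction = 0.3,
                         seed = 5)
  a <- simulate_short_reads(m, "left", p)
  b <- simulate_short_reads(m, "left", p)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(a, f1); write_fastq(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(nchar(a$seq) == nchar(a$qual)))
})

test_that("noiseless WT-only reads carry only the WT junction k-mer", {
  m <- toy_locus()
  p <- short_read_params(400, read_len = 40, integrated_fraction = 0,
                         per_base_error = 0, junction_span_frac = 1, seed = 8)
  rs <- simulate_short_reads(m, "left", p)
  jk <- junction_kmers(m)
  hit <- function(k) grepl(k, rs$seq, fixed = TRUE) |
    grepl(revcomp(k), rs$seq, fixed = TRUE)
  expect_equal(sum(hit(jk$left_edited)), 0L)
  # every spanning fragment shows the WT k-mer on at least one mate
  expect_true(all(tapply(hit(jk$left_wt), rs$pair_id, any)))
})

test_that("junction-assigned edited fraction matches the binomial expectation", {
  m <- test_model()
  p <- short_read_params(50000, integrated_fraction = 0.06,
                         per_base_error = 0, seed = 12)
  rs <- simulate_short_reads(m, "left", p)
  cnt <- count_junctions(rs, m, "left")
  n_inf <- cnt$n_edited + cnt$n_wt
  ci <- qbinom(c(0.005, 0.995), n_inf, 0.06)
  expect_gte(cnt$n_edited, ci[1])
  expect_lte(cnt$n_edited, ci[2])
})

test_that("junction control panel honors levels and amplification bias", {
  m <- toy_locus()
  p <- short_read_params(1, read_len = 40, per_base_error = 0,
                         junction_span_frac = 1, seed = 20)
  lv <- c(0, 0.02, 0.10)
  panel <- simulate_control_panel(m, "left", levels = lv, n_pairs = 3000,
                                  params = p, rho = 1, cycles = 20)
  expect_equal(vapply(panel, attr, 0, "expected_percent"), 100 * lv,
               ignore_attr = TRUE)
  obs <- vapply(panel, function(rs)
    observed_fraction(count_junctions(rs, m, "left")), numeric(1))
  # unbiased panel: observed close to nominal
  expect_lt(max(abs(obs - 100 * lv)), 1.5)
  # rho > 1 inflates every nonzero level
  panel2 <- simulate_control_panel(m, "left", levels = lv, n_pairs = 3000,
                                   params = p, rho = 1.05, cycles = 20)
  obs2 <- vapply(panel2, function(rs)
    observed_fraction(count_junctions(rs, m, "left")), numeric(1))
  expect_true(all(obs2[-1] > obs[-1]))
})

test_that("long-read simulation respects template mixing and d-region content", {
  m <- test_model()
  d <- m$itr_d_region
  # no ITR reads -> d-region absent everywhere (noiseless)
  p0 <- long_read_params(150, sub_rate = 0, ins_rate = 0, del_rate = 0,
                         itr_fraction = 0, wt_fraction = 0.3, seed = 2)
  r0 <- simulate_long_reads(m, "left", p0)
  expect_false(any(grepl(d, r0$seq, fixed = TRUE) |
                     grepl(revcomp(d), r0$seq, fixed = TRUE)))
  # all-ITR with full d-region -> every read contains it at the junction
  p1 <- long_read_params(100, sub_rate = 0, ins_rate = 0, del_rate = 0,
                         itr_fraction = 1, seed = 3)
  r1 <- simulate_long_reads(m, "left", p1)
  junction <- paste0(substr(m$left_flank, nchar(m$left_flank) - 5L,
                            nchar(m$left_flank)),
                     d, substr(m$left_arm, 1L, 6L))
  expect_true(all(grepl(junction, r1$seq, fixed = TRUE) |
                    grepl(revcomp(junction), r1$seq, fixed = TRUE)))
  # mispriming products have no genomic flank beyond the junction
  p2 <- long_read_params(60, sub_rate = 0, ins_rate = 0, del_rate = 0,
                         mispriming_fraction = 1, seed = 4)
  r2 <- simulate_long_reads(m, "left", p2)
  flank_tail <- substr(m$left_flank, nchar(m$left_flank) - 19L,
                       nchar(m$left_flank))
  expect_false(any(grepl(flank_tail, r2$seq, fixed = TRUE) |
                     grepl(revcomp(flank_tail), r2$seq, fixed = TRUE)))
  expect_true(all(nchar(r2$seq) == nchar(r2$qual)))
})

test_that("long-read noise model hits the configured error rate", {
  m <- test_model()
  p <- long_read_params(40, seed = 9) # defaults: 2/2/1% sub/ins/del
  r <- simulate_long_reads(m, "left", p)
  amp <- build_amplicons(m, "left")
  # noisy seamless reads should differ from the template by roughly 5%
  seam <- r[r$truth == "seamless", ]
  nm <- vapply(seq_len(nrow(seam)), function(i) {
    q <- seam$seq[i]
    al_f <- band_align(q, amp$edited, 0, band = 80)
    al_r <- band_align(revcomp(q), amp$edited, 0, band = 80)
    min(al_f$nm, al_r$nm) / nchar(q)
  }, numeric(1))
  expect_gt(mean(nm), 0.025)
  expect_lt(mean(nm), 0.09)
})

test_that("droplet simulation matches the Poisson class expectations", {
  # degenerate: nothing loaded
  d0 <- simulate_droplets(droplet_params(500, 0, 0, 0, seed = 1))
  expect_equal(d0$n_nn, 500L)
  # chi-square goodness of fit against the closed-form class fractions
  lam <- c(0.05, 0.10, 0.05)
  dt <- simulate_droplets(droplet_params(1e5, lam[1], lam[2], lam[3],
                                         seed = 42))
  expf <- expected_droplet_fractions(lam[1], lam[2], lam[3])
  obs <- c(dt$n_pp, dt$n_pn, dt$n_np, dt$n_nn)
  gof <- suppressWarnings(chisq.test(obs, p = expf))
  expect_gt(gof$p.value, 0.01)
  # total shearing destroys the linked species
  ds <- simulate_droplets(droplet_params(1e5, 0.05, 0.10, 0.05,
                                         shear_prob = 1, seed = 43))
  est <- estimate_linkage(ds)
  expect_lt(est$linkage_percent, 2)
})

test_that("SNV panel plants its variant at the requested levels", {
  m <- toy_locus()
  p <- short_read_params(1, read_len = 20, per_base_error = 0, seed = 31)
  panel <- simulate_control_panel(m, "right", levels = c(0, 0.5),
                                  n_pairs = 2000, params = p, type = "snv")
  pos <- attr(panel[[2]], "snv_pos")
  alt <- attr(panel[[2]], "snv_alt")
  arm <- m$right_arm
  probe <- substr(arm, pos - 4L, pos + 6L)
  alt_probe <- probe
  substr(alt_probe, 6L, 6L) <- alt
  hit0 <- grepl(alt_probe, panel[[1]]$seq, fixed = TRUE) |
    grepl(revcomp(alt_probe), panel[[1]]$seq, fixed = TRUE)
  hit50 <- grepl(alt_probe, panel[[2]]$seq, fixed = TRUE) |
    grepl(revcomp(alt_probe), panel[[2]]$seq, fixed = TRUE)
  expect_equal(sum(hit0), 0L)
  cov <- grepl(probe, panel[[2]]$seq, fixed = TRUE) |
    grepl(revcomp(probe), panel[[2]]$seq, fixed = TRUE) | hit50
  expect_gt(sum(hit50) / sum(cov), 0.4)
  expect_lt(sum(hit50) / sum(cov), 0.6)
})
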