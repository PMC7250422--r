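test_that("long-read filters apply the quality and two-stage length trims", {
  mk <- function(len, q = "I") read_set(paste0("r", len, q),
                                        strrep("A", len), strrep(q, len))
  rs <- do.call(rbind, list(mk(300), mk(800), mk(1500), mk(2500),
                            mk(1500, "$")))  # "$" = Q3, accuracy ~0.5
  class(rs) <- c("read_set", "data.frame")
  flt <- filter_long_reads(rs)
  expect_equal(nrow(flt$kept), 1L)
  expect_equal(flt$kept$id, "r1500I")
  reasons <- setNames(flt$excluded$reason, flt$excluded$id)
  expect_equal(unname(reasons[c("r300I", "r800I")]), c("short", "short"))
  expect_equal(unname(reasons["r2500I"]), "long")
  expect_equal(unname(reasons["r1500$"]), "low_quality")
})

test_that("three-way assignment puts noiseless reads on their own reference", {
  m <- test_model()
  amp <- build_amplicons(m, "left")
  rs <- read_set(c("seam", "wt", "itr"),
                 c(amp$edited, amp$wt, amp$itr),
                 strrep("I", nchar(c(amp$edited, amp$wt, amp$itr))))
  al <- align_three_way(rs, amp)
  expect_equal(al$assigned, c("seamless", "wt", "itr"))
  # full-length noiseless reads align end to end
  expect_equal(al$ref_start, c(0L, 0L, 0L))
  expect_equal(al$ref_end[3], nchar(amp$itr))
  # d-region fully matched for the ITR read
  expect_equal(al$d_match_run[3], nchar(m$itr_d_region))
})

test_that("an ITR-bearing read outscores the seamless reference by the avoided gap", {
  m <- test_model()
  amp <- build_amplicons(m, "left")
  al <- align_three_way(read_set("itr", amp$itr, strrep("I", nchar(amp$itr))),
                        amp)
  # full match on itr: 2 per base; on seamless the 20-base d-region must be
  # inserted: open 4 + 20 * extend 2 = 44 penalty plus 40 lost match bonus
  expect_equal(al$score_itr, 2L * nchar(amp$itr))
  expect_equal(al$score_itr - al$score_seamless, 84L)
})

test_that("the three ITR criteria gate classification", {
  m <- test_model()
  amp <- build_amplicons(m, "left")
  d <- m$itr_d_region
  r <- amp$regions$itr
  # noiseless full ITR read: all criteria met
  full <- itr_scan(simulate_long_reads(m, "left", long_read_params(
    5, sub_rate = 0, ins_rate = 0, del_rate = 0, itr_fraction = 1,
    seed = 2)), m, "left")
  expect_equal(unname(full$counts["n_itr_positive"]), 5L)
  # truncated before the genomic flank: no sequence beyond the junction
  no_flank <- substring(amp$itr, r$d_region["start"] + 1L, nchar(amp$itr))
  al <- classify_itr(align_three_way(read_set("t", no_flank,
                                              strrep("I", nchar(no_flank))),
                                     amp), amp)
  expect_false(al$is_itr[1])
  if (al$assigned[1] == "itr")
    expect_false(al$genomic_beyond_junction[1])
  # payload+arm only (no flank, no d-region): a mispriming product
  r_ed <- amp$regions$edited
  mis <- substring(amp$edited, r_ed$arm["start"] + 1L, nchar(amp$edited))
  al_mis <- classify_itr(align_three_way(read_set("m", mis,
                                                  strrep("I", nchar(mis))),
                                         amp), amp)
  expect_true(al_mis$mispriming[1])
  expect_false(al_mis$is_itr[1])
  # fewer than 5 junction bases matching the d-region: not ITR
  al_few <- al
  al_few$assigned[1] <- "itr"
  al_few$d_match_run[1] <- 3L
  al_few$ref_start[1] <- 0L; al_few$ref_end[1] <- nchar(amp$itr)
  re <- classify_itr(al_few, amp)
  expect_false(re$is_itr[1])
  expect_false(re$itr_5nt_match[1])
})

test_that("cross-contamination markers remove foreign reads", {
  m <- test_model()
  marker <- substr(m$wt_insert, 1, 20)
  seqs <- c(strrep("ACGT", 300),
            paste0(strrep("ACGT", 150), marker, strrep("TTGA", 150)))
  rs <- read_set(c("clean", "dirty"), seqs, strrep("I", nchar(seqs)))
  dec <- remove_cross_contamination(rs, c(wt_specific = marker))
  expect_equal(dec$kept$id, "clean")
  expect_equal(dec$excluded$reason, "contamination")
  # reverse-strand contamination is caught too
  rs_rc <- read_set("dirty_rc", revcomp(rs$seq[2]), rs$qual[2])
  expect_equal(nrow(suppressWarnings(
    remove_cross_contamination(rs_rc, c(wt = marker)))$kept), 0L)
  expect_warning(remove_cross_contamination(rs, NULL), "no contamination")
  expect_warning(
    remove_cross_contamination(rs[2, ], c(wt = marker)),
    "all reads removed")
})

test_that("the end-to-end scan assigns a noisy mixture to the right classes", {
  m <- test_model()
  lp <- long_read_params(400, itr_fraction = 0.4, wt_fraction = 0.2, seed = 13)
  lr <- simulate_long_reads(m, "left", lp)
  rep <- itr_scan(lr, m, "left")
  # conservation: classes sum to the input count
  expect_equal(sum(rep$counts[c("itr", "seamless", "wt", "unassigned",
                                "excluded")]),
               unname(rep$counts["n_input"]))
  truth <- lr$truth[match(rep$per_read$id, lr$id)]
  agree <- mean(rep$per_read$final_class == ifelse(truth == "seamless",
                                                   "seamless", truth))
  expect_gte(agree, 0.99)
  # every truly ITR read with full d-region passes all criteria
  expect_gte(sum(rep$per_read$is_itr) / sum(truth == "itr"), 0.95)
  # junction coverage is continuous for assigned references
  cov <- rep$coverage$itr
  span <- which(cov > 0)
  expect_true(all(cov[min(span):max(span)] > 0))
})

test_that("seamless-only runs never produce ITR calls", {
  m <- test_model()
  for (s in c(101, 202)) {
    lr <- simulate_long_reads(m, "right",
                              long_read_params(250, seed = s))
    rep <- itr_scan(lr, m, "right")
    expect_equal(unname(rep$counts["n_itr_positive"]), 0L)
  }
})

test_that("scanning an empty or fully filtered read set errors", {
  m <- test_model()
  short <- read_set("s", strrep("A", 100), strrep("I", 100))
  expect_error(itr_scan(short, m, "left"), "no reads left")
})
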