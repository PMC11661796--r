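pwm10 <- build_pwm("TATAAT", name = "minus10")

test_that("window_partition splits fluorescence by window motif score", {
  # 6 daughters: 3 with the consensus window, 3 scrambled
  seqs <- c(rep("GGTATAATGG", 3), rep("GGATTAATGG", 3))
  F <- c(3, 3, 2, 1, 1, 1)
  part <- window_partition(seqs, F, pwm10, 2)
  expect_equal(sort(part$F_with), c(2, 3, 3))
  expect_equal(part$F_without, c(1, 1, 1))
  # all daughters carry the consensus: F_without empty
  all_with <- window_partition(rep("GGTATAATGG", 4), rep(2, 4), pwm10, 2)
  expect_length(all_with$F_without, 0)
  # +Inf threshold puts everything in F_without
  none <- window_partition(seqs, F, pwm10, 2, threshold = Inf)
  expect_length(none$F_with, 0)
  expect_length(none$F_without, 6)
  expect_error(window_partition(seqs, F, pwm10, 5), "does not fit")
})

test_that("MWU association matches identity, separation and skip contracts", {
  # identical multisets: p at or near 1, zero effect
  x <- rep(c(1, 2, 3, 4), 5)
  r <- mwu_association(x, x)
  expect_gt(r$p, 0.99)
  expect_equal(r$delta_F, 0)
  # complete separation
  r2 <- mwu_association(rep(3, 20), rep(1, 20))
  expect_equal(r2$delta_F, 2)
  expect_lt(r2$p, 1e-6)
  # strictly-more-than-10 rule: 10 entries is too few
  expect_null(mwu_association(rep(1, 10), rep(2, 30)))
  expect_false(is.null(mwu_association(c(x, 1), c(x, 2))))
})

test_that("exact MWU p-values equal full permutation enumeration (n <= 8)", {
  set.seed(31)
  for (i in 1:12) {
    nx <- sample(3:7, 1); ny <- sample(3:7, 1)
    # tie-free samples so the exact path is exercised
    vals <- sample(seq(1, 4, length.out = 40), nx + ny)
    x <- vals[1:nx]; y <- vals[-(1:nx)]
    p_pkg <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, oracle_mwu_exact(x, y), tolerance = 1e-12)
  }
})

test_that("BH q-values equal the reference step-up oracle and are monotone", {
  set.seed(17)
  for (i in 1:10) {
    p <- runif(sample(5:40, 1))
    q <- p.adjust(p, method = "BH")
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

make_assoc_fixture <- function(n = 120, effect = 2, seed = 101) {
  # parent with a consensus -10 box at 0-based start 20 in a 60-mer
  set.seed(seed)
  parent <- random_dna(1, 60)
  substr(parent, 21, 26) <- "TATAAT"
  # daughters: half keep the box (high F), half destroy it (low F)
  keep <- rep(parent, n / 2)
  lose <- vapply(seq_len(n / 2), function(i) {
    d <- parent
    pos <- sample(21:26, 1)
    substr(d, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(d, pos, pos))[sample.int(3, 1)]
    d
  }, character(1))
  F <- c(rnorm(n / 2, 3 + effect - 2, 0.05), rnorm(n / 2, 1.2, 0.05))
  F <- pmin(pmax(F, 1), 4)
  list(parent = parent, seqs = c(keep, lose), F = F)
}

test_that("scan_associations recovers a planted loss with the right sign", {
  fx <- make_assoc_fixture()
  rec <- scan_associations(fx$parent, fx$seqs, fx$F, pwm10,
                           hotspot_peaks = 22L, parent_id = "P1",
                           channel = "gfp")
  expect_gt(nrow(rec), 0)
  at_box <- rec[rec$window_start == 20, ]
  expect_equal(nrow(at_box), 1)
  expect_equal(at_box$direction, "loss")
  expect_gt(at_box$delta_F, 0.5)
  expect_true(at_box$significant_effect)
  expect_true(all(rec$n_with > 10 & rec$n_without > 10))
  expect_true(all(abs(rec$delta_F) <= 3))
  # windows far from the hotspot are never recorded
  expect_true(all(rec$window_start <= 22 + 3 & rec$window_start + 6 > 22 - 3))
})

test_that("flat fluorescence yields no association records", {
  fx <- make_assoc_fixture()
  rec <- scan_associations(fx$parent, fx$seqs, rep(2, length(fx$seqs)),
                           pwm10, hotspot_peaks = 22L)
  expect_equal(nrow(rec), 0)
})

test_that("a planted gain is detected with positive effect", {
  set.seed(77)
  parent <- random_dna(1, 60)
  substr(parent, 21, 26) <- "TACGAT"     # not a consensus box
  gain <- rep(parent, 60)
  for (i in seq_along(gain)) substr(gain[i], 21, 26) <- "TATAAT"
  keep <- rep(parent, 60)
  F <- c(rnorm(60, 3.5, 0.05), rnorm(60, 1.2, 0.05))
  rec <- scan_associations(parent, c(gain, keep), F, pwm10,
                           hotspot_peaks = 22L)
  at_box <- rec[rec$window_start == 20, ]
  expect_equal(at_box$direction, "gain")
  expect_gt(at_box$delta_F, 0.5)
})

test_that("type-I error of the scan is controlled under label shuffling", {
  set.seed(19)
  n <- 200
  seqs <- random_dna(n, 40)
  F <- runif(n, 1, 4)
  pwm_loose <- build_pwm(c("TATAAT", "TACAAT", "TATGAT", "CATAAT"),
                         pseudocount = 1, name = "minus10")
  thr <- 2   # permissive threshold so both groups exceed 10 in most windows
  tested <- 0; hits <- 0
  for (r in 1:30) {
    Fs <- sample(F)
    for (ws in c(0, 10, 20, 30)) {
      part <- window_partition(seqs, Fs, pwm_loose, ws, threshold = thr)
      res <- mwu_association(part$F_with, part$F_without)
      if (is.null(res)) next
      tested <- tested + 1
      hits <- hits + (res$p < 0.05)
    }
  }
  expect_gt(tested, 50)
  se <- sqrt(0.05 * 0.95 / tested)
  expect_lte(hits / tested, 0.05 + 3 * se)
})

test_that("new_box_census reports exactly the gained start positions", {
  set.seed(23)
  parent <- random_dna(1, 120)
  # ensure no accidental consensus in the parent at the target windows
  substr(parent, 41, 46) <- "CCCCCC"
  substr(parent, 91, 96) <- "GGGGGG"
  expect_equal(new_box_census(parent, rep(parent, 3), pwm10), integer(0))
  d1 <- parent; substr(d1, 41, 46) <- "TATAAT"
  d2 <- parent; substr(d2, 41, 46) <- "TATAAT"; substr(d2, 91, 96) <- "TATAAT"
  cens <- new_box_census(parent, c(d1, d2, parent), pwm10)
  expect_setequal(cens, c(40L, 90L))
  # destroying a parent box adds nothing to the census
  p2 <- parent; substr(p2, 61, 66) <- "TATAAT"
  dd <- p2; substr(dd, 63, 63) <- "C"
  expect_equal(new_box_census(p2, dd, pwm10), integer(0))
})

test_that("gain classification separates homo, hetero and non-overlapping", {
  parent_hits <- data.frame(start = c(49, 48, 40),
                            end = c(55, 54, 46),
                            motif_class = c("minus10", "minus35", "minus10"))
  homo <- classify_gain(50, "minus10", 6, parent_hits)
  expect_equal(homo$gain_type, "homo")
  expect_equal(nrow(homo$overlapped), 2)   # both overlapping hits reported
  hetero <- classify_gain(50, "minus10", 6,
                          parent_hits[parent_hits$motif_class == "minus35", ])
  expect_equal(hetero$gain_type, "hetero")
  non <- classify_gain(10, "minus10", 6, parent_hits)
  expect_equal(non$gain_type, "non_overlapping")
  # half-open adjacency is not overlap
  adj <- classify_gain(46, "minus10", 6,
                       data.frame(start = 40, end = 46,
                                  motif_class = "minus10"))
  expect_equal(adj$gain_type, "non_overlapping")
})

test_that("spacing and TGn census counts cognate-spaced and extended boxes", {
  set.seed(29)
  parent <- random_dna(1, 120)
  substr(parent, 21, 26) <- "TTGACA"   # parent -35 at 0-based 20
  # daughter creates a -10 at start 43 => spacer 43 - (20+6) = 17, with TG at 40..41
  d <- parent
  substr(d, 41, 43) <- "TGA"
  substr(d, 44, 49) <- "TATAAT"
  cens <- census_spacing_and_tgn(new10 = 43L, new35 = integer(0),
                                 parent10 = integer(0), parent35 = 20L,
                                 seqs = d, pwm10 = pwm10)
  expect_equal(cens$n_new, 1)
  expect_equal(cens$n_spaced, 1)
  expect_equal(cens$n_tgn, 1)
  # spacer 25: not counted; no TG upstream
  d2 <- parent
  substr(d2, 52, 57) <- "TATAAT"
  substr(d2, 49, 50) <- "CC"
  cens2 <- census_spacing_and_tgn(new10 = 51L, new35 = integer(0),
                                  parent10 = integer(0), parent35 = 20L,
                                  seqs = d2, pwm10 = pwm10)
  expect_equal(cens2$n_spaced, 0)
  expect_equal(cens2$n_tgn, 0)
})

test_that("pooled BH families recompute q-values per motif class and channel", {
  rec <- data.frame(
    parent_id = "P1", channel = c("gfp", "gfp", "rfp"),
    window_start = 1:3, motif_class = "minus10",
    direction = "gain", n_with = 20, n_without = 20,
    delta_F = c(1, 0.2, 1), p = c(0.01, 0.04, 0.01), near_hotspot = TRUE,
    q = NA_real_, significant_effect = NA
  )
  pooled <- pool_bh(rec)
  expect_equal(pooled$q[1:2], oracle_bh(c(0.01, 0.04)))
  expect_equal(pooled$q[3], 0.01)   # rfp family of size 1
  expect_equal(pooled$significant_effect, c(TRUE, FALSE, TRUE))
})
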