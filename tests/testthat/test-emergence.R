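test_that("P_new is the promoter-indicator mean with the shared boundary", {
  expect_equal(compute_pnew(rep(1, 10)), 0)
  expect_equal(compute_pnew(c(1.0, 1.6, 2.0, 1.4)), 0.5)
  expect_equal(compute_pnew(c(1.5, 1.49)), 0.5)
  # consistency with classify_promoter
  set.seed(6)
  F <- runif(200, 1, 4)
  expect_equal(compute_pnew(F), mean(classify_promoter(F)))
  expect_equal(compute_pnew(F, strict = TRUE),
               mean(classify_promoter(F, strict = TRUE)))
  expect_error(compute_pnew(numeric(0)), "no daughters")
})

test_that("sigmoid fit recovers noiseless generating parameters to 1e-6", {
  x <- seq(1, 2, by = 0.1)
  y <- 0.4 / (1 + exp(-20 * (x - 1.5)))
  fit <- fit_sigmoid(x, y)
  expect_equal(unname(coef(fit)), c(0.4, 1.5, 20), tolerance = 1e-6)
  expect_false(fit$degenerate)
  expect_equal(predict(fit, x), y, tolerance = 1e-6)
  expect_true(all(summary(fit)$p_value < 0.05))
})

test_that("sigmoid fit under noise covers the truth within 3 standard errors", {
  set.seed(14)
  x <- runif(50, 1, 2)
  hits <- 0
  for (r in 1:40) {
    y <- 0.4 / (1 + exp(-20 * (x - 1.5))) + rnorm(50, 0, 0.02)
    y <- pmin(pmax(y, 0), 1)
    fit <- fit_sigmoid(x, y)
    se <- sqrt(diag(fit$vcov))
    hits <- hits + all(abs(coef(fit) - c(0.4, 1.5, 20)) <= 3 * se)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("flat response is flagged as a degenerate sigmoid fit", {
  fit <- fit_sigmoid(seq(1, 2, 0.1), rep(0, 11))
  expect_true(fit$degenerate)
  expect_equal(unname(coef(fit)["L"]), 0)
})

test_that("feature regression matches closed-form OLS", {
  # exact fixtures trigger lm's perfect-fit warning by design
  fr <- suppressWarnings(feature_regression(1:10, 2 * (1:10)))
  expect_equal(fr$slope, 2)
  expect_equal(fr$r2, 1)
  expect_lt(fr$p_wald, 1e-10)
  fr2 <- feature_regression(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(fr2$slope, 0.8)
  expect_equal(fr2$r2, 0.64)
  set.seed(2)
  fr3 <- suppressWarnings(feature_regression(rnorm(10), rep(0.3, 10)))
  expect_equal(fr3$slope, 0)
  expect_equal(fr3$r2, 0)
  expect_error(feature_regression(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("k-mer enumeration size equals the closed form for any range", {
  expect_equal(length(enumerate_kmers(1, 1)), 4)
  expect_equal(length(enumerate_kmers(1, 6)), 5460)
  for (kmin in 1:3) for (kmax in kmin:4) {
    expect_length(enumerate_kmers(kmin, kmax), sum(4^(kmin:kmax)))
  }
  expect_false(anyDuplicated(enumerate_kmers(1, 4)) > 0)
})

test_that("k-mer regression flags exactly the collinear k-mer family", {
  # 5 parents built from A/C only so that GTTG-family counts are controlled:
  # parent i carries i copies of GTTG separated by A-runs; P_new = i/10
  mk <- function(copies) {
    body <- paste(rep(c("GTTG", "AAAAAA"), copies), collapse = "")
    pad <- paste(rep("CA", (60 - nchar(body)) / 2), collapse = "")
    paste0(body, pad)
  }
  parents <- vapply(1:5, mk, character(1))
  names(parents) <- paste0("P", 1:5)
  pnew <- (1:5) / 10
  # perfect-fit warnings from summary.lm are expected in this exact fixture
  res <- suppressWarnings(
    kmer_analysis(parents, pnew, kmin = 4, kmax = 4, min_count = 3,
                  fdr = 0.05)
  )
  expect_equal(res$n_enumerated, 256)
  expect_true("GTTG" %in% res$significant)
  sig <- res$results[res$results$significant, ]
  # every significant k-mer's count vector is perfectly collinear with P_new
  expect_true(all(abs(sig$p) < 1e-6 | is.na(sig$p)))
  # leave-one-out report has one entry per parent
  expect_length(res$leave_one_out, 5)
})

test_that("scramble operations conserve composition and are seeded", {
  expect_equal(scramble_whole_parent("AAAA"), "AAAA")
  set.seed(1)
  s <- random_dna(1, 80)
  sc <- scramble_whole_parent(s, seed = 5)
  expect_equal(sort(strsplit(sc, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_equal(scramble_whole_parent(s, seed = 5),
               scramble_whole_parent(s, seed = 5))
})

test_that("motif-region scrambles are local and avoid new motifs", {
  pwm10 <- build_pwm("TATAAT", name = "minus10")
  set.seed(44)
  s <- random_dna(1, 60)
  substr(s, 21, 26) <- "TATAAT"
  out <- scramble_motif_region(s, 20, 6, list(pwm10), seed = 3)
  # flanks unchanged
  expect_equal(substr(out, 1, 20), substr(s, 1, 20))
  expect_equal(substr(out, 27, 60), substr(s, 27, 60))
  # composition of the region conserved
  expect_equal(sort(strsplit(substr(out, 21, 26), "")[[1]]),
               sort(strsplit("TATAAT", "")[[1]]))
  # no above-threshold -10 hit overlapping the region in the result
  hits <- scan_sequence(pwm10, out)
  expect_false(any(hits$start < 26 & hits$end > 20))
  # all-A region is trivially accepted unchanged
  s2 <- paste0(paste(rep("C", 20), collapse = ""), "AAAAAA",
               paste(rep("C", 20), collapse = ""))
  expect_equal(scramble_motif_region(s2, 20, 6, list(pwm10)), s2)
})

test_that("overlap null counts conserve totals and shift toward 'neither'", {
  pwm10 <- build_pwm("TATAAT", name = "minus10")
  pwm35 <- build_pwm("TTGACA", name = "minus35")
  set.seed(12)
  # parents tiled densely with consensus boxes
  mk <- function() {
    s <- random_dna(1, 150)
    for (st in c(10, 40, 70, 100, 130)) substr(s, st, st + 5) <- "TATAAT"
    for (st in c(25, 55, 85, 115)) substr(s, st, st + 5) <- "TTGACA"
    s
  }
  parents <- setNames(c(mk(), mk()), c("P1", "P2"))
  hotspots <- list(P1 = c(12L, 57L, 80L), P2 = c(27L, 102L))
  res <- overlap_null_counts(parents, hotspots, pwm10, pwm35, seed = 2)
  expect_equal(sum(res$observed), 5)
  expect_equal(sum(res$scrambled), 5)
  # direction over 50 seeds: scrambling increases the 'neither' share
  neither_shift <- vapply(1:50, function(sd) {
    r <- overlap_null_counts(parents, hotspots, pwm10, pwm35, seed = sd)
    r$scrambled["neither"] - r$observed["neither"]
  }, numeric(1))
  expect_gt(mean(neither_shift), 0)
  # parents with no motifs anywhere: all hotspots 'neither' in both conditions
  set.seed(3)
  bare <- setNames(paste(rep("C", 150), collapse = ""), "P1")
  r0 <- overlap_null_counts(bare, list(P1 = c(10L, 80L)), pwm10, pwm35)
  expect_equal(unname(r0$observed["neither"]), 2)
  expect_equal(unname(r0$scrambled["neither"]), 2)
})

test_that("chi-squared goodness of fit equals the one-line oracle", {
  oracle <- function(o, e) sum((o - e)^2 / e)
  set.seed(8)
  for (i in 1:20) {
    o <- rpois(4, 12); e <- rpois(4, 12) + 1
    r <- chisq_goodness_of_fit(o, e)
    expect_equal(r$chi2, oracle(o, e))
    expect_equal(r$df, 3)
    expect_equal(r$p, pchisq(oracle(o, e), 3, lower.tail = FALSE))
  }
  expect_error(chisq_goodness_of_fit(1:4, c(0, 1, 2, 3)), "> 0")
})

test_that("Tukey-fence outlier calling is two-sided and exact on quartiles", {
  expect_length(hns_candidate_outliers(rep(2, 8)), 0)
  expect_equal(unname(hns_candidate_outliers(c(0, 0, 0, 0, 0, 0, 0, 10))), 10)
  x <- c(-10, rnorm(20, 0, 0.1), 10)
  out <- hns_candidate_outliers(x)
  expect_true(all(c(-10, 10) %in% out))
  # frozen quartile arithmetic on the 8-vector (type-7 interpolation)
  v <- c(0, 0, 0, 0, 0, 0, 0, 10)
  expect_equal(oracle_percentile(v, 0.25), 0)
  expect_equal(oracle_percentile(v, 0.75), 0)
})
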