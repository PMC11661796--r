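#' Probability of promoter emergence for one parent
#'
#' The fraction of a parent's daughters whose fluorescence score reaches
#' the promoter threshold.
#'
#' @param F daughter fluorescence scores (a.u.); `NA` entries are excluded.
#' @param threshold promoter threshold, a.u.
#' @param strict boundary convention shared with [classify_promoter()].
#' @return fraction in \[0, 1\].
#' @export
compute_pnew <- function(F, threshold = 1.5, strict = FALSE) {
  F <- F[!is.na(F)]
  if (!length(F)) stop("no daughters with a score")
  mean(classify_promoter(F, threshold, strict))
}

#' Fit a sigmoid to the emergence probability vs parent fluorescence
#'
#' Nonlinear least-squares fit of
#' \eqn{P_{new} = L / (1 + e^{-k (x - x_0)})} — the canonical increasing
#' logistic with upper asymptote `L`, inflection `x0` (a.u.) and slope `k`.
#' (Some write the exponent as \eqn{-k(x_0 - x)}, in which case the fitted
#' `k` carries the opposite sign; the increasing form matches a rising
#' emergence probability with parent fluorescence.)
#'
#' @param x parent fluorescence scores (a.u.).
#' @param y per-parent emergence probabilities.
#' @param start named list of starting values (`L`, `x0`, `k`).
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return an object of class `sigmoid_fit`: list with `coefficients`
#'   (L, x0, k), `vcov`, `p_values` (per-parameter Wald), `fitted`,
#'   `residuals`, `converged`, `degenerate`, `fit` (the underlying `nls`
#'   object or `NULL`).
#' @export
fit_sigmoid <- function(x, y, start = list(L = max(y), x0 = 1.5, k = 10),
                        max_iter = 200) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 4) stop("need at least 4 points")
  if (all(y == 0) || max(y) - min(y) < sqrt(.Machine$double.eps)) {
    return(structure(
      list(coefficients = c(L = 0, x0 = NA_real_, k = NA_real_),
           vcov = NULL, p_values = NULL, fitted = rep(mean(y), length(y)),
           residuals = y - mean(y), converged = FALSE, degenerate = TRUE,
           fit = NULL),
      class = "sigmoid_fit"
    ))
  }
  dat <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ L / (1 + exp(-k * (x - x0))), data = dat, start = start,
    lower = c(L = 1e-9, x0 = -Inf, k = -Inf),
    upper = c(L = 1, x0 = Inf, k = Inf),
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-14, ptol = 1e-14)
  )
  sm <- summary(fit)
  structure(
    list(coefficients = coef(fit), vcov = vcov(fit),
         p_values = sm$coefficients[, "Pr(>|t|)"],
         fitted = fitted(fit), residuals = residuals(fit),
         converged = fit$convInfo$isConv %||% TRUE, degenerate = FALSE,
         fit = fit),
    class = "sigmoid_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate sigmoid fit (flat response, L -> 0)\n")
  } else {
    co <- x$coefficients
    cat(sprintf("Sigmoid fit: L = %.4g, x0 = %.4g a.u., k = %.4g\n",
                co["L"], co["x0"], co["k"]))
  }
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
summary.sigmoid_fit <- function(object, ...) {
  if (object$degenerate) return(print(object))
  data.frame(estimate = object$coefficients,
             std_error = sqrt(diag(object$vcov)),
             p_value = object$p_values)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  if (object$degenerate) stop("cannot predict from a degenerate fit")
  if (is.null(newdata)) return(object$fitted)
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  unname(co["L"] / (1 + exp(-co["k"] * (x - co["x0"]))))
}

#' Ordinary least-squares feature regression
#'
#' Regresses per-parent emergence probability on a sequence feature and
#' reports the slope, its Wald test p-value against zero, and the squared
#' Pearson correlation.
#'
#' @param x feature values, one per parent.
#' @param y response (e.g. P_new), one per parent.
#' @return list with `slope`, `intercept`, `p_wald`, `r2`.
#' @export
feature_regression <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("zero-variance feature")
  fit <- lm(y ~ x)
  co <- summary(fit)$coefficients
  p <- if (nrow(co) > 1) co["x", "Pr(>|t|)"] else NA_real_
  r2 <- if (sd(y) == 0) 0 else unname(cor(x, y)^2)
  list(slope = unname(coef(fit)["x"]), intercept = unname(coef(fit)[1]),
       p_wald = if (sd(y) == 0) NA_real_ else p, r2 = r2)
}

#' Enumerate all k-mers in a length range
#'
#' @param kmin,kmax inclusive k range.
#' @return character vector of all \eqn{\sum_k 4^k} k-mers.
#' @export
enumerate_kmers <- function(kmin = 1, kmax = 6) {
  unlist(lapply(kmin:kmax, function(k) {
    do.call(paste0, expand.grid(rep(list(BASES), k))[k:1])
  }), use.names = FALSE)
}

## overlapping occurrence counts of every substring of length kmin..kmax
count_kmers <- function(seq, kmin, kmax) {
  L <- nchar(seq)
  subs <- unlist(lapply(kmin:kmax, function(k) {
    if (L < k) return(character())
    substring(seq, 1:(L - k + 1), k:L)
  }))
  table(subs)
}

#' k-mer association with emergence probability
#'
#' Enumerates every k-mer from `kmin` to `kmax` bp, counts overlapping
#' occurrences on each parent's analyzed strand, keeps k-mers present at
#' least `min_count` times in at least one parent, regresses P_new on the
#' per-parent counts for each retained k-mer, applies Benjamini-Hochberg
#' at the given FDR, and refits with each parent left out to expose
#' single-parent leverage.
#'
#' @param seqs named character vector of parent sequences (analyzed
#'   strand).
#' @param pnew per-parent emergence probabilities, same order.
#' @param kmin,kmax k-mer length range.
#' @param min_count occurrence filter.
#' @param fdr Benjamini-Hochberg FDR.
#' @return list with `results` (data.frame: kmer, slope, p, q,
#'   significant), `significant` (character vector), `n_enumerated`,
#'   `n_candidates`, `leave_one_out` (named list: parent left out ->
#'   significant k-mers).
#' @export
kmer_analysis <- function(seqs, pnew, kmin = 1, kmax = 6, min_count = 3,
                          fdr = 0.05) {
  if (length(seqs) < 3) stop("need at least 3 parents")
  if (is.null(names(seqs))) names(seqs) <- paste0("P", seq_along(seqs))
  kmers <- enumerate_kmers(kmin, kmax)
  counts <- matrix(0L, length(seqs), length(kmers),
                   dimnames = list(names(seqs), kmers))
  for (i in seq_along(seqs)) {
    tb <- count_kmers(seqs[i], kmin, kmax)
    counts[i, names(tb)] <- as.integer(tb)
  }
  cand <- kmers[apply(counts, 2, max) >= min_count]
  test_set <- function(keep_parents) {
    res <- vapply(cand, function(km) {
      x <- counts[keep_parents, km]
      if (sd(x) == 0 || sd(pnew[keep_parents]) == 0)
        return(c(slope = NA_real_, p = NA_real_))
      fr <- feature_regression(x, pnew[keep_parents])
      c(slope = fr$slope, p = fr$p_wald)
    }, numeric(2))
    df <- data.frame(kmer = cand, slope = res["slope", ], p = res["p", ],
                     row.names = NULL, stringsAsFactors = FALSE)
    df$q <- p.adjust(df$p, method = "BH")
    df$significant <- !is.na(df$q) & df$q <= fdr
    df
  }
  full <- test_set(seq_along(seqs))
  loo <- lapply(seq_along(seqs), function(i) {
    d <- test_set(setdiff(seq_along(seqs), i))
    d$kmer[d$significant]
  })
  names(loo) <- names(seqs)
  list(results = full, significant = full$kmer[full$significant],
       n_enumerated = length(kmers), n_candidates = length(cand),
       leave_one_out = loo)
}

#' Scramble an entire parent sequence
#'
#' Uniform random permutation of the sequence's characters; base
#' composition is conserved exactly.
#'
#' @param seq DNA string.
#' @param seed optional integer seed.
#' @return permuted sequence.
#' @export
scramble_whole_parent <- function(seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(sample(x), collapse = "")
}

#' Scramble a motif region without creating new motifs
#'
#' Permutes only the characters of `[start, start + width)` (conserving the
#' region's composition, hence its GC content, and the spacing of flanking
#' elements) and rejects any shuffle that creates a new above-threshold hit
#' of an avoided PWM overlapping the region, retrying up to `max_tries`
#' times. Hits already present in the input sequence are not counted as
#' new.
#'
#' @param seq DNA string.
#' @param start 0-based region start.
#' @param width region width in bp.
#' @param pwms_to_avoid list of `pwm` objects.
#' @param seed optional integer seed.
#' @param max_tries attempts before failing.
#' @return the sequence with the region shuffled.
#' @export
scramble_motif_region <- function(seq, start, width, pwms_to_avoid = list(),
                                  seed = NULL, max_tries = 1000) {
  L <- nchar(seq)
  if (start < 0 || start + width > L) stop("region outside sequence")
  if (!is.null(seed)) set.seed(seed)
  region_hits <- function(s, pwm) {
    h <- scan_sequence(pwm, s)
    h[h$start < start + width & h$end > start, , drop = FALSE]$start
  }
  before <- lapply(pwms_to_avoid, function(p) region_hits(seq, p))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- (start + 1):(start + width)
  for (try in seq_len(max_tries)) {
    cand <- chars
    cand[idx] <- sample(chars[idx])
    cand_seq <- paste(cand, collapse = "")
    new_hit <- FALSE
    for (k in seq_along(pwms_to_avoid)) {
      if (length(setdiff(region_hits(cand_seq, pwms_to_avoid[[k]]),
                         before[[k]]))) { new_hit <- TRUE; break }
    }
    if (!new_hit) return(cand_seq)
  }
  stop("scramble_motif_region: no motif-free shuffle found in ",
       max_tries, " tries")
}

#' Hotspot/motif overlap counts on real vs scrambled parents
#'
#' Classifies every hotspot's -10/-35 overlap on the real parent sequences
#' and on scrambled versions (hotspot coordinates held fixed), returning
#' both 4-category count vectors over
#' `minus10_only / minus35_only / both / neither`.
#'
#' @param parents named character vector of parent sequences (analyzed
#'   strand).
#' @param hotspots named list: parent id -> integer vector of 0-based
#'   hotspot peaks.
#' @param pwm10,pwm35 the box PWMs.
#' @param seed optional integer seed for the scrambles.
#' @param n_reps scrambled replicates per parent (counts are averaged).
#' @param window hotspot overlap half-width in bp.
#' @return list with `observed` and `scrambled` named count vectors.
#' @export
overlap_null_counts <- function(parents, hotspots, pwm10, pwm35,
                                seed = NULL, n_reps = 1, window = 3) {
  if (!is.null(seed)) set.seed(seed)
  classes <- c("minus10_only", "minus35_only", "both", "neither")
  tally <- function(seqs) {
    cls <- unlist(lapply(names(hotspots), function(pid) {
      h10 <- scan_sequence(pwm10, seqs[[pid]])
      h35 <- scan_sequence(pwm35, seqs[[pid]])
      vapply(hotspots[[pid]], classify_hotspot_overlap, character(1),
             hits10 = h10, hits35 = h35, window = window)
    }))
    table(factor(cls, levels = classes))
  }
  observed <- tally(parents)
  scram <- Reduce(`+`, lapply(seq_len(n_reps), function(r) {
    tally(setNames(vapply(parents, scramble_whole_parent, character(1)),
                   names(parents)))
  })) / n_reps
  list(observed = c(observed), scrambled = c(scram))
}

#' Chi-squared goodness of fit between two overlap count vectors
#'
#' \eqn{\chi^2 = \sum_i (O_i - E_i)^2 / E_i} with the comparison group's
#' counts as expected values, and the p-value from the chi-squared
#' distribution with `length(observed) - 1` degrees of freedom.
#'
#' @param observed,expected count vectors of equal length; all expected
#'   counts must be positive.
#' @return list with `chi2`, `p`, `df`.
#' @export
chisq_goodness_of_fit <- function(observed, expected) {
  if (length(observed) != length(expected)) stop("length mismatch")
  if (any(expected <= 0)) stop("expected counts must all be > 0")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(chi2 = chi2, p = pchisq(chi2, df, lower.tail = FALSE), df = df)
}

#' Tukey-fence outlier calling for repressor-knockout screens
#'
#' Flags per-parent fluorescence changes lying outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by linear interpolation), the
#' standard box-plot whisker rule, to nominate candidate repressor targets.
#'
#' @param deltas named numeric vector of per-parent fluorescence changes
#'   (knockout minus wild-type), one channel at a time.
#' @param k fence multiplier.
#' @return the flagged subset of `deltas`.
#' @export
hns_candidate_outliers <- function(deltas, k = 1.5) {
  if (length(deltas) < 4) stop("need at least 4 values")
  q <- quantile(deltas, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  deltas[deltas < q[1] - k * iqr | deltas > q[2] + k * iqr]
}
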