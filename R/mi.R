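#' Split records into three pseudo-replicates
#'
#' Random partition into three disjoint subsets whose sizes differ by at
#' most one, used to estimate the sampling variability of the mutual
#' information profile.
#'
#' @param n number of records.
#' @param seed optional integer seed (reproducible partition).
#' @return integer vector of length `n` with replicate labels 1..3.
#' @export
split_pseudoreplicates <- function(n, seed = NULL) {
  if (n < 3) stop("need at least 3 records to form pseudo-replicates")
  if (!is.null(seed)) set.seed(seed)
  labels <- rep(1:3, length.out = n)
  sample(labels)
}

## round-half-up of F into bins 1..4
round_bin <- function(F) {
  pmin(pmax(floor(F + 0.5), 1L), 4L)
}

#' Positional mutual information between base identity and fluorescence
#'
#' For each position the plug-in mutual information (base 2) between the
#' base \eqn{b \in \{A,C,G,T\}} and the fluorescence score rounded
#' half-up to the nearest whole number \eqn{f \in \{1,2,3,4\}}, minus the
#' finite-sample correction \eqn{(n_b-1)(n_f-1)\log_2(e) / (2N)} with
#' \eqn{n_b = n_f = 4} and \eqn{N} the number of records (the
#' \eqn{O(N^{-2})} remainder of the expansion is unspecified and dropped).
#' Zero-probability cells contribute 0 to the double sum.
#'
#' @param seqs character vector of equal-length daughter sequences (or an
#'   integer matrix from the internal encoder).
#' @param F fluorescence scores, one per sequence, all finite.
#' @return numeric vector of corrected MI (bits), one entry per position;
#'   values can be negative for uninformative positions.
#' @export
mutual_information <- function(seqs, F) {
  mat <- if (is.matrix(seqs)) seqs else seqs_to_mat(seqs)
  if (length(F) != nrow(mat)) stop("one fluorescence score per sequence required")
  if (any(!is.finite(F))) stop("all fluorescence scores must be finite")
  N <- nrow(mat)
  if (N == 0) stop("empty record set")
  f <- round_bin(F)
  correction <- 9 * log2(exp(1)) / (2 * N)
  pf <- tabulate(f, 4L) / N
  vapply(seq_len(ncol(mat)), function(i) {
    joint <- tabulate(mat[, i] + 4L * (f - 1L), 16L) / N  # 4x4 in col-major b,f
    jm <- matrix(joint, 4, 4)
    pb <- rowSums(jm)
    terms <- jm * log2(jm / (pb %o% pf))
    sum(terms[jm > 0]) - correction
  }, numeric(1))
}

#' Gaussian smoothing of a positional profile
#'
#' One-dimensional Gaussian filter (kernel truncated at four standard
#' deviations, normalized to unit mass) with reflect-style boundary
#' handling, applied to MI profiles before hotspot calling and plotting.
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in positions.
#' @return smoothed vector, same length.
#' @export
smooth_profile <- function(x, sigma = 1) {
  if (sigma <= 0) return(x)
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  ## reflect padding: (c b a | a b c ... ) as in standard image filters
  pad <- c(x[pmin(r, n):1], x, x[n:pmax(n - r + 1, 1)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

#' Adjusted mutual information
#'
#' The mean MI across pseudo-replicates minus one standard deviation, with
#' every value below 0.0005 bits truncated to 0: a conservative profile in
#' which only positions whose signal exceeds replicate-to-replicate noise
#' survive.
#'
#' @param mean_mi,std_mi equal-length numeric vectors.
#' @param floor truncation threshold in bits.
#' @return adjusted MI vector (non-negative).
#' @export
adjusted_mi <- function(mean_mi, std_mi, floor = 0.0005) {
  if (length(mean_mi) != length(std_mi)) stop("length mismatch")
  a <- mean_mi - std_mi
  a[a < floor] <- 0
  a
}

#' Compute a full MI profile for one parent's daughters
#'
#' Splits the records into three pseudo-replicates, computes the corrected
#' MI profile per replicate, smooths each replicate profile with a Gaussian
#' kernel, then takes the mean and standard deviation across replicates and
#' forms the adjusted profile. (Smoothing each replicate before averaging
#' is the default; `smooth_first = FALSE` averages raw replicate profiles
#' and smooths the mean instead.)
#'
#' @param seqs daughter sequences (equal length).
#' @param F fluorescence scores for the analyzed channel (finite).
#' @param seed seed for the pseudo-replicate split.
#' @param sigma Gaussian kernel standard deviation.
#' @param smooth_first smooth per replicate before the mean/std (default)
#'   or after.
#' @param sd_denominator `"n"` (population, default) or `"n-1"` for the
#'   replicate standard deviation.
#' @return object of class `mi_profile`: list with `mean_mi`, `std_mi`,
#'   `adjusted`, `replicates` (3 x L matrix), `N` (records per replicate,
#'   approximate), `hotspots` (integer 0-based peak positions).
#' @export
mi_profile <- function(seqs, F, seed = NULL, sigma = 1, smooth_first = TRUE,
                       sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  mat <- if (is.matrix(seqs)) seqs else seqs_to_mat(seqs)
  ok <- is.finite(F)
  mat <- mat[ok, , drop = FALSE]
  F <- F[ok]
  rep_id <- split_pseudoreplicates(nrow(mat), seed)
  profiles <- t(vapply(1:3, function(r) {
    p <- mutual_information(mat[rep_id == r, , drop = FALSE], F[rep_id == r])
    if (smooth_first) smooth_profile(p, sigma) else p
  }, numeric(ncol(mat))))
  mean_mi <- colMeans(profiles)
  std_mi <- apply(profiles, 2, sd)
  if (sd_denominator == "n") std_mi <- std_mi * sqrt(2 / 3)
  if (!smooth_first) {
    mean_mi <- smooth_profile(mean_mi, sigma)
    std_mi <- smooth_profile(std_mi, sigma)
  }
  adj <- adjusted_mi(mean_mi, std_mi)
  structure(
    list(mean_mi = mean_mi, std_mi = std_mi, adjusted = adj,
         replicates = profiles, N = floor(nrow(mat) / 3),
         hotspots = find_hotspots(adj)),
    class = "mi_profile"
  )
}

#' @export
print.mi_profile <- function(x, ...) {
  cat(sprintf("MI profile over %d positions (%d records per pseudo-replicate)\n",
              length(x$mean_mi), x$N))
  cat(sprintf("hotspots at 0-based positions: %s\n",
              if (length(x$hotspots)) paste(x$hotspots, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @export
plot.mi_profile <- function(x, ...) {
  pos <- seq_along(x$mean_mi) - 1
  plot(pos, x$mean_mi, type = "l", xlab = "position (0-based)",
       ylab = "mutual information (bits)", ...)
  graphics::polygon(c(pos, rev(pos)),
                    c(x$mean_mi - x$std_mi, rev(x$mean_mi + x$std_mi)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(pos, x$mean_mi)
  if (length(x$hotspots))
    graphics::abline(v = x$hotspots, lty = 2, col = "red")
  invisible(x)
}

#' Call mutual-information hotspots
#'
#' A hotspot is a position whose adjusted MI (i) is at or above the 90th
#' percentile of the whole adjusted profile (linear interpolation between
#' order statistics, zeros included) and (ii) strictly exceeds the adjusted
#' MI of both neighbouring positions. The two boundary positions cannot be
#' hotspots.
#'
#' @param adjusted adjusted MI vector (length >= 3).
#' @param prob percentile used as the threshold.
#' @return integer vector of 0-based peak positions.
#' @export
find_hotspots <- function(adjusted, prob = 0.9) {
  n <- length(adjusted)
  if (n < 3) stop("profile too short")
  thr <- quantile(adjusted, prob, type = 7, names = FALSE)
  i <- 2:(n - 1)
  keep <- adjusted[i] >= thr &
    adjusted[i] > adjusted[i - 1] & adjusted[i] > adjusted[i + 1]
  i[keep] - 1L
}

#' Classify a hotspot's overlap with -10/-35 boxes
#'
#' A motif hit overlaps a hotspot when its half-open interval
#' `[start, start+width)` intersects the window `peak +/- window` bp.
#'
#' @param peak 0-based hotspot peak position.
#' @param hits10,hits35 hit data.frames from [scan_sequence()] in the same
#'   strand frame as the peak.
#' @param window half-width of the hotspot region in bp.
#' @return one of `"minus10_only"`, `"minus35_only"`, `"both"`, `"neither"`.
#' @export
classify_hotspot_overlap <- function(peak, hits10, hits35, window = 3) {
  ov <- function(hits) {
    nrow(hits) > 0 && any(hits$start <= peak + window &
                            hits$end > peak - window)
  }
  has10 <- ov(hits10)
  has35 <- ov(hits35)
  if (has10 && has35) "both"
  else if (has10) "minus10_only"
  else if (has35) "minus35_only"
  else "neither"
}

#' Write an MI profile and its hotspots to TSV files
#'
#' @param profile an `mi_profile` object.
#' @param parent_id,channel labels for the output.
#' @param profile_file,hotspot_file output paths (either may be `NULL`).
#' @export
write_mi_profile <- function(profile, parent_id, channel,
                             profile_file = NULL, hotspot_file = NULL) {
  if (!is.null(profile_file)) {
    utils::write.table(
      data.frame(parent_id = parent_id, channel = channel,
                 position = seq_along(profile$mean_mi) - 1,
                 mean_mi = profile$mean_mi, std_mi = profile$std_mi,
                 adjusted = profile$adjusted),
      profile_file, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(hotspot_file)) {
    utils::write.table(
      data.frame(parent_id = rep(parent_id, length(profile$hotspots)),
                 start = profile$hotspots, end = profile$hotspots + 1L,
                 name = rep("hotspot", length(profile$hotspots)),
                 score = profile$adjusted[profile$hotspots + 1L],
                 strand = rep(if (channel == "gfp") "+" else "-",
                              length(profile$hotspots))),
      hotspot_file, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  invisible(profile)
}
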