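#' Partition daughters by motif presence in a window
#'
#' Scores each daughter's window `[window_start, window_start + width)`
#' against the PWM and splits the fluorescence scores into a "Motif (+)"
#' list (window score at or above the threshold) and a "Motif (-)" list.
#'
#' @param seqs daughter sequences (equal length) or pre-encoded integer
#'   matrix.
#' @param F fluorescence scores, one per daughter.
#' @param pwm a `pwm` object.
#' @param window_start 0-based window start.
#' @param threshold score threshold in bits (default `pwm$threshold`).
#' @return list with `F_with` and `F_without` numeric vectors.
#' @export
window_partition <- function(seqs, F, pwm, window_start,
                             threshold = pwm$threshold) {
  mat <- if (is.matrix(seqs)) seqs else seqs_to_mat(seqs)
  w <- pwm$width
  if (window_start < 0 || window_start + w > ncol(mat))
    stop("window does not fit in the sequence")
  sub <- mat[, (window_start + 1):(window_start + w), drop = FALSE]
  s <- as.vector(score_matrix(pwm, sub))
  list(F_with = F[s >= threshold], F_without = F[s < threshold])
}

#' Mann-Whitney U association between motif presence and fluorescence
#'
#' Two-sided Mann-Whitney U test between the "with" and "without"
#' fluorescence lists, computed only when both lists contain more than
#' `min_n` values. Small tie-free groups are tested exactly; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param F_with,F_without numeric fluorescence lists.
#' @param min_n both lists must contain strictly more than this many values.
#' @return list with `p` and `delta_F = median(F_with) - median(F_without)`,
#'   or `NULL` (skip) when either list is too small.
#' @export
mwu_association <- function(F_with, F_without, min_n = 10) {
  if (length(F_with) <= min_n || length(F_without) <= min_n) return(NULL)
  ties <- anyDuplicated(c(F_with, F_without)) > 0
  exact <- !ties && length(F_with) < 9 && length(F_without) < 9
  p <- suppressWarnings(
    wilcox.test(F_with, F_without, alternative = "two.sided",
                exact = exact, correct = !exact)$p.value
  )
  if (!is.finite(p)) p <- 1   # fully tied data carries no evidence
  list(p = p, delta_F = median(F_with) - median(F_without))
}

## does a window [w, w+width) lie within +/- prox of any hotspot peak?
near_hotspot <- function(window_start, width, peaks, prox = 3) {
  if (!length(peaks)) return(FALSE)
  any(window_start <= peaks + prox & window_start + width > peaks - prox)
}

#' Sliding-window motif gain/loss association scan
#'
#' Slides a PWM-width window one position at a time across the parent,
#' partitions the daughters by motif presence in the window, tests each
#' window with a two-sided Mann-Whitney U test, and records every test
#' with p below `alpha` that lies within `prox` bp of a hotspot peak.
#' Benjamini-Hochberg q-values are then computed over the recorded set;
#' an association is a significant effect when its q-value passes the FDR
#' and the median fluorescence difference exceeds the effect threshold.
#' Direction is `"loss"` where the parent itself carries an
#' above-threshold motif in the window, `"gain"` otherwise.
#'
#' @param parent_seq the parent sequence (analyzed strand).
#' @param seqs,F daughter sequences and fluorescence scores.
#' @param pwm a `pwm` object.
#' @param hotspot_peaks integer vector of 0-based hotspot peaks.
#' @param alpha raw p-value recording threshold.
#' @param fdr Benjamini-Hochberg false-discovery rate.
#' @param effect minimum absolute median fluorescence difference (a.u.).
#' @param min_n passed to [mwu_association()].
#' @param prox hotspot proximity in bp.
#' @param parent_id,channel labels copied into the output.
#' @return data.frame of association records: `parent_id`, `channel`,
#'   `window_start`, `motif_class`, `direction`, `n_with`, `n_without`,
#'   `delta_F`, `p`, `q`, `near_hotspot`, `significant_effect`.
#' @export
scan_associations <- function(parent_seq, seqs, F, pwm, hotspot_peaks,
                              alpha = 0.05, fdr = 0.05, effect = 0.5,
                              min_n = 10, prox = 3,
                              parent_id = NA_character_, channel = NA_character_) {
  mat <- if (is.matrix(seqs)) seqs else seqs_to_mat(seqs)
  pvec <- seq_to_int(parent_seq)
  w <- pwm$width
  scores <- score_matrix(pwm, mat)                     # n x K
  pscores <- as.vector(score_matrix(pwm, matrix(pvec, nrow = 1)))
  K <- ncol(scores)
  rows <- vector("list", K)
  for (ws in 0:(K - 1)) {
    if (!near_hotspot(ws, w, hotspot_peaks, prox)) next
    with_idx <- scores[, ws + 1] >= pwm$threshold
    test <- mwu_association(F[with_idx], F[!with_idx], min_n)
    if (is.null(test) || test$p >= alpha) next
    rows[[ws + 1]] <- data.frame(
      parent_id = parent_id, channel = channel, window_start = ws,
      motif_class = pwm$name,
      direction = if (pscores[ws + 1] >= pwm$threshold) "loss" else "gain",
      n_with = sum(with_idx), n_without = sum(!with_idx),
      delta_F = test$delta_F, p = test$p,
      near_hotspot = TRUE, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(parent_id = character(), channel = character(),
                      window_start = integer(), motif_class = character(),
                      direction = character(), n_with = integer(),
                      n_without = integer(), delta_F = numeric(),
                      p = numeric(), q = numeric(), near_hotspot = logical(),
                      significant_effect = logical()))
  out$q <- p.adjust(out$p, method = "BH")
  out$significant_effect <- out$q <= fdr & abs(out$delta_F) > effect
  out
}

#' Benjamini-Hochberg correction over pooled association records
#'
#' Recomputes q-values and the significant-effect flag over a pooled family
#' of association records (by default per motif class and channel, across
#' parents — mirroring pooled supplementary tables).
#'
#' @param records row-bound association records from [scan_associations()].
#' @param fdr false-discovery rate.
#' @param effect minimum absolute median fluorescence difference (a.u.).
#' @param by columns defining each BH family.
#' @return the records with refreshed `q` and `significant_effect`.
#' @export
pool_bh <- function(records, fdr = 0.05, effect = 0.5,
                    by = c("motif_class", "channel")) {
  if (!nrow(records)) return(records)
  fam <- interaction(records[by], drop = TRUE)
  records$q <- ave(records$p, fam, FUN = function(p) p.adjust(p, "BH"))
  records$significant_effect <- records$q <= fdr & abs(records$delta_F) > effect
  records
}

#' Census of new motif positions created by mutation
#'
#' Unique 0-based start positions where at least one daughter carries an
#' above-threshold motif but the parent does not.
#'
#' @param parent_seq parent sequence (analyzed strand).
#' @param seqs daughter sequences.
#' @param pwm a `pwm` object.
#' @return sorted integer vector of new start positions.
#' @export
new_box_census <- function(parent_seq, seqs, pwm) {
  mat <- if (is.matrix(seqs)) seqs else seqs_to_mat(seqs)
  pscores <- as.vector(score_matrix(pwm, matrix(seq_to_int(parent_seq), nrow = 1)))
  dmax <- apply(score_matrix(pwm, mat), 2, max)
  sort(which(dmax >= pwm$threshold & pscores < pwm$threshold) - 1L)
}

#' Classify a gained box relative to preexisting boxes
#'
#' A new box overlapping (non-empty half-open interval intersection) a
#' parent box of the same motif class is a homo-gain; overlapping only the
#' other class, a hetero-gain; otherwise non-overlapping. When boxes of
#' both classes overlap, homo takes precedence and all overlapped parent
#' hits are reported.
#'
#' @param new_start 0-based start of the new box.
#' @param new_class motif class of the new box.
#' @param width box width in bp.
#' @param parent_hits data.frame of parent hits (columns `start`, `end`,
#'   `motif_class`).
#' @return list with `gain_type` (`"homo"`, `"hetero"` or
#'   `"non_overlapping"`) and `overlapped` (the overlapped parent hits).
#' @export
classify_gain <- function(new_start, new_class, width, parent_hits) {
  if (nrow(parent_hits)) {
    ov <- parent_hits$start < new_start + width & parent_hits$end > new_start
    overlapped <- parent_hits[ov, , drop = FALSE]
  } else {
    overlapped <- parent_hits
  }
  gain_type <- if (!nrow(overlapped)) "non_overlapping"
  else if (any(overlapped$motif_class == new_class)) "homo"
  else "hetero"
  list(gain_type = gain_type, overlapped = overlapped)
}

#' Spacing and TGn census over new boxes
#'
#' Counts how many new boxes have a cognate box — new or preexisting — at
#' promoter-like spacing (15-20 bp spacer), and how many new -10 boxes
#' carry the TG extension in at least one daughter that created them.
#'
#' @param new10,new35 integer vectors of new box start positions (from
#'   [new_box_census()]).
#' @param parent10,parent35 integer vectors of the parent's own box starts.
#' @param seqs daughter sequences (used for the TGn check).
#' @param pwm10 the -10 `pwm` (used to find which daughters created each
#'   new -10 box).
#' @param spacer_min,spacer_max spacer bounds in bp.
#' @return list with `n_new` (total new boxes), `n_spaced` (new boxes with
#'   a cognate at legal spacing), `n_new10`, `n_tgn` (new -10 boxes with
#'   the TG extension).
#' @export
census_spacing_and_tgn <- function(new10, new35, parent10, parent35,
                                   seqs, pwm10,
                                   spacer_min = 15, spacer_max = 20) {
  all10 <- sort(unique(c(new10, parent10)))
  all35 <- sort(unique(c(new35, parent35)))
  spaced10 <- vapply(new10, function(s) {
    any(s - (all35 + 6L) >= spacer_min & s - (all35 + 6L) <= spacer_max)
  }, logical(1))
  spaced35 <- vapply(new35, function(s) {
    any(all10 - (s + 6L) >= spacer_min & all10 - (s + 6L) <= spacer_max)
  }, logical(1))
  mat <- if (is.matrix(seqs)) seqs else seqs_to_mat(seqs)
  scores <- if (length(new10)) score_matrix(pwm10, mat) else NULL
  tgn <- vapply(new10, function(s) {
    if (s < 3) return(FALSE)
    carriers <- scores[, s + 1] >= pwm10$threshold
    any(mat[carriers, s - 2] == 4L & mat[carriers, s - 1] == 3L)  # T,G
  }, logical(1))
  list(n_new = length(new10) + length(new35),
       n_spaced = sum(spaced10) + sum(spaced35),
       n_new10 = length(new10), n_tgn = sum(tgn))
}

#' Write association records as CSV
#'
#' @param records association records.
#' @param file path.
#' @export
write_associations <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
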