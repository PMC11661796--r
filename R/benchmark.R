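#' End-to-end parameter recovery on synthetic sort-seq data
#'
#' Runs the full pipeline over seeded synthetic replicates and measures how
#' often the ground truth is recovered: (i) the fraction of planted
#' promoters for which at least one mutual-information hotspot lies within
#' 3 bp of a planted box, and (ii) the fraction of planted -10 positions at
#' which the sliding-window loss test recovers the planted effect sign
#' (box presence associated with higher fluorescence).
#'
#' Each replicate simulates `n_templates` parents with one planted
#' consensus promoter each (GFP/top strand), mutates them into
#' `daughters_per_parent` unique daughters, simulates binned reads, and
#' analyzes the resulting daughter table with [mi_profile()] and
#' [mwu_association()] exactly as real data would be.
#'
#' @param n_replicates number of seeded simulation replicates.
#' @param n_templates parents per replicate.
#' @param daughters_per_parent unique daughters per parent.
#' @param reads_per_daughter sequencing depth per channel.
#' @param bin_spillover adjacent-bin read spillover probability.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param prox hotspot-to-box proximity in bp.
#' @return list with `hotspot_recovery` and `sign_recovery` (fractions over
#'   all parents of all replicates), `n_parents` (total parents scored) and
#'   `per_replicate` (data.frame of per-replicate fractions).
#' @export
recovery_benchmark <- function(n_replicates = 20, n_templates = 10,
                               daughters_per_parent = 2000,
                               reads_per_daughter = 50,
                               bin_spillover = 0.05, seed = 1, prox = 3) {
  pwm10 <- build_pwm("TATAAT", name = "minus10")
  hot_hits <- sign_hits <- n <- 0
  per_rep <- data.frame(replicate = seq_len(n_replicates),
                        hotspot_recovery = NA_real_,
                        sign_recovery = NA_real_)
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(n_templates = n_templates,
                      daughters_per_parent = daughters_per_parent,
                      reads_per_daughter = reads_per_daughter,
                      bin_spillover = bin_spillover,
                      seed = seed + r)
    sim <- simulate_sortseq(cfg)
    tab <- sim$daughters
    F_all <- fluorescence_score(as.matrix(tab[paste0("gfp_bin", 1:4)]))
    rh <- rs <- 0
    for (pid in names(sim$parents)) {
      d <- tab$parent == pid
      mat <- seqs_to_mat(tab$sequence[d])
      F <- F_all[d]
      truth <- sim$truth$planted[[pid]]
      planted <- truth[truth$class %in% c("minus10", "minus35"), ]
      prof <- mi_profile(mat, F, seed = seed + r)
      near <- any(vapply(prof$hotspots, function(pk) {
        any(pk >= planted$start - prox & pk < planted$end + prox)
      }, logical(1)))
      rh <- rh + near
      s10 <- planted$start[planted$class == "minus10"][1]
      part <- window_partition(mat, F, pwm10, s10)
      mw <- mwu_association(part$F_with, part$F_without)
      rs <- rs + (!is.null(mw) && mw$delta_F > 0 && mw$p < 0.05)
      n <- n + 1
    }
    hot_hits <- hot_hits + rh
    sign_hits <- sign_hits + rs
    per_rep$hotspot_recovery[r] <- rh / n_templates
    per_rep$sign_recovery[r] <- rs / n_templates
  }
  list(hotspot_recovery = hot_hits / n, sign_recovery = sign_hits / n,
       n_parents = n, per_replicate = per_rep)
}
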