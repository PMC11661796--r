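#' Configuration for a synthetic sort-seq simulation
#'
#' Bundles every knob of the generator. The defaults emulate the study
#' conditions of a promoter-island sort-seq library: 150 bp templates,
#' error-prone-PCR daughters carrying 1-10 substitutions with mean ~2.5,
#' at least 2000 unique daughters per parent, and reads multinomially
#' distributed over 4 bins per channel with symmetric nearest-neighbour
#' spillover.
#'
#' The latent activity model is a logistic of summed PWM scores: per
#' strand, the activity is the best -10/-35 pair at 15-20 bp spacing
#' (boxes must score at or above the activity PWM threshold; a sequence
#' with no legal pair has activity 0), minus a repression term when a
#' planted H-NS site is intact, and
#' \eqn{F = 1 + 3 / (1 + e^{-(a - a_0)/s})}.
#'
#' @param n_templates number of 150 bp templates (each strand is analyzed
#'   as an independent parent).
#' @param seq_length template length in bp.
#' @param gc_content background GC fraction.
#' @param planted_promoters list (one entry per template, recycled) of
#'   lists with `minus35`, `minus10` (instance strings), `start35` (0-based)
#'   and `spacer` (15-20) and `strand` (`"top"`/`"bottom"`); `NULL` entries
#'   plant nothing.
#' @param decoy_boxes number of unpaired consensus boxes placed uniformly
#'   at random per template, subject to non-overlap and to not forming a
#'   legally spaced pair.
#' @param hns_sites optional list per template: `sequence`, `start`,
#'   `strand`, `strength` (activity units subtracted while the site is
#'   intact).
#' @param mutation_mean target mean substitutions per daughter
#'   (zero-truncated Poisson).
#' @param mutation_max cap on substitutions per daughter.
#' @param daughters_per_parent unique daughters per template.
#' @param reads_per_daughter sequencing depth per channel.
#' @param unsorted_mean mean Poisson reads per daughter in the unsorted
#'   library.
#' @param bin_spillover probability of a read landing in an adjacent bin.
#' @param activity hyperparameters of the latent activity model: list with
#'   `pwm10`, `pwm35` (activity PWMs), `w10`, `w35` (score weights), `a0`
#'   (midpoint) and `s` (scale).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_templates = 25,
                       seq_length = 150,
                       gc_content = 0.4,
                       planted_promoters = list(list(
                         minus35 = "TTGACA", minus10 = "TATAAT",
                         start35 = 60, spacer = 17, strand = "top")),
                       decoy_boxes = 4,
                       hns_sites = NULL,
                       mutation_mean = 2.5,
                       mutation_max = 10,
                       daughters_per_parent = 2000,
                       reads_per_daughter = 50,
                       unsorted_mean = 5,
                       bin_spillover = 0.05,
                       activity = NULL,
                       seed = 1) {
  if (bin_spillover < 0 || bin_spillover >= 0.5)
    stop("bin_spillover must lie in [0, 0.5)")
  if (mutation_max < 1) stop("mutation_max must be >= 1")
  if (is.null(activity)) {
    activity <- list(
      pwm10 = build_pwm("TATAAT", pseudocount = 0.01, name = "minus10"),
      pwm35 = build_pwm("TTGACA", pseudocount = 0.01, name = "minus35"),
      w10 = 1, w35 = 1, a0 = 20, s = 0.6
    )
  }
  structure(
    list(n_templates = n_templates, seq_length = seq_length,
         gc_content = gc_content, planted_promoters = planted_promoters,
         decoy_boxes = decoy_boxes, hns_sites = hns_sites,
         mutation_mean = mutation_mean, mutation_max = mutation_max,
         daughters_per_parent = daughters_per_parent,
         reads_per_daughter = reads_per_daughter,
         unsorted_mean = unsorted_mean, bin_spillover = bin_spillover,
         activity = activity, seed = seed),
    class = "sim_config"
  )
}

## place an element on the top-strand frame; bottom-strand elements are
## written as the reverse complement at mirrored coordinates
write_element <- function(chars, element, start, strand, L) {
  w <- nchar(element)
  if (strand == "bottom") {
    element <- revcomp(element)
    start <- L - w - start
  }
  if (start < 0 || start + w > L) stop("planted element outside sequence")
  chars[(start + 1):(start + w)] <- strsplit(element, "", fixed = TRUE)[[1]]
  chars
}

#' Generate one parent template with planted motifs
#'
#' Draws random background at the configured GC content, writes the planted
#' promoter boxes (and optional H-NS site) at their coordinates, and places
#' decoy consensus boxes uniformly at random subject to non-overlap with
#' all previously placed elements and to not forming a legally spaced
#' (15-20 bp) pair with any placed cognate box.
#'
#' @param config a `sim_config`.
#' @param template_index which template's planted elements to use.
#' @param seed optional integer seed.
#' @return list with `sequence` and `truth` (planted coordinates on the
#'   top-strand frame plus the element strand and class).
#' @export
generate_parent <- function(config, template_index = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$seq_length
  gc <- config$gc_content
  chars <- sample(BASES, L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  placed <- data.frame(start = integer(), end = integer(),
                       class = character(), strand = character())
  plant <- function(el, start, strand, class) {
    w <- nchar(el)
    top_start <- if (strand == "bottom") L - w - start else start
    chars <<- write_element(chars, el, start, strand, L)
    placed <<- rbind(placed, data.frame(start = top_start,
                                        end = top_start + w,
                                        class = class, strand = strand))
  }
  pp <- config$planted_promoters
  prom <- if (length(pp)) pp[[(template_index - 1) %% length(pp) + 1]] else NULL
  if (!is.null(prom)) {
    s35 <- prom$start35
    s10 <- s35 + 6 + prom$spacer
    plant(prom$minus35, s35, prom$strand, "minus35")
    plant(prom$minus10, s10, prom$strand, "minus10")
  }
  hns <- config$hns_sites
  site <- if (length(hns)) hns[[(template_index - 1) %% length(hns) + 1]] else NULL
  if (!is.null(site)) plant(site$sequence, site$start, site$strand, "HNS")
  if (config$decoy_boxes > 0) {
    decoy_pool <- c("TATAAT", "TTGACA")
    for (d in seq_len(config$decoy_boxes)) {
      el <- decoy_pool[(d - 1) %% 2 + 1]
      cls <- c("minus10", "minus35")[(d - 1) %% 2 + 1]
      ok <- FALSE
      for (try in 1:200) {
        start <- sample.int(L - 6 + 1, 1) - 1L
        if (nrow(placed) &&
            any(placed$start < start + 6 & placed$end > start)) next
        ## avoid creating a legally spaced pair with a placed cognate box
        other <- placed[placed$class != cls & placed$class != "HNS", ,
                        drop = FALSE]
        sp <- if (cls == "minus10") start - (other$start + 6L)
              else other$start - (start + 6L)
        if (length(sp) && any(sp >= 15 & sp <= 20)) next
        plant(el, start, "top", paste0("decoy_", cls))
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place decoy box after bounded retries")
    }
  }
  list(sequence = paste(chars, collapse = ""), truth = placed)
}

## zero-truncated Poisson rate whose truncated mean equals m
ztpois_lambda <- function(m) {
  if (m <= 1) stop("truncated mean must exceed 1")
  uniroot(function(l) l / (1 - exp(-l)) - m, c(1e-8, 4 * m))$root
}

#' Mutate a parent into daughter sequences
#'
#' Per daughter, the substitution count is drawn from a zero-truncated
#' Poisson whose truncated mean equals `mutation_mean`, capped at
#' `mutation_max`; positions are uniform without replacement and the
#' substituted base is uniform over the three alternatives. Every daughter
#' differs from the parent (Hamming distance equals the drawn count).
#'
#' @param parent parent sequence.
#' @param n number of daughters.
#' @param config a `sim_config` (uses `mutation_mean`, `mutation_max`).
#' @param seed optional integer seed.
#' @param unique_daughters deduplicate and redraw until `n` distinct
#'   daughters exist.
#' @return character vector of daughter sequences.
#' @export
mutate_daughters <- function(parent, n, config = sim_config(), seed = NULL,
                             unique_daughters = FALSE) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lambda <- ztpois_lambda(config$mutation_mean)
  px <- seq_to_int(parent)
  L <- length(px)
  draw <- function(m) {
    k <- rpois(m, lambda)
    while (any(k == 0)) k[k == 0] <- rpois(sum(k == 0), lambda)
    k <- pmin(k, config$mutation_max)
    vapply(k, function(ki) {
      pos <- sample.int(L, ki)
      x <- px
      ## uniform over the 3 alternative bases
      x[pos] <- ((x[pos] - 1L + sample.int(3L, ki, replace = TRUE)) %% 4L) + 1L
      int_to_seq(x)
    }, character(1))
  }
  out <- draw(n)
  if (unique_daughters) {
    out <- unique(out)
    while (length(out) < n) out <- unique(c(out, draw(n - length(out))))
    out <- out[seq_len(n)]
  }
  out
}

## activity of one strand's integer matrix under the activity model
strand_activity <- function(mat, act) {
  s10 <- score_matrix(act$pwm10, mat)
  s35 <- score_matrix(act$pwm35, mat)
  s10[s10 < act$pwm10$threshold] <- -Inf
  s35[s35 < act$pwm35$threshold] <- -Inf
  K <- ncol(s10)
  a <- matrix(-Inf, nrow(mat), K)
  for (sp in 15:20) {
    j10 <- (1:K) + 6L + sp
    ok <- j10 <= K
    if (!any(ok)) next
    cand <- act$w35 * s35[, ok, drop = FALSE] +
      act$w10 * s10[, j10[ok], drop = FALSE]
    a[, ok] <- pmax(a[, ok, drop = FALSE], cand)
  }
  best <- apply(a, 1, max)
  ifelse(is.finite(best), best, 0)
}

#' Latent fluorescence of sequences under the activity model
#'
#' Deterministic ground-truth fluorescence for both channels: activity is
#' computed on the top strand (GFP) and on the reverse complement (RFP),
#' reduced by `strength` for every planted H-NS site whose sequence is
#' intact at its planted position on the matching strand, and mapped
#' through the logistic \eqn{F = 1 + 3/(1 + e^{-(a - a_0)/s})}.
#'
#' @param seqs character vector of sequences.
#' @param config a `sim_config`.
#' @param hns_site optional single H-NS entry (as in `config$hns_sites`)
#'   applying to these sequences' template.
#' @return data.frame with `F_gfp` and `F_rfp`.
#' @export
latent_fluorescence <- function(seqs, config = sim_config(),
                                hns_site = NULL) {
  act <- config$activity
  mat_top <- seqs_to_mat(seqs)
  mat_bot <- seqs_to_mat(revcomp(seqs))
  a_top <- strand_activity(mat_top, act)
  a_bot <- strand_activity(mat_bot, act)
  if (!is.null(hns_site)) {
    L <- config$seq_length
    w <- nchar(hns_site$sequence)
    intact_on <- function(mat, start, site_seq) {
      target <- seq_to_int(site_seq)
      rowSums(mat[, (start + 1):(start + w), drop = FALSE] !=
                matrix(target, nrow(mat), w, byrow = TRUE)) == 0
    }
    if (hns_site$strand == "top") {
      intact <- intact_on(mat_top, hns_site$start, hns_site$sequence)
    } else {
      intact <- intact_on(mat_bot, hns_site$start, hns_site$sequence)
    }
    repress <- ifelse(intact, hns_site$strength, 0)
    a_top <- pmax(a_top - repress, 0) * (a_top > 0)
    a_bot <- pmax(a_bot - repress, 0) * (a_bot > 0)
  }
  logistic_F <- function(a) 1 + 3 / (1 + exp(-(a - act$a0) / act$s))
  data.frame(F_gfp = logistic_F(a_top), F_rfp = logistic_F(a_bot))
}

#' Simulate sorting-bin read counts for one channel
#'
#' The true bin is the fluorescence rounded half-up; `depth` reads are
#' multinomially distributed with probability \eqn{1 - 2\epsilon} on the
#' true bin and \eqn{\epsilon} on each existing adjacent bin (edge bins
#' renormalize over the existing neighbours).
#'
#' @param F latent fluorescence values in \[1, 4\].
#' @param depth reads per daughter.
#' @param eps adjacent-bin spillover probability.
#' @param seed optional integer seed.
#' @return integer matrix, one row per daughter, columns bins 1..4.
#' @export
simulate_bin_reads <- function(F, depth, eps = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(F < 1 | F > 4)) stop("fluorescence must lie in [1, 4]")
  true_bin <- round_bin(F)
  probs <- lapply(1:4, function(b) {
    p <- numeric(4)
    p[b] <- 1 - 2 * eps
    if (b > 1) p[b - 1] <- eps
    if (b < 4) p[b + 1] <- eps
    p / sum(p)
  })
  out <- matrix(0L, length(F), 4)
  for (b in 1:4) {
    idx <- which(true_bin == b)
    if (!length(idx)) next
    out[idx, ] <- t(rmultinom(length(idx), depth, probs[[b]]))
  }
  out
}

#' Simulate a full sort-seq dataset with ground truth
#'
#' Generates `n_templates` parents, mutates each into unique daughters,
#' assigns latent fluorescence under the activity model, and simulates
#' per-bin read counts for both channels plus an unsorted-library count.
#'
#' @param config a `sim_config`; `config$seed` seeds the whole simulation.
#' @return list of class `sortseq_sim` with `parents` (named character
#'   vector), `daughters` (daughter table: sequence, parent, bin counts,
#'   unsorted_reads), `truth` (list with per-parent planted coordinates
#'   and per-daughter latent fluorescence).
#' @export
simulate_sortseq <- function(config = sim_config()) {
  set.seed(config$seed)
  parents <- character(config$n_templates)
  names(parents) <- paste0("P", seq_len(config$n_templates))
  planted <- vector("list", config$n_templates)
  tabs <- vector("list", config$n_templates)
  latent <- vector("list", config$n_templates)
  for (t in seq_len(config$n_templates)) {
    gp <- generate_parent(config, template_index = t)
    parents[t] <- gp$sequence
    planted[[t]] <- gp$truth
    daughters <- mutate_daughters(gp$sequence, config$daughters_per_parent,
                                  config, unique_daughters = TRUE)
    hns <- config$hns_sites
    site <- if (length(hns)) hns[[(t - 1) %% length(hns) + 1]] else NULL
    lf <- latent_fluorescence(daughters, config, hns_site = site)
    gfp <- simulate_bin_reads(lf$F_gfp, config$reads_per_daughter,
                              config$bin_spillover)
    rfp <- simulate_bin_reads(lf$F_rfp, config$reads_per_daughter,
                              config$bin_spillover)
    tab <- data.frame(sequence = daughters, parent = names(parents)[t],
                      stringsAsFactors = FALSE)
    for (b in 1:4) tab[[paste0("gfp_bin", b)]] <- gfp[, b]
    for (b in 1:4) tab[[paste0("rfp_bin", b)]] <- rfp[, b]
    tab$unsorted_reads <- rpois(nrow(tab), config$unsorted_mean)
    tabs[[t]] <- tab
    lf$parent <- names(parents)[t]
    latent[[t]] <- lf
  }
  structure(
    list(parents = parents,
         daughters = do.call(rbind, tabs),
         truth = list(planted = setNames(planted, names(parents)),
                      latent = do.call(rbind, latent),
                      config = config)),
    class = "sortseq_sim"
  )
}

#' @export
print.sortseq_sim <- function(x, ...) {
  cat(sprintf("Synthetic sort-seq dataset: %d parents, %d daughters\n",
              length(x$parents), nrow(x$daughters)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits a parents FASTA, the daughter table CSV (the dialect read by
#' [read_daughter_table()]) and a ground-truth JSON; the files round-trip
#' losslessly through the package readers.
#'
#' @param sim a `sortseq_sim` object.
#' @param dir output directory (created if missing).
#' @return named character vector of file paths.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "parents.fasta")
  csv <- file.path(dir, "daughters.csv")
  truth <- file.path(dir, "truth.json")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$parents), fasta)
  write_daughter_table(sim$daughters, csv)
  jsonlite::write_json(
    list(planted = lapply(sim$truth$planted, function(d) as.list(d)),
         latent = sim$truth$latent),
    truth, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  c(parents = fasta, daughters = csv, truth = truth)
}
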