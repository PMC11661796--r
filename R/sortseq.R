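ECORI <- "GAATTC"
BAMHI <- "GGATCC"

#' Orient a merged read and assign its sorting bin
#'
#' Merged reads carry the insert between an EcoRI (`GAATTC`) and a BamHI
#' (`GGATCC`) cut site, with a bin barcode immediately upstream of the
#' EcoRI site. Reads lacking either site are rejected; when the BamHI site
#' precedes the EcoRI site the reverse complement is taken first (both
#' sites are palindromic, so orientation is decided purely by their order).
#' Barcode matching is exact and anchored immediately 5' of the EcoRI site.
#'
#' @param read a single merged read (DNA string).
#' @param barcodes named character vector: names are bin labels (e.g.
#'   `"gfp_1"`), values the barcode sequences.
#' @return list with `accepted` (logical); on acceptance `insert` (the
#'   sequence strictly between the cut sites) and `bin` (label); on
#'   rejection `reason`.
#' @export
orient_and_demux <- function(read, barcodes) {
  read <- toupper(read)
  pe <- regexpr(ECORI, read, fixed = TRUE)
  pb <- regexpr(BAMHI, read, fixed = TRUE)
  if (pe == -1L || pb == -1L)
    return(list(accepted = FALSE, reason = "missing cut site"))
  if (pb < pe) {
    read <- revcomp(read)
    pe <- regexpr(ECORI, read, fixed = TRUE)
    pb <- regexpr(BAMHI, read, fixed = TRUE)
  }
  if (pe == -1L || pb == -1L || pb < pe)
    return(list(accepted = FALSE, reason = "missing cut site"))
  bin <- NA_character_
  for (lab in names(barcodes)) {
    bc <- barcodes[[lab]]
    s <- pe - nchar(bc)
    if (s >= 1 && substr(read, s, pe - 1) == bc) { bin <- lab; break }
  }
  if (is.na(bin))
    return(list(accepted = FALSE, reason = "unknown barcode"))
  insert <- substr(read, pe + nchar(ECORI), pb - 1)
  list(accepted = TRUE, insert = insert, bin = bin)
}

#' Tabulate demultiplexed reads into a daughter table
#'
#' Runs [orient_and_demux()] over a set of merged reads and counts every
#' distinct insert per bin, producing the per-daughter bin-count table the
#' rest of the pipeline consumes.
#'
#' @param reads character vector of merged reads.
#' @param barcodes named character vector of bin barcodes; expected names
#'   are `gfp_1..gfp_4`, `rfp_1..rfp_4` and `unsorted`.
#' @return list with `table` (data.frame: sequence, gfp_bin1..4,
#'   rfp_bin1..4, unsorted_reads) and `rejections` (data.frame: read index,
#'   reason).
#' @export
demux_reads <- function(reads, barcodes) {
  bins <- c(paste0("gfp_", 1:4), paste0("rfp_", 1:4), "unsorted")
  res <- lapply(reads, orient_and_demux, barcodes = barcodes)
  acc <- vapply(res, `[[`, logical(1), "accepted")
  rej <- data.frame(
    read = which(!acc),
    reason = vapply(res[!acc], `[[`, character(1), "reason")
  )
  if (!any(acc)) {
    tab <- data.frame(sequence = character())
    for (b in bins) tab[[bin_column(b)]] <- integer()
    return(list(table = tab, rejections = rej))
  }
  ins <- vapply(res[acc], `[[`, character(1), "insert")
  bin <- vapply(res[acc], `[[`, character(1), "bin")
  seqs <- sort(unique(ins))
  tab <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (b in bins) {
    cnt <- table(factor(ins[bin == b], levels = seqs))
    tab[[bin_column(b)]] <- as.integer(cnt)
  }
  list(table = tab, rejections = rej)
}

bin_column <- function(bin) {
  if (bin == "unsorted") return("unsorted_reads")
  parts <- strsplit(bin, "_", fixed = TRUE)[[1]]
  paste0(parts[1], "_bin", parts[2])
}

#' Fluorescence score from per-bin read counts
#'
#' The score is the read-weighted mean bin index,
#' \eqn{F = \sum_f f \cdot R_f / \sum_f R_f}, in arbitrary units from 1.0
#' (all reads in the "none" bin) to 4.0 (all in the "high" bin).
#'
#' @param reads 4 counts (bins 1..4) or an n x 4 matrix of counts.
#' @return scalar or vector of scores; `NA` where all four counts are zero
#'   (the record is excluded from that channel).
#' @export
fluorescence_score <- function(reads) {
  if (is.null(dim(reads))) reads <- matrix(reads, nrow = 1)
  if (ncol(reads) != 4) stop("need counts for exactly 4 bins")
  if (any(reads < 0)) stop("negative read count")
  tot <- rowSums(reads)
  f <- as.vector(reads %*% (1:4)) / tot
  f[tot == 0] <- NA_real_
  if (length(f) == 1) f[[1]] else f
}

#' Map daughter sequences to their closest parent
#'
#' Assigns each equal-length daughter to the parent at minimal Hamming
#' distance; ties are broken by parent input order and flagged.
#'
#' @param seqs character vector of daughter sequences.
#' @param parents named character vector of parent sequences (names are
#'   parent ids).
#' @return data.frame with `parent_id`, `hamming`, `ambiguous`.
#' @export
map_to_parent <- function(seqs, parents) {
  if (is.null(names(parents))) names(parents) <- paste0("P", seq_along(parents))
  dm <- seqs_to_mat(seqs)
  pm <- seqs_to_mat(unname(parents))
  if (ncol(dm) != ncol(pm)) stop("daughter/parent length mismatch")
  D <- matrix(0L, nrow(dm), nrow(pm))
  for (p in seq_len(nrow(pm)))
    D[, p] <- rowSums(dm != matrix(pm[p, ], nrow(dm), ncol(dm), byrow = TRUE))
  best <- max.col(-D, ties.method = "first")
  hmin <- D[cbind(seq_len(nrow(D)), best)]
  amb <- rowSums(D == hmin) > 1
  data.frame(parent_id = names(parents)[best], hamming = hmin,
             ambiguous = amb, stringsAsFactors = FALSE)
}

#' Filter a parent-mapped daughter table
#'
#' Applies the study's quality filters in order: sequence length must equal
#' the template length; the daughter must occur at least once in the
#' unsorted library; total reads across all bins plus the unsorted library
#' must reach `min_total_reads`; the Hamming distance to the assigned
#' parent must not exceed `max_hamming`; finally every parent with fewer
#' than `min_daughters` surviving unique daughters is dropped along with
#' its daughters. Idempotent.
#'
#' @param tab daughter table with columns `sequence`, `parent_id`,
#'   `hamming`, `gfp_bin1..4`, `rfp_bin1..4`, `unsorted_reads`.
#' @param template_length expected daughter length in bp.
#' @param min_total_reads minimum summed reads (both channels' bins plus
#'   the unsorted count; configurable notion of "entire dataset").
#' @param max_hamming maximum allowed distance to the assigned parent.
#' @param min_daughters minimum surviving unique daughters per parent.
#' @param count_unsorted include the unsorted count in the total-read sum.
#' @return list with `kept` (filtered table) and `rejections` (data.frame:
#'   sequence, reason — one reason per dropped record).
#' @export
filter_daughters <- function(tab, template_length = 150,
                             min_total_reads = 30, max_hamming = 10,
                             min_daughters = 2000, count_unsorted = TRUE) {
  gcols <- paste0("gfp_bin", 1:4)
  rcols <- paste0("rfp_bin", 1:4)
  total <- rowSums(tab[gcols]) + rowSums(tab[rcols]) +
    if (count_unsorted) tab$unsorted_reads else 0
  reason <- rep(NA_character_, nrow(tab))
  reason[is.na(reason) & nchar(tab$sequence) != template_length] <- "length"
  reason[is.na(reason) & tab$unsorted_reads < 1] <- "absent_unsorted"
  reason[is.na(reason) & total < min_total_reads] <- "min_reads"
  reason[is.na(reason) & tab$hamming > max_hamming] <- "distance"
  keep <- is.na(reason)
  surv <- table(tab$parent_id[keep])
  low <- names(surv)[surv < min_daughters]
  reason[keep & tab$parent_id %in% low] <- "parent_too_few_daughters"
  keep <- is.na(reason)
  list(
    kept = tab[keep, , drop = FALSE],
    rejections = data.frame(sequence = tab$sequence[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
}

#' Promoter call from a fluorescence score
#'
#' @param F fluorescence score(s), a.u. in \[1, 4\].
#' @param threshold promoter threshold, a.u.
#' @param strict if `TRUE`, require `F > threshold` instead of
#'   `F >= threshold` (the boundary convention is configurable; the default
#'   `>=` is consistent with a 1.49 a.u. parent being called non-promoter).
#' @return logical vector.
#' @export
classify_promoter <- function(F, threshold = 1.5, strict = FALSE) {
  if (strict) F > threshold else F >= threshold
}

#' Score a daughter table: parent mapping and fluorescence
#'
#' Adds `parent_id`, `hamming`, `ambiguous`, `F_gfp` and `F_rfp` columns to
#' a raw daughter table (the two channels are scored independently from
#' their own bin counts; a record with no reads in one channel keeps the
#' other channel's score and gets `NA` in the empty one).
#'
#' @param tab daughter table with `sequence`, `gfp_bin1..4`, `rfp_bin1..4`,
#'   `unsorted_reads` columns.
#' @param parents named character vector of parent sequences.
#' @return the augmented daughter table.
#' @export
score_daughter_table <- function(tab, parents) {
  mp <- map_to_parent(tab$sequence, parents)
  tab$parent_id <- mp$parent_id
  tab$hamming <- mp$hamming
  tab$ambiguous <- mp$ambiguous
  tab$F_gfp <- fluorescence_score(as.matrix(tab[paste0("gfp_bin", 1:4)]))
  tab$F_rfp <- fluorescence_score(as.matrix(tab[paste0("rfp_bin", 1:4)]))
  tab
}

#' Read/write a daughter table CSV
#'
#' The CSV dialect mirrors the deposited supplementary daughter tables:
#' one row per unique daughter with columns `sequence`, `gfp_bin1..4`,
#' `rfp_bin1..4`, `unsorted_reads`, plus any columns added by
#' [score_daughter_table()].
#'
#' @param file path.
#' @param tab daughter table.
#' @return `read_daughter_table` returns a data.frame.
#' @export
read_daughter_table <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname read_daughter_table
#' @export
write_daughter_table <- function(tab, file) {
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
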