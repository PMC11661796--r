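#' Build a position weight matrix from aligned instances
#'
#' Converts a set of equal-length, gap-free DNA instances into a log2-odds
#' position weight matrix against a uniform background (25% each base).
#' The default hit threshold follows the standard practice of using the
#' total information content of the matrix, so that e.g. sigma70 -10 and
#' -35 box matrices derived from RegulonDB instances carry thresholds of
#' 3.98 and 3.39 bits respectively.
#'
#' @param instances character vector of equal-length DNA strings (A/C/G/T).
#' @param pseudocount additive count \eqn{\ge 0} applied to every base at
#'   every position before converting counts to frequencies. With the
#'   default 0, a base unobserved at a position scores `-Inf`.
#' @param name motif class label (e.g. `"minus10"`).
#' @param threshold hit threshold in bits; defaults to the information
#'   content of the matrix.
#' @return an object of class `pwm`: a list with `name`, `width`, `counts`
#'   (4 x width), `log_odds` (4 x width, bits), `pseudocount`,
#'   `info_content` (bits) and `threshold` (bits).
#' @examples
#' p <- build_pwm(c("TATAAT", "TACAAT"), name = "minus10")
#' score_window(p, "TATAAT")
#' @export
build_pwm <- function(instances, pseudocount = 0, name = "motif",
                      threshold = NULL) {
  if (length(instances) < 1) stop("need at least one instance")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  w <- nchar(instances[1])
  if (w < 1) stop("instances must have width >= 1")
  mat <- seqs_to_mat(instances)       # errors on ragged/non-ACGT input
  n <- nrow(mat)
  counts <- vapply(seq_len(w), function(j) tabulate(mat[, j], nbins = 4L),
                   numeric(4))
  dimnames(counts) <- list(BASES, NULL)
  freqs <- (counts + pseudocount) / (n + 4 * pseudocount)
  log_odds <- log2(freqs / 0.25)      # -Inf where freq == 0
  ic <- info_content_from_freqs(freqs)
  structure(
    list(name = name, width = w, counts = counts, log_odds = log_odds,
         pseudocount = pseudocount, info_content = ic,
         threshold = if (is.null(threshold)) ic else threshold),
    class = "pwm"
  )
}

info_content_from_freqs <- function(freqs) {
  plogp <- ifelse(freqs > 0, freqs * log2(freqs), 0)
  sum(2 + colSums(plogp))
}

#' Build a PWM from an IUPAC consensus
#'
#' Degenerate letters expand to equal frequencies over their allowed bases;
#' used for motifs published only as a consensus (e.g. the AT-rich UP
#' element, `NNAAAWWTWTTTTNNWAAASYM`).
#'
#' @param consensus a single IUPAC string.
#' @param name motif class label.
#' @param threshold hit threshold in bits (default: information content).
#' @return a `pwm` object (with `counts = NULL`).
#' @export
pwm_from_consensus <- function(consensus, name = "motif", threshold = NULL) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- which(!letters %in% names(IUPAC))
  if (length(bad)) stop("invalid IUPAC letter at position ", bad[1])
  freqs <- vapply(letters, function(l) {
    f <- numeric(4); names(f) <- BASES
    f[IUPAC[[l]]] <- 1 / length(IUPAC[[l]])
    f
  }, numeric(4))
  ic <- info_content_from_freqs(freqs)
  structure(
    list(name = name, width = length(letters), counts = NULL,
         log_odds = log2(freqs / 0.25), pseudocount = 0,
         info_content = ic,
         threshold = if (is.null(threshold)) ic else threshold),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, information content %.3f bits, threshold %.3f bits\n",
              x$name, x$width, x$info_content, x$threshold))
  if (!is.null(x$counts))
    cat(sprintf("built from %d instances (pseudocount %g)\n",
                sum(x$counts[, 1]), x$pseudocount))
  invisible(x)
}

#' Score a single window against a PWM
#'
#' @param pwm a `pwm` object.
#' @param window DNA string of length `pwm$width`.
#' @return score in bits (may be `-Inf` with pseudocount 0).
#' @export
score_window <- function(pwm, window) {
  x <- seq_to_int(window)
  if (length(x) != pwm$width)
    stop("window length ", length(x), " != PWM width ", pwm$width)
  sum(pwm$log_odds[cbind(x, seq_along(x))])
}

## all window scores along the rows of an integer matrix (n x L)
## returns n x (L - w + 1) matrix of scores in bits
score_matrix <- function(pwm, mat) {
  w <- pwm$width
  L <- ncol(mat)
  K <- L - w + 1
  if (K < 1) stop("sequence shorter than PWM width")
  s <- matrix(0, nrow(mat), K)
  for (j in seq_len(w)) {
    s <- s + matrix(pwm$log_odds[cbind(as.vector(mat[, j:(j + K - 1)]),
                                       j)],
                    nrow(mat), K)
  }
  s
}

#' Scan one strand of a sequence for motif hits
#'
#' Slides the PWM across every start position of the given sequence and
#' reports windows scoring at or above the threshold. The caller scans the
#' reverse complement separately for the bottom-strand channel; starts are
#' 0-based on the analyzed strand, intervals half-open
#' `[start, start + width)`.
#'
#' @param pwm a `pwm` object.
#' @param seq DNA string (length >= PWM width).
#' @param threshold hit threshold in bits (default `pwm$threshold`); use
#'   `-Inf` to return every window.
#' @param strand label recorded in the output (`"top"` or `"bottom"`).
#' @param parent_id identifier recorded in the output.
#' @return data.frame with columns `parent_id`, `strand`, `start`, `end`,
#'   `width`, `score`, `motif_class`, sorted by `start`.
#' @export
scan_sequence <- function(pwm, seq, threshold = pwm$threshold,
                          strand = "top", parent_id = NA_character_) {
  x <- seq_to_int(seq)
  scores <- as.vector(score_matrix(pwm, matrix(x, nrow = 1)))
  keep <- which(scores >= threshold)
  data.frame(
    parent_id = rep(parent_id, length(keep)),
    strand = rep(strand, length(keep)),
    start = keep - 1L, end = keep - 1L + pwm$width,
    width = rep(pwm$width, length(keep)),
    score = scores[keep],
    motif_class = rep(pwm$name, length(keep)),
    stringsAsFactors = FALSE
  )
}

#' Flag extended -10 boxes (TGn motif)
#'
#' A -10 hexamer is "extended" when a TG dinucleotide sits immediately
#' upstream separated by a single spacer base (consensus `TGnTATAAT`).
#'
#' @param seq the sequence the hit was called on (analyzed strand).
#' @param start 0-based start of the -10 hexamer.
#' @return `TRUE` iff `start >= 3` and positions `start-3, start-2` are "TG".
#' @export
annotate_tgn <- function(seq, start) {
  if (start < 3) return(FALSE)
  substr(seq, start - 2, start - 1) == "TG"  # 1-based substring of 0-based start-3,start-2
}

#' Pair -35 and -10 hits at promoter-like spacing
#'
#' Sigma70 promoters place the -10 box 15-20 bp (optimally 17 +/- 1 bp)
#' downstream of the -35 box. Returns all hit pairs whose spacer
#' `minus10$start - (minus35$start + 6)` falls within the bounds.
#'
#' @param hits35,hits10 hit data.frames from [scan_sequence()] on the same
#'   strand of the same parent.
#' @param spacer_min,spacer_max inclusive spacer bounds in bp.
#' @return data.frame with columns `start35`, `start10`, `spacer`,
#'   `score35`, `score10`.
#' @export
pair_boxes <- function(hits35, hits10, spacer_min = 15, spacer_max = 20) {
  out <- data.frame(start35 = integer(), start10 = integer(),
                    spacer = integer(), score35 = numeric(),
                    score10 = numeric())
  if (!nrow(hits35) || !nrow(hits10)) return(out)
  g <- expand.grid(i = seq_len(nrow(hits35)), j = seq_len(nrow(hits10)))
  spacer <- hits10$start[g$j] - (hits35$start[g$i] + 6L)
  keep <- spacer >= spacer_min & spacer <= spacer_max
  data.frame(start35 = hits35$start[g$i][keep],
             start10 = hits10$start[g$j][keep],
             spacer = spacer[keep],
             score35 = hits35$score[g$i][keep],
             score10 = hits10$score[g$j][keep])
}

#' Export/import a PWM as JSON
#'
#' @param pwm a `pwm` object.
#' @param file path.
#' @return `read_pwm_json` returns a `pwm` object.
#' @export
write_pwm_json <- function(pwm, file) {
  jsonlite::write_json(
    list(name = pwm$name, width = pwm$width,
         counts = if (is.null(pwm$counts)) NULL else unname(pwm$counts),
         log_odds = unname(pwm$log_odds),
         pseudocount = pwm$pseudocount,
         info_content = pwm$info_content, threshold = pwm$threshold),
    file, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(file)
}

#' @rdname write_pwm_json
#' @export
read_pwm_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  lo <- matrix(unlist(x$log_odds), nrow = 4,
               dimnames = list(BASES, NULL))
  counts <- if (is.null(x$counts)) NULL else
    matrix(unlist(x$counts), nrow = 4, dimnames = list(BASES, NULL))
  structure(
    list(name = x$name, width = x$width, counts = counts, log_odds = lo,
         pseudocount = x$pseudocount, info_content = x$info_content,
         threshold = x$threshold),
    class = "pwm"
  )
}

#' Write motif hits as BED-like TSV
#'
#' Columns: parent_id, start, end, name (motif class), score (bits),
#' strand (+/-); coordinates 0-based half-open.
#'
#' @param hits hit data.frame from [scan_sequence()].
#' @param file path.
#' @export
write_hits_bed <- function(hits, file) {
  bed <- data.frame(
    chrom = hits$parent_id, start = hits$start, end = hits$end,
    name = hits$motif_class, score = hits$score,
    strand = ifelse(hits$strand == "top", "+", "-")
  )
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Synthetic sigma70 box instance sets
#'
#' Small curated instance sets centred on the canonical -10 (`TATAAT`) and
#' -35 (`TTGACA`) consensus hexamers. These are synthetic stand-ins used
#' for examples and for the simulator's default activity model; they are
#' not the RegulonDB-derived instance collections, which must be supplied
#' as external files to reproduce published information contents.
#'
#' @return character vector of equal-length instances.
#' @export
synthetic_minus10_instances <- function() {
  c("TATAAT", "TATAAT", "TATAAT", "TATAAT", "TACAAT", "TATACT",
    "TAAAAT", "TATGAT", "CATAAT", "TATAGT", "TATTAT", "GATAAT")
}

#' @rdname synthetic_minus10_instances
#' @export
synthetic_minus35_instances <- function() {
  c("TTGACA", "TTGACA", "TTGACA", "TTGACA", "TTGACT", "TTGATA",
    "TTTACA", "TCGACA", "TTGAAA", "CTGACA", "TTGCCA", "GTGACA")
}
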