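#' @importFrom stats median pchisq quantile rbinom rmultinom rpois runif sd
#'   setNames uniroot lm coef vcov predict p.adjust wilcox.test rnorm
#' @importFrom utils combn read.csv write.csv
NULL

BASES <- c("A", "C", "G", "T")

## integer encoding A=1 C=2 G=3 T=4; anything else -> NA
seq_to_int <- function(seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
  if (anyNA(x)) {
    bad <- which(is.na(x))[1]
    stop("non-ACGT character at position ", bad, " of sequence")
  }
  x
}

## many equal-length sequences -> n x L integer matrix
seqs_to_mat <- function(seqs) {
  if (!length(seqs)) stop("no sequences")
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("sequences have unequal lengths")
  m <- match(
    unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
    BASES
  )
  if (anyNA(m)) stop("non-ACGT character in sequence set")
  matrix(m, nrow = length(seqs), ncol = L, byrow = TRUE)
}

int_to_seq <- function(x) paste(BASES[x], collapse = "")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param seq character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

## IUPAC degenerate letter -> allowed bases
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## read motif instances: FASTA (via Biostrings) or one-sequence-per-line text
#' Read aligned motif instances from a file
#'
#' Accepts FASTA (any line starting with `>`) or plain one-sequence-per-line
#' text. All instances must be equal-length DNA strings.
#'
#' @param file path to the instance file.
#' @return character vector of instance strings.
#' @export
read_motif_instances <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (any(startsWith(lines, ">"))) {
    as.character(Biostrings::readDNAStringSet(file))
  } else {
    toupper(trimws(lines))
  }
}
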