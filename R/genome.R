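# Sequence container and base-level utilities.
#
# Coordinates are 0-based throughout the package (BED-native); internal
# vectors are of course 1-based R indices, converted at the boundary.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Nucleotide sequence with coordinate conventions
#'
#' A minimal container for a named nucleotide sequence. All package
#' coordinates are 0-based; the first base of a contig is position 0.
#'
#' @param seq Character scalar over the alphabet `A/C/G/T` (a character
#'   vector of single bases is also accepted and collapsed).
#' @param id Contig label.
#' @param circular Logical; if `TRUE`, window operations may wrap around
#'   the origin.
#' @return An object of class `genome_seq`: a list with elements `id`,
#'   `seq` (character scalar) and `circular`.
#' @examples
#' g <- genome_seq("ACGTACGT", id = "toy")
#' genome_length(g)
#' @export
genome_seq <- function(seq, id = "contig", circular = FALSE) {
  if (length(seq) > 1L) seq <- paste(seq, collapse = "")
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) > 0L && grepl("[^ACGT]", seq))
    stop("genome_seq: sequence contains characters outside {A,C,G,T}")
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  n <- genome_length(x)
  gc <- if (n > 0) sprintf("%.3f", mean(base_ints(x) %in% c(2L, 3L))) else "NA"
  cat(sprintf("<genome_seq> %s: %d nt%s, GC = %s\n", x$id, n,
              if (x$circular) " (circular)" else "", gc))
  if (n > 0) {
    head_n <- min(n, 60L)
    cat(substr(x$seq, 1L, head_n), if (n > head_n) "..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Length of a genome_seq
#' @param g A [genome_seq()].
#' @return Integer number of nucleotides.
#' @export
genome_length <- function(g) nchar(g$seq)

# sequence -> integer codes 1..4 (A,C,G,T); very fast via utf8 codes
base_ints <- function(g) {
  s <- if (inherits(g, "genome_seq")) g$seq else g
  if (nchar(s) == 0L) return(integer(0))
  code <- integer(128)
  code[utf8ToInt("A") + 1L] <- 1L
  code[utf8ToInt("C") + 1L] <- 2L
  code[utf8ToInt("G") + 1L] <- 3L
  code[utf8ToInt("T") + 1L] <- 4L
  code[utf8ToInt(s) + 1L]
}

ints_to_seq <- function(b) {
  if (length(b) == 0L) return("")
  intToUtf8(utf8ToInt("ACGT")[b])
}

# logical vector: is the base strong (G or C)?
strong_mask <- function(b) b == 2L | b == 3L

#' Reverse complement of a sequence string
#' @param seq Character scalar over A/C/G/T.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return("")
  paste(rev(COMPLEMENT[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]),
        collapse = "")
}

#' Generate a random ancestral genome
#'
#' Draws an i.i.d. sequence with a target GC content:
#' P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param length Number of nucleotides (>= 0).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Optional integer seed; the result is reproducible given the
#'   same seed.
#' @param id Contig label.
#' @param circular Logical, passed to [genome_seq()].
#' @return A [genome_seq()].
#' @examples
#' generate_ancestor(50, gc = 0.6, seed = 1)
#' @export
generate_ancestor <- function(length, gc = 0.5, seed = NULL, id = "ancestor",
                              circular = FALSE) {
  if (length < 0) stop("generate_ancestor: length must be >= 0")
  if (gc < 0 || gc > 1) stop("generate_ancestor: gc must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (length == 0)
    return(genome_seq("", id = id, circular = circular))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  b <- sample.int(4L, length, replace = TRUE, prob = p)
  genome_seq(ints_to_seq(b), id = id, circular = circular)
}
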