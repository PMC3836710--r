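# Lineage-specific substitution inference by three-taxon parsimony,
# 4-fold-degenerate-site masks, CpG-context flags and global spectra.

#' Focal/sister/outgroup alignment
#'
#' Equal-length aligned sequences (gap `-` allowed). Substitution
#' coordinates are reported in focal-genome 0-based coordinates, i.e.
#' counting non-gap focal bases.
#'
#' @param focal,sister,outgroup Aligned sequence strings of equal
#'   length.
#' @param contig Contig label.
#' @return An object of class `triplet_alignment`.
#' @export
triplet_alignment <- function(focal, sister, outgroup, contig = "contig") {
  focal <- toupper(focal); sister <- toupper(sister); outgroup <- toupper(outgroup)
  if (nchar(focal) != nchar(sister) || nchar(focal) != nchar(outgroup))
    stop("triplet_alignment: sequences must have equal aligned lengths")
  structure(list(focal = focal, sister = sister, outgroup = outgroup,
                 contig = contig),
            class = "triplet_alignment")
}

# aligned string -> base codes 1..4, NA for gaps/ambiguity codes
.aln_ints <- function(s) {
  if (nchar(s) == 0L) return(integer(0))
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A") + 1L] <- 1L
  code[utf8ToInt("C") + 1L] <- 2L
  code[utf8ToInt("G") + 1L] <- 3L
  code[utf8ToInt("T") + 1L] <- 4L
  code[utf8ToInt(s) + 1L]
}

#' Call lineage-specific substitutions by parsimony
#'
#' Per gapless, unambiguous column: if focal and sister agree there is no
#' terminal-branch call; if they differ and the outgroup matches one of
#' them, the mismatching lineage carries a substitution from the outgroup
#' (ancestral) base to its own; if the outgroup matches neither, the
#' column is skipped. The ancestral context for the CpG flag is read from
#' the reconstructed ancestral states of the flanking columns.
#'
#' @param x A [triplet_alignment()] or [simulate_triplet()] result.
#' @param ... Passed to methods.
#' @return Data frame of class `substitutions` with columns `contig`,
#'   `pos` (focal 0-based), `anc`, `der`, `lineage`, `anc_5p`, `anc_3p`,
#'   `cpg`, `site_class`.
#' @examples
#' aln <- triplet_alignment("ACGA", "GCGA", "GCGA")
#' call_substitutions(aln)  # one focal-lineage G>A at position 0
#' @export
call_substitutions <- function(x, ...) UseMethod("call_substitutions")

#' @rdname call_substitutions
#' @export
call_substitutions.triplet_alignment <- function(x, ...) {
  f <- .aln_ints(x$focal)
  s <- .aln_ints(x$sister)
  o <- .aln_ints(x$outgroup)
  ncol <- length(f)
  eligible <- !is.na(f) & !is.na(s) & !is.na(o)
  # reconstructed ancestral state per column (NA where unresolvable)
  anc_state <- rep(NA_integer_, ncol)
  agree <- eligible & f == s
  anc_state[agree] <- f[agree]
  disagree <- eligible & f != s
  om <- disagree & (o == f | o == s)
  anc_state[om] <- o[om]
  focal_cols <- which(disagree & o == s)
  sister_cols <- which(disagree & o == f)
  cols <- c(focal_cols, sister_cols)
  lineage <- rep(c("focal", "sister"), c(length(focal_cols), length(sister_cols)))
  der <- c(f[focal_cols], s[sister_cols])
  anc <- o[cols]
  # focal 0-based coordinate of each alignment column
  focal_nongap <- if (ncol > 0L) utf8ToInt(x$focal) != utf8ToInt("-") else logical(0)
  coord <- cumsum(focal_nongap) - 1L
  ord <- order(cols)
  cols <- cols[ord]; lineage <- lineage[ord]; der <- der[ord]; anc <- anc[ord]
  a5 <- ifelse(cols > 1L, anc_state[pmax(cols - 1L, 1L)], NA_integer_)
  a3 <- ifelse(cols < ncol, anc_state[pmin(cols + 1L, ncol)], NA_integer_)
  cpg <- (anc == 2L & !is.na(a3) & a3 == 3L) |
         (anc == 3L & !is.na(a5) & a5 == 2L)
  out <- data.frame(contig = rep(x$contig, length(cols)),
                    pos = coord[cols],
                    anc = BASES[anc],
                    der = BASES[der],
                    lineage = lineage,
                    anc_5p = BASES[a5],
                    anc_3p = BASES[a3],
                    cpg = cpg,
                    site_class = rep("all", length(cols)))
  class(out) <- c("substitutions", "data.frame")
  out
}

#' @rdname call_substitutions
#' @export
call_substitutions.sim_triplet <- function(x, ...) {
  aln <- triplet_alignment(x$focal$seq, x$sister$seq, x$outgroup$seq,
                           contig = x$ancestor$id)
  call_substitutions(aln)
}

#' CpG-context flag for substitutions
#'
#' A substitution is in an ancestral CpG context iff the ancestral base
#' is C with ancestral 3' neighbour G, or (strand-symmetrically) G with
#' ancestral 5' neighbour C. Contig-edge sites with a missing flank are
#' treated as non-CpG.
#'
#' @param subs Data frame with columns `pos` and `anc`.
#' @param ancestral_seq The ancestral [genome_seq()] (or string).
#' @return Logical vector, one flag per substitution.
#' @export
flag_cpg <- function(subs, ancestral_seq) {
  b <- base_ints(ancestral_seq)
  n <- length(b)
  pos <- subs$pos
  anc <- match(subs$anc, BASES)
  a5 <- ifelse(pos >= 1L, b[pmax(pos, 1L)], NA_integer_)
  a3 <- ifelse(pos <= n - 2L, b[pmin(pos + 2L, n)], NA_integer_)
  (anc == 2L & !is.na(a3) & a3 == 3L) | (anc == 3L & !is.na(a5) & a5 == 2L)
}

#' Site eligibility mask
#'
#' @param mask Logical vector, one entry per contig position.
#' @param contig Contig label.
#' @param class Mask class label (`"all"` or `"fourfold"`).
#' @return Object of class `site_mask`.
#' @export
site_mask <- function(mask, contig = "contig", class = "all") {
  structure(list(contig = contig, mask = as.logical(mask), class = class),
            class = "site_mask")
}

# 2-base codon prefixes whose 4 codons all encode the same amino acid,
# derived from the standard genetic code
.fourfold_prefixes <- local({
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1, 2))
  keep <- vapply(pre, function(p) {
    aa <- gc[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1L && !any(aa == "*")
  }, logical(1))
  pre[keep]
})

#' Mask of 4-fold degenerate synonymous sites
#'
#' Marks third codon positions of 4-fold degenerate codon families
#' (Ala, Arg4, Gly, Leu4, Pro, Ser4, Thr, Val under the standard code).
#' Minus-strand CDS are evaluated on the reverse complement and mapped
#' back to genome coordinates. Transcripts whose concatenated CDS length
#' is not a multiple of three, or which contain internal stop codons, are
#' skipped with a warning.
#'
#' @param cds Data frame of CDS intervals: columns `start`, `end`
#'   (0-based half-open), optional `strand` (`"+"`/`"-"`, default
#'   `"+"`) and `transcript` (default: one transcript).
#' @param genome A [genome_seq()].
#' @return A [site_mask()] with class label `"fourfold"`.
#' @examples
#' g <- genome_seq("ATGGGATGGTAA")  # Met-Gly-Trp-stop
#' which(fourfold_mask(data.frame(start = 0, end = 12), g)$mask) - 1
#' @export
fourfold_mask <- function(cds, genome) {
  stopifnot(is.data.frame(cds), all(c("start", "end") %in% names(cds)))
  n <- genome_length(genome)
  if (any(cds$start < 0 | cds$end > n | cds$end <= cds$start))
    stop("fourfold_mask: CDS interval out of contig bounds")
  if (is.null(cds$strand)) cds$strand <- "+"
  if (is.null(cds$transcript)) cds$transcript <- "tx1"
  b <- base_ints(genome)
  chars <- BASES[b]
  mask <- logical(n)
  for (tx in unique(cds$transcript)) {
    ex <- cds[cds$transcript == tx, , drop = FALSE]
    strand <- ex$strand[1L]
    ex <- ex[order(ex$start), , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(ex)),
                         function(i) seq.int(ex$start[i] + 1L, ex$end[i])))
    if (strand == "-") idx <- rev(idx)
    if (length(idx) %% 3L != 0L) {
      warning("fourfold_mask: transcript '", tx,
              "' length not a multiple of 3; skipped")
      next
    }
    tx_chars <- chars[idx]
    if (strand == "-") tx_chars <- COMPLEMENT[tx_chars]
    nc <- length(idx) %/% 3L
    codons <- paste0(tx_chars[seq(1L, by = 3L, length.out = nc)],
                     tx_chars[seq(2L, by = 3L, length.out = nc)],
                     tx_chars[seq(3L, by = 3L, length.out = nc)])
    aa <- Biostrings::GENETIC_CODE[codons]
    if (nc > 1L && any(aa[-nc] == "*")) {
      warning("fourfold_mask: transcript '", tx,
              "' has an internal stop codon; skipped")
      next
    }
    four <- substr(codons, 1, 2) %in% .fourfold_prefixes
    third <- idx[seq(3L, by = 3L, length.out = nc)][four]
    mask[third] <- TRUE
  }
  site_mask(mask, contig = genome$id, class = "fourfold")
}

#' Restrict substitutions to a site mask
#'
#' @param subs A `substitutions` data frame.
#' @param mask A [site_mask()] (or `NULL` for no restriction).
#' @return The retained substitutions, `site_class` set to the mask
#'   class.
#' @export
mask_substitutions <- function(subs, mask) {
  if (is.null(mask)) return(subs)
  keep <- mask$mask[subs$pos + 1L]
  keep[is.na(keep)] <- FALSE
  out <- subs[keep, , drop = FALSE]
  out$site_class <- mask$class
  rownames(out) <- NULL
  out
}

#' Global substitution spectrum
#'
#' Counts and fractions of the 12 directed base changes and the 6
#' strand-symmetric categories (each category pooling its two directed
#' constituents).
#'
#' @param subs A `substitutions` data frame (columns `anc`, `der`).
#' @param mask Optional [site_mask()] restricting the counted
#'   substitutions.
#' @return Object of class `spectrum_table`: list with data frames
#'   `directed` and `category` (columns `change`/`category`, `count`,
#'   `fraction`), total `n` and an `empty` flag.
#' @export
global_spectrum <- function(subs, mask = NULL) {
  subs <- mask_substitutions(subs, mask)
  ch <- factor(paste0(subs$anc, ">", subs$der), levels = DIRECTED_CHANGES)
  dir_counts <- as.integer(table(ch))
  n <- sum(dir_counts)
  cat_of_change <- as.character(
    categorize_substitution(substr(DIRECTED_CHANGES, 1, 1),
                            substr(DIRECTED_CHANGES, 3, 3)))
  cat_counts <- vapply(CATEGORY_LEVELS,
                       function(cl) sum(dir_counts[cat_of_change == cl]),
                       integer(1))
  frac <- function(x) if (n > 0) x / n else rep(NA_real_, length(x))
  structure(list(
    directed = data.frame(change = DIRECTED_CHANGES, count = dir_counts,
                          fraction = frac(dir_counts)),
    category = data.frame(category = CATEGORY_LEVELS,
                          count = as.integer(cat_counts),
                          fraction = frac(as.integer(cat_counts))),
    n = n, empty = n == 0L), class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("<spectrum_table> %d substitutions%s\n", x$n,
              if (x$empty) " (empty: fractions undefined)" else ""))
  print(x$category, row.names = FALSE)
  invisible(x)
}
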