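# File I/O: FASTA via Biostrings, BED dyads, TSV tables with a
# provenance header, and the plain key-value run configuration.
#
# All coordinates are 0-based; BED intervals are half-open; every TSV
# written here carries '#'-prefixed provenance lines naming the package
# version, the seed and the conventions in force.

#' Read a (multi-)FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercased sequences, in file
#'   order. Gap characters (`-`) are preserved; characters outside the
#'   IUPAC set are rejected.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("read_fasta: malformed FASTA in ",
                                          path, ": ", conditionMessage(e)))
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector, a [genome_seq()], or a list of
#'   them.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genome_seq")) seqs <- list(seqs)
  if (is.list(seqs))
    seqs <- stats::setNames(vapply(seqs, function(g) g$seq, character(1)),
                            vapply(seqs, function(g) g$id, character(1)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read dyad calls from BED
#'
#' BED is 0-based, half-open. One-nt intervals give `pos = start`
#' directly; wider intervals (whole footprints) are collapsed to their
#' midpoint `floor((start + end - 1) / 2)` with a warning. Output is
#' sorted per contig.
#'
#' @param path BED file (3+ columns; column 5 is taken as the score when
#'   present).
#' @return A [dyad_calls()] table.
#' @export
read_bed_dyads <- function(path) {
  if (!file.exists(path)) stop("read_bed_dyads: no such file: ", path)
  bed <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           col.names = paste0("V", 1:12), fill = TRUE,
                           stringsAsFactors = FALSE)
  bed <- bed[!is.na(bed$V2), , drop = FALSE]
  start <- as.integer(bed$V2); end <- as.integer(bed$V3)
  if (any(end <= start))
    stop("read_bed_dyads: BED interval with end <= start")
  wide <- end - start > 1L
  if (any(wide))
    warning("read_bed_dyads: ", sum(wide),
            " interval(s) wider than 1 nt collapsed to their midpoint")
  pos <- ifelse(wide, (start + end - 1L) %/% 2L, start)
  score <- suppressWarnings(as.numeric(bed$V5))
  dyad_calls(pos, contig = as.character(bed$V1), score = score)
}

#' Write dyad calls as 6-column BED
#'
#' Dyads are written as 1-nt half-open intervals.
#'
#' @param dyads A [dyad_calls()] table.
#' @param path Output file.
#' @param provenance Optional provenance lines (see
#'   [provenance_header()]).
#' @return `path`, invisibly.
#' @export
write_bed_dyads <- function(dyads, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  sc <- ifelse(is.na(dyads$score), 0, dyads$score)
  writeLines(sprintf("%s\t%d\t%d\tdyad\t%g\t.", dyads$contig, dyads$pos,
                     dyads$pos + 1L, sc), con)
  invisible(path)
}

#' Provenance header lines for output files
#'
#' A reproducibility block written atop every TSV/BED output: package
#' version, seed, a short hash of the configuration, and the coordinate
#' conventions.
#'
#' @param seed Integer seed in force (or `NA`).
#' @param config Named list of the parameters that produced the output.
#' @return Character vector of `#`-prefixed lines.
#' @export
provenance_header <- function(seed = NA, config = list()) {
  cfg <- paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = "; ")
  c(sprintf("# dyadsub %s", as.character(utils::packageVersion("dyadsub"))),
    sprintf("# seed=%s config_hash=%s", seed, .fnv1a(cfg)),
    if (nzchar(cfg)) paste0("# config: ", cfg),
    "# coordinates: 0-based; BED half-open; distances unsigned nt unless stated")
}

# short rolling polynomial hash (mod 2^31 - 1) of a config string
.fnv1a <- function(s) {
  h <- 0
  if (nzchar(s)) for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a data frame as TSV with provenance header
#'
#' @param x Data frame.
#' @param path Output file.
#' @param provenance Header lines from [provenance_header()].
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return Data frame (provenance comment lines skipped).
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a plain key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values are coerced to numeric or logical where possible.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) stop("read_config: cannot parse line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (toupper(val) %in% c("TRUE", "FALSE"))
                    as.logical(toupper(val))
                  else val
  }
  out
}

#' Write a simulated triplet dataset to a directory
#'
#' Writes the gapless alignment (`alignment.fasta`, records named
#' ancestor/focal/sister/outgroup), the three dyad sets as BED, and the
#' planted substitutions as TSV.
#'
#' @param ds A [simulate_triplet()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_triplet <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_triplet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_header(ds$seed, list(
    label = ds$spec$label, genome_length = ds$spec$genome_length,
    gc = ds$spec$gc, footprint = ds$spec$footprint,
    min_linker = ds$spec$min_linker))
  write_fasta(list(ds$ancestor, ds$focal, ds$sister, ds$outgroup),
              file.path(dir, "alignment.fasta"))
  write_bed_dyads(ds$ancestral_dyads, file.path(dir, "dyads_ancestral.bed"), prov)
  write_bed_dyads(ds$focal_dyads, file.path(dir, "dyads_focal.bed"), prov)
  write_bed_dyads(ds$sister_dyads, file.path(dir, "dyads_sister.bed"), prov)
  write_tsv(ds$subs, file.path(dir, "planted_substitutions.tsv"), prov)
  invisible(dir)
}

#' Read CDS intervals from GFF3 or BED
#'
#' GFF3 files (via rtracklayer) contribute their `CDS` features with
#' 0-based half-open coordinates; plain BED (3-6 columns) is read
#' directly. The returned frame feeds [fourfold_mask()].
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @return Data frame with columns `start`, `end`, `strand`,
#'   `transcript`.
#' @export
read_cds_intervals <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("read_cds_intervals: reading GFF3 requires the rtracklayer package")
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[gr$type == "CDS", , drop = FALSE]
    parent <- if (!is.null(gr$Parent))
      vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1]
                                    else "tx1", character(1))
    else if (!is.null(gr$ID)) as.character(gr$ID) else rep("tx1", nrow(gr))
    data.frame(start = gr$start - 1L, end = gr$end,
               strand = as.character(gr$strand), transcript = parent)
  } else {
    bed <- utils::read.table(path, header = FALSE, sep = "",
                             comment.char = "#", fill = TRUE,
                             stringsAsFactors = FALSE)
    data.frame(start = as.integer(bed$V2), end = as.integer(bed$V3),
               strand = if (ncol(bed) >= 6) as.character(bed$V6) else "+",
               transcript = if (ncol(bed) >= 4) as.character(bed$V4) else "tx1")
  }
}
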