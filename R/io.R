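# Centralised readers/writers: depth TSV (samtools-depth dialect, 1-based),
# BED (0-based half-open), FASTA and JSON truth/report files. All
# coordinate conversion happens here to prevent off-by-one drift.

#' Write a depth profile as samtools-depth style TSV
#'
#' Columns: contig, 1-based position, depth. A `#` header line records the
#' generating seed when known.
#'
#' @param depth Named list of per-base depth vectors.
#' @param path Output file.
#' @param seed Optional seed to record in the header.
#' @export
write_depth_tsv <- function(depth, path, seed = NULL) {
  if (!is.null(seed))
    writeLines(paste0("#seed=", seed), path)
  for (ct in names(depth))
    data.table::fwrite(
      data.table::data.table(contig = ct, pos = seq_along(depth[[ct]]),
                             depth = depth[[ct]]),
      path, sep = "\t", col.names = FALSE, append = TRUE)
}

#' Read a samtools-depth style TSV into a depth profile
#'
#' @param path Input file (contig, 1-based position, depth; `#` comments
#'   ignored). Positions must be contiguous from 1 per contig.
#' @return Named list of integer depth vectors.
#' @export
read_depth_tsv <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "pos", "depth"))
  out <- lapply(split(dt, by = "contig", sorted = FALSE), function(d) {
    if (!identical(as.integer(d$pos), seq_len(nrow(d))))
      stop("positions not contiguous from 1 for contig ", d$contig[1])
    as.integer(d$depth)
  })
  out
}

#' Write candidate elements as BED (0-based half-open)
#'
#' @param elements `data.frame` with `contig`, `start`, `end` plus any
#'   annotation columns (written as extra BED columns).
#' @param path Output file.
#' @export
write_elements_bed <- function(elements, path) {
  cols <- c("contig", "start", "end",
            setdiff(names(elements), c("contig", "start", "end")))
  data.table::fwrite(elements[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
}

#' Read a BED file of elements
#'
#' @param path Input BED (0-based half-open).
#' @param extra_cols Names for columns beyond contig/start/end.
#' @return `data.frame` with `contig`, `start`, `end` and any extra columns.
#' @export
read_elements_bed <- function(path, extra_cols = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("contig", "start", "end", extra_cols)
  data.table::setnames(dt, seq_along(nm), nm)
  as.data.frame(dt)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
}

#' Read sequences from FASTA as a named character vector
#' @param path Input FASTA.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
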