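#' Genome assemblies
#'
#' A `genome_assembly` is the registry every scanner works from: a named set
#' of contig sequences (uppercase, alphabet A/C/G/T/N) with cached lengths,
#' GC fractions, and an optional designation of centromere contigs.
#'
#' @param seqs named character vector of DNA sequences (unique names).
#' @param centromere_ids character vector, subset of `names(seqs)`.
#' @return an object of class `genome_assembly` with elements `seqs`,
#'   `lengths`, `gc`, `all_n` (per-contig flag for gap-only sequences) and
#'   `centromere_ids`.
#' @export
genome_assembly <- function(seqs, centromere_ids = character()) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop_nonb("all contigs must be named")
  if (anyDuplicated(names(seqs)))
    stop_nonb("duplicate contig id: ",
              names(seqs)[anyDuplicated(names(seqs))])
  seqs <- toupper(seqs)
  for (id in names(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[id]])
    if (bad > 0L)
      stop_nonb(sprintf(
        "illegal character '%s' in contig '%s' at offset %d",
        substr(seqs[[id]], bad, bad), id, bad - 1L))
  }
  if (!all(centromere_ids %in% names(seqs)))
    stop_nonb("centromere ids not present in assembly: ",
              paste(setdiff(centromere_ids, names(seqs)), collapse = ", "))
  non_n <- nchar(seqs) - vapply(seqs, function(s)
    sum(utf8ToInt(s) == utf8ToInt("N")), 0L)
  structure(list(
    seqs = seqs,
    lengths = unname(nchar(seqs)),
    gc = unname(vapply(seqs, gc_fraction, 0)),
    all_n = unname(non_n == 0L),
    centromere_ids = as.character(centromere_ids)
  ), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d contigs, %s bp total\n",
              length(x$seqs), format(sum(as.numeric(x$lengths)),
                                     big.mark = ",")))
  if (length(x$centromere_ids))
    cat("  centromeres:", paste(x$centromere_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.genome_assembly <- function(x) length(x$seqs)

contig_ids <- function(assembly) names(assembly$seqs)

contig_seq <- function(assembly, id) {
  if (!id %in% names(assembly$seqs))
    stop_nonb("unknown contig id: ", id)
  assembly$seqs[[id]]
}

contig_length <- function(assembly, id) {
  if (!id %in% names(assembly$seqs)) stop_nonb("unknown contig id: ", id)
  assembly$lengths[[match(id, names(assembly$seqs))]]
}

#' Read a FASTA assembly
#'
#' Sequences are uppercased (soft-masking is ignored by default); characters
#' outside A/C/G/T/N are rejected with the contig name and 0-based offset.
#'
#' @param path FASTA file (plain or gzip).
#' @param centromere_ids contig ids to mark as centromeres.
#' @param drop_soft_masked replace lowercase (soft-masked) stretches with N
#'   instead of uppercasing them.
#' @return a [genome_assembly()].
#' @export
read_fasta <- function(path, centromere_ids = character(),
                       drop_soft_masked = FALSE) {
  if (!file.exists(path)) stop_nonb("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop_nonb("duplicate FASTA id: ", ids[anyDuplicated(ids)])
  seqs <- as.character(set)
  if (drop_soft_masked) seqs <- gsub("[acgtn]", "N", seqs)
  names(seqs) <- ids
  genome_assembly(seqs, centromere_ids = centromere_ids)
}

#' Write an assembly back to FASTA
#'
#' @param assembly a [genome_assembly()].
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  set <- Biostrings::DNAStringSet(assembly$seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' GC fraction of a DNA string
#'
#' (#G + #C) / (#non-N bases); defined as 0 for an all-N sequence.
#'
#' @param seq single non-empty DNA string.
#' @return fraction in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop_nonb("empty sequence")
  code <- utf8ToInt(toupper(seq))
  gc <- sum(code == 71L | code == 67L)          # G, C
  denom <- sum(code != 78L)                     # non-N
  if (denom == 0L) return(0)
  gc / denom
}

#' Write intervals as BED6(+1)
#'
#' Standard 0-based half-open BED; the score column is the raw score scaled
#' to an integer 0-1000 (against `score_max`), with the raw value repeated
#' in column 7 when a raw score is present.
#'
#' @param hits data frame with columns `contig`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path output file.
#' @param assembly optional [genome_assembly()]; when given, contig ids and
#'   bounds are validated against it.
#' @param score_max value mapping to 1000 (default 3, the asterisk maximum).
#' @export
write_bed <- function(hits, path, assembly = NULL, score_max = 3) {
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(c("contig", "start", "end") %in% names(hits)))
  if (!is.null(assembly)) {
    bad <- setdiff(unique(hits$contig), contig_ids(assembly))
    if (length(bad)) stop_nonb("unknown contig id: ", bad[[1L]])
    len <- assembly$lengths[match(hits$contig, contig_ids(assembly))]
    if (any(hits$start < 0L | hits$end > len | hits$start >= hits$end))
      stop_nonb("interval out of contig bounds")
  }
  name <- hits$name %||% rep(".", nrow(hits))
  strand <- hits$strand %||% rep(".", nrow(hits))
  raw <- hits$score
  if (is.null(raw)) {
    out <- data.frame(hits$contig, hits$start, hits$end, name,
                      0L, strand)
  } else {
    scaled <- as.integer(pmax(0, pmin(1000, round(1000 * raw / score_max))))
    out <- data.frame(hits$contig, hits$start, hits$end, name,
                      scaled, strand, raw)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a data frame
#'
#' Accepts 3-12 columns; returns `contig`, `start`, `end`, plus `name`,
#' `score`, `strand` when present.
#'
#' @param path BED file.
#' @return data frame (0 rows for an empty file).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_nonb("no such file: ", path)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0L) return(empty)
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (ncol(df) >= 5L) names(df)[5L] <- "score"
  if (ncol(df) >= 6L) names(df)[6L] <- "strand"
  if (ncol(df) >= 7L) names(df)[7L] <- "raw"
  df
}

#' Per-contig composition summary
#'
#' @param assembly a [genome_assembly()].
#' @return data frame with one row per contig: id, length, gc, all_n,
#'   centromere flag.
#' @export
assembly_summary <- function(assembly) {
  data.frame(
    id = contig_ids(assembly),
    length = assembly$lengths,
    gc = assembly$gc,
    all_n = assembly$all_n,
    centromere = contig_ids(assembly) %in% assembly$centromere_ids,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
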