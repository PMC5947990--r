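#' Load a genome from a FASTA file
#'
#' Reads every record, uppercases the sequence and normalises IUPAC ambiguity
#' codes (other than N) to N. The result is a light in-memory container keyed
#' by chromosome name; interval lookups are 0-based half-open.
#'
#' @param path Path to a FASTA file (multi-line records supported).
#' @return A `genome_seq` object: a named list of chromosome strings.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  # readDNAStringSet keeps the full header line; record name = first token
  nm <- sub("\\s.*$", "", names(set))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA record name: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTNRYSWKMBDHV]", seqs[[i]])
    if (bad > 0L) {
      stop("non-IUPAC character '", substr(seqs[[i]], bad, bad),
           "' in record ", nm[i], " at position ", bad)
    }
    # ambiguity codes are kept only as N: downstream guide logic treats N as
    # a poison base, and finer ambiguity carries no extra information here
    seqs[[i]] <- gsub("[RYSWKMBDHV]", "N", seqs[[i]])
    if (nchar(seqs[[i]]) == 0L) stop("empty sequence for record ", nm[i])
  }
  genome_seq(as.list(seqs))
}

#' Construct a genome container from named sequences
#'
#' @param chromosomes Named list (or named character vector) of uppercase
#'   DNA strings.
#' @return A `genome_seq` object.
#' @export
genome_seq <- function(chromosomes) {
  chromosomes <- as.list(chromosomes)
  if (is.null(names(chromosomes)) || anyNA(names(chromosomes)) ||
      any(names(chromosomes) == "")) {
    stop("every chromosome must be named")
  }
  if (anyDuplicated(names(chromosomes))) stop("duplicate chromosome names")
  if (any(vapply(chromosomes, nchar, 1L) == 0L)) stop("empty chromosome sequence")
  structure(list(chromosomes = chromosomes), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  len <- vapply(x$chromosomes, nchar, 1L)
  cat("genome_seq with", length(len), "chromosome(s),",
      format(sum(len), big.mark = ","), "bp total\n")
  for (nm in head(names(len), 10)) cat("  ", nm, ": ", len[[nm]], " bp\n", sep = "")
  if (length(len) > 10) cat("  ...\n")
  invisible(x)
}

#' Extract a genomic interval
#'
#' @param genome A `genome_seq`.
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open interval.
#' @return The interval sequence (exactly `end0 - start0` characters).
#' @export
genome_slice <- function(genome, chrom, start0, end0) {
  stopifnot(is(genome, "genome_seq"))
  seq <- genome$chromosomes[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  if (start0 < 0 || end0 > nchar(seq) || start0 > end0) {
    stop("interval [", start0, ",", end0, ") out of bounds for ", chrom,
         " (length ", nchar(seq), ")")
  }
  substr0(seq, start0, end0)
}

chrom_length <- function(genome, chrom) {
  seq <- genome$chromosomes[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  nchar(seq)
}

#' Write a genome to FASTA
#'
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unlist(genome$chromosomes))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
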