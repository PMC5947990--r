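#' Write the design table as TSV
#'
#' One row per emitted guide (failed targets keep a row carrying their
#' failure reason); mutation plans are serialised as
#' `pos:ref>alt:rationale` lists.
#'
#' @param x A `design_bundle` or `batch_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(x, path) {
  tab <- if (is(x, "batch_design")) x$table else bundle_rows(x)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

design_bundles <- function(x) {
  if (is(x, "batch_design")) x$designs else list(x)
}

#' Write ssODN donors as FASTA
#'
#' One record per design, named `transcript|tag|guide_rank`.
#'
#' @param x A `design_bundle` or `batch_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssodn_fasta <- function(x, path) {
  recs <- character()
  for (b in design_bundles(x)) {
    for (i in seq_len(nrow(b$guides))) {
      recs[paste(b$transcript_id, b$tag$name, b$guides$rank[i],
                 sep = "|")] <- b$donors[[i]]$full
    }
  }
  writeLines(unlist(lapply(names(recs), function(n)
    c(paste0(">", n), recs[[n]]))), path)
  invisible(path)
}

#' Write crRNA ordering oligos as FASTA
#'
#' @inheritParams write_ssodn_fasta
#' @export
write_crrna_fasta <- function(x, path) {
  recs <- character()
  for (b in design_bundles(x)) {
    for (i in seq_len(nrow(b$guides))) {
      recs[paste(b$transcript_id, b$tag$name, b$guides$rank[i],
                 sep = "|")] <- b$guides$crrna[i]
    }
  }
  writeLines(unlist(lapply(names(recs), function(n)
    c(paste0(">", n), recs[[n]]))), path)
  invisible(path)
}

#' Write selected guide loci as BED6
#'
#' Protospacer+PAM genomic footprints, 0-based half-open; the score column
#' is `round(ontarget * 1000)` and the strand column carries the genomic
#' strand of the guide. Designs without a genomic anchor (direct sequence
#' input) are skipped.
#'
#' @inheritParams write_ssodn_fasta
#' @export
write_guides_bed <- function(x, path) {
  lines <- character()
  for (b in design_bundles(x)) {
    region <- b$region
    if (is.na(region$chrom)) next
    for (i in seq_len(nrow(b$guides))) {
      g <- b$guides[i, ]
      fp <- pam_geometry(g)$fp
      gp <- region$gpos[(fp[1] + 1L):fp[2]]
      strand <- if (region$strand == g$strand) "+" else "-"
      lines <- c(lines, sprintf(
        "%s\t%d\t%d\t%s\t%d\t%s", region$chrom, min(gp), max(gp) + 1L,
        paste(b$transcript_id, b$tag$name, g$rank, sep = "|"),
        as.integer(round(g$ontarget * 1000)), strand))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write off-target hits as TSV
#'
#' @param hits Data frame from [find_offtargets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_offtargets_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Records the configuration, seed and package version alongside outputs
#' so a design run can be reproduced exactly.
#'
#' @param path Output path.
#' @param config A `design_config`.
#' @param seed Optional integer seed.
#' @param extra Optional named list merged into the record.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, config = design_config(), seed = NULL,
                               extra = list()) {
  meta <- c(list(package = "knocktag",
                 version = as.character(utils::packageVersion("knocktag")),
                 seed = seed,
                 config = unclass(config),
                 hydropathy_scale = "Kyte-Doolittle"),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
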