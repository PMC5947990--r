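#' Design guides and donors for one transcript
#'
#' Runs the full design chain: extract the stop-codon-centred window,
#' enumerate N20-NGG candidates, score them (on-target + off-target
#' specificity when a genome is supplied), rank by the proximity policy,
#' and assemble one ssODN donor and one 36-mer crRNA ordering oligo per
#' selected guide. Deterministic for fixed inputs and configuration.
#'
#' @param transcript_id Transcript to tag.
#' @param tag Tag name, `epitope_tag`, or in-frame coding sequence.
#' @param genome A `genome_seq`.
#' @param catalog A `transcript_catalog`.
#' @param config A `design_config`.
#' @param model Optional `ontarget_model`.
#' @param batch_mode Apply the batch cut-distance cap?
#' @param index Optional precomputed [offtarget_index()] (reused across
#'   targets in batch mode).
#' @return A `design_bundle`: ranked guide table (with crRNA oligos), one
#'   `ssodn_design` per guide, the design region, accumulated warnings and,
#'   for an empty design, a machine-readable `failure_reason`.
#' @export
design_for_target <- function(transcript_id, tag, genome, catalog,
                              config = design_config(), model = NULL,
                              batch_mode = FALSE, index = NULL) {
  tag <- get_tag(tag)
  notes <- character()
  grab <- function(expr) withCallingHandlers(expr, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  region <- tryCatch(
    grab(extract_design_region(transcript_id, catalog, genome,
                               config$window_nt)),
    error = function(e) stop("transcript ", transcript_id, ": ",
                             conditionMessage(e), call. = FALSE))
  candidates <- enumerate_guides(region)
  scored <- grab(score_guides(candidates, region, genome = genome,
                              model = model, config = config,
                              index = index))
  ranked <- grab(rank_guides(scored, config, batch_mode = batch_mode))

  failure <- NA_character_
  if (nrow(ranked) == 0L) {
    failure <- if (nrow(candidates) == 0L) {
      "no N20NGG site in the design window"
    } else if (!any(scored$in_utr3)) {
      "no guide cutting in the 3'UTR"
    } else if (batch_mode &&
               !any(scored$in_utr3 &
                    scored$cut_to_stop <= config$batch_max_distance)) {
      paste0("no guide within ", config$batch_max_distance, " bp of stop")
    } else {
      "no guide passes the specificity floor"
    }
  }

  donors <- list()
  keep <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    cand <- ranked[i, ]
    ok <- tryCatch({
      plan <- plan_pam_block(cand, region, config)
      donors[[length(donors) + 1L]] <-
        grab(assemble_ssodn(region, tag, cand, plan, config))
      TRUE
    }, error = function(e) {
      notes <<- c(notes, paste0("guide ", cand$protospacer, " dropped: ",
                                conditionMessage(e)))
      FALSE
    })
    keep[i] <- ok
  }
  ranked <- ranked[keep, , drop = FALSE]
  if (nrow(ranked) > 0L) {
    ranked$rank <- seq_len(nrow(ranked))
    ranked$crrna <- vapply(ranked$protospacer, build_crrna_oligo, "",
                           repeat_16nt = config$crrna_repeat,
                           USE.NAMES = FALSE)
  } else if (is.na(failure)) {
    failure <- "no donor could be assembled"
  }
  rownames(ranked) <- NULL

  structure(list(transcript_id = transcript_id, tag = tag,
                 guides = ranked, donors = donors, region = region,
                 tracrrna = tracrrna_constant(), config = config,
                 warnings = notes, failure_reason = failure),
            class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat("design_bundle for ", x$transcript_id, " (tag ", x$tag$name, ")\n",
      sep = "")
  if (nrow(x$guides) == 0L) {
    cat("  no design: ", x$failure_reason, "\n", sep = "")
  } else {
    for (i in seq_len(nrow(x$guides))) {
      g <- x$guides[i, ]
      cat(sprintf(
        "  #%d %s %s%s cut%+d nt from stop, on-target %.2f, specificity %s, donor %d nt\n",
        g$rank, g$protospacer, g$pam, g$strand, g$cut_to_stop, g$ontarget,
        ifelse(is.na(g$specificity), "NA", sprintf("%.1f", g$specificity)),
        nchar(x$donors[[i]]$full)))
    }
  }
  for (w in x$warnings) cat("  note: ", w, "\n", sep = "")
  invisible(x)
}

#' Batch design with 96-well plate layout
#'
#' Designs every target with the batch distance cap active and assigns
#' targets to wells A1-H12 in row-major order; targets beyond 96 spill onto
#' further plates. Control targets can be pinned to chosen wells on every
#' plate (repeated positive controls across the plate expose positional
#' artefacts in downstream screening).
#'
#' @param targets Character vector of transcript ids (duplicates are an
#'   error).
#' @param tag Tag for all targets.
#' @param genome,catalog,config,model As in [design_for_target()].
#' @param controls Optional named character vector, names = wells
#'   (e.g. `c(A1 = "SOX2", H12 = "SOX2")`), values = control transcript
#'   ids; pinned on every plate.
#' @return A `batch_design` list: `designs` (named `design_bundle` list),
#'   `table` (one row per emitted guide; failed targets appear with their
#'   failure reason), `plate_map`, and `summary`.
#' @export
batch_design <- function(targets, tag, genome, catalog,
                         config = design_config(), model = NULL,
                         controls = NULL) {
  targets <- as.character(targets)
  if (anyDuplicated(targets))
    stop("duplicate target ids: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  if (length(targets) == 0L)
    warning("empty target list; nothing to design", call. = FALSE)

  all_ids <- unique(c(targets, unname(controls)))
  index <- offtarget_index(genome)
  designs <- lapply(all_ids, function(id)
    design_for_target(id, tag, genome, catalog, config = config,
                      model = model, batch_mode = TRUE, index = index))
  names(designs) <- all_ids

  plate_map <- assign_wells(targets, controls)
  table <- do.call(rbind, lapply(targets, function(id)
    bundle_rows(designs[[id]])))
  if (is.null(table)) table <- bundle_rows(NULL)

  n_failed <- sum(vapply(designs[targets], function(b)
    nrow(b$guides) == 0L, TRUE))
  structure(list(designs = designs, table = table, plate_map = plate_map,
                 summary = list(n_targets = length(targets),
                                n_designed = length(targets) - n_failed,
                                n_failed = n_failed)),
            class = "batch_design")
}

assign_wells <- function(targets, controls = NULL) {
  wells <- plate_wells()
  if (!is.null(controls)) {
    bad <- setdiff(names(controls), wells)
    if (length(bad) > 0L) stop("unknown control wells: ",
                               paste(bad, collapse = ", "))
  }
  rows <- list()
  queue <- targets
  plate <- 0L
  while (length(queue) > 0L || plate == 0L) {
    plate <- plate + 1L
    for (w in wells) {
      if (!is.null(controls) && w %in% names(controls)) {
        rows[[length(rows) + 1L]] <- list(plate = plate, well = w,
                                          target_id = controls[[w]],
                                          is_control = TRUE)
      } else if (length(queue) > 0L) {
        rows[[length(rows) + 1L]] <- list(plate = plate, well = w,
                                          target_id = queue[1],
                                          is_control = FALSE)
        queue <- queue[-1]
      }
    }
    if (plate > 1000L) stop("plate assignment did not converge")
  }
  if (length(rows) == 0L) {
    return(data.frame(plate = integer(), well = character(),
                      target_id = character(), is_control = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}

bundle_rows <- function(bundle) {
  cols <- c("transcript_id", "tag", "rank", "protospacer", "pam", "strand",
            "cut_to_stop", "ontarget", "specificity", "mm0", "mm1", "mm2",
            "mm3", "crrna_36mer", "ssodn", "ssodn_len", "arm5", "arm3",
            "strand_emitted", "edits", "status")
  if (is.null(bundle)) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)),
                                 cols), stringsAsFactors = FALSE)
    return(df)
  }
  g <- bundle$guides
  if (nrow(g) == 0L) {
    return(data.frame(transcript_id = bundle$transcript_id,
                      tag = bundle$tag$name, rank = NA_integer_,
                      protospacer = NA, pam = NA, strand = NA,
                      cut_to_stop = NA, ontarget = NA, specificity = NA,
                      mm0 = NA, mm1 = NA, mm2 = NA, mm3 = NA,
                      crrna_36mer = NA, ssodn = NA, ssodn_len = NA,
                      arm5 = NA, arm3 = NA, strand_emitted = NA, edits = NA,
                      status = bundle$failure_reason,
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    d <- bundle$donors[[i]]
    data.frame(transcript_id = bundle$transcript_id, tag = bundle$tag$name,
               rank = g$rank[i], protospacer = g$protospacer[i],
               pam = g$pam[i], strand = g$strand[i],
               cut_to_stop = g$cut_to_stop[i], ontarget = g$ontarget[i],
               specificity = g$specificity[i], mm0 = g$mm0[i],
               mm1 = g$mm1[i], mm2 = g$mm2[i], mm3 = g$mm3[i],
               crrna_36mer = g$crrna[i], ssodn = d$full,
               ssodn_len = nchar(d$full),
               arm5 = d$arm_lengths[["arm5"]], arm3 = d$arm_lengths[["arm3"]],
               strand_emitted = d$strand_emitted,
               edits = format_edits(d), status = "ok",
               stringsAsFactors = FALSE)
  }))
}

format_edits <- function(donor) {
  if (nrow(donor$edits) == 0L) return(donor$rationale)
  paste0(donor$edits$region_offset, ":", donor$edits$ref, ">",
         donor$edits$alt, ":", donor$edits$rationale, collapse = ";")
}

#' @export
print.batch_design <- function(x, ...) {
  cat("batch_design: ", x$summary$n_targets, " target(s), ",
      x$summary$n_designed, " designed, ", x$summary$n_failed,
      " failed; ", nrow(x$table[!is.na(x$table$rank), , drop = FALSE]),
      " guide row(s) over ", max(c(1L, x$plate_map$plate)), " plate(s)\n",
      sep = "")
  invisible(x)
}

#' Predict wild-type and knock-in genotyping amplicon sizes
#'
#' Given primer positions flanking the insertion point, the knock-in
#' amplicon is the wild-type amplicon plus the tag length. A warning flags
#' wild-type amplicons outside the 400-600 bp band genotyping PCRs are
#' designed into.
#'
#' @param primer_offsets Length-2 integer vector: 0-based half-open span of
#'   the wild-type amplicon in design-region coordinates.
#' @param design A `design_bundle` (or an `epitope_tag`) supplying the
#'   insertion point and tag length.
#' @return Named vector `c(wt_len, ki_len)`.
#' @export
predict_genotyping_amplicons <- function(primer_offsets, design) {
  stopifnot(length(primer_offsets) == 2L)
  left <- primer_offsets[1]; right <- primer_offsets[2]
  if (is(design, "design_bundle")) {
    insertion <- design$region$stop_offset
    tag_len <- design$tag$length_nt
    if (!(left < insertion && right > insertion))
      stop("primers do not flank the insertion point (stop offset ",
           insertion, ")")
  } else {
    tag_len <- get_tag(design)$length_nt
    if (right <= left) stop("invalid primer offsets")
  }
  wt <- as.integer(right - left)
  if (wt < 400L || wt > 600L)
    warning("wild-type amplicon ", wt, " bp outside the 400-600 bp ",
            "genotyping design range", call. = FALSE)
  c(wt_len = wt, ki_len = wt + tag_len)
}
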