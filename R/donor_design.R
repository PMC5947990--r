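# standard published C-terminal epitope tag coding sequences
TAG_CATALOGUE <- list(
  V5     = "GGTAAGCCTATCCCTAACCCTCTCCTCGGTCTCGATTCTACG",
  `3XFLAG` = paste0("GACTACAAAGACCATGACGGTGATTATAAAGATCATGACATC",
                    "GATTACAAGGATGACGATGACAAG"),
  Myc    = "GAACAAAAACTCATCTCAGAAGAGGATCTG",
  HA     = "TACCCATACGATGTTCCAGATTACGCT"
)

#' Construct an epitope tag
#'
#' @param name Tag name.
#' @param nt In-frame coding sequence (length divisible by 3, no internal
#'   stop codon).
#' @return An `epitope_tag` with fields `name`, `aa`, `nt`, `length_nt`.
#' @export
epitope_tag <- function(name, nt) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3L != 0L)
    stop("tag coding sequence length must be divisible by 3")
  aa <- translate_dna(nt)
  if (grepl("*", aa, fixed = TRUE))
    stop("tag coding sequence contains an internal stop codon")
  structure(list(name = name, aa = aa, nt = nt, length_nt = nchar(nt)),
            class = "epitope_tag")
}

#' Look up an epitope tag
#'
#' The bundled catalogue carries the four standard short tags (V5 42 nt,
#' 3XFLAG 66 nt, Myc 30 nt, HA 27 nt). A custom tag can be supplied as an
#' `epitope_tag` object or as a raw in-frame coding sequence.
#'
#' @param name Catalogue name, `epitope_tag`, or nucleotide string.
#' @return An `epitope_tag`.
#' @export
get_tag <- function(name) {
  if (is(name, "epitope_tag")) return(name)
  if (name %in% names(TAG_CATALOGUE))
    return(epitope_tag(name, TAG_CATALOGUE[[name]]))
  if (grepl("^[ACGTacgt]+$", name) && nchar(name) %% 3L == 0L)
    return(epitope_tag("custom", name))
  stop("unknown tag '", name, "'; catalogue: ",
       paste(names(TAG_CATALOGUE), collapse = ", "),
       " (or supply an in-frame coding sequence)")
}

#' @export
print.epitope_tag <- function(x, ...) {
  cat("epitope_tag ", x$name, ": ", x$length_nt, " nt, peptide ", x$aa,
      "\n", sep = "")
  invisible(x)
}

#' Symmetric homology-arm lengths under the donor cap
#'
#' Both arms get `floor((cap - tag_len_nt) / 2)` nt (one nt of the cap goes
#' unused when the remainder is odd); the stop codon is budgeted inside the
#' 3' arm, the only convention under which a 66-nt tag leaves exactly 67-nt
#' arms within a 200-mer.
#'
#' @param tag_len_nt Tag length in nt.
#' @param cap Donor cap (default 200).
#' @param min_arm Minimum acceptable arm (default 30).
#' @return Named integer vector `c(arm5, arm3)`.
#' @export
compute_arm_lengths <- function(tag_len_nt, cap = 200L, min_arm = 30L) {
  stopifnot(cap > tag_len_nt)
  arm <- (cap - tag_len_nt) %/% 2L
  if (arm < min_arm)
    stop("insufficient homology: arms would be ", arm, " nt (< ", min_arm,
         ") for a ", tag_len_nt, " nt tag under a ", cap, "-mer cap")
  c(arm5 = arm, arm3 = arm)
}

#' Synonymous alternatives of a codon at one position
#'
#' @param codon A sense codon.
#' @param mutable_position 0, 1 or 2: the only position allowed to change.
#' @return Character vector (possibly empty, e.g. Trp/Met) of alternative
#'   codons encoding the same amino acid, sorted alphabetically.
#' @export
silent_substitutions <- function(codon, mutable_position) {
  codon <- toupper(codon)
  stopifnot(mutable_position %in% 0:2, nchar(codon) == 3L)
  if (is_stop_codon(codon)) stop("stop codons are never edited")
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa) || is.na(aa)) stop("not a valid codon: ", codon)
  alts <- vapply(setdiff(BASES, substr(codon, mutable_position + 1L,
                                       mutable_position + 1L)),
                 function(b) {
                   x <- codon
                   substr(x, mutable_position + 1L,
                          mutable_position + 1L) <- b
                   x
                 }, "")
  sort(unname(alts[Biostrings::GENETIC_CODE[alts] == aa]))
}

# region-coordinate indices of the two mutable PAM Gs (guide-strand PAM
# positions 3 then 2) and of the full protospacer+PAM footprint
pam_geometry <- function(candidate) {
  p <- candidate$region_offset
  if (candidate$strand == "+") {
    list(g_idx = c(p + 22L, p + 21L), pam_pos = c(3L, 2L),
         fp = c(p, p + 23L))
  } else {
    list(g_idx = c(p - 3L, p - 2L), pam_pos = c(3L, 2L),
         fp = c(p - 3L, p + 20L))
  }
}

# guide-strand PAM of a candidate read from a (possibly edited) region seq
guide_pam <- function(candidate, seq) {
  p <- candidate$region_offset
  if (candidate$strand == "+") substr0(seq, p + 20L, p + 23L)
  else revcomp(substr0(seq, p - 3L, p))
}

pam_is_cuttable <- function(pam) substr(pam, 2L, 3L) %in% c("GG", "AG")

#' Plan the PAM-blocking mutation of a donor
#'
#' Decides how the donor prevents Cas9 from re-cutting the edited allele.
#' If the tag insertion point falls strictly inside the protospacer/PAM
#' footprint the site is already disrupted and no edit is needed (override
#' with `always_block`). Otherwise one base is changed, in order of
#' preference: (i) PAM wholly in the 3'UTR - rewrite NGG to NGC (or NGT)
#' at the PAM-terminal G; (ii) a PAM G inside the coding sequence - the
#' alphabetically first synonymous codon change that also avoids leaving an
#' NGG/NAG at the register; (iii) no synonymous option - the single-base
#' substitution minimising the Kyte-Doolittle hydropathy change, then
#' charge-class change (D/E negative, K/R/H positive, others neutral), of
#' the altered residue; (iv) a PAM G in the 3'UTR when the other G sits on
#' the never-edited stop codon. If no edit can break the site the plan
#' fails.
#'
#' @param candidate Guide-table row.
#' @param region The `design_region`.
#' @param config `design_config` (policy NGC/NGT, `always_block`).
#' @return A `mutation_plan`: data frame of edits (region_offset, ref, alt,
#'   rationale) plus attributes.
#' @export
plan_pam_block <- function(candidate, region, config = design_config()) {
  seq <- region$sequence
  stop0 <- region$stop_offset
  geom <- pam_geometry(candidate)

  edits <- data.frame(region_offset = integer(), ref = character(),
                      alt = character(), rationale = character(),
                      stringsAsFactors = FALSE)
  # (a) insertion point strictly inside the protospacer+PAM footprint
  if (!config$always_block && geom$fp[1] < stop0 && stop0 < geom$fp[2]) {
    attr(edits, "rationale") <- "none_needed"
    class(edits) <- c("mutation_plan", class(edits))
    return(edits)
  }

  labels <- region$labels
  in_stop <- function(i) i >= stop0 && i < stop0 + 3L
  lab <- function(i) if (i < 0L || i >= nchar(seq)) "OUT" else labels[i + 1L]

  utr_edit <- function(which_g) {
    i <- geom$g_idx[which_g]
    ref <- substr0(seq, i, i + 1L)
    rationale <- paste0("PAM_NGG_to_", config$pam_block_policy)
    if (geom$pam_pos[which_g] == 3L) {
      new_base <- if (config$pam_block_policy == "NGC") "C" else "T"
    } else {
      new_base <- "C"   # PAM position 2: NGG -> NCG (avoids NAG)
    }
    # the guide strand base is new_base; store in region (plus) orientation
    alt <- if (candidate$strand == "+") new_base else revcomp(new_base)
    data.frame(region_offset = i, ref = ref, alt = alt,
               rationale = rationale, stringsAsFactors = FALSE)
  }

  apply_edit <- function(e) {
    s <- seq
    substr0(s, e$region_offset, e$region_offset + 1L) <- e$alt
    s
  }
  breaks_site <- function(e) !pam_is_cuttable(guide_pam(candidate,
                                                        apply_edit(e)))

  # (b) PAM wholly in the 3'UTR
  if (all(vapply(geom$g_idx, lab, "") == "UTR3")) {
    e <- utr_edit(1L)
    if (breaks_site(e)) return(accept_plan(e, seq))
  }

  codon_of <- function(i) {
    # CDS reading frame is anchored at the stop codon
    shift <- (stop0 - i) %% 3L
    start <- i - (3L - shift) %% 3L
    if (start < 0L || start + 3L > nchar(seq)) return(NULL)
    if (any(vapply(start:(start + 2L), lab, "") != "CDS")) return(NULL)
    list(start = start, codon = substr0(seq, start, start + 3L),
         pos = i - start)
  }

  # (c) synonymous change at a coding PAM G
  for (k in 1:2) {
    i <- geom$g_idx[k]
    if (lab(i) != "CDS" || in_stop(i)) next
    cd <- codon_of(i)
    if (is.null(cd) || is_stop_codon(cd$codon)) next
    for (alt_codon in silent_substitutions(cd$codon, cd$pos)) {
      e <- data.frame(region_offset = i, ref = substr0(seq, i, i + 1L),
                      alt = substr(alt_codon, cd$pos + 1L, cd$pos + 1L),
                      rationale = "silent_CDS", stringsAsFactors = FALSE)
      if (breaks_site(e)) return(accept_plan(e, seq))
    }
  }

  # (d) conservative missense change at a coding PAM G
  cons <- list()
  for (k in 1:2) {
    i <- geom$g_idx[k]
    if (lab(i) != "CDS" || in_stop(i)) next
    cd <- codon_of(i)
    if (is.null(cd) || is_stop_codon(cd$codon)) next
    aa0 <- Biostrings::GENETIC_CODE[[cd$codon]]
    for (b in setdiff(BASES, substr0(seq, i, i + 1L))) {
      alt_codon <- cd$codon
      substr(alt_codon, cd$pos + 1L, cd$pos + 1L) <- b
      aa1 <- Biostrings::GENETIC_CODE[[alt_codon]]
      if (aa1 == "*") next
      e <- data.frame(region_offset = i, ref = substr0(seq, i, i + 1L),
                      alt = b, rationale = "conservative_CDS",
                      stringsAsFactors = FALSE)
      if (!breaks_site(e)) next
      cons[[length(cons) + 1L]] <- list(
        e = e, dh = abs(KYTE_DOOLITTLE[[aa1]] - KYTE_DOOLITTLE[[aa0]]),
        dq = as.numeric(charge_class(aa1) != charge_class(aa0)),
        codon = alt_codon)
    }
  }
  if (length(cons) > 0L) {
    ord <- order(vapply(cons, `[[`, 1, "dh"),
                 vapply(cons, `[[`, 1, "dq"),
                 vapply(cons, `[[`, "", "codon"))
    return(accept_plan(cons[[ord[1]]]$e, seq))
  }

  # (e) a UTR3 PAM G when the other mutable G is on the stop codon
  for (k in 1:2) {
    if (lab(geom$g_idx[k]) != "UTR3") next
    e <- utr_edit(k)
    if (breaks_site(e)) return(accept_plan(e, seq))
  }

  stop("cannot block re-cutting for guide ", candidate$protospacer,
       ": no admissible PAM edit exists")
}

accept_plan <- function(edits, seq) {
  stopifnot(all(substr(seq, edits$region_offset + 1L,
                       edits$region_offset + 1L) == edits$ref))
  attr(edits, "rationale") <- edits$rationale[1]
  class(edits) <- c("mutation_plan", class(edits))
  edits
}

#' Assemble the ssODN donor
#'
#' Lays the donor out as 5' homology arm (ending at the last sense-codon
#' base), tag coding sequence, stop codon, then the remainder of the 3' arm
#' with the planned blocking edits applied (the stop codon is the first 3
#' nt of the 3'-arm budget). The oligo is emitted on the PAM strand by
#' default (reverse-complemented when the guide is on the region's minus
#' strand). Arms are truncated symmetrically, with a warning, when the
#' region is too short, and the assembly fails if they would fall below
#' `min_arm` or if the assembled donor still contains an intact
#' protospacer+NGG match for the guide.
#'
#' @param region `design_region`.
#' @param tag `epitope_tag`.
#' @param candidate Guide-table row the donor is matched to.
#' @param plan `mutation_plan` from [plan_pam_block()].
#' @param config `design_config`.
#' @return An `ssodn_design` object.
#' @export
assemble_ssodn <- function(region, tag, candidate, plan,
                           config = design_config()) {
  arms <- compute_arm_lengths(tag$length_nt, cap = config$ssodn_cap,
                              min_arm = config$min_arm)
  n <- nchar(region$sequence)
  stop0 <- region$stop_offset
  avail5 <- stop0
  avail3 <- n - stop0                      # stop codon + annotated UTR
  arm <- min(arms[["arm5"]], avail5, avail3)
  if (arm < arms[["arm5"]])
    warning("homology arms truncated to ", arm, " nt (region too short)",
            call. = FALSE)
  if (arm < config$min_arm)
    stop("region too short: homology arms would be ", arm, " nt (< ",
         config$min_arm, ")")

  span5 <- c(stop0 - arm, stop0)           # [start, end) region coords
  span3 <- c(stop0, stop0 + arm)
  arm5 <- substr0(region$sequence, span5[1], span5[2])
  arm3 <- substr0(region$sequence, span3[1], span3[2])

  applied <- plan[plan$region_offset >= span5[1] &
                    plan$region_offset < span3[2], , drop = FALSE]
  for (i in seq_len(nrow(applied))) {
    off <- applied$region_offset[i]
    if (off < span5[2]) {
      j <- off - span5[1]
      stopifnot(substr0(arm5, j, j + 1L) == applied$ref[i])
      substr0(arm5, j, j + 1L) <- applied$alt[i]
    } else {
      j <- off - span3[1]
      stopifnot(substr0(arm3, j, j + 1L) == applied$ref[i])
      substr0(arm3, j, j + 1L) <- applied$alt[i]
    }
  }

  stop_codon <- substr(arm3, 1L, 3L)
  full_plus <- paste0(arm5, tag$nt, arm3)
  if (nchar(full_plus) > config$ssodn_cap)
    stop("assembled donor exceeds the ", config$ssodn_cap, "-mer cap")

  residual <- donor_retains_site(full_plus, candidate)
  if (residual)
    stop("cannot block re-cutting: assembled donor retains an intact ",
         "protospacer+PAM match for guide ", candidate$protospacer)

  # in-frame junction check across the 5' arm / tag / stop boundary
  cds5 <- arm5
  flank <- sum(region$labels[(span5[1] + 1L):span5[2]] != "CDS")
  if (flank > 0L) cds5 <- substr(cds5, flank + 1L, nchar(cds5))
  trim <- nchar(cds5) %% 3L
  junction <- translate_dna(paste0(substr(cds5, trim + 1L, nchar(cds5)),
                                   tag$nt, stop_codon))

  pam_strand_seq <- if (candidate$strand == "+") full_plus
  else revcomp(full_plus)
  emitted <- if (config$emit_strand == "PAM") pam_strand_seq
  else revcomp(pam_strand_seq)

  structure(list(
    arm5 = arm5, tag_insert = tag$nt, stop = stop_codon,
    arm3 = substr(arm3, 4L, nchar(arm3)),
    full = emitted, full_region_orientation = full_plus,
    arm_lengths = c(arm5 = nchar(arm5), arm3 = nchar(arm3)),
    strand_emitted = config$emit_strand, tag = tag$name,
    edits = applied, rationale = attr(plan, "rationale"),
    junction_peptide = junction,
    hydropathy_scale = "Kyte-Doolittle"
  ), class = "ssodn_design")
}

# does the donor still contain an intact protospacer followed by NGG for
# this guide (on the guide's strand, anywhere - the insertion shifts the
# register, so any surviving exact site is a re-cut risk)?
donor_retains_site <- function(donor_plus, candidate) {
  pat <- if (candidate$strand == "+") {
    paste0(candidate$protospacer, "[ACGT]GG")
  } else {
    paste0("CC[ACGT]", revcomp(candidate$protospacer))
  }
  grepl(pat, donor_plus)
}

#' @export
print.ssodn_design <- function(x, ...) {
  cat("ssodn_design: ", nchar(x$full), " nt on the ",
      if (x$strand_emitted == "PAM") "PAM" else "non-PAM",
      " strand; arms ", x$arm_lengths[["arm5"]], "/",
      x$arm_lengths[["arm3"]], " nt; tag ", x$tag, " (",
      nchar(x$tag_insert), " nt)\n", sep = "")
  if (nrow(x$edits) > 0L) {
    cat("  blocking edits: ",
        paste0(x$edits$region_offset, ":", x$edits$ref, ">", x$edits$alt,
               ":", x$edits$rationale, collapse = ", "), "\n", sep = "")
  } else {
    cat("  blocking edits: none (", x$rationale, ")\n", sep = "")
  }
  cat("  junction: ...", substr(x$junction_peptide,
                                max(1L, nchar(x$junction_peptide) - 19L),
                                nchar(x$junction_peptide)), "\n", sep = "")
  invisible(x)
}
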