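test_that("the tag catalogue carries the four standard tags, validated", {
  sizes <- c(V5 = 42L, `3XFLAG` = 66L, Myc = 30L, HA = 27L)
  for (nm in names(sizes)) {
    tag <- get_tag(nm)
    expect_equal(tag$length_nt, unname(sizes[nm]))
    expect_equal(nchar(tag$nt), 3 * nchar(tag$aa))
    # independent translation check through Biostrings
    expect_equal(as.character(Biostrings::translate(
      Biostrings::DNAString(tag$nt))), tag$aa)
    expect_false(grepl("*", tag$aa, fixed = TRUE))
  }
  expect_equal(get_tag("V5")$aa, "GKPIPNPLLGLDST")
  expect_error(get_tag("SPOT"), "V5")
  expect_error(get_tag(paste0("GAT", "TAA", "GAT")), "internal stop")
  # a custom in-frame sequence becomes a tag
  expect_equal(get_tag("GATTACAAA")$length_nt, 9)
})

test_that("arm lengths reproduce the published tag-size table exactly", {
  expect_equal(compute_arm_lengths(66), c(arm5 = 67, arm3 = 67))
  expect_equal(compute_arm_lengths(42), c(arm5 = 79, arm3 = 79))
  expect_equal(compute_arm_lengths(30), c(arm5 = 85, arm3 = 85))
  expect_equal(compute_arm_lengths(27), c(arm5 = 86, arm3 = 86))
  expect_equal(27 + 2 * 86, 199)   # odd remainder leaves one nt unused
  expect_error(compute_arm_lengths(150), "insufficient homology")
})

test_that("synonymous substitutions come from the standard code", {
  expect_equal(silent_substitutions("CCG", 2), c("CCA", "CCC", "CCT"))
  expect_equal(silent_substitutions("TGG", 2), character(0))
  expect_equal(silent_substitutions("ATG", 2), character(0))
  expect_error(silent_substitutions("TAA", 0), "never edited")
  # oracle: enumerate the full codon table independently
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  aa_of <- function(cd) as.character(
    Biostrings::translate(Biostrings::DNAString(cd),
                          no.init.codon = TRUE))
  for (cd in sample(codons[vapply(codons, aa_of, "") != "*"], 15)) {
    for (pos in 0:2) {
      alts <- codons[vapply(codons, function(x)
        aa_of(x) == aa_of(cd) && x != cd &&
          sum(strsplit(x, "")[[1]] != strsplit(cd, "")[[1]]) == 1 &&
          substr(x, pos + 1, pos + 1) != substr(cd, pos + 1, pos + 1),
        TRUE)]
      expect_equal(silent_substitutions(cd, pos), sort(alts))
    }
  }
})

test_that("a UTR PAM is rewritten NGG->NGC (or NGT) at the terminal G", {
  r <- toy_region_with_guide(d = 20)
  g <- enumerate_guides(r)
  g <- g[g$cut_to_stop == 20, ]
  expect_equal(nrow(g), 1)
  plan <- plan_pam_block(g, r, design_config())
  expect_equal(nrow(plan), 1)
  expect_equal(plan$rationale, "PAM_NGG_to_NGC")
  expect_equal(plan$region_offset, g$region_offset + 22)
  expect_equal(plan$ref, "G")
  expect_equal(plan$alt, "C")
  plan_t <- plan_pam_block(g, r, design_config(pam_block_policy = "NGT"))
  expect_equal(plan_t$alt, "T")
  expect_equal(plan_t$rationale, "PAM_NGG_to_NGT")
})

test_that("tag insertion inside the target site means no edit is needed", {
  r <- toy_region_with_guide(d = 10)   # protospacer spans the stop codon
  g <- enumerate_guides(r)
  g <- g[g$cut_to_stop == 10, ]
  plan <- plan_pam_block(g, r, design_config())
  expect_equal(nrow(plan), 0)
  expect_equal(attr(plan, "rationale"), "none_needed")
  # --always-block forces an edit anyway
  plan_f <- plan_pam_block(g, r, design_config(always_block = TRUE))
  expect_gt(nrow(plan_f), 0)
})

test_that("a coding PAM G takes the first synonymous edit that kills the PAM", {
  # plus-strand guide entirely inside the CDS, PAM = last 3 nt of a CCG
  # codon frame: ...(20-nt protospacer)(A CCG...) with the terminal PAM G
  # the 3rd base of codon CCG
  proto <- "ACTATTACTATTACTATTAC"                  # no G/CC
  cds_tail <- "TAG"                                # not used: see below
  # layout: 21 codons: 7 codons protospacer (21 nt)... build explicitly:
  # CDS = filler codons + [proto padded to frame] + "CGG" PAM inside CDS
  # simplest: place proto so that PAM = "CGG" occupies one codon "CGG"?
  # codon CGG encodes Arg; silent at position 2: CGA/CGC/CGT -> CGA breaks
  # NGG and avoids NAG (PAM becomes CGA).
  filler <- strrep("ATT", 10)
  seq <- paste0(filler, proto, "CGG", strrep("ATT", 6), "TAA",
                strrep("ACT", 20))
  stop0 <- nchar(filler) + 20 + 3 + 18
  r <- design_region_from_sequence(seq, stop0)
  g <- enumerate_guides(r)
  g <- g[g$protospacer == proto & g$strand == "+", ]
  expect_equal(nrow(g), 1)
  plan <- plan_pam_block(g, r, design_config())
  expect_equal(plan$rationale, "silent_CDS")
  # terminal PAM G is the 3rd base of codon CGG (Arg): alphabetically
  # first synonymous alternative is CGA -> edit G>A at the PAM's last base
  expect_equal(plan$region_offset, g$region_offset + 22)
  expect_equal(plan$ref, "G")
  expect_equal(plan$alt, "A")
  # verify silence independently
  codon_start <- g$region_offset + 20
  before <- substr(seq, codon_start + 1, codon_start + 3)
  after <- before
  substr(after, 3, 3) <- plan$alt
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), no.init.codon = TRUE))
  expect_equal(tr(before), tr(after))
})

test_that("with no synonymous option the most conservative missense is chosen", {
  # PAM codon TGG (Trp: no synonymous single changes anywhere); candidates
  # are scored by hydropathy then charge: TGG->TCG (W->S) at the middle G
  # wins over TGC/TGT (W->C)
  proto <- "ACTATTACTATTACTATTAC"
  filler <- strrep("ATT", 10)
  seq <- paste0(filler, proto, "TGG", strrep("ATT", 6), "TAA",
                strrep("ACT", 20))
  stop0 <- nchar(filler) + 20 + 3 + 18
  r <- design_region_from_sequence(seq, stop0)
  g <- enumerate_guides(r)
  g <- g[g$protospacer == proto & g$strand == "+", ]
  plan <- plan_pam_block(g, r, design_config())
  expect_equal(plan$rationale, "conservative_CDS")
  expect_equal(plan$region_offset, g$region_offset + 21)  # middle G
  expect_equal(plan$alt, "C")                             # TGG -> TCG
})

test_that("donor assembly matches a manual string-built oracle", {
  r <- toy_region_with_guide(cds_nt = 150, utr_nt = 150, d = 20)
  g <- enumerate_guides(r)
  g <- g[g$cut_to_stop == 20, ]
  plan <- plan_pam_block(g, r, design_config())
  d <- assemble_ssodn(r, get_tag("V5"), g, plan, design_config())

  # oracle: 79-nt arms around the stop, V5 inserted before the stop, the
  # planned edit applied in the 3' arm
  seq <- r$sequence
  stop0 <- r$stop_offset
  arm5 <- substr(seq, stop0 - 79 + 1, stop0)
  arm3 <- substr(seq, stop0 + 1, stop0 + 79)
  off_in_arm3 <- plan$region_offset - stop0
  substr(arm3, off_in_arm3 + 1, off_in_arm3 + 1) <- plan$alt
  v5 <- get_tag("V5")$nt
  expect_equal(d$full, paste0(arm5, v5, arm3))
  expect_equal(nchar(d$full), 200)
  expect_equal(unname(d$arm_lengths), c(79, 79))
  # junction translation ends with the V5 peptide and a stop
  expect_match(d$junction_peptide, "GKPIPNPLLGLDST\\*$")
  # HA gives a 199-mer (27 + 2 x 86)
  plan_ha <- plan_pam_block(g, r, design_config())
  d_ha <- assemble_ssodn(r, get_tag("HA"), g, plan_ha, design_config())
  expect_equal(nchar(d_ha$full), 199)
})

test_that("minus-strand guides get the donor on their PAM strand", {
  # plant a minus-strand guide in the UTR: CCN + 20 nt, cut in the UTR
  set.seed(77)
  r0 <- toy_region_with_guide(d = 20, seed = 9)
  seq <- r0$sequence
  stop0 <- r0$stop_offset
  # minus guide with cut at stop+12: PAM CC at [cut-6, cut-4)
  cut <- stop0 + 3 + 12
  substr(seq, cut - 5, cut - 4) <- "CC"
  r <- design_region_from_sequence(seq, stop0)
  g <- enumerate_guides(r)
  gm <- g[g$strand == "-" & g$cut_to_stop == 12, ]
  expect_equal(nrow(gm), 1)
  plan <- plan_pam_block(gm, r, design_config())
  d <- assemble_ssodn(r, get_tag("V5"), gm, plan, design_config())
  # the emitted oligo is the reverse complement of the region-orientation
  # assembly
  expect_equal(d$full, rc_oracle(d$full_region_orientation))
  expect_equal(d$strand_emitted, "PAM")
  d2 <- assemble_ssodn(r, get_tag("V5"), gm, plan,
                       design_config(emit_strand = "nonPAM"))
  expect_equal(d2$full, d$full_region_orientation)
})

test_that("short regions truncate arms with a warning, or fail below min_arm", {
  r <- toy_region_with_guide(cds_nt = 60, utr_nt = 60, d = 20)
  g <- enumerate_guides(r)
  g <- g[g$cut_to_stop == 20, ]
  plan <- plan_pam_block(g, r, design_config())
  expect_warning(d <- assemble_ssodn(r, get_tag("V5"), g, plan,
                                     design_config()),
                 "truncated")
  expect_equal(unname(d$arm_lengths), c(57, 57))
  expect_lte(nchar(d$full), 200)

  r2 <- toy_region_with_guide(cds_nt = 27, utr_nt = 60, d = 20)
  g2 <- enumerate_guides(r2)
  g2 <- g2[g2$cut_to_stop == 20, ]
  plan2 <- plan_pam_block(g2, r2, design_config())
  expect_error(suppressWarnings(assemble_ssodn(r2, get_tag("V5"), g2,
                                               plan2, design_config())),
               "too short")
})

test_that("accepted donors never retain an intact target site", {
  # across seeds, tags and planted distances: donors stay under the cap,
  # arms symmetric, no intact protospacer+NGG for the guide, and all
  # donor/genome differences outside the tag are the planned edits
  tags <- c("V5", "3XFLAG", "Myc", "HA")
  n_checked <- 0
  for (seed in 1:7) {
    fx <- generate_fixtures(fixture_spec(seed = seed, n_transcripts = 4,
                                         guide_distances = c(9, 13, 18,
                                                             24)),
                            dir = tempfile())
    g <- load_genome(fx$paths$fasta)
    cat <- load_annotation(fx$paths$gtf, g)
    tag <- tags[(seed - 1) %% 4 + 1]
    for (id in names(cat)) {
      b <- design_for_target(id, tag, g, cat,
                             config = design_config(top_k = 4L))
      for (i in seq_len(nrow(b$guides))) {
        cand <- b$guides[i, ]
        donor <- b$donors[[i]]
        plus <- donor$full_region_orientation
        expect_lte(nchar(plus), 200)
        expect_equal(donor$arm_lengths[["arm5"]],
                     donor$arm_lengths[["arm3"]])
        pat <- if (cand$strand == "+") {
          paste0(cand$protospacer, "[ACGT]GG")
        } else {
          paste0("CC[ACGT]", rc_oracle(cand$protospacer))
        }
        expect_false(grepl(pat, plus))
        # reconstruct: donor minus tag must equal the reference arms
        # except at the planned edits
        ref <- paste0(
          substr(b$region$sequence,
                 b$region$stop_offset - donor$arm_lengths[["arm5"]] + 1,
                 b$region$stop_offset),
          substr(b$region$sequence, b$region$stop_offset + 1,
                 b$region$stop_offset + donor$arm_lengths[["arm3"]]))
        stripped <- paste0(substr(plus, 1, donor$arm_lengths[["arm5"]]),
                           substr(plus, donor$arm_lengths[["arm5"]] +
                                    nchar(donor$tag_insert) + 1,
                                  nchar(plus)))
        diffs <- which(strsplit(stripped, "")[[1]] !=
                         strsplit(ref, "")[[1]])
        expect_equal(length(diffs), nrow(donor$edits))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 50)
})
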