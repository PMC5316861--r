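# Guide-site discovery, off-target enumeration, silent-PAM donor design.

test_that("guide site discovery finds planted PAM-adjacent sites", {
  s <- "AAAAAAAAAAAAAAAAAAAAAAGG"
  hits <- find_guide_sites(s)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$protospacer, strrep("A", 20))
  expect_identical(hits$cut_site, 18L)

  # the reverse complement reports the same site on the minus strand
  hits_rc <- find_guide_sites(rc(s))
  expect_identical(nrow(hits_rc), 1L)
  expect_identical(hits_rc$strand, "-")
  expect_identical(hits_rc$protospacer, strrep("A", 20))

  expect_error(find_guide_sites(s, protospacer_length = 10L),
               class = "ampedit_param_error")
})

test_that("hit counts are invariant under reverse-complementing the sequence", {
  set.seed(13)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
    for (pam in c("NGG", "NNGRRT")) {
      h1 <- find_guide_sites(s, pam, if (pam == "NGG") 20L else 21L)
      h2 <- find_guide_sites(rc(s), pam, if (pam == "NGG") 20L else 21L)
      expect_identical(nrow(h1), nrow(h2))
      expect_identical(sum(h1$strand == "+"), sum(h2$strand == "-"))
    }
  }
})

test_that("NNGRRT discovery agrees with a regular-expression oracle", {
  scan_re <- function(s, pam, plen) {
    re <- paste0("(?=", pam_to_regex(pam), ")")
    starts <- gregexpr(re, s, perl = TRUE)[[1]]
    starts <- starts[starts > plen & starts + nchar(pam) - 1 <= nchar(s)]
    length(starts[starts > 0])
  }
  g <- fixture_locus$genome
  for (pam in c("NGG", "NNGRRT")) {
    plen <- if (pam == "NGG") 20L else 21L
    hits <- find_guide_sites(g, pam, plen)
    expect_identical(sum(hits$strand == "+"), scan_re(g, pam, plen))
    expect_identical(sum(hits$strand == "-"), scan_re(rc(g), pam, plen))
  }
  # every reported site has a protospacer immediately 5' of a matching PAM
  hits <- find_guide_sites(g, "NNGRRT", 21L)
  for (i in seq_len(min(nrow(hits), 25))) {
    strand_seq <- if (hits$strand[i] == "+") g else rc(g)
    st <- if (hits$strand[i] == "+") hits$start[i]
      else nchar(g) - hits$start[i] - 21L
    expect_identical(substr(strand_seq, st + 1, st + 21), hits$protospacer[i])
    expect_true(grepl(paste0("^", pam_to_regex("NNGRRT")),
                      substr(strand_seq, st + 22, st + 27)))
  }
})

test_that("the on-target site is reported with zero mismatches and no bulge", {
  g <- fixture_locus$guides
  gu <- guide(g$protospacer[g$name == "sp_ex53_5p"])
  ot <- enumerate_offtargets(gu, fixture_locus$genome)
  on <- ot[ot$mismatches == 0 & ot$bulge == "none", ]
  expect_gte(nrow(on), 1L)
  # protospacer starts 17 nt 5' of the annotated cut site
  expect_true(any(on$position == g$cut_site[g$name == "sp_ex53_5p"] - 17L))
})

test_that("planted off-target sites are recovered; beyond-threshold sites are not", {
  set.seed(55)
  proto <- fixture_locus$guides$protospacer[3]
  gu <- guide(proto)
  mutate_at <- function(x, k) {
    for (p in sample(nchar(x), k)) {
      substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(x, p, p)), 1)
    }
    x
  }
  subj <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE), collapse = "")
  site2 <- paste0(mutate_at(proto, 2L), "TGG")
  site4 <- paste0(mutate_at(proto, 4L), "AGG")
  subj <- paste0(substr(subj, 1, 3000), site2, substr(subj, 3001, 6000),
                 site4, substr(subj, 6001, 8000))
  ot <- enumerate_offtargets(gu, subj, max_mismatch = 3L)
  expect_true(any(ot$position == 3000 & ot$strand == "+" & ot$mismatches == 2))
  expect_false(any(ot$position == 6023 & ot$strand == "+"))
  # results are sorted by (mismatches, bulge size, position)
  expect_true(!is.unsorted(ot$mismatches))

  # degenerate bases in the subject are rejected with a position report
  expect_error(enumerate_offtargets(gu, "ACGTNACGT"),
               class = "ampedit_input_error")
})

test_that("bulged sites are found with the declared bulge type", {
  proto <- fixture_locus$guides$protospacer[4]
  gu <- guide(proto)
  flank <- function(n) strrep("C", n)
  # DNA bulge: one extra base inside the genomic site
  dna_site <- paste0(substr(proto, 1, 10), "T", substr(proto, 11, 20), "TGG")
  # RNA bulge: one guide base missing from the genomic site
  rna_site <- paste0(substr(proto, 1, 10), substr(proto, 12, 20), "TGG")
  subj <- paste0(flank(50), dna_site, flank(50), rna_site, flank(50))
  ot <- enumerate_offtargets(gu, subj, max_mismatch = 3L)
  expect_true(any(ot$bulge == "dna" & ot$mismatches <= 1))
  expect_true(any(ot$bulge == "rna" & ot$mismatches <= 1))
  # with bulges disabled the clean bulged sites disappear
  ot0 <- enumerate_offtargets(gu, subj, max_mismatch = 0L,
                              max_dna_bulge = 0L, max_rna_bulge = 0L)
  expect_identical(nrow(ot0), 0L)
})

test_that("off-target enumeration equals the brute-force all-windows oracle", {
  set.seed(31)
  for (rep in 1:6) {
    subj <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE), collapse = "")
    proto <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    gu <- guide(proto)
    got <- impl_offtarget_keys(enumerate_offtargets(gu, subj, max_mismatch = 3L),
                               nchar(subj))
    want <- oracle_offtargets(gu, subj, max_mm = 3L)
    expect_identical(got, want, info = sprintf("case %d", rep))
  }
})

test_that("donor design reproduces the fixture's silent G-to-A marker pair", {
  tpl <- design_hdr_template(fixture_locus)
  pam_edits <- tpl$edits[tpl$edits$purpose == "pam_kill", ]
  expect_identical(sort(pam_edits$position), sort(fixture_locus$hdr_markers$position))
  expect_true(all(pam_edits$ref == "G" & pam_edits$alt == "A"))
  expect_false(any(pam_edits$fallback))

  corr <- tpl$edits[tpl$edits$purpose == "variant_correction", ]
  expect_identical(corr$position, fixture_locus$pathogenic_variant$position)
  expect_identical(corr$alt, "C")
})

test_that("silent PAM edits leave the translation unchanged and break targeting", {
  tpl <- design_hdr_template(fixture_locus)
  cds_map <- ampedit:::locus_cds_map(fixture_locus)
  # translate the template's exon-53 portion before and after the PAM edits
  ex0 <- fixture_locus$seg_start[["exon53"]]
  exlen <- fixture_locus$seg_len[["exon53"]]
  wt_ex <- fixture_locus$segments$exon53
  ed_ex <- substr(tpl$sequence, ex0 - tpl$span[1] + 1, ex0 - tpl$span[1] + exlen)
  # undo the variant correction so only the pam_kill edits differ
  vp <- fixture_locus$pathogenic_variant$position - ex0
  ed_ex_pamonly <- ampedit:::substr_set(ed_ex, vp, "T")
  expect_identical(ampedit:::translate_dna(wt_ex),
                   ampedit:::translate_dna(ed_ex_pamonly))
  expect_false(identical(wt_ex, ed_ex_pamonly))

  # each edited PAM no longer matches NGG, so the guide loses its site
  for (nm in c("sp_ex53_5p", "sp_ex53_3p")) {
    gu <- guide(fixture_locus$guides$protospacer[fixture_locus$guides$name == nm])
    ot_wt <- enumerate_offtargets(gu, wt_ex, max_mismatch = 0L,
                                  max_dna_bulge = 0L, max_rna_bulge = 0L)
    ot_ed <- enumerate_offtargets(gu, ed_ex_pamonly, max_mismatch = 0L,
                                  max_dna_bulge = 0L, max_rna_bulge = 0L)
    expect_gte(nrow(ot_wt), 1L)
    expect_identical(nrow(ot_ed), 0L)
  }
})
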