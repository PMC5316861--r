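# Outcome classification, junction detection, search genotyping, summaries.

mk_read <- function(spec, hdr = FALSE, del_at = NULL, del_len = 0L) {
  r <- spec$sequence
  if (hdr) r <- ampedit:::apply_hdr_edits(r, spec)
  if (!is.null(del_at))
    r <- paste0(substr(r, 1, del_at), substr(r, del_at + del_len + 1, nchar(r)))
  r
}

test_that("classification follows the marker / window-indel / homology rules", {
  spec <- fixture_amps$ex53
  classify1 <- function(read, thr = 0.98) {
    classify_read(align_read(read, spec), spec, homology_threshold = thr)
  }
  # an error-free unedited read is unmodified
  expect_identical(classify1(spec$sequence)$label, "unmodified")

  # both markers + reverted variant + no indel + high identity -> hdr
  expect_identical(classify1(mk_read(spec, hdr = TRUE))$label, "hdr")

  # both markers plus a 4 nt window deletion -> mixed
  s <- spec$cut_sites[1]
  expect_identical(classify1(mk_read(spec, hdr = TRUE, del_at = s - 2, del_len = 4))$label,
                   "mixed")

  # window indel without markers -> nhej
  expect_identical(classify1(mk_read(spec, del_at = s - 2, del_len = 4))$label,
                   "nhej")

  # hdr fails the homology threshold when identity drops below it
  r <- mk_read(spec, hdr = TRUE)
  set.seed(1)
  for (p in sample(120:200, 4)) {
    b <- substr(r, p, p)
    r <- ampedit:::substr_set(r, p - 1, setdiff(c("A", "C", "G", "T"), b)[1])
  }
  res <- classify1(r, thr = 0.98)
  expect_identical(res$label, "unmodified")

  # threshold outside (0.5, 1] is a parameter error
  expect_error(classify1(spec$sequence, thr = 0.4), class = "ampedit_param_error")
})

test_that("template-span anchor rule discards donor contamination", {
  spec <- fixture_amps$ex53
  ts <- spec$template_span
  contaminant <- substr(spec$sequence, ts[1] + 1, ts[2])
  res <- classify_read(align_read(contaminant, spec), spec)
  expect_identical(res$label, "discarded")
  # a genuine genomic read covers the anchor and survives
  expect_identical(classify_read(align_read(spec$sequence, spec), spec)$label,
                   "unmodified")
})

test_that("single-marker reads are flagged partial and classified by indels", {
  spec <- fixture_amps$ex53
  m <- spec$hdr_markers
  r <- ampedit:::substr_set(spec$sequence, m$position[1], m$alt[1])
  res <- classify_read(align_read(r, spec), spec)
  expect_identical(res$label, "unmodified")
  expect_true(res$partial_hdr)
})

test_that("junction detection matches a mismatch-tolerant substring oracle", {
  set.seed(77)
  sigs <- fixture_locus$junction_signatures
  k <- 24L
  fused <- vapply(sigs, function(s) {
    paste0(substr(s$upstream, nchar(s$upstream) - 11, nchar(s$upstream)),
           substr(s$downstream, 1, 12))
  }, character(1))
  reads <- character(1000)
  for (i in seq_len(1000)) {
    r <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    u <- stats::runif(1)
    if (u < 0.4) {                      # plant a signature, sometimes mutated
      f <- fused[[sample(names(sigs), 1)]]
      if (stats::runif(1) < 0.5) {
        p <- sample(nchar(f), 1)
        substr(f, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(f, p, p)), 1)
      }
      pos <- sample(120 - k, 1)
      r <- paste0(substr(r, 1, pos), f, substr(r, pos + k + 1, 120))
      if (stats::runif(1) < 0.3) r <- rc(r)
    }
    reads[i] <- r
  }
  got <- detect_junctions(reads, fixture_locus, k = k, max_mismatch = 1L)
  for (i in seq_len(1000)) {
    hits <- names(sigs)[vapply(names(sigs), function(nm) {
      oracle_fuzzy_find(fused[[nm]], reads[i], 1L) ||
        oracle_fuzzy_find(rc(fused[[nm]]), reads[i], 1L)
    }, logical(1))]
    expected <- if (length(hits) == 0) NA_character_
      else if (length(hits) == 1) hits else "ambiguous"
    expect_identical(got[i], expected)
  }
})

test_that("junction detection classifies simulated excision and skip reads", {
  # genomic excision junction read
  jr <- ampedit:::junction_read(fixture_locus, "delta5253_genomic", 230L)
  expect_identical(detect_junction(jr, fixture_locus), "delta5253_genomic")
  # exon-skip transcript read
  sk <- ampedit:::junction_read(fixture_locus, "exon53_skip", 228L)
  expect_identical(detect_junction(sk, fixture_locus), "exon53_skip")
  # unedited reads carry no junction
  expect_true(is.na(detect_junction(fixture_amps$ex53$sequence, fixture_locus)))
  expect_error(detect_junctions("ACGT", fixture_locus, k = 10L),
               class = "ampedit_param_error")
})

test_that("search-sequence genotyping counts genotypes and edited-other", {
  spec <- fixture_amps$ex53
  tab <- default_search_table(spec)
  expect_true(all(nchar(tab) >= 20))
  s <- spec$cut_sites[1]
  reads <- c(
    hdr1 = mk_read(spec, hdr = TRUE),
    un1 = spec$sequence, un2 = spec$sequence,
    del7 = mk_read(spec, del_at = s - 3, del_len = 7),   # matches neither
    rcread = rc(spec$sequence))
  got <- genotype_by_search(reads, tab)
  expect_identical(got$count[got$genotype == "hdr"], 1L)
  expect_identical(got$count[got$genotype == "unmodified"], 3L)  # incl. rc
  expect_identical(got$count[got$genotype == "edited_other"], 1L)
  expect_equal(sum(got$fraction), 1)

  # containment in the table is a validation error
  expect_error(genotype_by_search(reads, c(a = tab[["unmodified"]],
                                           b = substr(tab[["unmodified"]], 1, 30))),
               class = "ampedit_table_error")
})

test_that("search genotyping agrees with classifier HDR calls on clean reads", {
  spec <- fixture_amps$ex53
  mix <- outcome_mix(nhej = c(0.03, 0.03), hdr = 0.05,
                     substitution_error_rate = 0)
  sim <- simulate_amplicon_reads(spec, mix, 2000, seed = 21L)
  cls <- classify_amplicon_reads(sim$reads, spec, fixture_locus)
  got <- genotype_by_search(sim$reads, default_search_table(spec))
  hdr_search <- got$count[got$genotype == "hdr"]
  hdr_class <- sum(cls$labels$label == "hdr")
  expect_identical(hdr_search, hdr_class)
})

test_that("summaries sum to one and report per-site percentages", {
  spec <- fixture_amps$ex53
  mix <- outcome_mix(nhej = c(0.012, 0.011), hdr = 0.0018, mixed = 0.0002,
                     substitution_error_rate = 0.001)
  sim <- simulate_amplicon_reads(spec, mix, 4000, seed = 31L)
  cls <- classify_amplicon_reads(sim$reads, spec, fixture_locus)
  s <- summarize_editing(cls, spec)
  frac_sum <- sum(unlist(s$pct)) / 100
  expect_equal(frac_sum, 1, tolerance = 1e-9)
  expect_true(all(unlist(s$pct) >= 0 & unlist(s$pct) <= 100))
  expect_identical(s$n_classified + s$n_discarded, s$n_total)
  expect_length(s$per_site_pct, 2L)

  # 23 edited of 1000 classified -> 2.3%
  fake <- data.frame(read_id = sprintf("r%04d", 1:1000),
                     label = c(rep("nhej", 20), rep("hdr", 2), rep("mixed", 1),
                               rep("unmodified", 977)),
                     reason = NA_character_, partial_hdr = FALSE)
  s2 <- summarize_editing(fake, spec)
  expect_equal(s2$edited_total_pct, 2.3)
  # 18 hdr of 10000 -> 0.18%
  fake3 <- data.frame(read_id = sprintf("r%05d", 1:10000),
                      label = c(rep("hdr", 18), rep("unmodified", 9982)),
                      reason = NA_character_, partial_hdr = FALSE)
  expect_equal(summarize_editing(fake3, spec)$hdr_pct_of_total, 0.18)
  # all unmodified -> every editing percentage zero
  fake2 <- data.frame(read_id = "a", label = "unmodified",
                      reason = NA_character_, partial_hdr = FALSE)
  s3 <- summarize_editing(fake2, spec)
  expect_identical(s3$edited_total_pct, 0)
  # empty classified set is an error
  fake4 <- data.frame(read_id = "a", label = "discarded", reason = "unalignable",
                      partial_hdr = FALSE)
  expect_error(summarize_editing(fake4, spec),
               class = "ampedit_denominator_error")
})

test_that("HDR share of edited is recovered near the simulated set point", {
  # emulates the strategy-2 genomic composition: ~8% of edited reads are HDR
  spec <- fixture_amps$ex53
  mix <- outcome_mix(nhej = c(0.0105, 0.0105), hdr = 0.0018, mixed = 0.0002,
                     substitution_error_rate = 0.001)
  sim <- simulate_amplicon_reads(spec, mix, 30000, seed = 51L)
  cls <- classify_amplicon_reads(sim$reads, spec, fixture_locus)
  s <- summarize_editing(cls, spec)
  n_edited <- round(s$edited_total_pct / 100 * s$n_classified)
  p <- 0.0018 / 0.023
  expect_lt(abs(s$hdr_share_of_edited_pct / 100 - p),
            3 * sqrt(p * (1 - p) / n_edited))
})
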