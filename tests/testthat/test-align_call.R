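# Quality trimming, alignment, indel calling, window/exclusion rules.

test_that("quality trimming follows the trailing-run rule", {
  # an all-Q37 read is unchanged
  r <- strrep("ACGT", 30)
  out <- trim_and_filter(c(a = r), c(a = strrep("F", 120)))
  expect_identical(unname(out$reads), r)
  expect_identical(out$stats, list(kept = 1L, trimmed = 0L, dropped = 0L))

  # 150 nt with the final 20 bases at Q2 trims to 130 nt
  r2 <- strrep("A", 150)
  q2 <- paste0(strrep("F", 130), strrep("#", 20))   # '#' = Q2
  out2 <- trim_and_filter(c(a = r2), c(a = q2))
  expect_identical(nchar(out2$reads[["a"]]), 130L)

  # an interior low-quality base is not trimmed
  q3 <- paste0(strrep("F", 60), "#", strrep("F", 89))
  out3 <- trim_and_filter(c(a = r2), c(a = q3))
  expect_identical(nchar(out3$reads[["a"]]), 150L)

  # a read trimmed below min_length is dropped and counted
  q4 <- paste0(strrep("F", 40), strrep("#", 110))
  out4 <- trim_and_filter(c(a = r2, b = r2), c(a = q4, b = strrep("F", 150)),
                          min_length = 50L)
  expect_identical(out4$stats$dropped, 1L)
  expect_identical(names(out4$reads), "b")

  # non-phred33 characters are an encoding error
  expect_error(trim_and_filter(c(a = "ACGT"), c(a = "F\x1fFF")),
               class = "ampedit_encoding_error")
})

test_that("a read identical to an amplicon substring has no variants", {
  spec <- fixture_amps$ex53
  call <- align_read(substr(spec$sequence, 11, 230), spec)
  expect_identical(nrow(call$variants), 0L)
  expect_identical(call$identity, 1)
  expect_false(any(call$window_hits))
})

test_that("a deletion spanning a cut site is called with a window hit", {
  spec <- fixture_amps$ex53
  s <- spec$cut_sites[1]
  read <- paste0(substr(spec$sequence, 1, s - 1), substr(spec$sequence, s + 2, spec$length))
  call <- align_read(read, spec)
  expect_identical(call$variants$kind, "del")
  expect_identical(call$variants$length, 2L)
  expect_true(call$window_hits[[1]])
  expect_false(call$window_hits[[2]])
  expect_identical(call$net_length_change, -2L)
})

test_that("reverse-complement reads are auto-detected and give identical calls", {
  spec <- fixture_amps$ex53
  s <- spec$cut_sites[2]
  read <- paste0(substr(spec$sequence, 1, s), "ACGT", substr(spec$sequence, s + 1, spec$length))
  fwd <- align_read(read, spec)
  rev <- align_read(rc(read), spec)
  expect_identical(rev$orientation, "-")
  expect_identical(fwd$variants[c("position", "kind", "length", "alt")],
                   rev$variants[c("position", "kind", "length", "alt")])
  expect_identical(fwd$window_hits, rev$window_hits)
})

test_that("indel left-normalization matches the exhaustive-placement oracle", {
  # random 60 nt contexts (AT-rich, to exercise homopolymer slides), interior
  # indels of length 1..5. Indels whose placement-equivalence range touches a
  # sequence boundary are skipped: under end-gap-free alignment those reads
  # are indistinguishable from shorter exact substrings, and in real use
  # they fall inside the end-exclusion zone.
  set.seed(4242)
  n_cases <- 1200L
  tested <- 0L
  for (case in seq_len(n_cases)) {
    ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                        prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    L <- sample(1:5, 1)
    if (stats::runif(1) < 0.5) {
      q <- sample(8:(52 - L), 1)
      read <- paste0(substr(ref, 1, q), substr(ref, q + L + 1, 60))
      expected <- oracle_leftmost_del(ref, read, L)
      kind <- "del"
    } else {
      q <- sample(8:52, 1)
      ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      read <- paste0(substr(ref, 1, q), ins, substr(ref, q + 1, 60))
      expected <- oracle_leftmost_ins(ref, read, L)
      kind <- "ins"
    }
    if (is.na(expected) || expected < 4L || expected + L > 56L) next
    tested <- tested + 1L
    spec <- amplicon_spec("ctx", ref, cut_sites = integer(0), end_exclusion = 0L)
    call <- align_read(read, spec)
    v <- call$variants[call$variants$kind == kind, , drop = FALSE]
    expect_identical(nrow(v), 1L, info = sprintf("case %d", case))
    expect_identical(v$position, expected, info = sprintf("case %d", case))
    expect_identical(v$length, L, info = sprintf("case %d", case))
  }
  expect_gt(tested, 1000L)
})

test_that("alignment score is invariant under joint reverse-complement", {
  spec <- fixture_amps$i51
  s <- spec$cut_sites[1]
  read <- paste0(substr(spec$sequence, 1, s - 3), substr(spec$sequence, s + 4, spec$length))
  spec_rc <- amplicon_spec("i51rc", rc(spec$sequence),
                           cut_sites = spec$length - s,
                           quant_halfwidth = spec$quant_halfwidth,
                           end_exclusion = spec$end_exclusion)
  c1 <- align_read(read, spec)
  c2 <- align_read(rc(read), spec_rc)
  expect_identical(c1$identity, c2$identity)
  expect_identical(c1$net_length_change, c2$net_length_change)
  expect_identical(unname(c1$window_hits), unname(c2$window_hits))
})

test_that("site edit fraction applies window and end-exclusion rules", {
  spec <- fixture_amps$i51
  s <- spec$cut_sites[1]
  mk_del <- function(pos, L) {
    paste0(substr(spec$sequence, 1, pos), substr(spec$sequence, pos + L + 1, spec$length))
  }
  mk_sub <- function(pos) {
    base <- substr(spec$sequence, pos + 1, pos + 1)
    ampedit:::substr_set(spec$sequence, pos, setdiff(c("A", "C", "G", "T"), base)[1])
  }
  reads <- c(
    rep(spec$sequence, 91),
    vapply(1:9, function(i) mk_del(s - 1, 2), character(1)))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  calls <- align_reads(reads, spec)
  # 100 covering reads, 9 with window indels -> 0.09
  expect_equal(site_edit_fraction(calls, spec, 1), 0.09)

  # an indel strictly outside the +/-5 window is not counted
  far <- align_reads(c(x = mk_del(s + 20, 3)), spec)
  expect_false(far$window_hits[1, 1])

  # a substitution inside the 25 nt end zone is flagged excluded
  endz <- align_reads(c(x = mk_sub(10)), spec)
  expect_true(endz$variants$excluded[1])
  expect_false(endz$window_hits[1, 1])

  # lone substitutions in the window do not count; runs >= 2 do
  lone <- align_reads(c(x = mk_sub(s)), spec)
  expect_false(lone$window_hits[1, 1])
  run2 <- ampedit:::substr_set(mk_sub(s), s + 1,
                               setdiff(c("A", "C", "G", "T"),
                                       substr(spec$sequence, s + 2, s + 2))[1])
  run2c <- align_reads(c(x = run2), spec)
  expect_true(run2c$window_hits[1, 1])

  # a zero denominator is an error
  short <- align_reads(c(x = substr(spec$sequence, 1, 60)), spec)
  expect_error(site_edit_fraction(short, spec, 1),
               class = "ampedit_denominator_error")
})

test_that("unrelated sequence is flagged unalignable and discarded downstream", {
  set.seed(8)
  garbage <- paste(sample(c("A", "C", "G", "T"), 230, replace = TRUE),
                   collapse = "")
  call <- align_read(garbage, fixture_amps$i51)
  expect_true(call$unalignable)
  res <- classify_read(call, fixture_amps$i51)
  expect_identical(res$label, "discarded")
  expect_identical(res$reason, "unalignable")
})

test_that("pair merging reconstructs the molecule and falls back cleanly", {
  spec <- fixture_amps$i51
  mol <- spec$sequence
  r1 <- substr(mol, 1, 150); r2 <- rc(substr(mol, nchar(mol) - 149, nchar(mol)))
  q <- strrep("F", 150)
  m <- merge_pairs(c(a = r1), c(a = q), c(a = r2), c(a = q))
  expect_true(m$merged[1])
  expect_identical(unname(m$reads), mol)

  # non-overlapping pairs fall back to the forward read
  m2 <- merge_pairs(c(a = substr(mol, 1, 60)), c(a = strrep("F", 60)),
                    c(a = rc(substr(mol, 170, 230))), c(a = strrep("F", 61)))
  expect_false(m2$merged[1])
  expect_identical(unname(m2$reads), substr(mol, 1, 60))
})
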