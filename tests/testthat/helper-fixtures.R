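# Shared fixtures (built once per test run) and independent oracles used by
# the property and acceptance tests. Oracles are deliberately written as
# plain exhaustive loops, independent of the package's implementation path.

fixture_locus <- build_fixture_locus(seed = 1L, intron_scale = 1000L)
fixture_amps <- derive_amplicons(fixture_locus)

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Exhaustive minimal-placement oracle for a deletion: the smallest 0-based
# start q such that removing q..q+L-1 from `ref` reproduces `read`.
oracle_leftmost_del <- function(ref, read, L) {
  n <- nchar(ref)
  for (q in 0:(n - L)) {
    cand <- paste0(substr(ref, 1, q), substr(ref, q + L + 1, n))
    if (cand == read) return(q)
  }
  NA_integer_
}

# Exhaustive minimal-placement oracle for an insertion: the smallest
# inter-base q at which inserting some L-mer into `ref` reproduces `read`.
oracle_leftmost_ins <- function(ref, read, L) {
  n <- nchar(ref)
  for (q in 0:n) {
    ins <- substr(read, q + 1, q + L)
    cand <- paste0(substr(ref, 1, q), ins, substr(ref, q + 1, n))
    if (cand == read) return(q)
  }
  NA_integer_
}

# Substring-with-<=k-mismatches oracle (plain position-by-position scan).
oracle_fuzzy_find <- function(pattern, subject, max_mm) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  np <- length(pc); ns <- length(sc)
  if (ns < np) return(FALSE)
  for (i in 1:(ns - np + 1)) {
    if (sum(sc[i:(i + np - 1)] != pc) <= max_mm) return(TRUE)
  }
  FALSE
}

iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                 D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

pam_to_regex <- function(pam) {
  paste(iupac_regex[strsplit(pam, "")[[1]]], collapse = "")
}

# Brute-force all-windows off-target oracle: for every candidate site start
# and strand, checks the PAM by regex and scores the protospacer with
# explicit bulge enumeration. Hits are keyed by the PAM they are adjacent
# to (strand + PAM start on that strand) with the best mismatch count, the
# canonical identity of a site regardless of which bulge placement is
# reported.
oracle_offtargets <- function(g, subject, max_mm = 3L) {
  n <- nchar(g$protospacer)
  gc <- strsplit(g$protospacer, "")[[1]]
  np <- nchar(g$pam_pattern)
  pam_re <- paste0("^", pam_to_regex(g$pam_pattern))
  best <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") subject else rc(subject)
    sc <- strsplit(s, "")[[1]]
    L <- length(sc)
    for (site_len in c(n - 1L, n, n + 1L)) {
      bulge <- if (site_len == n) "none" else if (site_len == n + 1L) "dna" else "rna"
      for (s0 in 0:(L - site_len - np)) {
        pam_seq <- substr(s, s0 + site_len + 1, s0 + site_len + np)
        if (!grepl(pam_re, pam_seq)) next
        site <- sc[(s0 + 1):(s0 + site_len)]
        mm <- Inf
        if (bulge == "none") {
          mm <- sum(site != gc)
        } else if (bulge == "rna") {
          for (d in 1:n) mm <- min(mm, sum(gc[-d] != site))
        } else {
          for (d in 1:(n + 1)) mm <- min(mm, sum(site[-d] != gc))
        }
        if (mm <= max_mm) {
          key <- sprintf("%s:%d", strand, s0 + site_len)   # PAM-local anchor
          if (is.null(best[[key]]) || mm < best[[key]]) best[[key]] <- mm
        }
      }
    }
  }
  sort(vapply(names(best), function(k) sprintf("%s:%d", k, best[[k]]),
              character(1), USE.NAMES = FALSE))
}

# Reduce implementation hits to the oracle's canonical key set:
# strand : PAM start on the scanned strand : mismatches.
impl_offtarget_keys <- function(df, subject_len) {
  if (!nrow(df)) return(character(0))
  site_len <- nchar(df$site)
  pam_local <- ifelse(df$strand == "+", df$position + site_len,
                      subject_len - df$position)
  key <- sprintf("%s:%d", df$strand, pam_local)
  best <- tapply(df$mismatches, key, min)
  sort(vapply(names(best), function(k) sprintf("%s:%d", k, best[[k]]),
              character(1), USE.NAMES = FALSE))
}
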