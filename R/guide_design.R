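# Guide-site discovery, brute-force off-target enumeration with single-base
# bulges, and codon-preserving silent-PAM HDR donor design.

#' Find all guide sites matching a PAM pattern
#'
#' Scans both strands for positions where the IUPAC PAM pattern matches
#' immediately 3' of a full-length protospacer. The cut site is annotated
#' 3 nt 5' of the PAM (the prototypical blunt cut).
#'
#' @param sequence DNA string (A/C/G/T only).
#' @param pam_pattern IUPAC PAM pattern (`"NGG"`, `"NNGRRT"`, ...).
#' @param protospacer_length protospacer length in nt (>= 17; 20 for
#'   SpCas9-type, 21 for SaCas9-type).
#' @return data.frame with `start` (0-based protospacer start on the forward
#'   strand), `strand`, `protospacer` (strand sequence), `pam` (observed PAM),
#'   `cut_site` (0-based inter-base position on forward coordinates).
#' @export
find_guide_sites <- function(sequence, pam_pattern = "NGG",
                             protospacer_length = 20L) {
  if (protospacer_length < 17L)
    stop_ampedit("ampedit_param_error", "protospacer_length must be >= 17")
  sequence <- toupper(sequence)
  if (!is_dna(sequence))
    stop_ampedit("ampedit_input_error", "sequence must be A/C/G/T only")
  if (!is_iupac(toupper(pam_pattern)))
    stop_ampedit("ampedit_param_error", "PAM pattern must be valid IUPAC")
  L <- nchar(sequence)
  np <- nchar(pam_pattern)

  scan_one <- function(s, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pam_pattern),
                                  Biostrings::DNAString(s), fixed = FALSE)
    ps <- BiocGenerics::start(m)            # 1-based PAM starts
    ps <- ps[ps > protospacer_length & ps + np - 1 <= nchar(s)]
    if (!length(ps)) return(NULL)
    proto <- substring(s, ps - protospacer_length, ps - 1)
    pam <- substring(s, ps, ps + np - 1)
    start_local <- ps - 1L - protospacer_length   # 0-based on this strand
    cut_local <- ps - 1L - 3L                     # inter-base, -3 from PAM
    if (strand == "+") {
      data.frame(start = start_local, strand = strand, protospacer = proto,
                 pam = pam, cut_site = cut_local, stringsAsFactors = FALSE)
    } else {
      data.frame(start = L - (start_local + protospacer_length),
                 strand = strand, protospacer = proto, pam = pam,
                 cut_site = L - cut_local, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(scan_one(sequence, "+"), scan_one(revcomp(sequence), "-"))
  if (is.null(out))
    out <- data.frame(start = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      cut_site = integer(0))
  out[order(out$start, out$strand), , drop = FALSE]
}

# Mismatches between guide chars and site chars under optional single-base
# bulges. Returns list(mm, bulge, bulge_size) for the best configuration
# (fewest mismatches; ties prefer no bulge, then the smaller bulge).
best_bulge_alignment <- function(guide_chars, window_chars, max_dna_bulge,
                                 max_rna_bulge) {
  n <- length(guide_chars)
  wl <- length(window_chars)
  best <- list(mm = Inf, bulge = "none", bulge_size = 0L)
  consider <- function(mm, bulge, size) {
    if (mm < best$mm ||
        (mm == best$mm && bulge == "none" && best$bulge != "none"))
      best <<- list(mm = mm, bulge = bulge, bulge_size = size)
  }
  # no bulge: site is the PAM-proximal n bases
  if (wl >= n) {
    site <- window_chars[(wl - n + 1):wl]
    consider(sum(site != guide_chars), "none", 0L)
  }
  # RNA bulge: one guide base unpaired, site has n-1 bases
  if (max_rna_bulge >= 1L && wl >= n - 1) {
    site <- window_chars[(wl - n + 2):wl]
    for (d in seq_len(n)) {
      g <- guide_chars[-d]
      consider(sum(g != site), "rna", 1L)
    }
  }
  # DNA bulge: one extra site base unpaired, site has n+1 bases
  if (max_dna_bulge >= 1L && wl >= n + 1) {
    site <- window_chars[(wl - n):wl]
    for (d in seq_len(n + 1)) {
      s <- site[-d]
      consider(sum(s != guide_chars), "dna", 1L)
    }
  }
  best
}

#' Enumerate off-target sites of a guide by brute force
#'
#' Exhaustively scans both strands of `subject` for PAM-adjacent sites whose
#' protospacer alignment to the guide — allowing at most one optional 1 nt
#' bulge on either the DNA or the RNA side — has at most `max_mismatch`
#' mismatches. No index or heuristic pre-filter is used.
#'
#' @param g a [guide()].
#' @param subject DNA string to scan (A/C/G/T only; degenerate bases are
#'   rejected with a position report).
#' @param max_mismatch maximum protospacer mismatches (default 3).
#' @param max_dna_bulge,max_rna_bulge maximum bulge sizes in nt (0 or 1).
#' @return data.frame sorted by (mismatches, bulge size, position) with
#'   `position` (0-based site start, forward strand), `strand`,
#'   `mismatches`, `bulge` (`none`/`dna`/`rna`), `bulge_size`,
#'   `site` (aligned site sequence on the guide strand), `pam`.
#' @export
enumerate_offtargets <- function(g, subject, max_mismatch = 3L,
                                 max_dna_bulge = 1L, max_rna_bulge = 1L) {
  stopifnot(inherits(g, "guide"))
  if (max_dna_bulge > 1L || max_rna_bulge > 1L)
    stop_ampedit("ampedit_param_error", "bulge sizes above 1 nt are not supported")
  subject <- toupper(subject)
  bad <- gregexpr("[^ACGT]", subject)[[1]]
  if (bad[1] != -1L)
    stop_ampedit("ampedit_input_error",
                 sprintf("degenerate base in subject at position(s) %s",
                         paste(bad - 1L, collapse = ", ")))
  n <- nchar(g$protospacer)
  np <- nchar(g$pam_pattern)
  guide_chars <- strsplit(g$protospacer, "")[[1]]
  L <- nchar(subject)

  scan_strand <- function(s, strand) {
    sc <- strsplit(s, "")[[1]]
    m <- Biostrings::matchPattern(Biostrings::DNAString(g$pam_pattern),
                                  Biostrings::DNAString(s), fixed = FALSE)
    ps <- BiocGenerics::start(m)
    ps <- ps[ps > n - max_rna_bulge & ps + np - 1 <= nchar(s)]
    rows <- list()
    for (p in ps) {
      w0 <- max(1L, p - n - max_dna_bulge)
      window <- sc[w0:(p - 1)]
      fit <- best_bulge_alignment(guide_chars, window, max_dna_bulge,
                                  max_rna_bulge)
      if (fit$mm <= max_mismatch) {
        site_len <- n + (fit$bulge == "dna") - (fit$bulge == "rna")
        s0 <- p - 1L - site_len          # 0-based site start on this strand
        pos <- if (strand == "+") s0 else L - (s0 + site_len)
        rows[[length(rows) + 1]] <- data.frame(
          position = pos, strand = strand, mismatches = fit$mm,
          bulge = fit$bulge, bulge_size = fit$bulge_size,
          site = paste(sc[(s0 + 1):(s0 + site_len)], collapse = ""),
          pam = paste(sc[p:(p + np - 1)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- rbind(scan_strand(subject, "+"), scan_strand(revcomp(subject), "-"))
  if (is.null(out))
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0), bulge = character(0),
                      bulge_size = integer(0), site = character(0),
                      pam = character(0)))
  out <- out[order(out$mismatches, out$bulge_size, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Silent-PAM HDR donor design

# CDS bookkeeping for the fixture locus: genomic coordinates of exonic
# bases in transcript order, and the CDS string.
locus_cds_map <- function(locus) {
  exons <- c("exon51", "exon52", "exon53", "exon54")
  gpos <- unlist(lapply(exons, function(e) {
    seq(locus$seg_start[[e]], length.out = locus$seg_len[[e]])
  }))
  list(gpos = gpos, cds = paste(vapply(exons, function(e)
    locus$segments[[e]], character(1)), collapse = ""))
}

# Is a single-base substitution at genomic position g (0-based) silent?
is_silent <- function(cds_map, g, alt) {
  i <- match(g, cds_map$gpos)           # 1-based CDS index
  if (is.na(i)) return(NA)              # non-coding
  codon_i <- (i - 1L) %/% 3L
  c0 <- codon_i * 3L + 1L
  if (c0 + 2L > nchar(cds_map$cds)) return(NA)   # partial trailing codon
  codon <- substr(cds_map$cds, c0, c0 + 2L)
  mutated <- codon
  substr(mutated, i - c0 + 1L, i - c0 + 1L) <- alt
  Biostrings::GENETIC_CODE[[codon]] == Biostrings::GENETIC_CODE[[mutated]]
}

transition_of <- function(base) c(A = "G", G = "A", C = "T", T = "C")[[base]]

#' Design a codon-preserving silent-PAM HDR donor template
#'
#' Extracts the locus span as the donor template, corrects the pathogenic
#' variant, and, for each guide whose PAM lies in coding sequence, installs
#' a single-base substitution that breaks the PAM pattern while leaving the
#' encoded amino acid unchanged (transitions preferred, matching the usual
#' G-to-A choices). When no silent PAM-breaking substitution exists, a
#' silent substitution in the PAM-proximal 8 nt seed is used instead and
#' the fallback recorded.
#'
#' @param locus an `editing_locus`.
#' @param guide_names names of locus guides whose PAMs must be disabled
#'   (default: the two exon-53 guides).
#' @param span length-2 integer (0-based half-open) locus span of the donor;
#'   must contain the guides' PAMs and the pathogenic variant.
#' @return a list of class `hdr_template` with `sequence` (edited donor),
#'   `span`, `edits` (data.frame `position`, `ref`, `alt`, `purpose`,
#'   `fallback`), and `frame_offset`.
#' @export
design_hdr_template <- function(locus, guide_names = c("sp_ex53_5p", "sp_ex53_3p"),
                                span = NULL) {
  stopifnot(inherits(locus, "editing_locus"))
  if (is.null(span)) {
    ex0 <- locus$seg_start[["exon53"]]
    span <- c(ex0 - 150L, ex0 + locus$seg_len[["exon53"]] + 150L)
  }
  span <- as.integer(span)
  gdf <- locus$guides[locus$guides$name %in% guide_names, , drop = FALSE]
  if (nrow(gdf) != length(guide_names))
    stop_ampedit("ampedit_param_error", "unknown guide name")
  cds_map <- locus_cds_map(locus)
  genome <- locus$genome
  var <- locus$pathogenic_variant
  if (var$position < span[1] || var$position >= span[2])
    stop_ampedit("ampedit_param_error", "span must contain the pathogenic variant")

  edits <- list()
  add_edit <- function(gpos, alt, purpose, fallback) {
    gpos <- as.integer(gpos)
    edits[[length(edits) + 1]] <<- data.frame(
      position = gpos, ref = substr(genome, gpos + 1, gpos + 1), alt = alt,
      purpose = purpose, fallback = fallback, stringsAsFactors = FALSE)
  }
  add_edit(var$position, var$alt, "variant_correction", FALSE)

  pat_chars_all <- strsplit(toupper(gdf$pam_pattern), "")
  for (gi in seq_len(nrow(gdf))) {
    # PAM genomic span (all fixture guides are + strand; general enough here)
    cut <- gdf$cut_site[gi]
    pam_start <- cut + 3L                 # cut is -3 from the PAM start
    np <- nchar(gdf$pam_pattern[gi])
    if (pam_start < span[1] || pam_start + np > span[2])
      stop_ampedit("ampedit_param_error", "span must contain every guide PAM")
    pat_chars <- pat_chars_all[[gi]]
    pam_chars <- strsplit(substr(genome, pam_start + 1, pam_start + np), "")[[1]]
    in_coding <- !is.na(match(pam_start, cds_map$gpos))
    if (!in_coding) next

    candidate <- NULL
    # constrained PAM positions first (mutating an N never breaks the PAM)
    for (k in seq_len(np)) {
      if (pat_chars[k] == "N") next
      g <- pam_start + k - 1L
      alts <- c(transition_of(pam_chars[k]),
                setdiff(DNA_BASES, c(pam_chars[k], transition_of(pam_chars[k]))))
      for (alt in alts) {
        trial <- pam_chars; trial[k] <- alt
        if (iupac_match_chars(pat_chars, trial)) next      # PAM still matches
        sil <- is_silent(cds_map, g, alt)
        if (isTRUE(sil)) { candidate <- list(g = g, alt = alt, fb = FALSE); break }
      }
      if (!is.null(candidate)) break
    }
    if (is.null(candidate)) {
      # fallback: silent substitution in the PAM-proximal 8 nt seed
      seed0 <- cut + 3L - 8L
      for (g in seq(cut + 2L, seed0)) {
        ref <- substr(genome, g + 1, g + 1)
        alts <- c(transition_of(ref), setdiff(DNA_BASES, c(ref, transition_of(ref))))
        for (alt in alts) {
          if (isTRUE(is_silent(cds_map, g, alt))) {
            candidate <- list(g = g, alt = alt, fb = TRUE); break
          }
        }
        if (!is.null(candidate)) break
      }
    }
    if (is.null(candidate))
      stop_ampedit("ampedit_design_failure",
                   sprintf("no silent PAM- or seed-breaking substitution for guide %s",
                           gdf$name[gi]))
    add_edit(candidate$g, candidate$alt, "pam_kill", candidate$fb)
  }

  edits <- do.call(rbind, edits)
  template <- substr(genome, span[1] + 1, span[2])
  for (i in seq_len(nrow(edits)))
    template <- substr_set(template, edits$position[i] - span[1], edits$alt[i])
  structure(list(sequence = template, span = span, edits = edits,
                 frame_offset = NA_integer_),
            class = "hdr_template")
}

#' @export
print.hdr_template <- function(x, ...) {
  cat(sprintf("hdr_template: %d nt spanning [%d, %d); %d edit(s)\n",
              nchar(x$sequence), x$span[1], x$span[2], nrow(x$edits)))
  print(x$edits)
  invisible(x)
}
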