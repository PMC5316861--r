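# Reference model: amplicon specifications, guides, and the synthetic
# dystrophin-like fixture locus used throughout the package.
#
# Coordinate conventions (used everywhere):
#   * positions are 0-based; intervals are half-open [start, end)
#   * cut sites are inter-base indices: cut site s lies between nt s-1 and nt s
#   * a nuclease cut offset of -3 means the blunt cut falls 3 nt 5' of the PAM

#' Construct an amplicon specification
#'
#' An `amplicon_spec` describes one reference amplicon: its sequence, the
#' predicted nuclease cut sites, the quantification window half-width around
#' each cut site, the end-exclusion zone in which called variants are ignored,
#' and (optionally) HDR marker substitutions, the pathogenic variant, the
#' coding intervals with their reading-frame offsets, and the span homologous
#' to the HDR donor template (used for the nested-primer anchor rule that
#' guards against template contamination).
#'
#' @param name identifier for the amplicon.
#' @param sequence uppercase DNA string (A/C/G/T only).
#' @param cut_sites integer vector of 0-based inter-base cut positions.
#' @param quant_halfwidth half-width (nt) of the quantification window around
#'   each cut site; an indel counts as an editing event only if it overlaps
#'   the window. Default 5.
#' @param end_exclusion number of nt at each amplicon end excluded from
#'   quantification. Default 25.
#' @param hdr_markers optional data.frame with columns `position` (0-based),
#'   `ref`, `alt`: the silent marker substitutions diagnostic of HDR.
#' @param pathogenic_variant optional list with `position`, `ref`, `alt`
#'   giving the pathogenic base on the amplicon (`ref`) and its corrected
#'   state (`alt`).
#' @param coding_intervals optional data.frame with columns `start`, `end`
#'   (0-based half-open) and `frame_offset` (nt from `start` to the first
#'   complete codon).
#' @param template_span optional length-2 integer vector (0-based half-open)
#'   marking the portion of the amplicon homologous to the HDR donor; the
#'   amplicon must extend beyond at least one boundary of the span.
#' @return an object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(name, sequence, cut_sites = integer(0),
                          quant_halfwidth = 5L, end_exclusion = 25L,
                          hdr_markers = NULL, pathogenic_variant = NULL,
                          coding_intervals = NULL, template_span = NULL) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (!is_dna(sequence))
    stop_ampedit("ampedit_invalid_spec", "amplicon sequence must be A/C/G/T only")
  len <- nchar(sequence)
  cut_sites <- as.integer(cut_sites)
  if (any(cut_sites < end_exclusion | cut_sites > len - end_exclusion))
    stop_ampedit("ampedit_invalid_spec",
                 "every cut site must lie within the end-exclusion bounds")
  base_at <- function(p) substr(sequence, p + 1, p + 1)
  if (!is.null(hdr_markers)) {
    hdr_markers <- as.data.frame(hdr_markers)
    stopifnot(all(c("position", "ref", "alt") %in% names(hdr_markers)))
    if (any(hdr_markers$position >= len))
      stop_ampedit("ampedit_invalid_spec", "marker position beyond amplicon end")
    ok <- vapply(seq_len(nrow(hdr_markers)),
                 function(i) base_at(hdr_markers$position[i]) == hdr_markers$ref[i],
                 logical(1))
    if (!all(ok))
      stop_ampedit("ampedit_invalid_spec",
                   "marker ref base does not match the amplicon sequence")
  }
  if (!is.null(pathogenic_variant)) {
    stopifnot(all(c("position", "ref", "alt") %in% names(pathogenic_variant)))
    if (base_at(pathogenic_variant$position) != pathogenic_variant$ref)
      stop_ampedit("ampedit_invalid_spec",
                   "pathogenic variant ref base does not match the amplicon sequence")
  }
  if (!is.null(coding_intervals)) {
    coding_intervals <- as.data.frame(coding_intervals)
    stopifnot(all(c("start", "end", "frame_offset") %in% names(coding_intervals)))
    ci <- coding_intervals[order(coding_intervals$start), , drop = FALSE]
    if (nrow(ci) > 1 && any(ci$start[-1] < ci$end[-nrow(ci)]))
      stop_ampedit("ampedit_invalid_spec", "coding intervals must be disjoint")
    if (any(ci$end > len))
      stop_ampedit("ampedit_invalid_spec", "coding interval beyond amplicon end")
    coding_intervals <- ci
  }
  if (!is.null(template_span)) {
    template_span <- as.integer(template_span)
    stopifnot(length(template_span) == 2)
    if (template_span[1] < 0 || template_span[2] > len ||
        template_span[1] >= template_span[2])
      stop_ampedit("ampedit_invalid_spec", "invalid template span")
    if (template_span[1] == 0 && template_span[2] == len)
      stop_ampedit("ampedit_invalid_spec",
                   "amplicon must extend beyond at least one template boundary (anchor rule)")
  }
  structure(list(name = name, sequence = sequence, length = len,
                 cut_sites = cut_sites,
                 quant_halfwidth = as.integer(quant_halfwidth),
                 end_exclusion = as.integer(end_exclusion),
                 hdr_markers = hdr_markers,
                 pathogenic_variant = pathogenic_variant,
                 coding_intervals = coding_intervals,
                 template_span = template_span),
            class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("amplicon_spec '%s': %d nt, %d cut site(s) [%s], window +/-%d nt, end exclusion %d nt\n",
              x$name, x$length, length(x$cut_sites),
              paste(x$cut_sites, collapse = ", "),
              x$quant_halfwidth, x$end_exclusion))
  if (!is.null(x$hdr_markers))
    cat(sprintf("  HDR markers at %s\n", paste(x$hdr_markers$position, collapse = ", ")))
  if (!is.null(x$pathogenic_variant))
    cat(sprintf("  pathogenic variant %s>%s at %d\n", x$pathogenic_variant$ref,
                x$pathogenic_variant$alt, x$pathogenic_variant$position))
  invisible(x)
}

#' Construct a guide description
#'
#' @param protospacer DNA string (20 nt for SpCas9-type, 21 nt for SaCas9-type).
#' @param pam_pattern IUPAC PAM pattern 3' of the protospacer
#'   (`"NGG"` for SpCas9, `"NNGRRT"` for SaCas9).
#' @param strand `"+"` or `"-"`.
#' @param cut_offset signed nt from the PAM-proximal protospacer end to the
#'   blunt cut (default -3).
#' @return an object of class `guide`.
#' @export
guide <- function(protospacer, pam_pattern = "NGG", strand = "+", cut_offset = -3L) {
  protospacer <- toupper(protospacer)
  pam_pattern <- toupper(pam_pattern)
  if (!is_dna(protospacer))
    stop_ampedit("ampedit_invalid_guide", "protospacer must be A/C/G/T only")
  if (!is_iupac(pam_pattern))
    stop_ampedit("ampedit_invalid_guide", "PAM pattern must be valid IUPAC")
  stopifnot(strand %in% c("+", "-"))
  structure(list(protospacer = protospacer, pam_pattern = pam_pattern,
                 strand = strand, cut_offset = as.integer(cut_offset)),
            class = "guide")
}

# ---------------------------------------------------------------------------
# Fixture locus

new_editing_locus <- function(segments, guides, stop_codon_position,
                              pathogenic_variant, hdr_markers,
                              junction_signatures, intron_scale, seed) {
  lens <- vapply(segments, nchar, integer(1))
  if (any(lens == 0))
    stop_ampedit("ampedit_invalid_locus", "all locus segments must be non-empty")
  if ((lens[["exon52"]] + lens[["exon53"]]) %% 3 != 0)
    stop_ampedit("ampedit_invalid_locus",
                 "exon 52 + exon 53 must sum to a multiple of 3 (frame-neutral excision)")
  seg_start <- c(0L, cumsum(lens))[seq_along(lens)]
  names(seg_start) <- names(segments)
  genome <- paste(unlist(segments), collapse = "")
  transcript <- paste0(segments$exon51, segments$exon52, segments$exon53, segments$exon54)
  ex53_cuts <- guides$cut_site[guides$name %in% c("sp_ex53_5p", "sp_ex53_3p")]
  if (!(stop_codon_position > min(ex53_cuts) && stop_codon_position + 3 <= max(ex53_cuts)))
    stop_ampedit("ampedit_invalid_locus",
                 "premature stop codon must lie between the two exon-53 cut sites")
  structure(list(segments = segments, seg_start = seg_start, seg_len = lens,
                 genome = genome, transcript = transcript,
                 guides = guides,
                 stop_codon_position = stop_codon_position,
                 pathogenic_variant = pathogenic_variant,
                 hdr_markers = hdr_markers,
                 junction_signatures = junction_signatures,
                 intron_scale = intron_scale, seed = seed),
            class = "editing_locus")
}

#' @export
print.editing_locus <- function(x, ...) {
  cat(sprintf("editing_locus: %d nt genome, %d nt transcript, %d guides, seed %d\n",
              nchar(x$genome), nchar(x$transcript), nrow(x$guides), x$seed))
  cat(sprintf("  segments: %s\n",
              paste(sprintf("%s(%d)", names(x$seg_len), x$seg_len), collapse = " ")))
  invisible(x)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fixed layout of the surrogate exon 53 (0-based offsets within the exon):
#   protospacer A = [31, 51), PAM A = codon at [51, 54) = AGG, cut A = 48
#   premature stop TAA = codon at [66, 69) (pathogenic T at 66; corrected C)
#   protospacer B = [70, 90), PAM B = codon at [90, 93) = AGG, cut B = 87
#   silent HDR markers: third PAM base at 53 and 92, G -> A (AGG -> AGA, Arg)
# The exon is codon-aligned at its start (exon51 + exon52 lengths sum to a
# multiple of 3), so both PAM codons and the stop are in frame.
EX53_LAYOUT <- list(protoA = c(31L, 51L), pamA = 51L, cutA = 48L,
                    stop = 66L, protoB = c(70L, 90L), pamB = 90L, cutB = 87L,
                    markers = c(53L, 92L))

# Exon boundaries within the spliced transcript (0-based): exon51 [0,119),
# exon52 [119,237), exon53 [237,449), exon54 [449,569). Exons 52+53 sum to
# 330 nt; exon 53 is codon-aligned. The whole CDS is built from sense codons
# (plus the planted features) so that the only in-frame stop is the planted
# mutant TAA, and codon 39 is fixed to CTG so the exon51/exon54 fusion codon
# created by the delta-52/53 excision stays sense for any exon 54 start base.
EXON_LENS <- c(exon51 = 119L, exon52 = 118L, exon53 = 212L, exon54 = 120L)

build_cds <- function() {
  lay <- EX53_LAYOUT
  codons <- sample(sense_codons(), 189, replace = TRUE)
  codons[40] <- "CTG"                    # codon 39: Leu for any third base
  ex53_codon0 <- 79L                     # exon 53 starts at codon 79
  codons[ex53_codon0 + lay$pamA / 3 + 1] <- "AGG"    # codon 96, PAM A
  codons[ex53_codon0 + lay$stop / 3 + 1] <- "TAA"    # codon 101, mutant stop
  codons[ex53_codon0 + lay$pamB / 3 + 1] <- "AGG"    # codon 109, PAM B
  paste0(paste(codons, collapse = ""), random_dna(2))  # 569 nt
}

#' Build the synthetic mdx4cv-like fixture locus
#'
#' Constructs a deterministic multi-exon surrogate locus emulating the
#' geometry of the dystrophin exon 52/53 region in the mdx4cv mouse: exons 52
#' and 53 jointly contribute 330 transcript nt (so their excision is
#' frame-neutral and removes 110 codons), a premature TAA stop created by a
#' C-to-T nonsense change sits in exon 53 between two exon-53 guide sites, and
#' intron guides flanking exons 52-53 support the multi-exon excision
#' strategy. The ~45 kb intron span of the real locus is scaled down to
#' `intron_scale` nt; only the junction sequences, never the span length,
#' matter to downstream analysis.
#'
#' @param seed integer seed; construction is pure in `(seed, intron_scale)`.
#' @param intron_scale surrogate intron length in nt (>= 200).
#' @return an `editing_locus` with segments, guides, the pathogenic variant,
#'   HDR marker positions, and junction signature k-mers for the
#'   delta-exon-52/53 genomic and transcript junctions and the exon-53-skip
#'   transcript junction.
#' @examples
#' loc <- build_fixture_locus(seed = 1)
#' nchar(loc$segments$exon52) + nchar(loc$segments$exon53)  # 330
#' @export
build_fixture_locus <- function(seed = 1L, intron_scale = 1000L) {
  intron_scale <- as.integer(intron_scale)
  if (intron_scale < 200L)
    stop_ampedit("ampedit_size_error",
                 "intron_scale must be >= 200 nt to host the end exclusions and windows")
  with_seed(stage_seed(seed, "fixture"), {
    lay <- EX53_LAYOUT
    cds <- build_cds()
    bounds <- c(0L, cumsum(EXON_LENS))
    exon51 <- substr(cds, bounds[1] + 1, bounds[2])  # 119 nt
    exon52 <- substr(cds, bounds[2] + 1, bounds[3])  # 118 nt
    exon53 <- substr(cds, bounds[3] + 1, bounds[4])  # 212 nt
    exon54 <- substr(cds, bounds[4] + 1, bounds[5])  # 120 nt
    intron51 <- random_dna(intron_scale)
    intron52 <- random_dna(intron_scale)
    intron53 <- random_dna(intron_scale)

    # Plant one SpCas9-type guide near the middle of introns 51 and 53.
    plant_intron_guide <- function(intron) {
      c0 <- as.integer(nchar(intron) %/% 2L) - 10L
      intron <- substr_set(intron, c0 + 20L, "TGG")
      list(intron = intron, proto = substr(intron, c0 + 1, c0 + 20),
           cut_local = c0 + 17L, pam = substr(intron, c0 + 21, c0 + 23))
    }
    g51 <- plant_intron_guide(intron51); intron51 <- g51$intron
    g53 <- plant_intron_guide(intron53); intron53 <- g53$intron

    segments <- list(exon51 = exon51, intron51 = intron51, exon52 = exon52,
                     intron52 = intron52, exon53 = exon53, intron53 = intron53,
                     exon54 = exon54)
    lens <- vapply(segments, nchar, integer(1))
    seg_start <- c(0L, cumsum(lens))[seq_along(lens)]
    names(seg_start) <- names(segments)
    ex53_0 <- seg_start[["exon53"]]

    guides <- data.frame(
      name = c("sp_i51", "sp_i53", "sp_ex53_5p", "sp_ex53_3p"),
      protospacer = c(g51$proto, g53$proto,
                      substr(exon53, lay$protoA[1] + 1, lay$protoA[2]),
                      substr(exon53, lay$protoB[1] + 1, lay$protoB[2])),
      pam = c(g51$pam, g53$pam,
              substr(exon53, lay$pamA + 1, lay$pamA + 3),
              substr(exon53, lay$pamB + 1, lay$pamB + 3)),
      pam_pattern = "NGG", strand = "+", cut_offset = -3L,
      cut_site = as.integer(c(seg_start[["intron51"]] + g51$cut_local,
                              seg_start[["intron53"]] + g53$cut_local,
                              ex53_0 + lay$cutA, ex53_0 + lay$cutB)),
      segment = c("intron51", "intron53", "exon53", "exon53"),
      stringsAsFactors = FALSE)

    stop_codon_position <- ex53_0 + lay$stop
    pathogenic_variant <- list(position = stop_codon_position, ref = "T", alt = "C")
    hdr_markers <- data.frame(position = ex53_0 + lay$markers, ref = "G", alt = "A")

    genome <- paste(unlist(segments), collapse = "")
    cut_g51 <- guides$cut_site[guides$name == "sp_i51"]
    cut_g53 <- guides$cut_site[guides$name == "sp_i53"]
    side <- function(s, from_end) substr(s, nchar(s) - from_end + 1, nchar(s))
    junction_signatures <- list(
      delta5253_genomic = list(
        upstream = side(substr(genome, 1, cut_g51), 30),
        downstream = substr(genome, cut_g53 + 1, cut_g53 + 30)),
      delta5253_transcript = list(
        upstream = side(exon51, 30), downstream = substr(exon54, 1, 30)),
      exon53_skip = list(
        upstream = side(exon52, 30), downstream = substr(exon54, 1, 30)))

    transcript <- paste0(exon51, exon52, exon53, exon54)
    for (nm in names(junction_signatures)) {
      sig <- junction_signatures[[nm]]
      fused <- paste0(side(sig$upstream, 12), substr(sig$downstream, 1, 12))
      hit <- grepl(fused, genome, fixed = TRUE) ||
        grepl(fused, transcript, fixed = TRUE) ||
        grepl(revcomp(fused), genome, fixed = TRUE)
      if (hit)
        stop_ampedit("ampedit_invalid_locus",
                     sprintf("junction signature '%s' occurs in the unedited locus", nm))
    }

    new_editing_locus(segments, guides, stop_codon_position,
                      pathogenic_variant, hdr_markers,
                      junction_signatures, intron_scale, as.integer(seed))
  })
}

# Spliced transcript variants of the locus.
locus_transcript <- function(locus, kind = c("mutant", "wt", "skip53", "delta5253")) {
  kind <- match.arg(kind)
  s <- locus$segments
  switch(kind,
         mutant = paste0(s$exon51, s$exon52, s$exon53, s$exon54),
         wt = {
           tx <- paste0(s$exon51, s$exon52, s$exon53, s$exon54)
           pos <- nchar(s$exon51) + nchar(s$exon52) +
             (locus$stop_codon_position - locus$seg_start[["exon53"]])
           substr_set(tx, pos, locus$pathogenic_variant$alt)
         },
         skip53 = paste0(s$exon51, s$exon52, s$exon54),
         delta5253 = paste0(s$exon51, s$exon54))
}

#' Derive the study amplicons from a fixture locus
#'
#' Builds one ~200-250 nt genomic amplicon per individual intron target site
#' (cut site centred), the nested-style strategy-2 genomic amplicon spanning
#' both exon-53 cut sites, both HDR markers and the premature stop (with one
#' end anchored outside the HDR template span, emulating the nested primer
#' that guards against donor-template contamination), and transcript
#' amplicons spanning the exon 52/53 region and the exon 51/54 region.
#'
#' @param locus an `editing_locus` from [build_fixture_locus()].
#' @param target_length nominal genomic amplicon length in nt (default 230).
#' @return a named list of `amplicon_spec` objects
#'   (`i51`, `i53`, `ex53`, `tx5253`, `tx5154`).
#' @export
derive_amplicons <- function(locus, target_length = 230L) {
  stopifnot(inherits(locus, "editing_locus"))
  gdf <- locus$guides
  seg_start <- locus$seg_start
  seg_len <- locus$seg_len

  intron_amplicon <- function(guide_name, segment, length_nt) {
    cut_g <- gdf$cut_site[gdf$name == guide_name]
    s0 <- seg_start[[segment]]; s1 <- s0 + seg_len[[segment]]
    half <- min(floor(length_nt / 2), cut_g - s0, s1 - cut_g)
    if (2 * half < 200L)
      stop_ampedit("ampedit_placement_error",
                   sprintf("guide %s too close to segment boundary for a >=200 nt amplicon",
                           guide_name))
    start <- cut_g - half
    amplicon_spec(name = guide_name,
                  sequence = substr(locus$genome, start + 1, start + 2 * half),
                  cut_sites = cut_g - start)
  }

  i51 <- intron_amplicon("sp_i51", "intron51", target_length)
  i53 <- intron_amplicon("sp_i53", "intron53", max(200L, target_length - 6L))
  names(i51$cut_sites) <- "sp_i51"; names(i53$cut_sites) <- "sp_i53"
  i51$name <- "i51"; i53$name <- "i53"

  # Strategy-2 nested genomic amplicon: 10 nt of intron 52, all of exon 53,
  # 8 nt of intron 53. The first 18 nt lie outside the donor-template span,
  # providing the anchor that genuine genomic reads must cover.
  ex53_0 <- seg_start[["exon53"]]
  lay <- EX53_LAYOUT
  start <- ex53_0 - 10L
  seq_ex53 <- substr(locus$genome, start + 1, start + 230L)
  ex53 <- amplicon_spec(
    name = "ex53", sequence = seq_ex53,
    cut_sites = c(sp_ex53_5p = 10L + lay$cutA, sp_ex53_3p = 10L + lay$cutB),
    hdr_markers = data.frame(position = 10L + lay$markers, ref = "G", alt = "A"),
    pathogenic_variant = list(position = 10L + lay$stop, ref = "T", alt = "C"),
    coding_intervals = data.frame(start = 10L, end = 222L, frame_offset = 0L),
    template_span = c(18L, 230L))

  # Transcript amplicon spanning exon 52 into exon 53 past the 3' cut site.
  tx <- locus_transcript(locus, "mutant")
  e51 <- seg_len[["exon51"]]; e52 <- seg_len[["exon52"]]
  tx_start <- e51 + 30L                       # 30 nt into exon 52
  tx_end <- e51 + e52 + 140L                  # 140 nt into exon 53
  ex53_tx0 <- e51 + e52                       # transcript offset of exon 53
  off <- ex53_tx0 - tx_start
  tx5253 <- amplicon_spec(
    name = "tx5253", sequence = substr(tx, tx_start + 1, tx_end),
    cut_sites = c(sp_ex53_5p = off + lay$cutA, sp_ex53_3p = off + lay$cutB),
    hdr_markers = data.frame(position = off + lay$markers, ref = "G", alt = "A"),
    pathogenic_variant = list(position = off + lay$stop, ref = "T", alt = "C"),
    coding_intervals = data.frame(start = 0L, end = tx_end - tx_start,
                                  frame_offset = (3L - tx_start %% 3L) %% 3L))

  # Transcript amplicon around the exon 51/52 boundary (strategy-1 RT
  # reference; the excision product itself is recognised by its junction
  # signature, not by alignment to this reference).
  t0 <- e51 - 110L
  tx5154 <- amplicon_spec(
    name = "tx5154", sequence = substr(tx, t0 + 1, t0 + 220L),
    coding_intervals = data.frame(start = 0L, end = 220L,
                                  frame_offset = (3L - t0 %% 3L) %% 3L))

  list(i51 = i51, i53 = i53, ex53 = ex53, tx5253 = tx5253, tx5154 = tx5154)
}

# ---------------------------------------------------------------------------
# Serialization: FASTA for sequences, JSON sidecar for annotations.

#' Write amplicon specifications to FASTA plus a JSON sidecar
#'
#' @param specs named list of `amplicon_spec` objects.
#' @param fasta,json output file paths.
#' @return invisibly, the two paths.
#' @export
write_amplicons <- function(specs, fasta, json) {
  seqs <- Biostrings::DNAStringSet(vapply(specs, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(specs, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, fasta)
  meta <- lapply(specs, function(s) {
    s <- unclass(s)
    s$sequence <- NULL
    s
  })
  jsonlite::write_json(meta, json, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(fasta = fasta, json = json))
}

#' Read amplicon specifications written by [write_amplicons()]
#'
#' @param fasta,json input file paths.
#' @return a named list of `amplicon_spec` objects.
#' @export
read_amplicons <- function(fasta, json) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  out <- lapply(names(seqs), function(nm) {
    m <- meta[[nm]]
    amplicon_spec(name = nm, sequence = as.character(seqs[[nm]]),
                  cut_sites = m$cut_sites %||% integer(0),
                  quant_halfwidth = m$quant_halfwidth,
                  end_exclusion = m$end_exclusion,
                  hdr_markers = m$hdr_markers,
                  pathogenic_variant = if (!is.null(m$pathogenic_variant))
                    as.list(m$pathogenic_variant) else NULL,
                  coding_intervals = m$coding_intervals,
                  template_span = m$template_span)
  })
  names(out) <- names(seqs)
  out
}
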