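# Synthetic amplicon read simulator with recoverable per-read ground truth.
#
# Emulates pooled amplicon deep-sequencing read sets: unmodified reads,
# NHEJ reads carrying one indel whose breakpoint lies inside a cut-site
# quantification window, HDR reads carrying both silent marker substitutions
# with the pathogenic variant reverted, mixed HDR/NHEJ reads, exon-excision
# junction reads, exon-skip transcript reads, donor-template contaminant
# reads, and uniform substitution sequencing error applied on top.

#' Default signed indel length distribution
#'
#' Geometric length law truncated at `max_len`, with deletion/insertion sign
#' drawn independently. This is a typical Cas9 editing spectrum shape; the
#' source data constrain only the window rule, not the spectrum, so the law
#' is fully overridable wherever an `outcome_mix` is accepted.
#'
#' @param p geometric parameter for |length| (default 0.35).
#' @param max_len truncation bound on |length| (default 60).
#' @param p_deletion probability that an indel is a deletion (default 0.7).
#' @return named numeric vector of probabilities; names are signed lengths
#'   (negative = deletion, positive = insertion).
#' @export
default_indel_law <- function(p = 0.35, max_len = 60L, p_deletion = 0.7) {
  lens <- seq_len(max_len)
  mass <- stats::dgeom(lens - 1, p)
  mass <- mass / sum(mass)
  law <- c(rev(mass * p_deletion), mass * (1 - p_deletion))
  names(law) <- c(rev(-lens), lens)
  law
}

#' Reweight an indel length law to a target frame-preserving mass
#'
#' Rescales the probabilities of signed lengths that are multiples of 3
#' (net frame-preserving events) against all others so that the
#' frame-preserving mass equals `target`; used to emulate editing spectra
#' with a stated fraction of in-frame events.
#'
#' @param target desired total probability on lengths divisible by 3.
#' @param law base law (default [default_indel_law()]).
#' @return a named numeric law summing to 1.
#' @export
indel_law_with_frame_mass <- function(target, law = default_indel_law()) {
  stopifnot(target > 0, target < 1)
  lens <- as.integer(names(law))
  inframe <- lens %% 3L == 0L
  m <- sum(law[inframe])
  stopifnot(m > 0, m < 1)
  law[inframe] <- law[inframe] * target / m
  law[!inframe] <- law[!inframe] * (1 - target) / (1 - m)
  law
}

#' Construct an outcome mixture for the read simulator
#'
#' Fractions describe the per-read category law. `nhej` gives one fraction
#' per cut site of the amplicon (in cut-site order). The `unmodified`
#' fraction, if `NULL`, is set to the remainder so the law sums to 1.
#'
#' @param nhej numeric vector of per-site NHEJ fractions (may be empty).
#' @param hdr fraction of HDR reads (both markers, variant reverted, no
#'   window indel).
#' @param mixed fraction of mixed HDR/NHEJ reads (markers plus window indel).
#' @param junction_delta5253 fraction of multi-exon excision junction reads.
#' @param exon53_skip fraction of exon-53-skip transcript junction reads.
#' @param template_contaminant fraction of reads covering only the donor
#'   template span (lacking the anchor).
#' @param unmodified unmodified fraction, or `NULL` for the remainder.
#' @param indel_length_law named numeric law over signed indel lengths.
#' @param substitution_error_rate per-base substitution sequencing error.
#' @param read_length read length in nt, or `NULL` for full-amplicon reads
#'   (merged paired-end cover of a short amplicon).
#' @param paired simulate paired 150 nt reads covering the amplicon from
#'   both ends instead of single merged reads.
#' @return an object of class `outcome_mix`.
#' @export
outcome_mix <- function(nhej = numeric(0), hdr = 0, mixed = 0,
                        junction_delta5253 = 0, exon53_skip = 0,
                        template_contaminant = 0, unmodified = NULL,
                        indel_length_law = default_indel_law(),
                        substitution_error_rate = 0.001,
                        read_length = NULL, paired = FALSE) {
  named <- c(hdr = hdr, mixed = mixed,
             junction_delta5253 = junction_delta5253,
             exon53_skip = exon53_skip,
             template_contaminant = template_contaminant)
  if (length(nhej)) names(nhej) <- paste0("nhej_site_", seq_along(nhej))
  partial <- sum(nhej) + sum(named)
  if (is.null(unmodified)) unmodified <- 1 - partial
  fractions <- c(unmodified = unmodified, nhej, named)
  if (any(fractions < -1e-12))
    stop_ampedit("ampedit_invalid_mix", "outcome fractions must be nonnegative")
  fractions <- pmax(fractions, 0)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_ampedit("ampedit_invalid_mix", "outcome fractions must sum to 1")
  if (abs(sum(indel_length_law) - 1) > 1e-9 || any(indel_length_law < 0))
    stop_ampedit("ampedit_invalid_mix", "indel length law must be a probability law")
  lens <- as.integer(names(indel_length_law))
  if (any(is.na(lens)) || any(lens == 0) || any(abs(lens) > 60))
    stop_ampedit("ampedit_invalid_mix",
                 "indel law support must be signed lengths with 1 <= |len| <= 60")
  structure(list(fractions = fractions, n_sites = length(nhej),
                 indel_length_law = indel_length_law,
                 substitution_error_rate = substitution_error_rate,
                 read_length = read_length, paired = isTRUE(paired)),
            class = "outcome_mix")
}

# Sample one signed indel length.
draw_indel_len <- function(law) {
  as.integer(sample(names(law), 1, prob = law))
}

# Apply one indel to an amplicon sequence such that it overlaps the
# quantification window of cut site `cut` (inter-base). Deletion midpoints
# and insertion points are uniform within +/- halfwidth of the cut; deletions
# are clamped inside the quantifiable region.
apply_window_indel <- function(seq, cut, halfwidth, end_excl, len_signed) {
  n <- nchar(seq)
  if (len_signed > 0) {
    p <- sample(seq(cut - halfwidth, cut + halfwidth), 1)
    ins <- random_dna(len_signed)
    list(seq = paste0(substr(seq, 1, p), ins, substr(seq, p + 1, n)),
         indel = sprintf("%+d@%d", len_signed, p),
         len = len_signed, pos = p)
  } else {
    L <- -len_signed
    m <- sample(seq(cut - halfwidth, cut + halfwidth - 1), 1)
    a <- m - floor(L / 2)
    a <- max(a, end_excl)
    a <- min(a, n - end_excl - L)
    list(seq = paste0(substr(seq, 1, a), substr(seq, a + L + 1, n)),
         indel = sprintf("%+d@%d", len_signed, a),
         len = len_signed, pos = a)
  }
}

apply_hdr_edits <- function(seq, spec) {
  if (is.null(spec$hdr_markers))
    stop_ampedit("ampedit_config_error",
                 "HDR/mixed categories require hdr_markers on the amplicon spec")
  for (i in seq_len(nrow(spec$hdr_markers)))
    seq <- substr_set(seq, spec$hdr_markers$position[i], spec$hdr_markers$alt[i])
  if (!is.null(spec$pathogenic_variant))
    seq <- substr_set(seq, spec$pathogenic_variant$position,
                      spec$pathogenic_variant$alt)
  seq
}

junction_read <- function(locus, signature, rl) {
  sig <- locus$junction_signatures[[signature]]
  if (is.null(sig))
    stop_ampedit("ampedit_config_error",
                 sprintf("locus has no junction signature '%s'", signature))
  half <- floor(rl / 2)
  ups <- switch(signature,
                delta5253_genomic = substr(locus$genome, 1,
                                           locus$guides$cut_site[locus$guides$name == "sp_i51"]),
                delta5253_transcript = locus$segments$exon51,
                exon53_skip = paste0(locus$segments$exon51, locus$segments$exon52))
  downs <- switch(signature,
                  delta5253_genomic = substr(locus$genome,
                                             locus$guides$cut_site[locus$guides$name == "sp_i53"] + 1,
                                             nchar(locus$genome)),
                  locus$segments$exon54)
  paste0(substr(ups, nchar(ups) - half + 1, nchar(ups)),
         substr(downs, 1, rl - half))
}

#' Simulate amplicon reads with known ground truth
#'
#' Draws `n` reads i.i.d. from the category law of `mix`, constructs each
#' read from the amplicon (or the locus, for junction categories), applies
#' uniform substitution sequencing error, and emits a per-read truth table.
#'
#' @param spec an [amplicon_spec()].
#' @param mix an [outcome_mix()]; per-site NHEJ fractions must match the
#'   number of cut sites on `spec`.
#' @param n number of reads (>= 1).
#' @param seed integer seed; output is byte-identical for identical
#'   `(spec, mix, n, seed)`.
#' @param locus an `editing_locus`; required when `mix` contains junction or
#'   exon-skip fractions.
#' @return a list of class `sim_reads` with elements `reads` (named character
#'   vector), `quals` (phred33 quality strings), `truth` (data.frame with
#'   `read_id`, `true_label`, `true_site`, `true_indel`), and `pairs` (when
#'   `mix$paired`, a list with `r1`, `r2`, and quality strings).
#' @export
simulate_amplicon_reads <- function(spec, mix, n, seed = 1L, locus = NULL) {
  stopifnot(inherits(spec, "amplicon_spec"), inherits(mix, "outcome_mix"), n >= 1)
  if (mix$n_sites > 0 && mix$n_sites != length(spec$cut_sites))
    stop_ampedit("ampedit_config_error",
                 "mix has per-site NHEJ fractions for a different number of cut sites")
  junction_cats <- intersect(names(mix$fractions),
                             c("junction_delta5253", "exon53_skip"))
  needs_locus <- any(mix$fractions[junction_cats] > 0)
  if (needs_locus && is.null(locus))
    stop_ampedit("ampedit_config_error",
                 "junction/exon-skip categories require the locus")
  if (mix$fractions[["template_contaminant"]] > 0 && is.null(spec$template_span))
    stop_ampedit("ampedit_config_error",
                 "template_contaminant requires template_span on the amplicon spec")

  with_seed(seed, {
    cats <- names(mix$fractions)
    labels <- sample(cats, n, replace = TRUE, prob = mix$fractions)
    rl <- mix$read_length %||% spec$length
    hw <- spec$quant_halfwidth; ee <- spec$end_exclusion

    reads <- character(n)
    indels <- rep(NA_character_, n)
    sites <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      lab <- labels[i]
      if (lab == "unmodified") {
        reads[i] <- spec$sequence
      } else if (startsWith(lab, "nhej_site_")) {
        k <- as.integer(sub("nhej_site_", "", lab))
        sites[i] <- k
        r <- apply_window_indel(spec$sequence, spec$cut_sites[k], hw, ee,
                                draw_indel_len(mix$indel_length_law))
        reads[i] <- r$seq; indels[i] <- r$indel
      } else if (lab == "hdr") {
        reads[i] <- apply_hdr_edits(spec$sequence, spec)
      } else if (lab == "mixed") {
        k <- sample(seq_along(spec$cut_sites), 1)
        sites[i] <- k
        r <- apply_window_indel(apply_hdr_edits(spec$sequence, spec),
                                spec$cut_sites[k], hw, ee,
                                draw_indel_len(mix$indel_length_law))
        reads[i] <- r$seq; indels[i] <- r$indel
        # a deletion that removes a marker base leaves a read whose
        # observable state is plain NHEJ; the truth label follows the read
        if (r$len < 0 &&
            any(spec$hdr_markers$position >= r$pos &
                spec$hdr_markers$position < r$pos - r$len))
          labels[i] <- paste0("nhej_site_", k)
      } else if (lab %in% c("junction_delta5253", "exon53_skip")) {
        # transcript amplicons (tx*) carry the exon51/54 fusion; genomic
        # amplicons the genomic excision junction
        signame <- if (lab == "exon53_skip") "exon53_skip"
          else if (startsWith(spec$name, "tx")) "delta5253_transcript"
          else "delta5253_genomic"
        reads[i] <- junction_read(locus, signame, rl)
      } else if (lab == "template_contaminant") {
        ts <- spec$template_span
        reads[i] <- substr(spec$sequence, ts[1] + 1, ts[2])
      }
    }

    # Uniform substitution error applied after outcome construction.
    er <- mix$substitution_error_rate
    if (er > 0) {
      for (i in seq_len(n)) {
        len <- nchar(reads[i])
        k <- stats::rbinom(1, len, er)
        if (k > 0) {
          pos <- sample.int(len, k)
          ch <- strsplit(reads[i], "")[[1]]
          for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
          reads[i] <- paste(ch, collapse = "")
        }
      }
    }

    ids <- sprintf("read_%06d", seq_len(n))
    names(reads) <- ids
    quals <- vapply(nchar(reads), function(l) strrep("F", l), character(1))  # Q37
    names(quals) <- ids
    truth <- data.frame(read_id = ids, true_label = sub("_site_[0-9]+$", "", labels),
                        true_site = sites, true_indel = indels,
                        stringsAsFactors = FALSE)

    out <- list(reads = reads, quals = quals, truth = truth, spec_name = spec$name)
    if (mix$paired) {
      prl <- 150L
      r1 <- substr(reads, 1, pmin(prl, nchar(reads)))
      r2 <- revcomp(substr(reads, pmax(1L, nchar(reads) - prl + 1L), nchar(reads)))
      names(r1) <- names(r2) <- ids
      out$pairs <- list(r1 = r1, r2 = r2,
                        q1 = vapply(nchar(r1), function(l) strrep("F", l), character(1)),
                        q2 = vapply(nchar(r2), function(l) strrep("F", l), character(1)))
    }
    class(out) <- "sim_reads"
    out
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d reads for amplicon '%s'\n", length(x$reads), x$spec_name))
  print(table(x$truth$true_label))
  invisible(x)
}

#' Write simulated reads as FASTQ (phred33) plus a truth TSV
#'
#' @param sim a `sim_reads` object.
#' @param fastq output FASTQ path (uncompressed).
#' @param truth_tsv optional path for the truth table.
#' @return invisibly, the FASTQ path.
#' @export
write_sim_fastq <- function(sim, fastq, truth_tsv = NULL) {
  x <- Biostrings::DNAStringSet(sim$reads)
  q <- Biostrings::PhredQuality(sim$quals)
  qs <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(qs, fastq)
  if (!is.null(truth_tsv))
    utils::write.table(sim$truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fastq)
}

#' Read a phred33 FASTQ into sequences and quality strings
#'
#' @param path FASTQ file path.
#' @return list with `reads` and `quals`, both named character vectors.
#' @export
read_fastq <- function(path) {
  # the FASTQ id line duplicates into metadata columns that are then
  # dropped; the warning is noise for plain read sets
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  reads <- as.character(qs)
  quals <- as.character(Biostrings::quality(qs))
  ids <- sub("\\s.*$", "", names(qs))
  names(reads) <- names(quals) <- ids
  list(reads = reads, quals = quals)
}
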