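# Per-read outcome classification (unmodified / NHEJ / HDR / mixed /
# junction / discarded), search-sequence genotyping, and aggregation into
# editing summaries.

OUTCOME_LEVELS <- c("unmodified", "nhej", "hdr", "mixed",
                    "junction_delta5253", "exon53_skip", "discarded")

# Does the call carry a substitution with base `alt` at amplicon position
# `pos`? Substitution runs are stored merged, so index into the run.
has_sub_at <- function(v, pos, alt) {
  if (!nrow(v)) return(FALSE)
  s <- v[v$kind == "sub", , drop = FALSE]
  if (!nrow(s)) return(FALSE)
  hit <- s$position <= pos & pos < s$position + s$length
  if (!any(hit)) return(FALSE)
  i <- which(hit)[1]
  substr(s$alt[i], pos - s$position[i] + 1, pos - s$position[i] + 1) == alt
}

# Is the base at `pos` deleted by any deletion in the call?
has_del_at <- function(v, pos) {
  d <- v[v$kind == "del", , drop = FALSE]
  any(d$position <= pos & pos < d$position + d$length)
}

markers_present <- function(v, spec) {
  m <- spec$hdr_markers
  vapply(seq_len(nrow(m)),
         function(i) has_sub_at(v, m$position[i], m$alt[i]), logical(1))
}

#' Classify one read's edit call into an editing outcome
#'
#' Classification rules: a read is `discarded` when unalignable or when a
#' donor-template span is declared and the read fails to cover the anchor
#' outside it; `hdr` when all marker substitutions are present, the
#' pathogenic variant is reverted, no quantification-window indel is called,
#' and alignment identity meets the homology threshold; `mixed` when all
#' markers are present together with at least one window indel; `nhej` when
#' a window indel is present without the markers; otherwise `unmodified`.
#' Reads carrying a strict subset of the markers are classified by their
#' indel status and flagged `partial_hdr`.
#'
#' @param call a single-read call from [align_read()].
#' @param spec the [amplicon_spec()]; must carry `hdr_markers` for HDR
#'   classification.
#' @param homology_threshold minimum alignment identity for an HDR call
#'   (default 0.98; must lie in (0.5, 1]).
#' @return a list with `label` (one of `unmodified`, `nhej`, `hdr`, `mixed`,
#'   `discarded`), `reason` (for discards), and `partial_hdr`.
#' @export
classify_read <- function(call, spec, homology_threshold = 0.98) {
  if (homology_threshold <= 0.5 || homology_threshold > 1)
    stop_ampedit("ampedit_param_error",
                 "homology_threshold must lie in (0.5, 1]")
  if (call$unalignable)
    return(list(label = "discarded", reason = "unalignable", partial_hdr = FALSE))
  if (!is.null(spec$template_span) && !call$covers_anchor)
    return(list(label = "discarded", reason = "no_anchor", partial_hdr = FALSE))
  v <- call$variants
  window_indel <- any(call$window_hits)
  partial <- FALSE
  markers_all <- FALSE
  if (!is.null(spec$hdr_markers)) {
    mp <- markers_present(v, spec)
    markers_all <- all(mp)
    partial <- any(mp) && !all(mp)
  }
  label <- if (markers_all) {
    reverted <- is.null(spec$pathogenic_variant) ||
      has_sub_at(v, spec$pathogenic_variant$position, spec$pathogenic_variant$alt)
    if (window_indel) "mixed"
    else if (reverted && call$identity >= homology_threshold) "hdr"
    else "unmodified"
  } else if (window_indel) "nhej" else "unmodified"
  list(label = label, reason = NA_character_, partial_hdr = partial)
}

#' Detect an exon-junction signature in a read
#'
#' Searches the read (both orientations) for the fusion k-mer of each named
#' junction (k/2 nt upstream + k/2 nt downstream of the junction point),
#' allowing up to `max_mismatch` mismatches.
#'
#' @param read DNA string.
#' @param locus an `editing_locus` carrying `junction_signatures`.
#' @param k fusion k-mer length (>= 16; default 24).
#' @param max_mismatch mismatches tolerated in the k-mer (default 1).
#' @return the junction name, `NA` if none matches, or `"ambiguous"` if more
#'   than one distinct junction matches (such reads are discarded).
#' @export
detect_junction <- function(read, locus, k = 24L, max_mismatch = 1L) {
  detect_junctions(read, locus, k, max_mismatch)[1]
}

#' Vectorized junction detection over a read set
#'
#' @inheritParams detect_junction
#' @param reads character vector of read sequences.
#' @return character vector: junction name, `NA`, or `"ambiguous"` per read.
#' @export
detect_junctions <- function(reads, locus, k = 24L, max_mismatch = 1L) {
  stopifnot(inherits(locus, "editing_locus"))
  if (k < 16L)
    stop_ampedit("ampedit_param_error", "junction k-mer length must be >= 16")
  half <- floor(k / 2)
  set <- Biostrings::DNAStringSet(reads)
  hits <- matrix(FALSE, length(reads), length(locus$junction_signatures),
                 dimnames = list(NULL, names(locus$junction_signatures)))
  for (nm in names(locus$junction_signatures)) {
    sig <- locus$junction_signatures[[nm]]
    ups <- sig$upstream; dns <- sig$downstream
    fused <- paste0(substr(ups, nchar(ups) - half + 1, nchar(ups)),
                    substr(dns, 1, k - half))
    cnt <- Biostrings::vcountPattern(fused, set, max.mismatch = max_mismatch) +
      Biostrings::vcountPattern(revcomp(fused), set, max.mismatch = max_mismatch)
    hits[, nm] <- cnt > 0
  }
  nhit <- rowSums(hits)
  out <- rep(NA_character_, length(reads))
  one <- nhit == 1
  out[one] <- colnames(hits)[apply(hits[one, , drop = FALSE], 1, which)]
  out[nhit > 1] <- "ambiguous"
  out
}

#' Genotype reads by exact search sequences
#'
#' Counts, for each read, the first named search sequence found as an exact
#' substring (either orientation). Reads matching none are tallied as
#' `edited_other`. This mirrors manual genotype quantification by searching
#' for defined sequences in quality-filtered FASTQ reads.
#'
#' @param reads character vector of read sequences.
#' @param search_table named character vector of search sequences (each
#'   >= 20 nt; no sequence may contain another, in either orientation).
#' @return data.frame with `genotype`, `count`, `fraction`.
#' @export
genotype_by_search <- function(reads, search_table) {
  stopifnot(length(search_table) >= 1, !is.null(names(search_table)))
  if (any(nchar(search_table) < 20))
    stop_ampedit("ampedit_table_error", "each search sequence must be >= 20 nt")
  for (i in seq_along(search_table)) for (j in seq_along(search_table)) {
    if (i != j && (grepl(search_table[i], search_table[j], fixed = TRUE) ||
                   grepl(revcomp(search_table[i]), search_table[j], fixed = TRUE)))
      stop_ampedit("ampedit_table_error",
                   sprintf("search sequence '%s' contains '%s'",
                           names(search_table)[j], names(search_table)[i]))
  }
  set <- Biostrings::DNAStringSet(reads)
  assigned <- rep(NA_character_, length(reads))
  for (nm in names(search_table)) {
    cnt <- Biostrings::vcountPattern(search_table[[nm]], set, fixed = TRUE) +
      Biostrings::vcountPattern(revcomp(search_table[[nm]]), set, fixed = TRUE)
    hit <- is.na(assigned) & cnt > 0
    assigned[hit] <- nm
  }
  assigned[is.na(assigned)] <- "edited_other"
  tab <- table(factor(assigned, levels = c(names(search_table), "edited_other")))
  data.frame(genotype = names(tab), count = as.integer(tab),
             fraction = as.integer(tab) / length(reads),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the fixture-locus search sequences for genotyping
#'
#' DNA search sequences span both exon-53 cut sites and the pathogenic
#' variant; RNA search sequences start within exon 52 and extend past the 3'
#' cut site. The `unmodified` sequence is the reference state and `hdr` the
#' marker-carrying, variant-reverted state.
#'
#' @param spec the strategy-2 amplicon (`ex53` or `tx5253`).
#' @return named character vector with `hdr` and `unmodified` entries.
#' @export
default_search_table <- function(spec) {
  stopifnot(!is.null(spec$hdr_markers), length(spec$cut_sites) == 2)
  lo <- min(spec$cut_sites) - 12L
  hi <- max(spec$cut_sites) + 12L
  ref <- substr(spec$sequence, lo + 1, hi)
  hdr <- substr(apply_hdr_edits(spec$sequence, spec), lo + 1, hi)
  c(hdr = hdr, unmodified = ref)
}

#' Classify a full read set against an amplicon
#'
#' Pipeline step tying junction detection, alignment, and per-read
#' classification together: reads carrying a junction signature are labelled
#' by the junction; the rest are aligned and classified by markers and
#' window indels.
#'
#' @param reads named character vector of (trimmed) read sequences.
#' @param spec an [amplicon_spec()].
#' @param locus optional `editing_locus`; junction detection is skipped when
#'   absent.
#' @param homology_threshold HDR homology threshold (default 0.98).
#' @param params an [align_params()].
#' @param junction_k,junction_mismatch junction detection parameters.
#' @return a list of class `classified_reads` with `labels` (data.frame:
#'   `read_id`, `label`, `reason`, `partial_hdr`) and `calls` (an
#'   `edit_calls` object for the aligned subset).
#' @export
classify_amplicon_reads <- function(reads, spec, locus = NULL,
                                    homology_threshold = 0.98,
                                    params = align_params(),
                                    junction_k = 24L, junction_mismatch = 1L) {
  n <- length(reads)
  ids <- names(reads) %||% sprintf("read_%06d", seq_len(n))
  labels <- rep(NA_character_, n)
  reasons <- rep(NA_character_, n)
  partial <- logical(n)

  if (!is.null(locus)) {
    j <- detect_junctions(reads, locus, junction_k, junction_mismatch)
    amb <- !is.na(j) & j == "ambiguous"
    labels[amb] <- "discarded"; reasons[amb] <- "ambiguous_junction"
    jn <- !is.na(j) & !amb
    labels[jn] <- ifelse(j[jn] == "exon53_skip", "exon53_skip",
                         "junction_delta5253")
  }

  todo <- which(is.na(labels))
  calls <- NULL
  if (length(todo)) {
    calls <- align_reads(stats::setNames(reads[todo], ids[todo]), spec, params)
    vindex <- calls_variant_index(calls)
    for (k in seq_along(todo)) {
      res <- classify_read(extract_call(calls, k, vindex), spec, homology_threshold)
      labels[todo[k]] <- res$label
      reasons[todo[k]] <- res$reason
      partial[todo[k]] <- res$partial_hdr
    }
  }
  structure(list(labels = data.frame(read_id = ids, label = labels,
                                     reason = reasons, partial_hdr = partial,
                                     stringsAsFactors = FALSE),
                 calls = calls, spec_name = spec$name),
            class = "classified_reads")
}

#' Aggregate per-read labels and calls into an editing summary
#'
#' Percentages are reported over classified (non-discarded) reads.
#' `edited_total_pct` counts NHEJ + HDR + mixed + junction + exon-skip
#' reads; per-site percentages use, as denominator, classified alignable
#' reads whose span covers that site's window.
#'
#' @param classified a `classified_reads` object (or a label data.frame).
#' @param spec the [amplicon_spec()].
#' @return a list of class `editing_summary`.
#' @export
summarize_editing <- function(classified, spec) {
  labels <- if (inherits(classified, "classified_reads")) classified$labels
            else classified
  calls <- if (inherits(classified, "classified_reads")) classified$calls else NULL
  n_total <- nrow(labels)
  disc <- labels$label == "discarded"
  n_classified <- sum(!disc)
  if (n_classified == 0)
    stop_ampedit("ampedit_denominator_error", "no classified reads to summarize")
  counts <- table(factor(labels$label[!disc],
                         levels = setdiff(OUTCOME_LEVELS, "discarded")))
  pct <- 100 * as.numeric(counts) / n_classified
  names(pct) <- names(counts)
  edited_levels <- c("nhej", "hdr", "mixed", "junction_delta5253", "exon53_skip")
  edited_total_pct <- sum(pct[edited_levels])

  per_site <- NULL
  if (!is.null(calls) && length(spec$cut_sites)) {
    keep <- labels$label[match(calls$read_id, labels$read_id)] != "discarded"
    sub <- subset_calls(calls, keep)
    per_site <- vapply(seq_along(spec$cut_sites), function(k) {
      100 * site_edit_fraction(sub, spec, k)
    }, numeric(1))
    names(per_site) <- names(spec$cut_sites) %||%
      paste0("site_", seq_along(spec$cut_sites))
  }

  reason_tab <- table(labels$reason[disc], useNA = "no")
  structure(list(
    spec_name = spec$name,
    n_total = n_total, n_discarded = sum(disc), n_classified = n_classified,
    discard_reasons = as.list(reason_tab),
    counts = as.list(counts),
    pct = as.list(pct),
    edited_total_pct = edited_total_pct,
    per_site_pct = as.list(per_site %||% numeric(0)),
    hdr_pct_of_total = pct[["hdr"]],
    mixed_pct_of_total = pct[["mixed"]],
    hdr_share_of_edited_pct = if (edited_total_pct > 0)
      100 * pct[["hdr"]] / edited_total_pct else 0,
    n_partial_hdr = sum(labels$partial_hdr, na.rm = TRUE)),
    class = "editing_summary")
}

subset_calls <- function(calls, keep) {
  out <- calls
  for (f in c("read_id", "identity", "unalignable", "covers_anchor",
              "net_length_change", "aligned_start", "aligned_end", "orientation"))
    out[[f]] <- calls[[f]][keep]
  out$window_hits <- calls$window_hits[keep, , drop = FALSE]
  out$variants <- calls$variants[calls$variants$read_id %in% out$read_id, ,
                                 drop = FALSE]
  out
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("editing_summary for '%s': %d reads (%d discarded)\n",
              x$spec_name, x$n_total, x$n_discarded))
  cat(sprintf("  edited %.3f%% | NHEJ %.3f%% | HDR %.3f%% | mixed %.3f%%\n",
              x$edited_total_pct, x$pct$nhej, x$pct$hdr, x$pct$mixed))
  if (length(x$per_site_pct))
    cat(sprintf("  per-site edited%%: %s\n",
                paste(sprintf("%s=%.3f", names(x$per_site_pct),
                              unlist(x$per_site_pct)), collapse = ", ")))
  invisible(x)
}
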