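# Reading-frame consequence analysis of edited reads and the functional-ORF
# roll-up: which edited reads keep the frame, and which of those also lose
# the premature stop codon (and so can express a functional protein).

FRAME_CATEGORIES <- c("frameshift", "inframe_indel", "inframe_del_no_stop", "hdr")

# Net coding-length change: inserted nt at points strictly inside a coding
# interval minus deleted coding nt.
net_coding_change <- function(v, coding) {
  if (!nrow(v)) return(0L)
  total <- 0L
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "ins") {
      p <- v$position[i]
      if (any(coding$start < p & p < coding$end)) total <- total + v$length[i]
    } else if (v$kind[i] == "del") {
      d0 <- v$position[i]; d1 <- d0 + v$length[i]
      for (j in seq_len(nrow(coding))) {
        ov <- min(d1, coding$end[j]) - max(d0, coding$start[j])
        if (ov > 0) total <- total - ov
      }
    }
  }
  total
}

# Rebuild the edited coding sequence of one interval from a variant table.
edited_coding_seq <- function(amplicon, v, start, end) {
  subs <- v[v$kind == "sub", , drop = FALSE]
  dels <- v[v$kind == "del", , drop = FALSE]
  inss <- v[v$kind == "ins", , drop = FALSE]
  out <- character(0)
  for (p in seq(start, end - 1L)) {
    if (nrow(inss)) {
      k <- which(inss$position == p & start < p & p < end)
      if (length(k)) out <- c(out, inss$alt[k])
    }
    if (nrow(dels) && any(dels$position <= p & p < dels$position + dels$length))
      next
    base <- substr(amplicon, p + 1, p + 1)
    if (nrow(subs)) {
      k <- which(subs$position <= p & p < subs$position + subs$length)
      if (length(k))
        base <- substr(subs$alt[k[1]], p - subs$position[k[1]] + 1,
                       p - subs$position[k[1]] + 1)
    }
    out <- c(out, base)
  }
  paste(out, collapse = "")
}

#' Reading-frame consequence of one edited read
#'
#' HDR reads are category `hdr`. Other edited reads are `frameshift` when
#' the net coding-length change is not a multiple of 3; in-frame reads are
#' `inframe_del_no_stop` when the reconstructed coding sequence no longer
#' contains an in-frame stop within the amplicon coding span (the premature
#' stop deleted, or its pathogenic base reverted or substituted away, with
#' no new stop created), and `inframe_indel` otherwise. Mixed reads are
#' frame-analyzed by their indels with the markers reverting the variant.
#'
#' @param call a single-read call from [align_read()].
#' @param label the read's outcome label (`nhej`, `hdr`, or `mixed`).
#' @param spec an [amplicon_spec()] with `coding_intervals` and
#'   `pathogenic_variant` set.
#' @return one of `"frameshift"`, `"inframe_indel"`, `"inframe_del_no_stop"`,
#'   `"hdr"`.
#' @export
frame_consequence <- function(call, label, spec) {
  stopifnot(label %in% c("nhej", "hdr", "mixed"))
  if (is.null(spec$coding_intervals) || is.null(spec$pathogenic_variant))
    stop_ampedit("ampedit_config_error",
                 "frame analysis requires coding_intervals and pathogenic_variant")
  if (label == "hdr") return("hdr")
  v <- call$variants
  coding <- spec$coding_intervals
  net <- net_coding_change(v, coding)
  if (net %% 3L != 0L) return("frameshift")
  # In-frame: translate the edited coding span and look for any stop.
  has_stop <- FALSE
  for (j in seq_len(nrow(coding))) {
    cs <- edited_coding_seq(spec$sequence, v, coding$start[j], coding$end[j])
    off <- coding$frame_offset[j]
    aa <- translate_dna(substr(cs, off + 1, nchar(cs)))
    if (grepl("*", aa, fixed = TRUE)) { has_stop <- TRUE; break }
  }
  if (has_stop) "inframe_indel" else "inframe_del_no_stop"
}

#' Frame-category report over the edited reads of a sample
#'
#' Construct either from per-read categories (`categories`) or directly from
#' aggregate category percentages (`percent`), e.g. printed category values.
#'
#' @param categories character vector of per-read frame categories over
#'   edited reads (values from `frameshift`, `inframe_indel`,
#'   `inframe_del_no_stop`, `hdr`).
#' @param percent named numeric vector of category percentages of edited
#'   reads (must cover the four categories and sum to 100).
#' @return an object of class `frame_report` with `percent` (named vector),
#'   `n_edited`, and `functional_pct`.
#' @export
frame_report <- function(categories = NULL, percent = NULL) {
  if (is.null(categories) == is.null(percent))
    stop_ampedit("ampedit_param_error",
                 "provide exactly one of categories or percent")
  if (!is.null(categories)) {
    if (!length(categories))
      stop_ampedit("ampedit_denominator_error", "no edited reads to report on")
    stopifnot(all(categories %in% FRAME_CATEGORIES))
    tab <- table(factor(categories, levels = FRAME_CATEGORIES))
    percent <- 100 * as.numeric(tab) / length(categories)
    names(percent) <- FRAME_CATEGORIES
    n <- length(categories)
  } else {
    stopifnot(all(FRAME_CATEGORIES %in% names(percent)))
    percent <- percent[FRAME_CATEGORIES]
    if (abs(sum(percent) - 100) > 1e-6)
      stop_ampedit("ampedit_param_error",
                   "category percentages must sum to 100 over edited reads")
    n <- NA_integer_
  }
  structure(list(percent = percent, n_edited = n,
                 functional_pct = unname(percent[["inframe_del_no_stop"]] +
                                           percent[["hdr"]])),
            class = "frame_report")
}

#' @export
print.frame_report <- function(x, ...) {
  cat("frame_report (% of edited reads):\n")
  for (nm in names(x$percent))
    cat(sprintf("  %-20s %7.3f\n", nm, x$percent[[nm]]))
  cat(sprintf("  %-20s %7.3f\n", "functional ORF", x$functional_pct))
  invisible(x)
}

#' Functional-ORF percentage of edited reads
#'
#' The roll-up of edited reads able to express a functional protein:
#' in-frame deletions lacking the premature stop plus pure HDR reads
#' (mixed HDR/NHEJ reads are folded into the indel categories, not the HDR
#' bar), as a percentage of edited reads.
#'
#' @param report a [frame_report()].
#' @return numeric percentage of edited reads.
#' @export
functional_orf_fraction <- function(report) {
  stopifnot(inherits(report, "frame_report"))
  report$functional_pct
}

#' Frame-analyze the edited reads of a classified sample
#'
#' @param classified a `classified_reads` object from
#'   [classify_amplicon_reads()].
#' @param spec the [amplicon_spec()].
#' @return a list with `per_read` (data.frame `read_id`, `label`,
#'   `category`, `functional`) and `report` (a [frame_report()]), or `NULL`
#'   when no aligned edited reads exist.
#' @export
frame_analyze <- function(classified, spec) {
  stopifnot(inherits(classified, "classified_reads"))
  lab <- classified$labels
  edited <- lab$label %in% c("nhej", "hdr", "mixed")
  if (!any(edited)) return(NULL)
  calls <- classified$calls
  idx <- match(lab$read_id[edited], calls$read_id)
  vindex <- calls_variant_index(calls)
  cats <- character(sum(edited))
  for (k in seq_along(idx)) {
    cats[k] <- frame_consequence(extract_call(calls, idx[k], vindex),
                                 lab$label[edited][k], spec)
  }
  per_read <- data.frame(read_id = lab$read_id[edited],
                         label = lab$label[edited], category = cats,
                         functional = cats %in% c("inframe_del_no_stop", "hdr"),
                         stringsAsFactors = FALSE)
  list(per_read = per_read, report = frame_report(categories = cats))
}
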