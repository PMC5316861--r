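# Read QC, global alignment of reads to their amplicon, and indel calling
# under the quantification-window / end-exclusion rules.
#
# Alignment scoring deliberately favours one contiguous indel over scattered
# gaps (match +5, mismatch -4, gap open -12, gap extend -1), matching the
# spectra produced by nuclease editing of a short amplicon. All indels are
# left-normalized before window overlap is evaluated, so calls are invariant
# to where the aligner happens to place a gap inside a repeat.

#' Alignment and calling parameters
#'
#' @param match,mismatch,gap_open,gap_ext affine alignment scores.
#' @param min_identity reads below this identity are flagged unalignable and
#'   discarded downstream (default 0.6).
#' @param min_sub_run minimum length of a contiguous substitution run for it
#'   to count as an editing event inside a quantification window; lone
#'   substitutions are ignored to guard against sequencing error (default 2).
#' @param gapless_max_mm fast-path bound: a full-length read whose direct
#'   comparison to the amplicon shows at most this many mismatches is called
#'   without dynamic programming (default 8).
#' @return a list of class `align_params`.
#' @export
align_params <- function(match = 5, mismatch = -4, gap_open = 12, gap_ext = 1,
                         min_identity = 0.6, min_sub_run = 2L,
                         gapless_max_mm = 8L) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, min_identity = min_identity,
                 min_sub_run = as.integer(min_sub_run),
                 gapless_max_mm = as.integer(gapless_max_mm)),
            class = "align_params")
}

#' Quality-trim and length-filter phred33 reads
#'
#' Trims the maximal run of 3' bases whose quality is below `q_threshold`
#' (scanning from the 3' end, trimming stops at the first base at or above
#' the threshold), then drops reads shorter than `min_length`.
#'
#' @param reads named character vector of read sequences.
#' @param quals matching phred33 quality strings.
#' @param q_threshold phred quality threshold (default 30).
#' @param min_length minimum post-trim read length (default 50).
#' @return list with `reads`, `quals` (trimmed, survivors only) and `stats`
#'   (`kept`, `trimmed`, `dropped`).
#' @export
trim_and_filter <- function(reads, quals, q_threshold = 30L, min_length = 50L) {
  stopifnot(length(reads) == length(quals))
  keep_len <- integer(length(reads))
  for (i in seq_along(reads)) {
    q <- utf8ToInt(quals[[i]])
    if (any(q < 33L))
      stop_ampedit("ampedit_encoding_error",
                   "quality string contains non-phred33 characters")
    q <- q - 33L
    ok <- which(q >= q_threshold)
    keep_len[i] <- if (length(ok)) max(ok) else 0L
  }
  trimmed <- sum(keep_len < nchar(reads))
  out_reads <- substr(reads, 1, keep_len)
  out_quals <- substr(quals, 1, keep_len)
  keep <- keep_len >= min_length
  list(reads = out_reads[keep], quals = out_quals[keep],
       stats = list(kept = sum(keep), trimmed = trimmed,
                    dropped = sum(!keep)))
}

#' Merge overlapping read pairs by exact-overlap consensus
#'
#' Pairs overlapping by at least `min_overlap` nt with at most
#' `max_mismatch` mismatches are merged (base of the higher-quality read at
#' conflicts); otherwise the forward read alone is returned.
#'
#' @param r1,r2 forward and reverse read sequences (r2 as sequenced, i.e.
#'   reverse-complement orientation).
#' @param q1,q2 phred33 quality strings.
#' @param min_overlap minimum overlap in nt (default 20).
#' @param max_mismatch maximum mismatches tolerated in the overlap (default 2).
#' @return list with `reads` (merged or forward-only sequences), `quals`,
#'   and `merged` (logical vector).
#' @export
merge_pairs <- function(r1, q1, r2, q2, min_overlap = 20L, max_mismatch = 2L) {
  n <- length(r1)
  out <- character(n); oq <- character(n); merged <- logical(n)
  r2rc <- revcomp(r2)
  q2r <- vapply(q2, function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE)
  for (i in seq_len(n)) {
    a <- strsplit(r1[i], "")[[1]]; b <- strsplit(r2rc[i], "")[[1]]
    qa <- utf8ToInt(q1[i]); qb <- utf8ToInt(q2r[i])
    la <- length(a); lb <- length(b)
    found <- FALSE
    for (o in seq(min(la, lb), min_overlap)) {
      sa <- seq(la - o + 1, la); sb <- seq_len(o)
      mism <- which(a[sa] != b[sb])
      if (length(mism) <= max_mismatch) {
        cons_a <- a[sa]; cons_q <- pmax(qa[sa], qb[sb])
        take_b <- qb[sb] > qa[sa]
        cons_a[take_b] <- b[sb][take_b]
        cons_a[mism][qb[sb][mism] <= qa[sa][mism]] <- a[sa][mism][qb[sb][mism] <= qa[sa][mism]]
        out[i] <- paste(c(a[seq_len(la - o)], cons_a, b[-sb]), collapse = "")
        oq[i] <- intToUtf8(c(qa[seq_len(la - o)], cons_q, qb[-sb]))
        merged[i] <- TRUE; found <- TRUE
        break
      }
    }
    if (!found) { out[i] <- r1[i]; oq[i] <- q1[i] }
  }
  names(out) <- names(r1); names(oq) <- names(r1)
  list(reads = out, quals = oq, merged = merged)
}

# Left-normalize a deletion [pos, pos+len) on `seq` (0-based).
left_normalize_del <- function(seq, pos, len, lower = 0L) {
  while (pos > lower &&
         substr(seq, pos, pos) == substr(seq, pos + len, pos + len)) {
    pos <- pos - 1L
  }
  pos
}

# Left-normalize an insertion of `ins` at inter-base `pos` on `seq`;
# returns list(pos, ins) after rotating the inserted string as it shifts.
left_normalize_ins <- function(seq, pos, ins, lower = 0L) {
  k <- nchar(ins)
  while (pos > lower &&
         substr(seq, pos, pos) == substr(ins, k, k)) {
    ins <- paste0(substr(ins, k, k), substr(ins, 1, k - 1))
    pos <- pos - 1L
  }
  list(pos = pos, ins = ins)
}

# Parse one gapped alignment (aligned pattern/subject strings of equal
# length, subject starting at 0-based sub0 on the amplicon) into a variant
# table with merged runs: columns position, kind (ins/del/sub), length, alt.
parse_gapped <- function(ap, as_, sub0, amplicon) {
  pa <- strsplit(ap, "")[[1]]
  sa <- strsplit(as_, "")[[1]]
  m <- length(pa)
  sub_gap <- sa == "-"
  pat_gap <- pa == "-"
  # amplicon position at each column (position of the subject base, or of
  # the next subject base for insertion columns)
  apos <- sub0 + cumsum(!sub_gap) - !sub_gap  # 0-based; ins columns point at next base
  state <- ifelse(sub_gap, "ins", ifelse(pat_gap, "del",
                  ifelse(pa == sa, "match", "sub")))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  vars <- list()
  for (j in seq_along(r$values)) {
    st <- r$values[j]
    if (st == "match") next
    i0 <- starts[j]; i1 <- ends[j]
    if (st == "ins") {
      vars[[length(vars) + 1]] <- list(position = apos[i0], kind = "ins",
                                       length = i1 - i0 + 1L,
                                       alt = paste(pa[i0:i1], collapse = ""))
    } else if (st == "del") {
      vars[[length(vars) + 1]] <- list(position = apos[i0], kind = "del",
                                       length = i1 - i0 + 1L, alt = "")
    } else {
      vars[[length(vars) + 1]] <- list(position = apos[i0], kind = "sub",
                                       length = i1 - i0 + 1L,
                                       alt = paste(pa[i0:i1], collapse = ""))
    }
  }
  n_match <- sum(state == "match")
  span <- c(sub0, sub0 + sum(!sub_gap))  # [start, end) on amplicon
  if (length(vars)) {
    v <- do.call(rbind, lapply(vars, as.data.frame))
  } else {
    v <- data.frame(position = integer(0), kind = character(0),
                    length = integer(0), alt = character(0))
  }
  list(variants = v, n_match = n_match, n_cols = m, span = span)
}

# Normalize, annotate exclusion zones, and order a variant table.
finalize_variants <- function(v, amplicon, len, ee) {
  if (nrow(v)) {
    v$position <- as.integer(v$position)
    v$length <- as.integer(v$length)
    for (i in seq_len(nrow(v))) {
      if (v$kind[i] == "del") {
        v$position[i] <- left_normalize_del(amplicon, v$position[i], v$length[i])
      } else if (v$kind[i] == "ins") {
        nrm <- left_normalize_ins(amplicon, v$position[i], v$alt[i])
        v$position[i] <- nrm$pos; v$alt[i] <- nrm$ins
      }
    }
    v <- v[order(v$position, v$kind), , drop = FALSE]
    v$excluded <- ifelse(v$kind == "ins",
                         v$position < ee | v$position > len - ee,
                         v$position + v$length <= ee | v$position >= len - ee)
  } else {
    v$excluded <- logical(0)
  }
  v
}

# Rightmost equivalent placement of a stored (left-normalized) indel.
right_normalize_del <- function(seq, pos, len, upper) {
  while (pos + len < upper &&
         substr(seq, pos + 1, pos + 1) == substr(seq, pos + len + 1, pos + len + 1))
    pos <- pos + 1L
  pos
}

right_normalize_ins <- function(seq, pos, ins, upper) {
  while (pos < upper &&
         substr(seq, pos + 1, pos + 1) == substr(ins, 1, 1)) {
    ins <- paste0(substr(ins, 2, nchar(ins)), substr(ins, 1, 1))
    pos <- pos + 1L
  }
  pos
}

# Window-hit logical vector (one element per cut site) for one variant
# table. Indel placement inside a repeat is ambiguous, so the overlap test
# uses the indel's full placement-equivalence envelope (leftmost to
# rightmost normalization): the call is then invariant to where the aligner
# put the gap.
window_hits_for <- function(v, spec, min_sub_run) {
  hw <- spec$quant_halfwidth
  n <- spec$length
  if (!nrow(v)) return(rep(FALSE, length(spec$cut_sites)))
  qual <- !v$excluded &
    (v$kind %in% c("ins", "del") |
       (v$kind == "sub" & v$length >= min_sub_run))
  if (!any(qual)) return(rep(FALSE, length(spec$cut_sites)))
  vv <- v[qual, , drop = FALSE]
  lo <- vv$position
  hi <- integer(nrow(vv))
  for (i in seq_len(nrow(vv))) {
    hi[i] <- switch(vv$kind[i],
      del = right_normalize_del(spec$sequence, vv$position[i], vv$length[i], n) +
        vv$length[i] - 1L,
      ins = right_normalize_ins(spec$sequence, vv$position[i], vv$alt[i], n),
      sub = vv$position[i] + vv$length[i] - 1L)
  }
  is_ins <- vv$kind == "ins"
  vapply(spec$cut_sites, function(s) {
    w_lo <- ifelse(is_ins, s - hw, s - hw)
    w_hi <- ifelse(is_ins, s + hw, s + hw - 1L)
    any(lo <= w_hi & hi >= w_lo)
  }, logical(1))
}

#' Align a set of reads to an amplicon and call variants
#'
#' Performs end-gap-free global alignment of each read against the amplicon
#' under affine gap scoring (reverse-complement orientation auto-detected by
#' best score), extracts insertion/deletion/substitution runs,
#' left-normalizes indels, and evaluates quantification-window overlap and
#' end-exclusion rules. Full-length reads whose direct base comparison shows
#' few mismatches are called without dynamic programming.
#'
#' @param reads named character vector of read sequences.
#' @param spec an [amplicon_spec()].
#' @param params an [align_params()].
#' @return an object of class `edit_calls`: per-read vectors (`read_id`,
#'   `identity`, `unalignable`, `covers_anchor`, `net_length_change`,
#'   `aligned_start`, `aligned_end`, `orientation`), a logical
#'   `window_hits` matrix (reads x cut sites), and a `variants` data.frame
#'   (`read_id`, `position`, `kind`, `length`, `alt`, `excluded`).
#' @export
align_reads <- function(reads, spec, params = align_params()) {
  stopifnot(inherits(spec, "amplicon_spec"))
  n <- length(reads)
  ids <- names(reads) %||% sprintf("read_%06d", seq_len(n))
  amplicon <- spec$sequence
  len <- spec$length
  ee <- spec$end_exclusion

  identity <- numeric(n); unalignable <- logical(n)
  a_start <- integer(n); a_end <- integer(n)
  net <- integer(n); orient <- rep("+", n)
  var_list <- vector("list", n)
  empty_v <- data.frame(position = integer(0), kind = character(0),
                        length = integer(0), alt = character(0),
                        excluded = logical(0))

  too_short <- nchar(reads) < 30L
  need_dp <- rep(TRUE, n)
  amp_chars <- strsplit(amplicon, "")[[1]]
  rc_cache <- NULL

  # Fast path 1: read identical to the amplicon.
  idx <- which(reads == amplicon)
  if (length(idx)) {
    identity[idx] <- 1; a_start[idx] <- 0L; a_end[idx] <- len
    var_list[idx] <- list(empty_v)
    need_dp[idx] <- FALSE
  }

  # Fast path 2: full-length read, few mismatches, no gaps needed.
  cand <- which(need_dp & nchar(reads) == len & !too_short)
  for (i in cand) {
    ch <- strsplit(reads[i], "")[[1]]
    mm <- which(ch != amp_chars)
    use <- ch
    if (length(mm) > params$gapless_max_mm) {
      rc <- revcomp(reads[i])
      ch2 <- strsplit(rc, "")[[1]]
      mm2 <- which(ch2 != amp_chars)
      if (length(mm2) <= params$gapless_max_mm) {
        mm <- mm2; use <- ch2; orient[i] <- "-"
      } else next
    }
    v <- empty_v
    if (length(mm)) {
      # group contiguous mismatch positions into substitution runs
      grp <- cumsum(c(TRUE, diff(mm) != 1L))
      v <- do.call(rbind, lapply(split(mm, grp), function(pp) {
        data.frame(position = pp[1] - 1L, kind = "sub",
                   length = length(pp),
                   alt = paste(use[pp], collapse = ""))
      }))
      rownames(v) <- NULL
    }
    v <- finalize_variants(v, amplicon, len, ee)
    var_list[[i]] <- v
    identity[i] <- (len - length(mm)) / len
    a_start[i] <- 0L; a_end[i] <- len
    need_dp[i] <- FALSE
  }

  # Fast path 3: exact substring of the amplicon (either orientation).
  cand <- which(need_dp & nchar(reads) < len & !too_short)
  for (i in cand) {
    p <- regexpr(reads[i], amplicon, fixed = TRUE)
    o <- "+"
    if (p < 0) {
      p <- regexpr(revcomp(reads[i]), amplicon, fixed = TRUE)
      o <- "-"
    }
    if (p > 0) {
      identity[i] <- 1; orient[i] <- o
      a_start[i] <- p - 1L; a_end[i] <- p - 1L + nchar(reads[i])
      var_list[[i]] <- empty_v
      need_dp[i] <- FALSE
    }
  }

  # Dynamic programming for the rest.
  idx <- which(need_dp & !too_short)
  if (length(idx)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(params$match, params$mismatch)
    subj <- Biostrings::DNAString(amplicon)
    pats_f <- Biostrings::DNAStringSet(reads[idx])
    pats_r <- Biostrings::reverseComplement(pats_f)
    aln_f <- Biostrings::pairwiseAlignment(pats_f, subj, type = "global-local",
                                           substitutionMatrix = mat,
                                           gapOpening = params$gap_open,
                                           gapExtension = params$gap_ext)
    aln_r <- Biostrings::pairwiseAlignment(pats_r, subj, type = "global-local",
                                           substitutionMatrix = mat,
                                           gapOpening = params$gap_open,
                                           gapExtension = params$gap_ext)
    sc_f <- BiocGenerics::score(aln_f); sc_r <- BiocGenerics::score(aln_r)
    use_r <- sc_r > sc_f
    ap_f <- as.character(Biostrings::pattern(aln_f))
    as_f <- as.character(Biostrings::subject(aln_f))
    ap_r <- as.character(Biostrings::pattern(aln_r))
    as_r <- as.character(Biostrings::subject(aln_r))
    st_f <- BiocGenerics::start(Biostrings::subject(aln_f))
    st_r <- BiocGenerics::start(Biostrings::subject(aln_r))
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (use_r[k]) {
        parsed <- parse_gapped(ap_r[k], as_r[k], st_r[k] - 1L, amplicon)
        orient[i] <- "-"
      } else {
        parsed <- parse_gapped(ap_f[k], as_f[k], st_f[k] - 1L, amplicon)
      }
      # percent identity over alignment length (columns incl. gaps)
      identity[i] <- if (parsed$n_cols > 0) parsed$n_match / parsed$n_cols else 0
      a_start[i] <- parsed$span[1]; a_end[i] <- parsed$span[2]
      var_list[[i]] <- finalize_variants(parsed$variants, amplicon, len, ee)
    }
  }

  unalignable <- too_short | identity < params$min_identity
  var_list[too_short] <- list(empty_v)

  wh <- matrix(FALSE, n, length(spec$cut_sites),
               dimnames = list(NULL, names(spec$cut_sites)))
  for (i in seq_len(n)) {
    v <- var_list[[i]]
    if (nrow(v)) {
      net[i] <- as.integer(sum(v$length[v$kind == "ins"]) -
                             sum(v$length[v$kind == "del"]))
      if (length(spec$cut_sites))
        wh[i, ] <- window_hits_for(v, spec, params$min_sub_run)
    }
  }

  covers_anchor <- rep(TRUE, n)
  if (!is.null(spec$template_span)) {
    ts <- spec$template_span
    covers_anchor <- a_start < ts[1] | a_end > ts[2]
  }

  nv <- vapply(var_list, nrow, integer(1))
  variants <- if (any(nv > 0)) {
    vdf <- do.call(rbind, var_list[nv > 0])
    vdf$read_id <- rep(ids[nv > 0], nv[nv > 0])
    rownames(vdf) <- NULL
    vdf[, c("read_id", "position", "kind", "length", "alt", "excluded")]
  } else {
    cbind(data.frame(read_id = character(0)), empty_v)
  }

  structure(list(read_id = ids, identity = identity,
                 unalignable = unalignable, covers_anchor = covers_anchor,
                 net_length_change = net, aligned_start = a_start,
                 aligned_end = a_end, orientation = orient,
                 window_hits = wh, variants = variants,
                 spec_name = spec$name, params = params),
            class = "edit_calls")
}

#' @export
print.edit_calls <- function(x, ...) {
  cat(sprintf("edit_calls: %d reads vs amplicon '%s'; %d unalignable; %d variant rows\n",
              length(x$read_id), x$spec_name, sum(x$unalignable),
              nrow(x$variants)))
  invisible(x)
}

#' Align a single read and return its edit call
#'
#' Single-read convenience wrapper around [align_reads()].
#'
#' @param read DNA string (length >= 30 nt).
#' @param spec an [amplicon_spec()].
#' @param params an [align_params()].
#' @return a list with the per-read call fields (`variants`, `window_hits`,
#'   `identity`, `covers_anchor`, `net_length_change`, `unalignable`,
#'   `aligned_start`, `aligned_end`, `orientation`).
#' @export
align_read <- function(read, spec, params = align_params()) {
  if (nchar(read) < 30L)
    stop_ampedit("ampedit_input_error", "read must be at least 30 nt")
  calls <- align_reads(c(read = read), spec, params)
  extract_call(calls, 1L)
}

# Row indices of calls$variants grouped by read_id (fast per-read lookup).
calls_variant_index <- function(calls) {
  split(seq_len(nrow(calls$variants)),
        factor(calls$variants$read_id, levels = unique(calls$variants$read_id)))
}

# Pull read i out of an edit_calls object as a single-read call. `vindex`
# (from calls_variant_index) avoids a full variant-table scan per read.
extract_call <- function(calls, i, vindex = NULL) {
  v <- if (is.null(vindex)) {
    calls$variants[calls$variants$read_id == calls$read_id[i], , drop = FALSE]
  } else {
    rows <- vindex[[calls$read_id[i]]]
    if (is.null(rows)) calls$variants[0, , drop = FALSE]
    else calls$variants[rows, , drop = FALSE]
  }
  rownames(v) <- NULL
  list(read_id = calls$read_id[i], variants = v,
       window_hits = calls$window_hits[i, ],
       identity = calls$identity[i],
       covers_anchor = calls$covers_anchor[i],
       net_length_change = calls$net_length_change[i],
       unalignable = calls$unalignable[i],
       aligned_start = calls$aligned_start[i],
       aligned_end = calls$aligned_end[i],
       orientation = calls$orientation[i])
}

#' Fraction of covering reads carrying a window-overlapping edit at one site
#'
#' The denominator is the set of alignable reads whose aligned span covers
#' the full quantification window of the site; the numerator those with a
#' qualifying variant (any indel, or a substitution run of at least the
#' configured length) overlapping the window. Variants inside the
#' end-exclusion zones never count.
#'
#' @param calls an `edit_calls` object from [align_reads()].
#' @param spec the [amplicon_spec()] the calls were made against.
#' @param site_index 1-based index into `spec$cut_sites`.
#' @return the edited fraction (numeric scalar in [0, 1]).
#' @export
site_edit_fraction <- function(calls, spec, site_index) {
  stopifnot(inherits(calls, "edit_calls"),
            site_index >= 1, site_index <= length(spec$cut_sites))
  s <- spec$cut_sites[site_index]
  hw <- spec$quant_halfwidth
  covering <- !calls$unalignable &
    calls$aligned_start <= s - hw & calls$aligned_end >= s + hw
  if (!any(covering))
    stop_ampedit("ampedit_denominator_error",
                 "no alignable reads cover the site's quantification window")
  sum(calls$window_hits[covering, site_index]) / sum(covering)
}
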