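# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

is_iupac <- function(x) {
  grepl("^[ACGTRYSWKMBDHVN]+$", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
iupac_match_base <- function(pattern_base, base) {
  base %in% IUPAC_MAP[[pattern_base]]
}

# TRUE where the IUPAC pattern (split into chars) matches the site chars.
iupac_match_chars <- function(pattern_chars, site_chars) {
  if (length(pattern_chars) != length(site_chars)) return(FALSE)
  all(mapply(function(p, b) b %in% IUPAC_MAP[[p]], pattern_chars, site_chars))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Sense (non-stop) codons only, so generated coding sequence carries no
# premature stop other than the one planted deliberately.
sense_codons <- function() {
  codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

random_coding <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

translate_dna <- function(x) {
  n <- floor(nchar(x) / 3)
  if (n == 0) return("")
  codons <- substring(x, seq(1, by = 3, length.out = n), seq(3, by = 3, length.out = n))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

substr_set <- function(x, pos0, value) {
  # Replace nchar(value) characters starting at 0-based pos0.
  paste0(substr(x, 1, pos0), value, substr(x, pos0 + nchar(value) + 1, nchar(x)))
}

#' Derive a deterministic per-stage seed from a single run seed
#'
#' All randomness in the package flows from one integer seed; independent
#' stages (simulation per amplicon, etc.) use substreams derived by stable
#' string hashing of the stage name, so adding or reordering stages does not
#' perturb the others.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m + h) %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ampedit <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "ampedit_error")))
}
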