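# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate `expr` under a local RNG seeded with `seed`; the caller's RNG
# state is untouched. seed = NULL means: use whatever RNG state is current.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Deterministic fan-out of one user-facing seed into per-stage streams.
# Keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + stage * 104729) %% .Machine$integer.max)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)
}

check_count <- function(x, name, min = 1) {
  if (!is_count(x) || x < min) {
    stop_usage("`%s` must be an integer >= %d (got %s)", name, min,
               paste(format(x), collapse = ","))
  }
  as.integer(x)
}

roman_chrom <- function(i) paste0("chr", as.character(utils::as.roman(i)))

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# All 61 sense codons.
sense_codons <- function() {
  all <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste0,
               collapse = "")
  setdiff(all, STOP_CODONS)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}
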