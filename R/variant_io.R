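# Variant / pooled-frequency data model and file formats.
#
# The in-memory representation of a pooled variant table is an ordinary
# tibble with one row per (pool, variant) and columns:
#   pool_id     pool label ("A", "B", ...)
#   chrom       chromosome name ("chrXVI" style)
#   pos         1-based position of the first altered base
#   ref, alt    altered bases on the plus strand. SNV: single bases.
#               Deletion: ref = deleted bases, alt = "". Insertion:
#               ref = "", alt = inserted bases.
#   change_label  human-readable DNA change ("A > G", "delACTT", "insT")
#   gene_id     gene name or NA
#   annotation  free-text effect annotation or NA
#   frequency   pooled allele frequency in [0, 1]
#   depth       read depth or NA
#   anchor      VCF anchor base for indels (kept so VCF round-trips are
#               exact); NA when unknown
#
# Indel coordinates follow the shorthand dialect in which `pos` is the
# first deleted/inserted base; conversion to and from the left-aligned
# VCF anchor representation shifts by one.

#' Build a DNA change label from ref/alt alleles
#'
#' Renders the shorthand used in printed variant tables: `"A > G"` for
#' substitutions, `"delACTT"` for deletions and `"insA"` for insertions.
#'
#' @param ref,alt Character vectors of plus-strand alleles; a deletion has
#'   `alt = ""`, an insertion `ref = ""`.
#' @return Character vector of labels.
#' @export
#' @examples
#' change_label(c("A", "ACTT", ""), c("G", "", "T"))
change_label <- function(ref, alt) {
  mapply(function(r, a) {
    if (nchar(r) > 0 && nchar(a) == 0) {
      paste0("del", r)
    } else if (nchar(r) == 0 && nchar(a) > 0) {
      paste0("ins", a)
    } else if (nchar(r) > 0 && nchar(a) > 0) {
      paste0(r, " > ", a)
    } else {
      stop_usage("ref and alt cannot both be empty")
    }
  }, ref, alt, USE.NAMES = FALSE)
}

#' Parse a DNA change label into ref/alt alleles
#'
#' Inverse of [change_label()]. Accepts `"A > G"` (spaces optional),
#' `"delACTT"` and `"insT"`.
#'
#' @param label Character vector of change labels.
#' @return A tibble with columns `ref` and `alt`.
#' @export
parse_change <- function(label) {
  out <- lapply(label, function(x) {
    x <- trimws(x)
    if (grepl("^del[ACGTN]+$", x)) {
      c(sub("^del", "", x), "")
    } else if (grepl("^ins[ACGTN]+$", x)) {
      c("", sub("^ins", "", x))
    } else if (grepl("^[ACGTN]+\\s*>\\s*[ACGTN]+$", x)) {
      parts <- strsplit(x, ">")[[1]]
      trimws(parts)
    } else {
      stop_usage("unparseable DNA change token: '%s'", x)
    }
  })
  tibble(ref = vapply(out, `[`, "", 1), alt = vapply(out, `[`, "", 2))
}

#' Construct a pooled variant frequency table
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (see package
#'   conventions: `pos` is the first altered base; deletions have
#'   `alt = ""`).
#' @param frequency Pooled allele frequency in `[0, 1]`.
#' @param pool_id Pool label (recycled).
#' @param gene_id,annotation,depth,anchor Optional per-variant metadata.
#' @return A validated pooled variant tibble.
#' @export
pool_table <- function(chrom, pos, ref, alt, frequency, pool_id = "pool1",
                       gene_id = NA_character_, annotation = NA_character_,
                       depth = NA_integer_, anchor = NA_character_) {
  tbl <- tibble(
    pool_id = as.character(pool_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    change_label = change_label(toupper(ref), toupper(alt)),
    gene_id = as.character(gene_id), annotation = as.character(annotation),
    frequency = as.numeric(frequency),
    depth = as.integer(depth), anchor = as.character(anchor)
  )
  validate_pool_table(tbl)
}

#' Validate a pooled variant table
#'
#' Checks positions, allele classes, frequency bounds and per-pool
#' uniqueness of (chrom, pos, alt).
#'
#' @param tbl A pooled variant tibble.
#' @return The table, invisibly unchanged, for piping.
#' @export
validate_pool_table <- function(tbl) {
  need <- c("pool_id", "chrom", "pos", "ref", "alt", "frequency")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop_usage("pool table is missing columns: %s", paste(miss, collapse = ", "))
  }
  if (nrow(tbl) == 0) return(tbl)
  if (any(tbl$pos < 1)) stop_usage("positions must be >= 1")
  bad_freq <- !is.na(tbl$frequency) & (tbl$frequency < 0 | tbl$frequency > 1)
  if (any(bad_freq)) stop_usage("frequencies must lie in [0, 1]")
  if (any(nchar(tbl$ref) == 0 & nchar(tbl$alt) == 0)) {
    stop_usage("ref and alt cannot both be empty")
  }
  key <- paste(tbl$pool_id, tbl$chrom, tbl$pos, tbl$alt, sep = "\r")
  if (anyDuplicated(key)) {
    stop_usage("duplicate (chrom, pos, alt) within a pool")
  }
  tbl
}

variant_key <- function(tbl) paste(tbl$chrom, tbl$pos, tbl$ref, tbl$alt, sep = ":")

# ---- VCF ------------------------------------------------------------------

#' Read a pooled VCF into a variant frequency table
#'
#' Consumes VCF v4.2 as produced by pooled-continuous variant callers, with
#' the pooled allele frequency in the INFO `AF` key (one value per ALT
#' allele) and optionally total depth in `DP`. Multi-allelic sites are split
#' into biallelic records. Left-aligned indels are converted to the
#' first-altered-base coordinate convention (the VCF anchor base is kept in
#' the `anchor` column so that [write_vcf()] round-trips exactly).
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param pool_id Pool label for all records; defaults to the file name
#'   without extension.
#' @return A pooled variant tibble.
#' @export
read_vcf <- function(path, pool_id = NULL) {
  pool_id <- pool_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0) {
    return(pool_table(character(), integer(), character(), character(),
                      numeric(), pool_id = character()))
  }
  if (is.null(dim(fix))) fix <- t(fix)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  af_str <- vapply(fix$INFO, function(s) {
    hit <- regmatches(s, regexpr("(?:^|;)AF=[^;]*", s))
    if (length(hit) == 0) NA_character_ else sub("^;?AF=", "", hit)
  }, character(1), USE.NAMES = FALSE)
  dp_str <- vapply(fix$INFO, function(s) {
    hit <- regmatches(s, regexpr("(?:^|;)DP=[^;]*", s))
    if (length(hit) == 0) NA_character_ else sub("^;?DP=", "", hit)
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(af_str)) {
    stop_usage("VCF data line %d has no AF INFO key in %s",
               which(is.na(af_str))[1], path)
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- as.numeric(strsplit(af_str[i], ",", fixed = TRUE)[[1]])
    if (length(afs) == 1 && length(alts) > 1) afs <- rep(afs, length(alts))
    if (length(afs) != length(alts)) {
      stop_usage("VCF data line %d: %d ALT alleles but %d AF values",
                 i, length(alts), length(afs))
    }
    dp <- suppressWarnings(as.integer(dp_str[i]))
    do.call(rbind, lapply(seq_along(alts), function(j) {
      vcf_to_canonical(fix$CHROM[i], as.integer(fix$POS[i]), fix$REF[i],
                       alts[j], afs[j], dp)
    }))
  })
  rows <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  pool_table(
    chrom = rows$chrom, pos = as.integer(rows$pos), ref = rows$ref,
    alt = rows$alt, frequency = as.numeric(rows$frequency),
    pool_id = pool_id, depth = as.integer(rows$depth), anchor = rows$anchor
  )
}

# One VCF (CHROM, POS, REF, ALT) record -> canonical first-altered-base row.
vcf_to_canonical <- function(chrom, pos, ref, alt, af, dp) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) > 1 && nchar(alt) >= 1 &&
      substr(ref, 1, nchar(alt)) == alt && nchar(alt) == 1) {
    # deletion with one anchor base
    c(chrom = chrom, pos = pos + 1L, ref = substr(ref, 2, nchar(ref)),
      alt = "", frequency = af, depth = dp, anchor = substr(ref, 1, 1))
  } else if (nchar(alt) > 1 && nchar(ref) == 1 &&
             substr(alt, 1, 1) == ref) {
    # insertion with one anchor base
    c(chrom = chrom, pos = pos + 1L, ref = "",
      alt = substr(alt, 2, nchar(alt)), frequency = af, depth = dp,
      anchor = ref)
  } else {
    c(chrom = chrom, pos = pos, ref = ref, alt = alt, frequency = af,
      depth = dp, anchor = NA_character_)
  }
}

#' Write a pooled variant table as VCF v4.2
#'
#' Emits one data line per record with the pooled allele frequency in the
#' INFO `AF` key and depth (when present) in `DP`. Indels are emitted
#' left-aligned with an anchor base: the anchor recorded by [read_vcf()] if
#' the record came from a VCF, otherwise the IUPAC placeholder `N` (the
#' reference genome is not required). An `EFF` INFO key is written for
#' records carrying a non-missing `annotation`.
#'
#' @param tbl A pooled variant tibble (one pool).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(tbl, path) {
  validate_pool_table(tbl)
  if (length(unique(tbl$pool_id)) > 1) {
    stop_usage("write_vcf() writes one pool per file; got pools: %s",
               paste(unique(tbl$pool_id), collapse = ", "))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=supscreen",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Pooled allele frequency">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Coding effect label">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  lines <- character(nrow(tbl))
  if (nrow(tbl) > 0) {
    for (i in seq_len(nrow(tbl))) {
      r <- tbl[i, ]
      anch <- if (!is.null(r$anchor) && !is.na(r$anchor)) r$anchor else "N"
      if (nchar(r$alt) == 0) {          # deletion
        pos <- r$pos - 1L; ref <- paste0(anch, r$ref); alt <- anch
      } else if (nchar(r$ref) == 0) {   # insertion
        pos <- r$pos - 1L; ref <- anch; alt <- paste0(anch, r$alt)
      } else {
        pos <- r$pos; ref <- r$ref; alt <- r$alt
      }
      info <- paste0("AF=", format(r$frequency, digits = 10))
      if (!is.na(r$depth)) info <- paste0(info, ";DP=", r$depth)
      if (!is.null(r$annotation) && !is.na(r$annotation)) {
        info <- paste0(info, ";EFF=", gsub("[;=[:space:]]", "_", r$annotation))
      }
      lines[i] <- paste(r$chrom, pos, ".", ref, alt, ".", ".", info,
                        sep = "\t")
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# ---- printed-table dialect ------------------------------------------------

#' Read a printed-style pooled variant TSV
#'
#' Parses the tab-separated dialect used in printed suppressor-screen
#' tables: columns `chromosome_position` (e.g. `"chrXVI_65946"`),
#' `dna_change` (`"A > G"`, `"delACTT"`, `"delT"`), `annotation`, `gene`
#' (e.g. `"CLN2 (YPL256C)"`), `description` and `frequency`. The position
#' is taken as the first altered base.
#'
#' @param path Path to the TSV file. Column names are matched
#'   case-insensitively; `description` is optional.
#' @param pool_id Pool label; defaults to the file name without extension.
#' @return A pooled variant tibble.
#' @export
read_table1_tsv <- function(path, pool_id = NULL) {
  pool_id <- pool_id %||% sub("\\.[tc]sv$", "", basename(path))
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(gsub("[^a-z_]", "_", tolower(names(raw))))
  need <- c("chromosome_position", "dna_change", "frequency")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop_usage("TSV is missing columns: %s", paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(pool_table(character(), integer(), character(), character(),
                      numeric(), pool_id = character()))
  }
  cp <- raw$chromosome_position
  if (!all(grepl("^.+_[0-9]+$", cp))) {
    stop_usage("unparseable chromosome_position token: '%s'",
               cp[!grepl("^.+_[0-9]+$", cp)][1])
  }
  chrom <- sub("_[0-9]+$", "", cp)
  pos <- as.integer(sub("^.*_", "", cp))
  alleles <- parse_change(raw$dna_change)
  gene_id <- if ("gene" %in% names(raw)) {
    g <- gsub("\\*", "", raw$gene)
    trimws(sub("\\s*\\(.*$", "", g))
  } else NA_character_
  pool_table(
    chrom = chrom, pos = pos, ref = alleles$ref, alt = alleles$alt,
    frequency = as.numeric(raw$frequency), pool_id = pool_id,
    gene_id = gene_id,
    annotation = if ("annotation" %in% names(raw)) raw$annotation
                 else NA_character_
  )
}

#' Write a pooled variant table as TSV
#'
#' Emits the same printed-table dialect that [read_table1_tsv()] reads,
#' with an extra `depth` column when depths are present.
#'
#' @param tbl A pooled variant tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pool_tsv <- function(tbl, path) {
  validate_pool_table(tbl)
  out <- data.frame(
    chromosome_position = paste0(tbl$chrom, "_", tbl$pos),
    dna_change = tbl$change_label,
    annotation = ifelse(is.na(tbl$annotation), "", tbl$annotation),
    gene = ifelse(is.na(tbl$gene_id), "", tbl$gene_id),
    frequency = tbl$frequency,
    stringsAsFactors = FALSE
  )
  if (!all(is.na(tbl$depth))) out$depth <- tbl$depth
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene models ----------------------------------------------------------

#' Read single-interval gene models with their coding sequences
#'
#' Loads CDS intervals from a BED12 or GFF3 file (single-interval CDS
#' features) and extracts each coding sequence from the accompanying FASTA,
#' reverse-complementing minus-strand genes into coding orientation.
#'
#' @param path BED12 or GFF3 file. BED gene ids come from the `name`
#'   column; GFF3 ids from the `ID` attribute of `CDS` features.
#' @param fasta_path FASTA with the chromosome sequences named as in
#'   `path`.
#' @return A gene-model tibble with columns `gene_id`, `chrom`,
#'   `cds_start`, `cds_end`, `strand`, `cds_seq` (validated by
#'   [validate_gene_models()]).
#' @export
read_gene_models <- function(path, fasta_path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(GenomicRanges::mcols(gr))) {
    gr <- gr[GenomicRanges::mcols(gr)$type == "CDS"]
    ids <- GenomicRanges::mcols(gr)$ID
  } else {
    ids <- GenomicRanges::mcols(gr)$name
  }
  if (is.null(ids) || anyNA(ids)) stop_usage("gene models lack names/IDs")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  missing_chr <- setdiff(unique(chroms), names(seqs))
  if (length(missing_chr) > 0) {
    stop_usage("FASTA lacks sequences for: %s",
               paste(missing_chr, collapse = ", "))
  }
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  cds <- vapply(seq_along(gr), function(i) {
    s <- Biostrings::subseq(seqs[[chroms[i]]], starts[i], ends[i])
    if (strands[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  genes <- tibble(
    gene_id = as.character(ids), chrom = chroms,
    cds_start = as.integer(starts), cds_end = as.integer(ends),
    strand = strands, cds_seq = cds
  )
  validate_gene_models(genes)
}

#' Validate gene models
#'
#' Enforces the coding-sequence invariants: length divisible by 3, an
#' initiator ATG on the coding strand, and no internal stop codon.
#'
#' @param genes A gene-model tibble (see [read_gene_models()]).
#' @return The validated tibble.
#' @export
validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "cds_start", "cds_end", "strand", "cds_seq")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    stop_usage("gene models missing columns: %s", paste(miss, collapse = ", "))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    n <- nchar(g$cds_seq)
    if (n %% 3 != 0) {
      stop_usage("gene %s: CDS length %d not divisible by 3", g$gene_id, n)
    }
    if (n != g$cds_end - g$cds_start + 1) {
      stop_usage("gene %s: CDS sequence length does not match interval",
                 g$gene_id)
    }
    if (substr(g$cds_seq, 1, 3) != "ATG") {
      stop_usage("gene %s: CDS does not start with ATG", g$gene_id)
    }
    codons <- substring(g$cds_seq, seq(1, n, 3), seq(3, n, 3))
    internal <- codons[-length(codons)]
    if (any(internal %in% STOP_CODONS)) {
      stop_usage("gene %s: internal stop codon at codon %d", g$gene_id,
                 which(internal %in% STOP_CODONS)[1])
    }
  }
  genes
}
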