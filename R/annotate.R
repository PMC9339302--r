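# Minimal coding-effect annotation: classify SNVs and indels against
# single-interval gene models and render codon-level labels in the style
# used in suppressor-screen tables ("K407E", "Y87fs", "Frameshift at T222").
#
# Codon numbering is 1-based from the initiator ATG. For indels the
# reported codon is the one containing the leftmost altered base in coding
# orientation, which for a frameshift is also the first codon at which the
# mutant protein can diverge from wildtype.

EFFECT_CLASSES <- c("missense", "synonymous", "nonsense", "frameshift",
                    "in_frame_indel", "intergenic", "noncoding")

#' Annotate the coding consequence of one variant against one gene model
#'
#' SNVs inside the CDS are classified by translating the affected codon on
#' the coding strand (missense / synonymous / nonsense); indels are
#' frameshifts when their length is not a multiple of 3, in-frame indels
#' otherwise. Variants outside the CDS are `intergenic`. Minus-strand
#' genes are handled in coding orientation (plus-strand alleles are
#' complemented).
#'
#' @param variant A one-row pooled variant tibble (or list) with `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param gene A one-row gene-model tibble (see [read_gene_models()]).
#' @param style `"short"` renders frameshifts as `"Y87fs"`; `"long"` as
#'   `"Frameshift at Y87"`.
#' @return A one-row tibble with `effect_class`, `ref_residue`,
#'   `codon_index`, `alt_residue`, `preserved_residues` (complete codons
#'   upstream of the first affected codon) and `label`.
#' @export
#' @examples
#' gene <- tibble::tibble(gene_id = "G1", chrom = "chrI", cds_start = 1L,
#'                        cds_end = 9L, strand = "+", cds_seq = "ATGAAATGG")
#' annotate(list(chrom = "chrI", pos = 4L, ref = "A", alt = "G"), gene)
annotate <- function(variant, gene, style = c("short", "long")) {
  style <- match.arg(style)
  v <- as.list(variant)
  g <- as.list(gene)
  if (v$chrom != g$chrom) {
    stop_usage("variant on %s but gene %s is on %s", v$chrom, g$gene_id,
               g$chrom)
  }
  n_ref <- nchar(v$ref); n_alt <- nchar(v$alt)
  first <- v$pos
  last <- if (n_ref > 0) v$pos + n_ref - 1L else v$pos
  if (last < g$cds_start || first > g$cds_end) {
    return(effect_row("intergenic", label = "intergenic"))
  }
  minus <- identical(g$strand, "-")
  cds_len <- nchar(g$cds_seq)
  # coding-orientation offset (1-based within CDS) of a plus-strand position
  offset_of <- function(pos) {
    if (minus) g$cds_end - pos + 1L else pos - g$cds_start + 1L
  }
  if (n_ref == 1 && n_alt == 1) {
    off <- offset_of(first)
    if (off < 1 || off > cds_len) {
      return(effect_row("noncoding", label = "noncoding"))
    }
    codon_index <- as.integer(ceiling(off / 3))
    within <- off - 3L * (codon_index - 1L)
    codon <- substr(g$cds_seq, 3 * codon_index - 2, 3 * codon_index)
    ref_cs <- if (minus) comp_base(v$ref) else v$ref
    alt_cs <- if (minus) comp_base(v$alt) else v$alt
    if (substr(codon, within, within) != ref_cs) {
      stop_usage("ref allele %s disagrees with CDS of %s at codon %d",
                 v$ref, g$gene_id, codon_index)
    }
    mutant <- codon
    substr(mutant, within, within) <- alt_cs
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(mutant)
    cls <- if (aa_alt == aa_ref) "synonymous"
           else if (aa_alt == "*") "nonsense" else "missense"
    lbl <- paste0(aa_ref, codon_index, aa_alt)
    return(effect_row(cls, aa_ref, codon_index, aa_alt,
                      preserved = codon_index - 1L, label = lbl))
  }
  # indel: leftmost altered base in coding orientation
  indel_len <- abs(n_ref - n_alt)
  alt_positions <- if (n_ref > 0) first:last else first
  offs <- vapply(alt_positions, offset_of, numeric(1))
  offs <- offs[offs >= 1 & offs <= cds_len]
  if (length(offs) == 0) return(effect_row("noncoding", label = "noncoding"))
  off1 <- min(offs)
  codon_index <- as.integer(ceiling(off1 / 3))
  codon <- substr(g$cds_seq, 3 * codon_index - 2, 3 * codon_index)
  aa_ref <- translate_codon(codon)
  if (indel_len %% 3 != 0) {
    lbl <- if (style == "short") {
      paste0(aa_ref, codon_index, "fs")
    } else {
      paste0("Frameshift at ", aa_ref, codon_index)
    }
    effect_row("frameshift", aa_ref, codon_index,
               preserved = codon_index - 1L, label = lbl)
  } else {
    kind <- if (n_ref > n_alt) "del" else "ins"
    effect_row("in_frame_indel", aa_ref, codon_index,
               preserved = codon_index - 1L,
               label = paste0(aa_ref, codon_index, kind))
  }
}

effect_row <- function(class, ref_residue = NA_character_,
                       codon_index = NA_integer_,
                       alt_residue = NA_character_,
                       preserved = NA_integer_, label = NA_character_) {
  tibble(effect_class = class, ref_residue = ref_residue,
         codon_index = as.integer(codon_index), alt_residue = alt_residue,
         preserved_residues = as.integer(preserved), label = label)
}

#' Annotate every record of a pooled variant table
#'
#' Each variant is matched to the single gene model whose CDS interval
#' overlaps it (on the same chromosome); non-overlapping variants are
#' annotated `intergenic`. Two overlapping genes at one variant is an
#' error naming both.
#'
#' @param tbl A pooled variant tibble.
#' @param genes A gene-model tibble.
#' @inheritParams annotate
#' @return The input table with columns `gene_id` (filled from the
#'   overlapping gene), `effect_class`, `codon_index`, `annotation`
#'   (the rendered label) added/updated.
#' @export
annotate_table <- function(tbl, genes, style = c("short", "long")) {
  style <- match.arg(style)
  validate_pool_table(tbl)
  if (nrow(tbl) == 0) {
    return(mutate(tbl, effect_class = character(0),
                  codon_index = integer(0)))
  }
  eff <- vector("list", nrow(tbl))
  gid <- tbl$gene_id
  for (i in seq_len(nrow(tbl))) {
    v <- tbl[i, ]
    span_end <- if (nchar(v$ref) > 0) v$pos + nchar(v$ref) - 1L else v$pos
    hit <- which(genes$chrom == v$chrom & genes$cds_start <= span_end &
                   genes$cds_end >= v$pos)
    if (length(hit) > 1) {
      stop_usage("variant %s_%d overlaps multiple genes: %s", v$chrom, v$pos,
                 paste(genes$gene_id[hit], collapse = ", "))
    }
    if (length(hit) == 0) {
      eff[[i]] <- effect_row("intergenic", label = "intergenic")
    } else {
      eff[[i]] <- annotate(v, genes[hit, ], style = style)
      gid[i] <- genes$gene_id[hit]
    }
  }
  eff <- bind_rows(eff)
  out <- tbl
  out$gene_id <- gid
  out$annotation <- eff$label
  out$effect_class <- eff$effect_class
  out$codon_index <- eff$codon_index
  out
}

#' Translate a coding sequence to protein
#'
#' Straightforward codon-by-codon translation with the standard nuclear
#' genetic code; used both by the annotator's callers and as a brute-force
#' oracle when diffing mutant against wildtype proteins. Trailing partial
#' codons (as arise downstream of a frameshift) are dropped.
#'
#' @param cds Coding-orientation nucleotide string.
#' @return Single-letter amino-acid string (stops rendered as `*`).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3
  if (n < 3) return("")
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  paste(vapply(codons, translate_codon, character(1)), collapse = "")
}

#' Apply a variant to a coding sequence
#'
#' Edits the coding-orientation CDS of `gene` according to `variant`
#' (plus-strand alleles; minus-strand genes handled by complementation),
#' returning the mutant CDS. Used to drive brute-force protein diffs.
#'
#' @inheritParams annotate
#' @return Mutant coding-orientation nucleotide string.
#' @export
mutate_cds <- function(variant, gene) {
  v <- as.list(variant); g <- as.list(gene)
  minus <- identical(g$strand, "-")
  cds <- g$cds_seq
  n_ref <- nchar(v$ref)
  if (minus) {
    ref_cs <- revcomp(v$ref); alt_cs <- revcomp(v$alt)
    # coding-orientation start of the edited span
    start <- if (n_ref > 0) g$cds_end - (v$pos + n_ref - 1L) + 1L
             else g$cds_end - v$pos + 2L
  } else {
    ref_cs <- v$ref; alt_cs <- v$alt
    start <- if (n_ref > 0) v$pos - g$cds_start + 1L
             else v$pos - g$cds_start + 1L
  }
  if (n_ref > 0) {
    if (substr(cds, start, start + n_ref - 1L) != ref_cs) {
      stop_usage("ref allele does not match CDS of %s", g$gene_id)
    }
    paste0(substr(cds, 1, start - 1L), alt_cs,
           substr(cds, start + n_ref, nchar(cds)))
  } else {
    # insertion before coding position `start`
    paste0(substr(cds, 1, start - 1L), alt_cs,
           substr(cds, start, nchar(cds)))
  }
}
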