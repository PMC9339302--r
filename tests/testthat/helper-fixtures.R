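# Shared fixtures. Gene models are synthetic CDSs engineered so that the
# printed screen-table variants land on the intended codons and reproduce
# the printed annotation labels; sequences are generated, not genomic.

table1_path <- function(pool) {
  system.file("extdata", paste0("table1_pool", pool, ".tsv"),
              package = "supscreen", mustWork = TRUE)
}

read_pool_fixture <- function(pool) {
  read_table1_tsv(table1_path(pool), pool_id = pool)
}

# Synthetic gene models for every Pool A row. All plus-strand; each CDS is
# pinned (via synth_cds overrides) so the printed DNA change produces the
# printed protein-level label.
table1_genes <- function() {
  gene <- function(gene_id, chrom, pos, offset, n_codons, overrides,
                   seed) {
    cds_start <- pos - offset + 1L
    tibble::tibble(
      gene_id = gene_id, chrom = chrom, cds_start = cds_start,
      cds_end = cds_start + 3L * n_codons - 1L, strand = "+",
      cds_seq = synth_cds(n_codons, seed = seed, overrides = overrides)
    )
  }
  dplyr::bind_rows(
    # delACTT at first base of codon 222 (ACT); next codon starts with T
    gene("CLN2", "chrXVI", 65946L, 664L, 297L,
         list("222" = "ACT", "223" = "TGG"), seed = 101),
    # A > G at first base of codon 407 (AAA -> GAA, K -> E)
    gene("SMC2", "chrVI", 218888L, 1219L, 450L, list("407" = "AAA"),
         seed = 102),
    # G > C at second base of codon 233 (AGT -> ACT, S -> T)
    gene("GIT1", "chrIII", 297908L, 698L, 300L, list("233" = "AGT"),
         seed = 103),
    # G > C at first base of codon 139 (GTG -> CTG, V -> L)
    gene("CAF40", "chrXIV", 90717L, 415L, 200L, list("139" = "GTG"),
         seed = 104),
    # G > C at third base of codon 588 (TTG -> TTC, L -> F)
    gene("SEF1", "chrII", 98352L, 1764L, 600L, list("588" = "TTG"),
         seed = 105),
    # delT at first base of codon 87 (TAT, Y)
    gene("PTH1", "chrVIII", 484285L, 259L, 190L, list("87" = "TAT"),
         seed = 106),
    # A > T at third base of codon 654 (GAA -> GAT, E -> D)
    gene("AIM44", "chrXVI", 252349L, 1962L, 700L, list("654" = "GAA"),
         seed = 107),
    # G > T at third base of codon 137 (TGG -> TGT, W -> C)
    gene("MSH5", "chrIV", 178744L, 411L, 200L, list("137" = "TGG"),
         seed = 108),
    # C > T at second base of codon 13 (ACT -> ATT, T -> I)
    gene("RPL31A", "chrIV", 322263L, 38L, 113L, list("13" = "ACT"),
         seed = 109)
  )
}

# expected short-style labels for the Pool A rows, in file order
table1_poolA_labels <- c("T222fs", "K407E", "S233T", "V139L", "L588F",
                         "Y87fs", "E654D", "W137C", "T13I")

# hand-rolled reverse complement, independent of the package's own
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# a filled binary disk in an h x w matrix
make_disk <- function(h, w, cy, cx, diameter) {
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ((ys - cy)^2 + (xs - cx)^2 <= (diameter / 2)^2) * 1L
}

# founder built by hand (bypasses spawn_revertant) for linkage tests
manual_founder <- function(sup, passengers) {
  f <- list(suppressor = sup, passengers = passengers, m = nrow(passengers))
  class(f) <- "founder_strain"
  f
}
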