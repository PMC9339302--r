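test_that("engineered fixture variants reproduce the printed labels", {
  genes <- table1_genes()
  pa <- read_pool_fixture("A")

  smc2 <- annotate(pa[pa$gene_id == "SMC2", ],
                   genes[genes$gene_id == "SMC2", ])
  expect_equal(smc2$effect_class, "missense")
  expect_equal(smc2$label, "K407E")
  expect_equal(smc2$codon_index, 407L)

  pth1 <- annotate(pa[pa$gene_id == "PTH1", ],
                   genes[genes$gene_id == "PTH1", ])
  expect_equal(pth1$effect_class, "frameshift")
  expect_equal(pth1$label, "Y87fs")

  cln2 <- annotate(pa[pa$gene_id == "CLN2", ],
                   genes[genes$gene_id == "CLN2", ], style = "long")
  expect_equal(cln2$label, "Frameshift at T222")
})

test_that("a 4-base deletion at CDS nucleotide 664 frameshifts at codon 222", {
  cds <- synth_cds(297, seed = 9, overrides = list("222" = "ACT",
                                                   "223" = "TGG"))
  gene <- tibble::tibble(gene_id = "G", chrom = "chrI", cds_start = 1000L,
                         cds_end = 1000L + 891L - 1L, strand = "+",
                         cds_seq = cds)
  variant <- list(chrom = "chrI", pos = 1000L + 663L,
                  ref = substr(cds, 664, 667), alt = "")
  ann <- annotate(variant, gene)
  expect_equal(ann$effect_class, "frameshift")
  expect_equal(ann$codon_index, 222L)          # ceil(664 / 3)
  expect_equal(ann$preserved_residues, 221L)
  # brute-force check: proteins agree on exactly 221 leading residues
  wt <- translate_cds(cds)
  mut <- translate_cds(mutate_cds(variant, gene))
  common <- 0
  while (common < nchar(mut) &&
         substr(wt, common + 1, common + 1) == substr(mut, common + 1,
                                                      common + 1)) {
    common <- common + 1
  }
  expect_equal(common, 221)
})

test_that("in-frame deletions are not frameshifts", {
  cds <- synth_cds(50, seed = 2)
  gene <- tibble::tibble(gene_id = "G", chrom = "chrI", cds_start = 1L,
                         cds_end = 150L, strand = "+", cds_seq = cds)
  v <- list(chrom = "chrI", pos = 10L, ref = substr(cds, 10, 12), alt = "")
  ann <- annotate(v, gene)
  expect_equal(ann$effect_class, "in_frame_indel")
  expect_false(grepl("fs", ann$label))
})

test_that("annotate_table labels the full printed pool against fixture genes", {
  genes <- table1_genes()
  pa <- read_pool_fixture("A")
  ann <- annotate_table(pa, genes, style = "short")
  expect_equal(ann$annotation, table1_poolA_labels)
  expect_true(all(ann$effect_class %in% c("missense", "frameshift")))

  # intergenic variant and empty table
  lone <- pool_table("chrIX", 5000L, "A", "G", 0.5)
  expect_equal(annotate_table(lone, genes)$effect_class, "intergenic")
  expect_equal(nrow(annotate_table(pa[0, ], genes)), 0)
})

test_that("SNV annotations agree with brute-force protein diffs on random genes", {
  genome <- build_genome(4, 6, 80, seed = 31)
  genes <- genome$genes
  set.seed(77)
  for (rep in 1:60) {
    g <- genes[sample(nrow(genes), 1), ]
    off <- sample(4:(nchar(g$cds_seq)), 1)
    ref_cs <- substr(g$cds_seq, off, off)
    alt_cs <- sample(setdiff(c("A", "C", "G", "T"), ref_cs), 1)
    if (g$strand == "+") {
      v <- list(chrom = g$chrom, pos = g$cds_start + off - 1L,
                ref = ref_cs, alt = alt_cs)
    } else {
      v <- list(chrom = g$chrom, pos = g$cds_end - off + 1L,
                ref = chartr("ACGT", "TGCA", ref_cs),
                alt = chartr("ACGT", "TGCA", alt_cs))
    }
    ann <- annotate(v, g)
    wt <- translate_cds(g$cds_seq)
    mut <- translate_cds(mutate_cds(v, g))
    diff_at <- which(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])
    if (ann$effect_class == "synonymous") {
      expect_length(diff_at, 0)
    } else {
      expect_equal(ann$codon_index, diff_at[1])
      expect_equal(ann$ref_residue, substr(wt, diff_at[1], diff_at[1]))
      expect_equal(ann$alt_residue, substr(mut, diff_at[1], diff_at[1]))
      expect_equal(ann$effect_class,
                   if (ann$alt_residue == "*") "nonsense" else "missense")
    }
  }
})

test_that("frameshift codon equals first divergent residue under brute force", {
  genome <- build_genome(2, 5, 60, seed = 13)
  genes <- genome$genes
  set.seed(5)
  for (rep in 1:30) {
    g <- genes[sample(nrow(genes), 1), ]
    len <- sample(c(1, 2, 4), 1)
    off <- sample(4:(nchar(g$cds_seq) - len - 3), 1)
    ref_cs <- substr(g$cds_seq, off, off + len - 1)
    if (g$strand == "+") {
      v <- list(chrom = g$chrom, pos = g$cds_start + off - 1L, ref = ref_cs,
                alt = "")
    } else {
      v <- list(chrom = g$chrom, pos = g$cds_end - (off + len - 1L) + 1L,
                ref = revcomp_chr(ref_cs), alt = "")
    }
    ann <- annotate(v, g)
    expect_equal(ann$effect_class, "frameshift")
    wt <- strsplit(translate_cds(g$cds_seq), "")[[1]]
    mut <- strsplit(translate_cds(mutate_cds(v, g)), "")[[1]]
    n <- min(length(wt), length(mut))
    diverge <- which(wt[1:n] != mut[1:n])
    first_div <- if (length(diverge) > 0) diverge[1] else n + 1
    # the mutant protein cannot diverge before the reported codon
    expect_gte(first_div, ann$codon_index)
  }
})

test_that("annotation guards reject inconsistent inputs", {
  genes <- table1_genes()
  v <- list(chrom = "chrXVI", pos = 65946L, ref = "ACTT", alt = "")
  expect_error(annotate(v, genes[genes$gene_id == "SMC2", ]), "chrVI")

  overlapping <- dplyr::bind_rows(
    genes[genes$gene_id == "CLN2", ],
    dplyr::mutate(genes[genes$gene_id == "CLN2", ], gene_id = "CLN2B")
  )
  pa <- read_pool_fixture("A")
  expect_error(annotate_table(pa, overlapping), "CLN2.*CLN2B")
})
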