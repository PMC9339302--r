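test_that("build_genome produces valid, deterministic genomes", {
  g <- build_genome(1, 1, 100, seed = 7)
  expect_equal(nrow(g$genes), 1)
  expect_equal(nchar(g$genes$cds_seq), 300)

  expect_identical(build_genome(3, 2, 50, seed = 11),
                   build_genome(3, 2, 50, seed = 11))

  big <- build_genome(16, 10, 300, seed = 1)
  expect_equal(nrow(big$genes), 160)
  expect_silent(validate_gene_models(big$genes))
  expect_false(anyDuplicated(big$chromosomes$name) > 0)
  lens <- stats::setNames(big$chromosomes$length, big$chromosomes$name)
  expect_true(all(big$genes$cds_start >= 1))
  expect_true(all(big$genes$cds_end <= lens[big$genes$chrom]))

  expect_error(build_genome(0, 1, 10), "n_chromosomes")
})

test_that("synth_cds honours overrides and CDS invariants", {
  cds <- synth_cds(297, seed = 4, overrides = list("222" = "ACT"))
  expect_equal(nchar(cds), 891)
  expect_equal(substr(cds, 1, 3), "ATG")
  expect_equal(substr(cds, 664, 666), "ACT")
  codons <- substring(cds, seq(1, 888, 3), seq(3, 890, 3))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  expect_error(synth_cds(10, overrides = list("5" = "TAA")), "stop")
  expect_error(synth_cds(10, overrides = list("1" = "AAA")), "initiator")
})

test_that("spawn_revertant yields one suppressor and distinct passenger loci", {
  genome <- build_genome(4, 4, 80, seed = 21)
  f0 <- spawn_revertant(genome, m = 0, seed = 1)
  expect_equal(nrow(f0$passengers), 0)
  expect_equal(nrow(f0$suppressor), 1)

  f8 <- spawn_revertant(genome, m = 8, seed = 2)
  all_loci <- c(paste(f8$suppressor$chrom, f8$suppressor$pos),
                paste(f8$passengers$chrom, f8$passengers$pos))
  expect_length(all_loci, 9)
  expect_equal(anyDuplicated(all_loci), 0)
  # suppressor is a 4-base frameshift deletion inside a gene
  expect_equal(nchar(f8$suppressor$ref), 4)
  expect_equal(f8$suppressor$alt, "")

  expect_error(spawn_revertant(genome, m = nrow(genome$genes)), "passengers")
})

test_that("selection fixes the suppressor; unlinked passengers are fair coins", {
  genome <- build_genome(4, 4, 80, seed = 3)
  founder <- spawn_revertant(genome, m = 6, seed = 4)
  seg <- draw_segregants(founder, cross_spec(), n = 10000, seed = 5)
  loci <- attr(seg, "loci")
  sup_col <- which(loci$is_suppressor)
  expect_equal(mean(seg[, sup_col]), 1.0)     # forced by selection, exact
  # binomial closed form: SE = sqrt(0.25 / 10000) = 0.005
  pass_freq <- colMeans(seg[, -sup_col, drop = FALSE])
  expect_true(all(abs(pass_freq - 0.5) <= 3 * 0.005))
})

test_that("complete linkage under the Haldane map keeps passengers fixed", {
  sup <- pool_table("chrI", 100L, "ACTT", "", NA_real_, pool_id = "founder",
                    gene_id = "SUP")
  pass <- pool_table(c("chrI", "chrII"), c(100L, 500L), c("A", "C"),
                     c("G", "T"), NA_real_, pool_id = "founder",
                     gene_id = c("LINKED", "FREE"))
  founder <- manual_founder(sup, pass)
  seg <- draw_segregants(founder, cross_spec(recombination_model = "haldane"),
                         n = 2000, seed = 6)
  loci <- attr(seg, "loci")
  # d = 0 cM from the suppressor -> recombination fraction 0 -> frequency 1
  expect_equal(mean(seg[, which(loci$gene_id == "LINKED")]), 1.0)
  freq_free <- mean(seg[, which(loci$gene_id == "FREE")])
  expect_true(abs(freq_free - 0.5) <= 3 * sqrt(0.25 / 2000))
})

test_that("make_pool returns true frequencies as multiples of 1/k", {
  genome <- build_genome(2, 3, 60, seed = 8)
  founder <- spawn_revertant(genome, m = 3, seed = 9)
  ps <- pool_spec(k = 6)
  seg <- draw_segregants(founder, cross_spec(), n = 6, seed = 10)
  freqs <- make_pool(seg, ps)
  expect_true(all(abs(freqs * 6 - round(freqs * 6)) < 1e-12))
  loci <- attr(seg, "loci")
  expect_equal(unname(freqs[loci$locus[loci$is_suppressor]]), 1.0)

  all1 <- seg; all1[, ] <- 1L
  expect_true(all(make_pool(all1, ps) == 1.0))
  half <- seg; half[, ] <- rep(c(1L, 0L), each = 3)
  expect_true(all(make_pool(half, ps) == 0.5))
  expect_error(make_pool(seg[1:5, ], ps), "k=6")
})

test_that("unlinked-passenger fixation matches the 2^-k binomial tail", {
  set.seed(42)
  n_pools <- 10000
  for (k in c(2, 6, 10)) {
    carried <- matrix(rbinom(n_pools * k, 1, 0.5), nrow = n_pools)
    p_hat <- mean(rowMeans(carried) == 1)
    p_true <- 2^-k
    se <- sqrt(p_true * (1 - p_true) / n_pools)
    expect_true(abs(p_hat - p_true) <= 3 * se,
                info = sprintf("k=%d: %.5f vs %.5f", k, p_hat, p_true))
  }
})

test_that("sequencing noise has binomial moments and is seed-reproducible", {
  genome <- build_genome(1, 2, 60, seed = 12)
  founder <- spawn_revertant(genome, m = 1, seed = 13)
  seg <- draw_segregants(founder, cross_spec(), n = 6, seed = 14)
  freqs <- make_pool(seg, pool_spec(k = 6))

  # error-free fixed site reads exactly 1.0
  noiseless <- sequence_pool(freqs, pool_spec(k = 6, depth = 100,
                                              base_error = 0, seed = 15))
  loci <- attr(seg, "loci")
  expect_equal(noiseless$frequency[match(loci$locus[loci$is_suppressor],
                                         paste(noiseless$chrom, noiseless$pos,
                                               noiseless$ref, noiseless$alt,
                                               sep = ":"))], 1.0)

  # observed frequency of a 0.5 site is unbiased: 10,000 replicate sites
  tf <- stats::setNames(rep(0.5, 10000), paste0("chrI:", 1:10000, ":A:G"))
  vars <- pool_table("chrI", 1:10000, "A", "G", NA_real_)
  vars$locus <- paste(vars$chrom, vars$pos, vars$ref, vars$alt, sep = ":")
  obs <- sequence_pool(tf, pool_spec(k = 6, depth = 100, base_error = 0,
                                     seed = 16), variants = vars)
  # var(alt/depth) ~ 0.25 E[1/depth] ~ 0.25/99 -> SE of the mean ~ 5e-4
  expect_true(abs(mean(obs$frequency, na.rm = TRUE) - 0.5) <= 3 * 5.2e-4)

  twice <- sequence_pool(freqs, pool_spec(k = 6, seed = 99))
  again <- sequence_pool(freqs, pool_spec(k = 6, seed = 99))
  expect_identical(twice, again)
})

test_that("simulate_screen is deterministic per seed and carries truth", {
  genome <- build_genome(3, 4, 60, seed = 17)
  s1 <- simulate_screen(genome, m = 5, n_pools = 2, seed = 18)
  s2 <- simulate_screen(genome, m = 5, n_pools = 2, seed = 18)
  expect_identical(s1$pools, s2$pools)
  expect_equal(sum(s1$truth$is_suppressor), 1)
  tf_cols <- grep("^true_freq_", names(s1$truth))
  expect_true(all(s1$truth[s1$truth$is_suppressor, tf_cols] == 1.0))
})
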