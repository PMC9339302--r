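# Synthetic suppressor-screen generator.
#
# Emulates the genetics of a spontaneous suppressor screen in haploid
# yeast: a founder revertant carrying one suppressor mutation plus m
# unlinked passenger heterozygosities is backcrossed to wildtype, spores
# with the revertant phenotype are selected, pooled (default 6 per pool)
# and the pool sequenced at finite depth so each variant gets an observed
# pooled allele frequency. Every stage is seeded and returns its ground
# truth.

#' Generate a synthetic sense-codon CDS
#'
#' Builds a valid coding sequence: initiator ATG followed by random sense
#' codons (no internal stop). Specific codons can be pinned with
#' `overrides`, e.g. to place a known residue at a known codon index.
#'
#' @param n_codons Number of codons (>= 1); the CDS has `3 * n_codons` nt.
#' @param seed Optional integer seed.
#' @param overrides Named list/vector mapping codon index to a fixed codon
#'   (e.g. `list("222" = "ACT")`). Index 1 must be ATG if overridden.
#' @return Nucleotide string of length `3 * n_codons`.
#' @export
#' @examples
#' synth_cds(5, seed = 1, overrides = list("3" = "AAA"))
synth_cds <- function(n_codons, seed = NULL, overrides = NULL) {
  n_codons <- check_count(n_codons, "n_codons")
  codons <- with_seed_if(seed, {
    c("ATG", sample(sense_codons(), n_codons - 1, replace = TRUE))
  })
  if (!is.null(overrides)) {
    idx <- as.integer(names(overrides))
    if (anyNA(idx) || any(idx < 1 | idx > n_codons)) {
      stop_usage("override codon indices must lie in 1..%d", n_codons)
    }
    for (j in seq_along(idx)) {
      cod <- toupper(as.character(overrides[[j]]))
      if (!grepl("^[ACGT]{3}$", cod)) stop_usage("invalid codon '%s'", cod)
      if (idx[j] == 1 && cod != "ATG") {
        stop_usage("codon 1 must be the initiator ATG")
      }
      if (idx[j] > 1 && idx[j] < n_codons && cod %in% STOP_CODONS) {
        stop_usage("override would place an internal stop at codon %d", idx[j])
      }
      codons[idx[j]] <- cod
    }
  }
  paste(codons, collapse = "")
}

#' Build a scaled-down synthetic genome with gene models
#'
#' Lays out `genes_per_chromosome` genes per chromosome, each a
#' `cds_codons`-codon CDS generated by [synth_cds()], separated by 200 bp
#' of intergenic spacer. Strands alternate so both orientations are
#' exercised. Deterministic for a fixed seed.
#'
#' @param n_chromosomes,genes_per_chromosome,cds_codons Positive counts.
#' @param seed Optional integer seed.
#' @return A list of class `genome_spec` with elements `chromosomes`
#'   (tibble `name`, `length`) and `genes` (gene-model tibble as in
#'   [read_gene_models()]).
#' @export
build_genome <- function(n_chromosomes, genes_per_chromosome, cds_codons,
                         seed = NULL) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  genes_per_chromosome <- check_count(genes_per_chromosome,
                                      "genes_per_chromosome")
  cds_codons <- check_count(cds_codons, "cds_codons")
  spacer <- 200L
  cds_len <- 3L * cds_codons
  chrom_len <- genes_per_chromosome * (cds_len + spacer) + spacer
  genes <- with_seed_if(seed, {
    rows <- vector("list", n_chromosomes * genes_per_chromosome)
    k <- 0
    for (ci in seq_len(n_chromosomes)) {
      for (gi in seq_len(genes_per_chromosome)) {
        k <- k + 1
        start <- spacer + (gi - 1L) * (cds_len + spacer) + 1L
        rows[[k]] <- tibble(
          gene_id = sprintf("GENE_%02d_%02d", ci, gi),
          chrom = roman_chrom(ci),
          cds_start = start, cds_end = start + cds_len - 1L,
          strand = if (k %% 2 == 0) "-" else "+",
          cds_seq = synth_cds(cds_codons)
        )
      }
    }
    bind_rows(rows)
  })
  genome <- list(
    chromosomes = tibble(name = roman_chrom(seq_len(n_chromosomes)),
                         length = rep(chrom_len, n_chromosomes)),
    genes = validate_gene_models(genes)
  )
  class(genome) <- "genome_spec"
  genome
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosomes, %d genes, %s bp total\n",
              nrow(x$chromosomes), nrow(x$genes),
              format(sum(x$chromosomes$length), big.mark = ",")))
  invisible(x)
}

# plus-strand alleles of a variant defined inside a gene's CDS in coding
# coordinates. cds_pos: 1-based coding offset of the first altered base.
cds_variant <- function(gene, cds_pos, ref_len, alt_cs) {
  minus <- gene$strand == "-"
  ref_cs <- substr(gene$cds_seq, cds_pos, cds_pos + ref_len - 1L)
  if (minus) {
    pos <- gene$cds_end - (cds_pos + ref_len - 1L) + 1L
    list(pos = as.integer(pos), ref = revcomp(ref_cs),
         alt = revcomp(alt_cs))
  } else {
    list(pos = as.integer(gene$cds_start + cds_pos - 1L), ref = ref_cs,
         alt = alt_cs)
  }
}

#' Draw a founder revertant strain
#'
#' Picks one gene to carry the suppressor mutation -- a 4-base frameshift
#' deletion inside its CDS -- and `m` further genes to carry passenger
#' SNVs, emulating the spontaneous co-occurring mutations of a revertant
#' isolate. All loci are pairwise distinct.
#'
#' @param genome A `genome_spec` from [build_genome()].
#' @param m Number of passenger mutations (>= 0).
#' @param seed Optional integer seed.
#' @return A list of class `founder_strain` with `suppressor` and
#'   `passengers` (variant tibbles with plus-strand alleles and
#'   `gene_id`), and `m`.
#' @export
spawn_revertant <- function(genome, m, seed = NULL) {
  m <- check_count(m, "m", min = 0)
  genes <- genome$genes
  if (nrow(genes) < m + 1) {
    stop_usage("genome has %d genes but m=%d passengers + 1 suppressor needed",
               nrow(genes), m)
  }
  with_seed_if(seed, {
    picked <- sample(nrow(genes), m + 1)
    sup_gene <- genes[picked[1], ]
    # 4-base deletion wholly inside the CDS, away from the initiator
    del_start <- sample(4:(nchar(sup_gene$cds_seq) - 4L), 1)
    sv <- cds_variant(sup_gene, del_start, 4L, "")
    suppressor <- pool_table(
      chrom = sup_gene$chrom, pos = sv$pos, ref = sv$ref, alt = sv$alt,
      frequency = NA_real_, pool_id = "founder", gene_id = sup_gene$gene_id
    )
    passengers <- if (m > 0) {
      rows <- lapply(picked[-1], function(ix) {
        g <- genes[ix, ]
        p <- sample(2:nchar(g$cds_seq), 1)  # spare the initiator's A
        ref_cs <- substr(g$cds_seq, p, p)
        alt_cs <- sample(setdiff(DNA_BASES, ref_cs), 1)
        pv <- cds_variant(g, p, 1L, alt_cs)
        pool_table(chrom = g$chrom, pos = pv$pos, ref = pv$ref, alt = pv$alt,
                   frequency = NA_real_, pool_id = "founder",
                   gene_id = g$gene_id)
      })
      bind_rows(rows)
    } else {
      suppressor[0, ]
    }
    founder <- list(suppressor = suppressor, passengers = passengers, m = m)
    class(founder) <- "founder_strain"
    founder
  })
}

founder_variants <- function(founder) {
  v <- bind_rows(mutate(founder$suppressor, is_suppressor = TRUE),
                 mutate(founder$passengers, is_suppressor = FALSE))
  v$locus <- variant_key(v)
  v
}

#' Specify the backcross design
#'
#' @param n_backcrosses Number of backcrosses to wildtype (>= 1;
#'   default 2).
#' @param recombination_model `"unlinked"` treats every passenger as an
#'   independent fair coin per selected segregant; `"haldane"`
#'   additionally links passengers that share the suppressor's chromosome,
#'   with recombination fraction `r = (1 - exp(-2 d / 100)) / 2` at map
#'   distance `d` cM and carrier probability `(1 - r)^n_backcrosses`.
#' @param map_cM_per_kb Map rate used only under `"haldane"` (default
#'   0.35 cM/kb, a typical budding-yeast average).
#' @param select_revertant_phenotype Keep only spores carrying the
#'   suppressor (default TRUE).
#' @return A list of class `cross_spec`.
#' @export
cross_spec <- function(n_backcrosses = 2, recombination_model = c("unlinked",
                       "haldane"), map_cM_per_kb = 0.35,
                       select_revertant_phenotype = TRUE) {
  n_backcrosses <- check_count(n_backcrosses, "n_backcrosses")
  spec <- list(
    n_backcrosses = n_backcrosses,
    recombination_model = match.arg(recombination_model),
    map_cM_per_kb = map_cM_per_kb,
    select_revertant_phenotype = isTRUE(select_revertant_phenotype)
  )
  class(spec) <- "cross_spec"
  spec
}

#' Draw phenotype-selected haploid segregants
#'
#' Simulates spores from the final backcross. With phenotype selection on,
#' every segregant carries the suppressor allele. Unlinked passengers
#' segregate as independent fair coins per segregant; under the Haldane
#' model, passengers on the suppressor's chromosome are co-inherited with
#' probability `(1 - r)^n_backcrosses`.
#'
#' @param founder A `founder_strain` from [spawn_revertant()].
#' @param cross A `cross_spec`.
#' @param n Number of segregants to draw (>= 1).
#' @param seed Optional integer seed.
#' @return Integer 0/1 matrix, `n` rows (segregants) by one column per
#'   locus; column names are locus keys, with attributes `loci` (variant
#'   tibble) carrying the locus metadata.
#' @export
draw_segregants <- function(founder, cross = cross_spec(), n, seed = NULL) {
  n <- check_count(n, "n")
  loci <- founder_variants(founder)
  nl <- nrow(loci)
  geno <- with_seed_if(seed, {
    g <- matrix(0L, nrow = n, ncol = nl, dimnames = list(NULL, loci$locus))
    sup <- which(loci$is_suppressor)
    g[, sup] <- if (cross$select_revertant_phenotype) 1L else rbinom(n, 1, 0.5)
    for (j in setdiff(seq_len(nl), sup)) {
      p <- 0.5
      if (cross$recombination_model == "haldane" &&
          loci$chrom[j] == loci$chrom[sup] &&
          cross$select_revertant_phenotype) {
        d_cM <- abs(loci$pos[j] - loci$pos[sup]) / 1000 * cross$map_cM_per_kb
        r <- (1 - exp(-2 * d_cM / 100)) / 2
        p <- (1 - r)^cross$n_backcrosses
      }
      g[, j] <- rbinom(n, 1, p)
    }
    g
  })
  attr(geno, "loci") <- loci
  geno
}

#' Specify pooling and sequencing parameters
#'
#' @param k Segregants per pool (default 6).
#' @param depth Mean reads per site (Poisson mean, default 100).
#' @param base_error Per-read error probability in `[0, 0.5)` (default
#'   0.001).
#' @param seed Optional integer seed for sequencing noise.
#' @return A list of class `pool_spec`.
#' @export
pool_spec <- function(k = 6, depth = 100, base_error = 0.001, seed = NULL) {
  k <- check_count(k, "k")
  if (!is.numeric(depth) || depth < 1) stop_usage("depth must be >= 1")
  if (!is.numeric(base_error) || base_error < 0 || base_error >= 0.5) {
    stop_usage("base_error must lie in [0, 0.5)")
  }
  spec <- list(k = k, depth = depth, base_error = base_error, seed = seed)
  class(spec) <- "pool_spec"
  spec
}

#' Pool segregants into true per-locus allele frequencies
#'
#' @param segregants Genotype matrix from [draw_segregants()] with exactly
#'   `pool$k` rows.
#' @param pool A `pool_spec`.
#' @return Named numeric vector of true pool frequencies (multiples of
#'   `1/k`), with the `loci` attribute forwarded.
#' @export
make_pool <- function(segregants, pool = pool_spec()) {
  if (nrow(segregants) != pool$k) {
    stop_usage("pool expects k=%d segregants, got %d", pool$k,
               nrow(segregants))
  }
  freqs <- colMeans(segregants)
  attr(freqs, "loci") <- attr(segregants, "loci")
  freqs
}

#' Sequence a pool: observed frequencies under Poisson/binomial noise
#'
#' Per locus, the site depth is `Poisson(depth)` and the alt-read count is
#' `Binomial(depth_i, f (1 - e) + (1 - f) e)` for true frequency `f` and
#' per-read error `e`; the observed frequency is the read ratio. A locus
#' that happens to draw depth 0 gets frequency `NA`.
#'
#' @param true_freqs Named frequency vector from [make_pool()] (with its
#'   `loci` attribute) or any named vector over loci of `variants`.
#' @param pool A `pool_spec`.
#' @param pool_id Pool label for the output table.
#' @param variants Optional variant tibble with a `locus` column; defaults
#'   to the `loci` attribute of `true_freqs`.
#' @return A pooled variant tibble with observed `frequency` and `depth`.
#' @export
sequence_pool <- function(true_freqs, pool = pool_spec(), pool_id = "pool1",
                          variants = NULL) {
  loci <- variants %||% attr(true_freqs, "loci")
  if (is.null(loci)) stop_usage("no locus metadata supplied")
  f <- as.numeric(true_freqs)[match(loci$locus, names(true_freqs))]
  if (anyNA(f)) stop_usage("true_freqs is missing loci")
  out <- with_seed_if(pool$seed, {
    depth_i <- rpois(length(f), pool$depth)
    p_alt <- f * (1 - pool$base_error) + (1 - f) * pool$base_error
    alt <- rbinom(length(f), depth_i, p_alt)
    tibble(depth = depth_i, alt = alt)
  })
  pool_table(
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    frequency = ifelse(out$depth > 0, out$alt / out$depth, NA_real_),
    pool_id = pool_id, gene_id = loci$gene_id, depth = out$depth
  )
}

#' Simulate a complete pooled-segregant suppressor screen
#'
#' Convenience wrapper: founder from [spawn_revertant()], `n_pools`
#' independent pools of `pool$k` phenotype-selected segregants each, true
#' pool frequencies and sequenced (noisy) pool tables.
#'
#' @param genome A `genome_spec`.
#' @param m Passenger count.
#' @param n_pools Number of segregant pools (default 2).
#' @param cross A `cross_spec`.
#' @param pool A `pool_spec`.
#' @param seed Integer seed fanned out deterministically to every stage.
#' @return A list of class `screen_sim`: `founder`, `truth` (variant
#'   tibble with `is_suppressor` and one `true_freq_<pool>` column per
#'   pool) and `pools` (named list of observed pooled variant tibbles).
#' @export
simulate_screen <- function(genome, m = 8, n_pools = 2, cross = cross_spec(),
                            pool = pool_spec(), seed = NULL) {
  n_pools <- check_count(n_pools, "n_pools")
  founder <- spawn_revertant(genome, m, seed = derive_seed(seed, 1))
  truth <- founder_variants(founder)
  pools <- vector("list", n_pools)
  names(pools) <- paste0("pool", LETTERS[seq_len(n_pools)])
  for (i in seq_len(n_pools)) {
    seg <- draw_segregants(founder, cross, n = pool$k,
                           seed = derive_seed(seed, 10 + i))
    tf <- make_pool(seg, pool)
    truth[[paste0("true_freq_", names(pools)[i])]] <- as.numeric(tf)
    pool_i <- pool
    pool_i$seed <- derive_seed(seed, 100 + i)
    pools[[i]] <- sequence_pool(tf, pool_i, pool_id = names(pools)[i])
  }
  out <- list(founder = founder, truth = truth, pools = pools)
  class(out) <- "screen_sim"
  out
}

#' Write screen ground truth as TSV
#'
#' @param sim A `screen_sim` from [simulate_screen()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  tf_cols <- grep("^true_freq_", names(sim$truth), value = TRUE)
  out <- data.frame(
    locus = paste0(sim$truth$chrom, "_", sim$truth$pos),
    dna_change = sim$truth$change_label,
    gene = sim$truth$gene_id,
    is_suppressor = sim$truth$is_suppressor,
    sim$truth[tf_cols],
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
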