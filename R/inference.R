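# Core inference: fixation filtering per pool, cross-pool intersection of
# fixed variants, expected chance-fixation of passengers, and candidate
# ranking. The genetic logic: after backcrossing and phenotype selection,
# only the suppressor mutation is carried by every pooled segregant and so
# sits at pooled allele frequency 1.0 in every pool, while unlinked
# passengers segregate randomly and land at intermediate frequencies.

#' Specify the fixation filter
#'
#' @param min_frequency Minimum pooled allele frequency to call a variant
#'   "fixed" (default 0.95: observed frequencies are read ratios, so exact
#'   1.0 is brittle at finite depth; use 1.0 for printed tables whose
#'   values are exact).
#' @param min_depth Minimum depth (default 10); ignored for records
#'   without a depth.
#' @param exclude_genes Gene ids to drop (e.g. genes already known to
#'   suppress and excluded by complementation testing).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(min_frequency = 0.95, min_depth = 10,
                        exclude_genes = character()) {
  if (!is.numeric(min_frequency) || min_frequency <= 0 || min_frequency > 1) {
    stop_usage("min_frequency must lie in (0, 1]")
  }
  spec <- list(min_frequency = min_frequency, min_depth = min_depth,
               exclude_genes = as.character(exclude_genes))
  class(spec) <- "filter_spec"
  spec
}

#' Keep the fixed variants of one pool
#'
#' Retains records with `frequency >= min_frequency`, depth either absent
#' or `>= min_depth`, and gene not excluded. Input order is preserved.
#'
#' @param tbl A pooled variant tibble.
#' @param spec A [filter_spec()].
#' @return The filtered tibble.
#' @export
filter_fixed <- function(tbl, spec = filter_spec()) {
  validate_pool_table(tbl)
  if (nrow(tbl) == 0) return(tbl)
  keep <- !is.na(tbl$frequency) & tbl$frequency >= spec$min_frequency
  if (!is.null(tbl$depth)) {
    keep <- keep & (is.na(tbl$depth) | tbl$depth >= spec$min_depth)
  }
  if (length(spec$exclude_genes) > 0 && !is.null(tbl$gene_id)) {
    keep <- keep & (is.na(tbl$gene_id) | !(tbl$gene_id %in% spec$exclude_genes))
  }
  tbl[keep, , drop = FALSE]
}

#' Intersect fixed variants across pools
#'
#' Applies [filter_fixed()] to each pool and reports the variants fixed in
#' every pool -- the candidate suppressors. Matching is variant-level
#' (chromosome + position + alleles) by default; gene-level matching also
#' implicates a gene hit by different alleles in different revertants.
#'
#' @param tables A list of pooled variant tibbles (one per pool), or a
#'   single tibble covering several `pool_id`s.
#' @param spec A [filter_spec()].
#' @param match_by `"variant"` or `"gene"`.
#' @param k Optional pool size used to compute the expected number of
#'   passengers fixed in all pools by chance (see
#'   [expected_false_fixed()]); the passenger count `m` is estimated as
#'   the mean per-pool count of non-fixed variants.
#' @return A list of class `candidate_report`: `shared_candidates` (tibble
#'   with per-pool `freq_<pool>` columns), `per_pool_fixed` (named list of
#'   fixed-variant tibbles), `n_pools`, `match_by`, `expected_false_fixed`.
#' @export
intersect_pools <- function(tables, spec = filter_spec(),
                            match_by = c("variant", "gene"), k = NULL) {
  match_by <- match.arg(match_by)
  if (is.data.frame(tables)) {
    tables <- split(tables, tables$pool_id)
  }
  ids <- vapply(tables, function(t) {
    u <- unique(t$pool_id)
    if (length(u) != 1) stop_usage("each table must hold exactly one pool")
    u
  }, character(1))
  if (anyDuplicated(ids)) {
    stop_usage("duplicate pool ids: %s", paste(ids[duplicated(ids)],
                                               collapse = ", "))
  }
  names(tables) <- ids
  if (length(tables) < 2) {
    warning("intersecting fewer than 2 pools: every fixed variant is 'shared'")
  }
  fixed <- lapply(tables, filter_fixed, spec = spec)
  keyfun <- function(t) {
    if (match_by == "gene") as.character(t$gene_id) else variant_key(t)
  }
  shared_keys <- Reduce(intersect, lapply(fixed, keyfun))
  shared_keys <- shared_keys[!is.na(shared_keys)]
  first <- fixed[[1]]
  shared <- first[match(shared_keys, keyfun(first)), , drop = FALSE]
  shared$frequency <- NULL
  shared$depth <- NULL
  shared$pool_id <- NULL
  for (id in ids) {
    f <- fixed[[id]]
    shared[[paste0("freq_", id)]] <- f$frequency[match(shared_keys, keyfun(f))]
  }
  eff <- NA_real_
  if (!is.null(k)) {
    m_hat <- mean(vapply(seq_along(tables), function(i) {
      nrow(tables[[i]]) - nrow(fixed[[i]])
    }, numeric(1)))
    eff <- expected_false_fixed(round(m_hat), k, length(tables))
  }
  report <- list(shared_candidates = as_tibble(shared),
                 per_pool_fixed = fixed, n_pools = length(tables),
                 match_by = match_by, expected_false_fixed = eff)
  class(report) <- "candidate_report"
  report
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report> %d pools, %d shared candidate(s) [%s-level]\n",
              x$n_pools, nrow(x$shared_candidates), x$match_by))
  for (id in names(x$per_pool_fixed)) {
    cat(sprintf("  pool %s: %d fixed variant(s)\n", id,
                nrow(x$per_pool_fixed[[id]])))
  }
  if (!is.na(x$expected_false_fixed)) {
    cat(sprintf("  expected passengers fixed in all pools by chance: %.4g\n",
                x$expected_false_fixed))
  }
  if (nrow(x$shared_candidates) > 0) print(x$shared_candidates)
  invisible(x)
}

#' Expected number of passengers fixed in all pools by chance
#'
#' An unlinked passenger is carried by each phenotype-selected segregant
#' with probability 1/2, so it reaches frequency 1.0 in a pool of `k`
#' with probability `2^-k`, and in all of `n_pools` independent pools
#' with probability `(2^-k)^n_pools`. With `m` passengers the expected
#' count of such chance fixations is `m * 2^(-k * n_pools)`.
#'
#' @param m Passenger count (>= 0).
#' @param k Segregants per pool (>= 1).
#' @param n_pools Number of pools (>= 1).
#' @return Expected count (numeric scalar).
#' @export
#' @examples
#' expected_false_fixed(8, 6, 1)   # 0.125
#' expected_false_fixed(8, 6, 2)   # ~0.00195
expected_false_fixed <- function(m, k, n_pools) {
  m <- check_count(m, "m", min = 0)
  k <- check_count(k, "k")
  n_pools <- check_count(n_pools, "n_pools")
  m * 2^(-k * as.numeric(n_pools))
}

#' Rank shared candidates by predicted impact
#'
#' Protein-truncating effects (frameshift, nonsense) rank above missense,
#' which ranks above everything else; ties are broken by mean pooled
#' frequency (descending) and then genomic coordinate.
#'
#' @param report A `candidate_report` from [intersect_pools()], whose
#'   shared candidates carry an `effect_class` column (see
#'   [annotate_table()]), or such a tibble directly.
#' @param annotations Optional named character vector mapping locus key
#'   (`"chrom:pos:ref:alt"`) to effect class, used when the candidates
#'   are not yet annotated.
#' @return The shared-candidate tibble in rank order, with a `rank`
#'   column.
#' @export
rank_candidates <- function(report, annotations = NULL) {
  tbl <- if (inherits(report, "candidate_report")) {
    report$shared_candidates
  } else {
    report
  }
  if (nrow(tbl) == 0) return(mutate(tbl, rank = integer(0)))
  eff <- tbl$effect_class
  if (is.null(eff) && !is.null(annotations)) {
    eff <- unname(annotations[variant_key(tbl)])
  }
  if (is.null(eff)) eff <- rep(NA_character_, nrow(tbl))
  prio <- ifelse(eff %in% c("frameshift", "nonsense"), 1L,
                 ifelse(eff %in% "missense", 2L, 3L))
  freq_cols <- grep("^freq_", names(tbl), value = TRUE)
  mean_freq <- if (length(freq_cols) > 0) {
    rowMeans(as.matrix(tbl[freq_cols]), na.rm = TRUE)
  } else {
    rep(0, nrow(tbl))
  }
  ord <- order(prio, -mean_freq, tbl$chrom, tbl$pos)
  out <- tbl[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Serialize a candidate report
#'
#' Writes the shared candidates as TSV and the full report (shared
#' candidates plus per-pool fixed lists and the expected chance-fixation
#' count) as JSON.
#'
#' @param report A `candidate_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_candidate_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(report$shared_candidates, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- list(
      n_pools = report$n_pools,
      match_by = report$match_by,
      expected_false_fixed = report$expected_false_fixed,
      shared_candidates = report$shared_candidates,
      per_pool_fixed = lapply(report$per_pool_fixed, function(t) {
        t[c("pool_id", "chrom", "pos", "change_label", "gene_id", "frequency")]
      })
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(report)
}
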