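#' SNP density of a genomic unit
#'
#' The exact ratio of SNP count to unit size (species genome or gene length,
#' in bp); no scaling constant is applied.
#'
#' @param snp_count SNP count(s).
#' @param unit_size Unit size(s) in bp (> 0).
#' @return `snp_count / unit_size`, vectorized.
#' @export
snp_density <- function(snp_count, unit_size) {
  if (any(unit_size <= 0)) stop("unit size must be positive")
  snp_count / unit_size
}

#' Per-sample, per-species SNP density table
#'
#' One row per (sample, species) pair in which the species is present, with
#' the sample's SNP count for that species (zero if present but without
#' SNPs), the genome size and the density.
#'
#' @param cohort A [simulate_cohort()] / [read_cohort()] object.
#' @return Data frame with columns `sample_id`, `unit_id`, `snp_count`,
#'   `unit_size`, `density`.
#' @export
species_density_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  base <- cohort$depth[cohort$depth$present,
                       c("sample_id", "species_id")]
  key <- paste(cohort$snps$sample_id, cohort$snps$species_id)
  cnt <- table(key)
  base$snp_count <- as.integer(cnt[paste(base$sample_id, base$species_id)])
  base$snp_count[is.na(base$snp_count)] <- 0L
  base$unit_size <- cohort$species$genome_size[
    match(base$species_id, cohort$species$species_id)]
  data.frame(sample_id = base$sample_id, unit_id = base$species_id,
             snp_count = base$snp_count, unit_size = base$unit_size,
             density = snp_density(base$snp_count, base$unit_size),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Prevalence filter
#'
#' Retains species observed in at least `min_samples` samples, either within
#' at least one season (`scope = "per-season"`) or overall.
#'
#' @param presence Data frame with columns `sample_id`, `species_id` and a
#'   logical `present` (e.g. the cohort's `depth` table).
#' @param meta Sample metadata (`sample_id`, `season`).
#' @param min_samples Minimum number of samples.
#' @param scope `"per-season"` or `"overall"`.
#' @return Character vector of retained species ids.
#' @export
prevalence_filter <- function(presence, meta, min_samples = 8,
                              scope = c("per-season", "overall")) {
  scope <- match.arg(scope)
  pres <- presence[presence$present, c("sample_id", "species_id")]
  if (scope == "overall") {
    n <- table(pres$species_id)
    return(sort(as.character(names(n)[n >= min_samples])))
  }
  season <- meta$season[match(pres$sample_id, meta$sample_id)]
  if (anyNA(season)) stop("sample id missing from metadata")
  n <- table(pres$species_id, season)
  if (nrow(n) == 0L) return(character(0))
  sort(as.character(rownames(n)[apply(n, 1, max) >= min_samples]))
}

#' Sequencing-depth filter
#'
#' Retains species whose mean sequencing depth exceeds `min_depth` (strict
#' `>`) in at least `min_samples` samples.
#'
#' @param depth Data frame with columns `sample_id`, `species_id`,
#'   `mean_depth`.
#' @param min_depth Fold-coverage threshold (strict).
#' @param min_samples Minimum number of qualifying samples.
#' @return Character vector of retained species ids.
#' @export
depth_filter <- function(depth, min_depth = 10, min_samples = 3) {
  ok <- depth[depth$mean_depth > min_depth, ]
  n <- table(ok$species_id)
  sort(as.character(names(n)[n >= min_samples]))
}

#' Cyclic seasonal pattern selection
#'
#' For every unit (species or gene) three pairwise Wilcoxon rank-sum tests
#' are run on its per-sample densities: wet vs each dry season and the two
#' dry seasons against each other. A unit is selected iff both wet-vs-dry
#' p-values fall below `alpha_wd` while the dry-vs-dry p-value does not fall
#' below `alpha_dd` - i.e. the unit differs from both dry seasons but the
#' dry seasons are indistinguishable. Raw p-values drive selection (no
#' multiple-testing adjustment); a Benjamini-Hochberg column over the
#' binding wet-vs-dry p-value is reported for transparency only.
#'
#' Units with fewer than two density values in any season group are not
#' testable and are returned with `NA` p-values and `selected = FALSE`.
#'
#' @param density A density table ([species_density_table()] or
#'   [gene_snp_density()]).
#' @param meta Sample metadata (`sample_id`, `season`).
#' @param alpha_wd Significance level for the two wet-vs-dry tests.
#' @param alpha_dd Level below which the dry seasons count as different
#'   (selection requires `p_dry_vs_dry >= alpha_dd`).
#' @return Data frame of class `cyclic_patterns`: `unit_id`,
#'   `p_wet_vs_dry2013`, `p_wet_vs_dry2014`, `p_dry_vs_dry`, `p_bh`,
#'   `selected`, `direction` (`"wet-up"` / `"wet-down"`).
#' @export
cyclic_pattern_select <- function(density, meta, alpha_wd = 0.05,
                                  alpha_dd = 0.05) {
  season <- meta$season[match(density$sample_id, meta$sample_id)]
  if (anyNA(season)) stop("sample id missing from metadata")
  if (!all(c("dry2013", "wet2014", "dry2014") %in% meta$season))
    stop("a season group is empty")
  idx <- split(seq_len(nrow(density)), density$unit_id)
  stats <- vapply(idx, function(i) {
    d <- density$density[i]
    s <- season[i]
    wet <- d[s == "wet2014"]
    dry13 <- d[s == "dry2013"]
    dry14 <- d[s == "dry2014"]
    if (length(wet) < 2 || length(dry13) < 2 || length(dry14) < 2)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(wilcoxon_rank_sum(wet, dry13)$p_two_sided,
      wilcoxon_rank_sum(wet, dry14)$p_two_sided,
      wilcoxon_rank_sum(dry13, dry14)$p_two_sided,
      mean(wet) - mean(c(dry13, dry14)))
  }, numeric(4))
  out <- data.frame(unit_id = names(idx),
                    p_wet_vs_dry2013 = stats[1, ],
                    p_wet_vs_dry2014 = stats[2, ],
                    p_dry_vs_dry = stats[3, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$selected <- !is.na(out$p_wet_vs_dry2013) &
    out$p_wet_vs_dry2013 < alpha_wd & out$p_wet_vs_dry2014 < alpha_wd &
    out$p_dry_vs_dry >= alpha_dd
  out$direction <- ifelse(is.na(stats[4, ]), NA_character_,
                          ifelse(stats[4, ] >= 0, "wet-up", "wet-down"))
  p_bind <- pmax(out$p_wet_vs_dry2013, out$p_wet_vs_dry2014)
  out$p_bh <- p.adjust(p_bind, method = "BH")
  out <- out[c("unit_id", "p_wet_vs_dry2013", "p_wet_vs_dry2014",
               "p_dry_vs_dry", "p_bh", "selected", "direction")]
  attr(out, "alpha_wd") <- alpha_wd
  attr(out, "alpha_dd") <- alpha_dd
  class(out) <- c("cyclic_patterns", "data.frame")
  out
}

#' @export
print.cyclic_patterns <- function(x, ...) {
  cat(sprintf(
    "cyclic pattern selection: %d of %d unit(s) selected (alpha_wd = %g, alpha_dd = %g)\n",
    sum(x$selected, na.rm = TRUE), nrow(x), attr(x, "alpha_wd"),
    attr(x, "alpha_dd")))
  if (any(x$selected))
    cat("  selected:", paste(x$unit_id[x$selected], collapse = ", "), "\n")
  invisible(x)
}

#' Gene-level SNP density table
#'
#' Assigns each SNP to the gene whose 1-based closed interval contains its
#' position (boundary positions included) and keeps genes whose SNPs are
#' present in at least `min_samples` samples. For every kept gene a density
#' row is produced for each sample in which the species is present (zero
#' count if the sample has no SNP in the gene); density uses gene length as
#' the unit size.
#'
#' @param cohort A `cohort` object.
#' @param min_samples Minimum number of samples with at least one SNP in the
#'   gene.
#' @return Density table (`sample_id`, `unit_id` = gene id, `snp_count`,
#'   `unit_size`, `density`).
#' @export
gene_snp_density <- function(cohort, min_samples = 8) {
  stopifnot(inherits(cohort, "cohort"))
  parts <- lapply(unique(cohort$genes$species_id), function(sp) {
    genes <- cohort$genes[cohort$genes$species_id == sp, ]
    genes <- genes[order(genes$start), ]
    if (nrow(genes) == 0L) return(NULL)
    snps <- cohort$snps[cohort$snps$species_id == sp, ]
    gi <- findInterval(snps$position, genes$start)
    inside <- gi >= 1L & snps$position <= genes$end[pmax(gi, 1L)]
    snps <- snps[inside, ]
    gid <- genes$gene_id[gi[inside]]
    if (nrow(snps) == 0L) return(NULL)
    key <- paste(snps$sample_id, gid)
    cnt <- table(key)

    hit_samples <- tapply(snps$sample_id, gid, function(s)
      length(unique(s)))
    keep <- names(hit_samples)[hit_samples >= min_samples]
    if (length(keep) == 0L) return(NULL)

    present <- cohort$depth$sample_id[cohort$depth$present &
                                        cohort$depth$species_id == sp]
    grid <- expand.grid(sample_id = present, gene_id = keep,
                        stringsAsFactors = FALSE)
    grid$snp_count <- as.integer(cnt[paste(grid$sample_id, grid$gene_id)])
    grid$snp_count[is.na(grid$snp_count)] <- 0L
    glen <- genes$end - genes$start + 1L
    grid$unit_size <- glen[match(grid$gene_id, genes$gene_id)]
    data.frame(sample_id = grid$sample_id, unit_id = grid$gene_id,
               snp_count = grid$snp_count, unit_size = grid$unit_size,
               density = snp_density(grid$snp_count, grid$unit_size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Binary strain-profile matrix of one species
#'
#' The site universe is the union, over samples carrying the species, of SNP
#' sites with mutated allele frequency strictly above `af_threshold`. Each
#' included sample contributes one binary row; samples lacking the species
#' contribute no row (absence of evidence is not an all-reference genotype).
#'
#' @param cohort A `cohort` object.
#' @param species_id Species to profile.
#' @param af_threshold Allele-frequency threshold (strict `>`; default 0.5).
#' @return Integer 0/1 matrix of class `profile_matrix`, samples x sites;
#'   column names are site positions.
#' @export
profile_matrix <- function(cohort, species_id, af_threshold = 0.5) {
  stopifnot(inherits(cohort, "cohort"))
  included <- cohort$depth$sample_id[cohort$depth$present &
                                       cohort$depth$species_id == species_id]
  snps <- cohort$snps[cohort$snps$species_id == species_id &
                        cohort$snps$sample_id %in% included &
                        cohort$snps$af > af_threshold, ]
  sites <- sort(unique(snps$position))
  m <- matrix(0L, nrow = length(included), ncol = length(sites),
              dimnames = list(included, as.character(sites)))
  if (nrow(snps) > 0)
    m[cbind(match(snps$sample_id, included),
            match(snps$position, sites))] <- 1L
  class(m) <- c("profile_matrix", class(m))
  m
}

#' Pairwise Manhattan distances between sample profiles
#'
#' On binary rows the Manhattan distance equals the Hamming count of
#' differing sites.
#'
#' @param m A [profile_matrix()] (or any numeric matrix, rows = samples).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
manhattan_distances <- function(m) {
  as.matrix(dist(unclass(m), method = "manhattan"))
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomerative merging (average linkage by default) of the
#' pairwise distances, serializable to Newick with branch lengths derived
#' from merge heights.
#'
#' @param distances Symmetric distance matrix (e.g.
#'   [manhattan_distances()]).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `snp_dendrogram` wrapping the merge tree.
#' @export
hierarchical_cluster <- function(distances,
                                 linkage = c("average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  hc <- hclust(as.dist(distances), method = linkage)
  structure(list(hclust = hc, linkage = linkage), class = "snp_dendrogram")
}

#' @export
print.snp_dendrogram <- function(x, ...) {
  cat("snp_dendrogram:", length(x$hclust$labels), "leaves,",
      x$linkage, "linkage, top merge height", max(x$hclust$height), "\n")
  invisible(x)
}

#' @method plot snp_dendrogram
#' @export
plot.snp_dendrogram <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Serialize / read a dendrogram as Newick
#'
#' @param dendro A [hierarchical_cluster()] result.
#' @param path File path.
#' @return `to_newick()` returns the Newick string; `read_newick()` returns
#'   an [ape::read.tree()] phylo object.
#' @export
to_newick <- function(dendro) {
  stopifnot(inherits(dendro, "snp_dendrogram"))
  ape::write.tree(ape::as.phylo(dendro$hclust))
}

#' @rdname to_newick
#' @export
write_newick <- function(dendro, path) {
  writeLines(to_newick(dendro), path)
  invisible(path)
}

#' @rdname to_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Concordance percentage helper
#'
#' `100 * n_in_cluster / n_total`, rounded to two decimals - the unit in
#' which season concordance is reported (13 of 19 -> 68.42).
#'
#' @param n_in_cluster Samples of the season found in its majority cluster.
#' @param n_total Samples of the season present in the tree.
#' @return Percent, two decimals.
#' @export
concordance_pct <- function(n_in_cluster, n_total) {
  if (n_total <= 0) stop("no samples of this season present")
  round(100 * n_in_cluster / n_total, 2)
}

#' Season concordance of a sample tree
#'
#' Cuts the dendrogram into `k = 2` clusters at the top merge. The wet
#' cluster is the cluster holding the majority of wet-season samples (a tie
#' is an error); the dry cluster is the other one. Concordance is the
#' percentage of wet samples in the wet cluster, and of dry samples (both
#' dry seasons pooled) in the dry cluster, each over the samples present in
#' the tree.
#'
#' @param dendro A [hierarchical_cluster()] result over sample leaves.
#' @param meta Sample metadata (`sample_id`, `season`).
#' @param k Number of clusters to cut (2 for the wet/dry reading).
#' @return List with `wet_pct`, `dry_pct` (two decimals), and the cluster
#'   assignment vector.
#' @export
season_concordance <- function(dendro, meta, k = 2) {
  stopifnot(inherits(dendro, "snp_dendrogram"))
  cl <- cutree(dendro$hclust, k = k)
  season <- meta$season[match(names(cl), meta$sample_id)]
  if (anyNA(season)) stop("sample id missing from metadata")
  wet <- season == "wet2014"
  if (!any(wet)) stop("no wet-season samples present")
  wet_by_cluster <- tapply(wet, cl, sum)
  top <- sort(wet_by_cluster, decreasing = TRUE)
  if (length(top) > 1 && top[1] == top[2])
    stop("wet-season majority cluster is tied")
  wet_cluster <- as.integer(names(top)[1])
  wet_pct <- concordance_pct(sum(wet & cl == wet_cluster), sum(wet))
  dry <- !wet
  dry_pct <- concordance_pct(sum(dry & cl != wet_cluster), sum(dry))
  list(wet_pct = wet_pct, dry_pct = dry_pct, clusters = cl,
       wet_cluster = wet_cluster)
}
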