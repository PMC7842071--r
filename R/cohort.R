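#' Species table for the synthetic seasonal cohort
#'
#' The 15 prevalent gut species carried by the default cohort, with genome
#' sizes in bp and the wet-season enrichment truth flag. Thirteen sizes are
#' the published assembly sizes of the corresponding species; the two marked
#' species (`P_stercorea`, `B_uniformis`) carry synthetic placeholder sizes.
#' The eight `enriched = TRUE` species are the planted wet-season-enriched
#' set.
#'
#' @return Data frame with columns `species_id`, `genome_size`, `enriched`.
#' @export
hadza_species <- function() {
  data.frame(
    species_id = c("A_hadrus", "C_mitsuokai", "C_comes", "E_biforme",
                   "E_hallii", "R_inulinivorans", "R_bromii", "R_obeum",
                   "F_prausnitzii", "P_copri", "M_smithii",
                   "T_succinifaciens", "R_lactaris", "P_stercorea",
                   "B_uniformis"),
    genome_size = c(3172613, 2671313, 3238915, 2415920,
                    2722180, 4048462, 2539482, 2607950,
                    3080849, 3507873, 1853160,
                    2731853, 2729735, 2500000,
                    4500000),
    enriched = c(rep(TRUE, 8), rep(FALSE, 7)),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic seasonal cohort
#'
#' Defaults encode the emulated study design: 40 samples in three season
#' groups of 8 (2013 dry), 19 (2014 wet) and 13 (2014 dry); 15 prevalent
#' species of which 8 carry planted wet-season SNP enrichment (factor 1.5 on
#' the negative-binomial mean SNP count); two season-associated strain
#' haplotypes per species inducing wet/dry cluster structure; and per-species
#' gene models supporting the gene-level analysis.
#'
#' @param season_sizes Named vector of samples per season
#'   (`dry2013`, `wet2014`, `dry2014`).
#' @param species Species table as in [hadza_species()].
#' @param baseline_density Baseline SNPs per bp (mean count =
#'   `genome_size * baseline_density`).
#' @param enrichment_factor Multiplicative wet-season increase of the mean
#'   SNP count for enriched species (>= 1).
#' @param overdispersion Variance-to-mean ratio of the negative-binomial
#'   SNP counts (> 1).
#' @param presence_prob Per-sample Bernoulli presence probability of each
#'   species.
#' @param strain_divergence Number of wet-private and dry-private haplotype
#'   sites per species.
#' @param haplotype_fidelity Probability that a sample carries a site of its
#'   own season's haplotype (sites of the other haplotype are carried with
#'   probability `1 - haplotype_fidelity`).
#' @param shared_pool_factor Size of the shared background site pool,
#'   relative to the largest per-sample mean SNP count.
#' @param genes_per_species,gene_mean_len Gene-model scale (count and mean
#'   length in bp).
#' @param n_cyclic_genes Planted cyclic genes per enriched species
#'   (gene-restricted extra wet-season SNPs).
#' @param gene_enrichment_factor Wet-season multiplier of the SNP rate
#'   inside planted cyclic genes.
#' @param include_outlier If `TRUE`, one 2014-dry sample draws from the wet
#'   strain haplotype (the "child outlier" analogue).
#' @param depth_meanlog,depth_sdlog Log-normal per-sample/species mean
#'   sequencing depth model.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(season_sizes = c(dry2013 = 8, wet2014 = 19,
                                           dry2014 = 13),
                          species = hadza_species(),
                          baseline_density = 1e-3,
                          enrichment_factor = 1.5,
                          overdispersion = 2,
                          presence_prob = 0.95,
                          strain_divergence = 100,
                          haplotype_fidelity = 0.85,
                          shared_pool_factor = 3,
                          genes_per_species = 400,
                          gene_mean_len = 600,
                          n_cyclic_genes = 3,
                          gene_enrichment_factor = 6,
                          include_outlier = TRUE,
                          depth_meanlog = log(20),
                          depth_sdlog = 0.4) {
  stopifnot(all(c("dry2013", "wet2014", "dry2014") %in% names(season_sizes)),
            all(season_sizes >= 2),
            all(c("species_id", "genome_size", "enriched") %in%
                  names(species)),
            all(species$genome_size > 0),
            enrichment_factor >= 1, overdispersion > 1,
            strain_divergence >= 0,
            haplotype_fidelity >= 0, haplotype_fidelity <= 1,
            baseline_density >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a three-season synthetic cohort
#'
#' Generates per-sample, per-species SNP sets with allele frequencies. For
#' each species the per-sample SNP count is negative-binomial with mean
#' `genome_size * baseline_density`, multiplied by `enrichment_factor` in
#' wet-season samples of planted species. Each species carries a shared
#' background site pool plus wet-private and dry-private strain-haplotype
#' site sets; a sample carries its own season's haplotype sites with
#' probability `haplotype_fidelity` (the opposite haplotype's with the
#' complementary probability), at allele frequencies concentrated near 1,
#' which induces the wet/dry cluster structure seen in
#' allele-frequency-thresholded profiles. Background sites get low allele
#' frequencies. Planted cyclic genes receive extra wet-season SNPs
#' restricted to the gene interval.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the documented default cohort is `seed = 1`.
#' @return An object of class `cohort`: a list with data frames `samples`
#'   (`sample_id`, `season`, `subject_tag`), `species`, `snps`
#'   (`sample_id`, `species_id`, `position`, `ref`, `alt`, `af`), `genes`
#'   (1-based closed intervals, with the `cyclic` truth flag) and `depth`
#'   (`sample_id`, `species_id`, `present`, `mean_depth`), plus the config
#'   and seed.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  cfg <- config

  sizes <- cfg$season_sizes[c("dry2013", "wet2014", "dry2014")]
  n_samples <- sum(sizes)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    season = rep(names(sizes), sizes),
    subject_tag = NA_character_,
    stringsAsFactors = FALSE)
  if (cfg$include_outlier) {
    out_idx <- max(which(samples$season == "dry2014"))
    samples$subject_tag[out_idx] <- "child_outlier"
  }

  species <- cfg$species
  depth_parts <- vector("list", nrow(species))
  gene_parts <- vector("list", nrow(species))
  base_rows <- vector("list", nrow(species))
  is_wet_smp <- samples$season == "wet2014"

  # --- pass 1: species-level cohort (pools, presence, per-sample SNP sets)
  for (si in seq_len(nrow(species))) {
    sp <- species$species_id[si]
    glen <- species$genome_size[si]
    enriched <- species$enriched[si]
    mu_base <- glen * cfg$baseline_density

    # site pools: shared background + two disjoint strain haplotypes
    n_shared <- round(cfg$shared_pool_factor * mu_base *
                        cfg$enrichment_factor)
    div <- cfg$strain_divergence
    pos_all <- sample.int(glen, n_shared + 2L * div)
    ref_all <- sample(BASES, length(pos_all), replace = TRUE)
    alt_all <- other_base(ref_all,
                          sample.int(3L, length(pos_all), replace = TRUE))
    pool <- data.frame(position = pos_all, ref = ref_all, alt = alt_all,
                       stringsAsFactors = FALSE)
    shared <- pool[seq_len(n_shared), ]
    hap_wet <- pool[n_shared + seq_len(div), ]
    hap_dry <- pool[n_shared + div + seq_len(div), ]

    present <- rbinom(n_samples, 1L, cfg$presence_prob) == 1L
    mean_depth <- ifelse(present,
                         rlnorm(n_samples, cfg$depth_meanlog,
                                cfg$depth_sdlog), 0)
    depth_parts[[si]] <- data.frame(
      sample_id = samples$sample_id, species_id = sp,
      present = present, mean_depth = round(mean_depth, 2),
      stringsAsFactors = FALSE)

    rows_by_sample <- vector("list", n_samples)
    for (smp in seq_len(n_samples)) {
      if (!present[smp]) next
      is_wet <- is_wet_smp[smp]
      wet_strain <- is_wet || identical(samples$subject_tag[smp],
                                        "child_outlier")
      mu <- mu_base * if (is_wet && enriched) cfg$enrichment_factor else 1
      nb_size <- mu / (cfg$overdispersion - 1)
      n_snp <- rnbinom(1L, mu = mu, size = nb_size)

      own <- if (wet_strain) hap_wet else hap_dry
      oth <- if (wet_strain) hap_dry else hap_wet
      own_take <- own[runif(nrow(own)) < cfg$haplotype_fidelity, ]
      oth_take <- oth[runif(nrow(oth)) < 1 - cfg$haplotype_fidelity, ]
      hap <- rbind(own_take, oth_take)
      hap$af <- rbeta(nrow(hap), 9, 1)

      n_bg <- min(max(0L, n_snp - nrow(hap)), nrow(shared))
      bg <- shared[sample.int(nrow(shared), n_bg), ]
      bg$af <- rbeta(n_bg, 1, 5)
      rows_by_sample[[smp]] <- rbind(hap, bg)
    }
    base_rows[[si]] <- rows_by_sample
  }

  # --- pass 2: gene layer, drawn after the whole species-level cohort so
  # that gene-model configuration never perturbs the base cohort of a seed
  for (si in seq_len(nrow(species))) {
    sp <- species$species_id[si]
    glen <- species$genome_size[si]
    genes <- make_gene_models(glen, cfg$genes_per_species,
                              mean_len = cfg$gene_mean_len)
    genes$species_id <- sp
    genes$gene_id <- if (nrow(genes))
      sprintf("%s_g%04d", sp, seq_len(nrow(genes))) else character()
    genes$cyclic <- logical(nrow(genes))
    cyc_pools <- list()
    if (species$enriched[si] && cfg$n_cyclic_genes > 0 && nrow(genes) > 0) {
      cyc <- sample.int(nrow(genes), min(cfg$n_cyclic_genes, nrow(genes)))
      genes$cyclic[cyc] <- TRUE
      cyc_pools <- lapply(cyc, function(gi) {
        span <- genes$start[gi]:genes$end[gi]
        lambda <- length(span) * cfg$baseline_density *
          (cfg$gene_enrichment_factor - 1)
        k <- max(5L, round(3 * lambda))
        p <- sample(span, min(k, length(span)))
        r <- sample(BASES, length(p), replace = TRUE)
        data.frame(position = p, ref = r,
                   alt = other_base(r, sample.int(3L, length(p),
                                                  replace = TRUE)),
                   lambda = lambda, stringsAsFactors = FALSE)
      })
    }
    gene_parts[[si]] <- genes
    if (length(cyc_pools)) {
      for (smp in which(is_wet_smp)) {
        rows <- base_rows[[si]][[smp]]
        if (is.null(rows)) next  # species absent in this wet sample
        for (cp in cyc_pools) {
          m <- min(rpois(1L, cp$lambda), nrow(cp))
          if (m > 0) {
            ex <- cp[sample.int(nrow(cp), m), c("position", "ref", "alt")]
            ex$af <- rbeta(m, 1, 5)
            rows <- rbind(rows, ex)
          }
        }
        base_rows[[si]][[smp]] <- rows
      }
    }
  }

  # --- finalize: dedupe, sort, round allele frequencies
  snp_parts <- list()
  for (si in seq_len(nrow(species))) {
    for (smp in seq_len(n_samples)) {
      rows <- base_rows[[si]][[smp]]
      if (is.null(rows)) next
      rows <- rows[!duplicated(rows$position), , drop = FALSE]
      rows <- rows[order(rows$position), ]
      snp_parts[[length(snp_parts) + 1L]] <- data.frame(
        sample_id = samples$sample_id[smp],
        species_id = species$species_id[si],
        position = rows$position, ref = rows$ref, alt = rows$alt,
        af = pmin(1, pmax(1e-4, round(rows$af, 4))),
        stringsAsFactors = FALSE)
    }
  }

  genes <- do.call(rbind, gene_parts)
  genes <- genes[c("species_id", "gene_id", "start", "end", "cyclic")]
  rownames(genes) <- NULL
  snps <- do.call(rbind, snp_parts)
  rownames(snps) <- NULL
  structure(list(samples = samples, species = species, snps = snps,
                 genes = genes, depth = do.call(rbind, depth_parts),
                 config = cfg, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("synthetic seasonal cohort:",
      nrow(x$samples), "samples (",
      paste(sprintf("%s=%d", names(table(x$samples$season)),
                    table(x$samples$season)), collapse = ", "), "),",
      nrow(x$species), "species,",
      format(nrow(x$snps), big.mark = ","), "SNP records,",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Lay out non-overlapping gene models on a genome
#'
#' Gene lengths are normal around `mean_len` (floored at 60 bp); genes are
#' tiled left to right with geometric gaps scaled to fit the genome.
#'
#' @param genome_size Genome length in bp.
#' @param n_genes Number of genes.
#' @param mean_len Mean gene length in bp.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Data frame with `start`, `end` (1-based closed), `length`;
#'   intervals are disjoint and within the genome.
#' @export
make_gene_models <- function(genome_size, n_genes, mean_len = 600,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_genes == 0L)
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  len <- pmax(60L, as.integer(round(rnorm(n_genes, mean_len, mean_len / 4))))
  if (sum(len) + n_genes > genome_size)
    stop("genes cannot fit in genome")
  slack <- genome_size - sum(len)
  mean_gap <- slack / (n_genes + 1)
  gaps <- as.numeric(rgeom(n_genes, 1 / (mean_gap + 1)))
  if (sum(gaps) > slack)
    gaps <- floor(gaps * (slack / sum(gaps)))
  start <- cumsum(c(1L, len[-n_genes])) + cumsum(gaps)
  data.frame(start = as.integer(start),
             end = as.integer(start + len - 1L),
             length = len)
}

#' Write a cohort to plain-text files
#'
#' Emits one VCF per sample (allele frequency in INFO/AF), a sample-metadata
#' TSV, a species TSV carrying the enrichment truth, a depth/presence TSV,
#' and the gene models as a BED-like TSV (0-based half-open on disk, stated
#' in its header; 1-based closed in memory). [read_cohort()] reads the
#' directory back; the round trip reproduces the SNP sets exactly (allele
#' frequencies are stored at 4 decimals).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @export
emit_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  tsv <- function(df, name, header) {
    con <- file(file.path(dir, name), "w")
    on.exit(close(con))
    writeLines(header, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  tsv(cohort$samples, "samples.tsv", "#sample_id\tseason\tsubject_tag")
  tsv(cohort$species, "species.tsv", "#species_id\tgenome_size\tenriched")
  tsv(cohort$depth, "depth.tsv", "#sample_id\tspecies_id\tpresent\tmean_depth")
  bed <- data.frame(species_id = cohort$genes$species_id,
                    start0 = cohort$genes$start - 1L,
                    end = cohort$genes$end,
                    gene_id = cohort$genes$gene_id,
                    cyclic = cohort$genes$cyclic)
  tsv(bed, "genes.bed",
      c("# gene models: 0-based half-open intervals (BED convention)",
        "#species_id\tstart\tend\tgene_id\tcyclic"))

  contigs <- sprintf("##contig=<ID=%s,length=%d>",
                     cohort$species$species_id, cohort$species$genome_size)
  for (smp in cohort$samples$sample_id) {
    rows <- cohort$snps[cohort$snps$sample_id == smp, ]
    rows <- rows[order(match(rows$species_id, cohort$species$species_id),
                       rows$position), ]
    con <- file(file.path(dir, paste0(smp, ".vcf")), "w")
    writeLines(c("##fileformat=VCFv4.2", contigs,
                 paste0("##INFO=<ID=AF,Number=1,Type=Float,",
                        "Description=\"Mutated allele frequency\">"),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(rows) > 0)
      writeLines(paste(rows$species_id, rows$position, ".", rows$ref,
                       rows$alt, ".", "PASS",
                       sprintf("AF=%.4f", rows$af), sep = "\t"), con)
    close(con)
  }
  invisible(dir)
}

#' @rdname emit_cohort
#' @param dir Directory previously written by [emit_cohort()].
#' @return `read_cohort()` returns a `cohort` object (without generator
#'   config or seed).
#' @export
read_cohort <- function(dir) {
  rd <- function(name, cols, classes) {
    df <- read.delim(file.path(dir, name), header = FALSE,
                     comment.char = "#", col.names = cols,
                     colClasses = classes, na.strings = "NA")
    df
  }
  samples <- rd("samples.tsv", c("sample_id", "season", "subject_tag"),
                c("character", "character", "character"))
  species <- rd("species.tsv", c("species_id", "genome_size", "enriched"),
                c("character", "integer", "logical"))
  depth <- rd("depth.tsv", c("sample_id", "species_id", "present",
                             "mean_depth"),
              c("character", "character", "logical", "numeric"))
  bed <- rd("genes.bed", c("species_id", "start0", "end", "gene_id",
                           "cyclic"),
            c("character", "integer", "integer", "character", "logical"))
  genes <- data.frame(species_id = bed$species_id, gene_id = bed$gene_id,
                      start = bed$start0 + 1L, end = bed$end,
                      cyclic = bed$cyclic, stringsAsFactors = FALSE)
  snps <- lapply(samples$sample_id, function(smp) {
    lines <- readLines(file.path(dir, paste0(smp, ".vcf")))
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) == 0L) return(NULL)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(sample_id = smp,
               species_id = vapply(parts, `[`, "", 1L),
               position = as.integer(vapply(parts, `[`, "", 2L)),
               ref = vapply(parts, `[`, "", 4L),
               alt = vapply(parts, `[`, "", 5L),
               af = as.numeric(sub("AF=", "", vapply(parts, `[`, "", 8L),
                                   fixed = TRUE)),
               stringsAsFactors = FALSE)
  })
  structure(list(samples = samples, species = species,
                 snps = do.call(rbind, snps), genes = genes, depth = depth,
                 config = NULL, seed = NULL),
            class = "cohort")
}
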