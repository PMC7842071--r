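test_that("snp_density is the exact count/size ratio", {
  expect_equal(snp_density(0, 1000), 0)
  expect_equal(snp_density(2608, 2607950), 2608 / 2607950)
  expect_equal(snp_density(2608, 2607950), 1.00002e-3, tolerance = 1e-4)
  expect_equal(snp_density(10, 2000), snp_density(10, 1000) / 2)
  expect_error(snp_density(1, 0), "positive")
})

test_that("prevalence filter keeps species present in enough samples", {
  meta <- data.frame(
    sample_id = sprintf("s%02d", 1:20),
    season = rep(c("dry2013", "wet2014", "dry2014"), c(4, 10, 6)))
  pres <- expand.grid(sample_id = meta$sample_id,
                      species_id = c("sp1", "sp2"),
                      stringsAsFactors = FALSE)
  # sp1 present in 8 wet samples only; sp2 present in 3 samples per season
  pres$present <- with(pres, (species_id == "sp1" &
                                sample_id %in% sprintf("s%02d", 5:12)) |
                         (species_id == "sp2" &
                            sample_id %in% sprintf("s%02d", c(1:3, 5:7, 15:17))))
  expect_identical(prevalence_filter(pres, meta, 8), "sp1")
  expect_identical(prevalence_filter(pres, meta, 1), c("sp1", "sp2"))
  expect_identical(prevalence_filter(pres, meta, 11), character(0))
  # overall scope pools seasons
  expect_identical(prevalence_filter(pres, meta, 9, scope = "overall"),
                   "sp2")
})

test_that("depth filter applies a strict > threshold", {
  depth <- data.frame(sample_id = rep(sprintf("s%d", 1:3), 2),
                      species_id = rep(c("hi", "lo"), each = 3),
                      mean_depth = c(10.5, 10.5, 10.5, 10, 10, 10))
  expect_identical(depth_filter(depth, 10, 3), "hi")
  depth$mean_depth <- 0
  expect_identical(depth_filter(depth, 10, 3), character(0))
})

test_that("cyclic selection implements the wet-vs-both-dry rule", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:40),
                     season = rep(c("dry2013", "wet2014", "dry2014"),
                                  c(8, 19, 13)))
  mk_density <- function(unit, values) {
    data.frame(sample_id = meta$sample_id, unit_id = unit,
               snp_count = NA, unit_size = 1, density = values)
  }
  # deterministic values: jitter interleaves the two dry seasons so the
  # dry-vs-dry test stays null while wet separates (or not) by level
  jit <- (seq_len(40) %% 7) / 10
  lvl <- function(d13, wet, d14)
    rep(c(d13, wet, d14), c(8, 19, 13)) + jit
  dens <- rbind(mk_density("up", lvl(5, 10, 5)),
                mk_density("none", lvl(5, 5, 5)),
                mk_density("half", lvl(5, 10, 10)))
  cp <- cyclic_pattern_select(dens, meta)
  expect_true(cp$selected[cp$unit_id == "up"])
  expect_identical(cp$direction[cp$unit_id == "up"], "wet-up")
  expect_false(cp$selected[cp$unit_id == "none"])
  expect_false(cp$selected[cp$unit_id == "half"])  # dry seasons differ

  # invariant to sample order
  perm <- sample(nrow(dens))
  cp2 <- cyclic_pattern_select(dens[perm, ], meta)
  expect_equal(cp2, cp)

  # symmetric in the two dry seasons
  meta_swap <- meta
  meta_swap$season <- ifelse(meta$season == "dry2013", "dry2014",
                             ifelse(meta$season == "dry2014", "dry2013",
                                    meta$season))
  cp3 <- cyclic_pattern_select(dens, meta_swap)
  expect_identical(cp3$selected, cp$selected)
  expect_equal(cp3$p_dry_vs_dry, cp$p_dry_vs_dry)

  # a unit missing one season group entirely is not testable
  dens_na <- dens[!(dens$unit_id == "up" & meta$season[match(
    dens$sample_id, meta$sample_id)] == "dry2013"), ]
  cp4 <- cyclic_pattern_select(dens_na, meta)
  expect_true(is.na(cp4$p_wet_vs_dry2013[cp4$unit_id == "up"]))
  expect_false(cp4$selected[cp4$unit_id == "up"])
})

test_that("gene densities use closed intervals and the prevalence gate", {
  co <- list(
    samples = data.frame(sample_id = c("s1", "s2", "s3"),
                         season = c("dry2013", "wet2014", "dry2014")),
    species = data.frame(species_id = "sp", genome_size = 10000L,
                         enriched = TRUE),
    genes = data.frame(species_id = "sp", gene_id = c("gA", "gB"),
                       start = c(101L, 501L), end = c(200L, 700L),
                       cyclic = FALSE),
    depth = data.frame(sample_id = c("s1", "s2", "s3"), species_id = "sp",
                       present = TRUE, mean_depth = 20),
    snps = data.frame(
      sample_id = c("s1", "s1", "s1", "s2", "s3"),
      species_id = "sp",
      position = c(101L, 200L, 201L, 150L, 150L),  # boundaries + outside
      ref = "A", alt = "G", af = 0.9))
  class(co) <- "cohort"
  gd <- gene_snp_density(co, min_samples = 3)
  # gA got SNPs from all 3 samples (boundary positions count; 201 does not)
  expect_identical(sort(unique(gd$unit_id)), "gA")
  expect_equal(gd$snp_count[gd$sample_id == "s1"], 2)
  expect_equal(gd$unit_size[1], 100)
  # below the prevalence gate nothing survives
  expect_null(gene_snp_density(co, min_samples = 4))
})

test_that("profile matrices apply a strict AF threshold per present sample", {
  co <- list(
    samples = data.frame(sample_id = c("s1", "s2", "s3"),
                         season = c("wet2014", "wet2014", "dry2014")),
    species = data.frame(species_id = "sp", genome_size = 1000L,
                         enriched = FALSE),
    genes = NULL,
    depth = data.frame(sample_id = c("s1", "s2", "s3"), species_id = "sp",
                       present = c(TRUE, TRUE, FALSE), mean_depth = 20),
    snps = data.frame(
      sample_id = c("s1", "s1", "s2", "s2", "s3"),
      species_id = "sp",
      position = c(10L, 20L, 10L, 20L, 30L),
      ref = "A", alt = "G",
      af = c(0.9, 0.5, 0.9, 0.51, 0.9)))
  class(co) <- "cohort"
  pm <- profile_matrix(co, "sp")
  # s3 lacks the species -> no row; its site 30 is not in the universe
  expect_identical(rownames(pm), c("s1", "s2"))
  expect_identical(colnames(pm), c("10", "20"))
  # AF exactly 0.5 is excluded (strict >), 0.51 is included
  expect_equal(pm["s1", ], c("10" = 1L, "20" = 0L))
  expect_equal(pm["s2", ], c("10" = 1L, "20" = 1L))

  # two samples with identical profiles give identical rows
  expect_identical(unname(pm["s1", "10"]), unname(pm["s2", "10"]))
})

test_that("Manhattan distances equal Hamming counts and form a metric", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(0, 0, 1, 1))
  d <- manhattan_distances(m)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["a", "b"], 2)
  expect_equal(d["a", "c"], 4)  # complementary rows of length 4
  expect_equal(d, t(d))

  set.seed(13)
  r <- matrix(rbinom(20 * 30, 1, 0.4), nrow = 20)
  dr <- manhattan_distances(r)
  for (k in 1:50) {
    ijk <- sample(20, 3)
    expect_lte(dr[ijk[1], ijk[3]],
               dr[ijk[1], ijk[2]] + dr[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("hierarchical clustering merges nearest groups first", {
  d2 <- matrix(c(0, 7, 7, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  hc2 <- hierarchical_cluster(d2)
  expect_equal(hc2$hclust$height, 7)

  d3 <- matrix(c(0, 1, 10,
                 1, 0, 10,
                 10, 10, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- hierarchical_cluster(d3)
  expect_equal(sort(cutree(hc3$hclust, 2)[c("A", "B")]),
               c(A = 1L, B = 1L))
  expect_equal(hc3$hclust$height[1], 1)

  # ultrametric input yields the same tree under all linkages
  du <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 4,
                 8, 8, 4, 0), 4, byrow = TRUE,
               dimnames = list(letters[1:4], letters[1:4]))
  hs <- lapply(c("average", "complete", "single"), function(l)
    hierarchical_cluster(du, linkage = l)$hclust)
  for (h in hs[-1]) {
    expect_equal(h$height, hs[[1]]$height)
    expect_identical(cutree(h, 2), cutree(hs[[1]], 2))
  }
  # merge heights are non-decreasing
  expect_true(all(diff(hs[[1]]$height) >= 0))
})

test_that("Newick export round-trips the tree topology", {
  set.seed(14)
  m <- matrix(rbinom(6 * 40, 1, 0.5), nrow = 6,
              dimnames = list(paste0("s", 1:6), NULL))
  hc <- hierarchical_cluster(manhattan_distances(m))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, nwk)
  tree <- read_newick(nwk)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, rownames(m))
  expect_equal(ape::dist.topo(ape::unroot(tree),
                              ape::unroot(ape::as.phylo(hc$hclust))), 0,
               ignore_attr = TRUE)
})

test_that("season concordance reads the two-cluster cut correctly", {
  # perfectly separated profiles -> 100 / 100
  set.seed(15)
  meta <- data.frame(sample_id = sprintf("s%d", 1:8),
                     season = rep(c("wet2014", "dry2014"), each = 4))
  m <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), 4), nrow = 4, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 1, 1, 1), 4), nrow = 4, byrow = TRUE))
  rownames(m) <- meta$sample_id
  m <- m + matrix(rbinom(48, 1, 0.05), nrow = 8)  # slight noise
  m[m > 1] <- 1
  sc <- season_concordance(hierarchical_cluster(manhattan_distances(m)),
                           meta)
  expect_equal(sc$wet_pct, 100.00)
  expect_equal(sc$dry_pct, 100.00)

  # concordance is invariant to leaf rotations (row permutations)
  perm <- sample(8)
  sc2 <- season_concordance(
    hierarchical_cluster(manhattan_distances(m[perm, ])), meta)
  expect_equal(sc2$wet_pct, sc$wet_pct)
  expect_equal(sc2$dry_pct, sc$dry_pct)
})
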