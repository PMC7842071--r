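test_that("single and overlapping reads stack at their encoded origins", {
  g <- synthesize_genomes(c(a = 200), seed = 21)
  one <- manual_reads("a", 10L, substring(g$seq[[1]], 10, 84))
  pu <- build_pileup(one, g)
  cols <- pileup_columns(pu)
  expect_equal(nrow(cols), 75)
  expect_true(all(cols$depth == 1))
  expect_equal(range(cols$position), c(10, 84))

  two <- manual_reads("a", c(10L, 50L),
                      substring(g$seq[[1]], c(10, 50), c(84, 124)))
  cols2 <- pileup_columns(build_pileup(two, g))
  expect_true(all(cols2$depth[cols2$position < 50] == 1))
  expect_true(all(cols2$depth[cols2$position %in% 50:84] == 2))
  expect_true(all(cols2$depth[cols2$position > 84] == 1))

  oob <- manual_reads("a", 150L, substring(g$seq[[1]], 100, 174))
  expect_error(build_pileup(oob, g), "outside reference")
})

test_that("minus-strand reads are re-oriented to the reference", {
  g <- synthesize_genomes(c(a = 300), seed = 22)
  tpl <- substring(g$seq[[1]], 40, 114)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tpl)))
  rd <- manual_reads("a", 40L, rc, strand = "-")
  cols <- pileup_columns(build_pileup(rd, g))
  expect_equal(nrow(cols), 75)
  # every stacked base matches the reference -> no alt counts anywhere
  refbase <- substring(g$seq[[1]], cols$position, cols$position)
  for (b in c("A", "C", "G", "T"))
    expect_true(all(cols[[b]][refbase != b] == 0))
})

test_that("thresholds gate calls as specified on a hand-built column", {
  # depth 12 at one site: 6 reads ref, 6 reads alt -> alt_freq 0.5
  g <- genome_set(c(a = strrep("A", 40)))
  alt_reads <- manual_reads("a", rep(5L, 6), rep("G", 6))
  ref_reads <- manual_reads("a", rep(5L, 6), rep("A", 6))
  rd <- rbind(alt_reads, ref_reads)
  pu <- build_pileup(rd, g)
  calls <- call_snps(pu, g, caller_config(10, 2, 15, 0.2))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 5)
  expect_identical(calls$alt, "G")
  expect_equal(calls$alt_freq, 0.5)
  expect_equal(calls$depth, 12)

  # all-reference column -> no call
  expect_equal(nrow(call_snps(build_pileup(ref_reads, g), g,
                              benchmark_config())), 0)

  # raising min_coverage above the depth suppresses the call
  expect_equal(nrow(call_snps(pu, g, caller_config(13, 2, 15, 0.2))), 0)
  # raising min_var_freq above 0.5 suppresses the call
  expect_equal(nrow(call_snps(pu, g, caller_config(10, 2, 15, 0.6))), 0)
})

test_that("alt ties break by fixed base order A<C<G<T", {
  g <- genome_set(c(a = strrep("A", 20)))
  rd <- manual_reads("a", rep(3L, 6), c("T", "T", "T", "C", "C", "C"))
  calls <- call_snps(build_pileup(rd, g), g, benchmark_config())
  expect_identical(calls$alt, "C")
})

test_that("raising any threshold never increases the number of calls", {
  g <- synthesize_genomes(c(a = 30000), seed = 23)
  tr <- draw_snp_truth(g, 25, seed = 24)
  rd <- simulate_reads(apply_snps(g, tr), depth_to_read_count(8, g),
                       seed = 25)
  pu <- build_pileup(rd, g)
  base <- nrow(call_snps(pu, g, caller_config(2, 1, 1, 0.1)))
  for (cfg in list(caller_config(6, 1, 1, 0.1),
                   caller_config(2, 4, 1, 0.1),
                   caller_config(2, 1, 30, 0.1),
                   caller_config(2, 1, 1, 0.5)))
    expect_lte(nrow(call_snps(pu, g, cfg)), base)
})

test_that("low-quality bases are excluded by the pileup quality floor", {
  g <- genome_set(c(a = strrep("A", 20)))
  lowq <- manual_reads("a", 3L, "G", qual_char = "+")  # Q10
  hiq <- manual_reads("a", 3L, "G", qual_char = "H")   # Q39
  expect_equal(nrow(pileup_columns(build_pileup(lowq, g))), 0)
  expect_equal(pileup_columns(build_pileup(hiq, g))$depth, 1)
})

test_that("dense-mismatch tails are soft-clipped like an aligner would", {
  g <- synthesize_genomes(c(a = 500), seed = 26)
  # emulate a deletion at read offset 30: the tail is shifted by one base
  shifted <- paste0(substring(g$seq[[1]], 100, 128),
                    substring(g$seq[[1]], 130, 175))
  rd <- manual_reads("a", 100L, shifted)
  cols_clip <- pileup_columns(build_pileup(rd, g, clip_tails = TRUE))
  cols_raw <- pileup_columns(build_pileup(rd, g, clip_tails = FALSE))
  ref <- function(p) substring(g$seq[[1]], p, p)
  mism <- function(cols) {
    sum(vapply(seq_len(nrow(cols)), function(i) {
      b <- ref(cols$position[i])
      cols$depth[i] - cols[[b]][i]
    }, numeric(1)))
  }
  expect_gt(mism(cols_raw), 20)  # naive stacking: shifted tail mismatches
  # clipping triggers before a 4th mismatching base can accumulate
  expect_lte(mism(cols_clip), 3)
  expect_lt(nrow(cols_clip), nrow(cols_raw))
})

test_that("a zero-error fully covered run recovers the truth list exactly", {
  g <- synthesize_genomes(c(a = 20000, b = 12000), seed = 27)
  tr <- draw_snp_truth(g, 30, seed = 28)
  rd <- simulate_reads(apply_snps(g, tr), depth_to_read_count(15, g),
                       error = error_model(0, 0, 0), seed = 29)
  calls <- call_snps(build_pileup(rd, g), g, benchmark_config())
  rep <- eval_report(calls, tr, g)
  expect_equal(rep$sensitivity, 100.0)
  expect_equal(rep$selectivity, 100.0)
  expect_equal(rep$counts$false_positive, 0)
  # alt allele frequency is 1 at every truth site (reads carry the mutation)
  expect_true(all(calls$alt_freq == 1))
})

test_that("VCF round trip is lossless and validates its records", {
  g <- synthesize_genomes(c(a = 50000), seed = 30)
  tr <- draw_snp_truth(g, 40, seed = 31)
  rd <- simulate_reads(apply_snps(g, tr), depth_to_read_count(12, g),
                       seed = 32)
  calls <- call_snps(build_pileup(rd, g), g, benchmark_config())
  expect_gt(nrow(calls), 0)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, g, vcf)
  back <- read_vcf(vcf)
  expect_identical(back$genome_id, calls$genome_id)
  expect_equal(back$position, calls$position)
  expect_identical(back$alt, calls$alt)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$alt_reads, calls$alt_reads)
  expect_equal(back$alt_freq, calls$alt_freq, tolerance = 1e-4)
  expect_equal(back$mean_qual, calls$mean_qual, tolerance = 1e-2)

  # AF formatting at 4 decimals
  line <- grep("^[^#]", readLines(vcf), value = TRUE)[1]
  expect_match(line, "AF=[01]\\.\\d{4};")

  # empty call set -> header-only VCF that reads back empty
  write_vcf(calls[0, ], g, vcf)
  expect_true(all(startsWith(readLines(vcf), "#")))
  expect_equal(nrow(read_vcf(vcf)), 0)

  # an independent VCF parser agrees on the records
  write_vcf(calls, g, vcf)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), calls$position)
  expect_identical(unname(v@fix[, "ALT"]), calls$alt)
  af <- as.numeric(sub(".*AF=([^;]+).*", "\\1", v@fix[, "INFO"]))
  expect_equal(af, calls$alt_freq, tolerance = 1e-4)

  # coordinate 0 is rejected
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "a\t0\t.\tA\tG\t.\tPASS\tDP=1"), bad)
  expect_error(read_vcf(bad), "coordinate|invalid")
})
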