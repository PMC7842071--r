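#' Construct a genome set
#'
#' A `genome_set` is a named collection of chromosome-free bacterial reference
#' sequences over the strict alphabet `{A,C,G,T}`. It is the unit the read
#' simulator, pileup builder and evaluator all operate on.
#'
#' @param sequences Named character vector of DNA sequences.
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(sequences) {
  if (length(sequences) == 0L) stop("genome set must contain at least one genome")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all genomes must be named")
  if (anyDuplicated(names(sequences))) stop("duplicate genome labels")
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("non-ACGT characters in genome(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(list(seq = sequences, lengths = nchar(sequences)),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$seq), "genome(s),",
      format(total_size(x), big.mark = ","), "bp total\n")
  for (g in names(x$seq))
    cat("  ", g, ": ", format(x$lengths[[g]], big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Total size of a genome set in base pairs
#' @param genomes A `genome_set`.
#' @return Integer sum of member genome lengths.
#' @export
total_size <- function(genomes) {
  stopifnot(inherits(genomes, "genome_set"))
  sum(as.numeric(genomes$lengths))
}

#' Genome sizes of the five-species benchmark reference set
#'
#' Sizes (bp) of the five prevalent human-gut species used as the benchmark
#' reference set: Faecalibacterium prausnitzii, Prevotella copri,
#' Methanobrevibacter smithii, Eubacterium biforme and Treponema
#' succinifaciens. Their sum is 13,589,655 bp, the denominator of the
#' SNP-coverage metric.
#'
#' @param scale Multiplicative scale factor applied to every size (rounded);
#'   `scale = 0.1` gives the 1/10-scale set used for fast benchmark
#'   replicates, which preserves depth and SNP density.
#' @return Named numeric vector of genome sizes in bp.
#' @export
benchmark_genome_sizes <- function(scale = 1) {
  sizes <- c(F_prausnitzii  = 3080849,
             P_copri        = 3507873,
             M_smithii      = 1853160,
             E_biforme      = 2415920,
             T_succinifaciens = 2731853)
  if (scale <= 0) stop("scale must be positive")
  round(sizes * scale)
}

#' Synthesize random reference genomes
#'
#' Generates i.i.d. base sequences at a requested GC fraction. Stands in for
#' real reference genomes: base composition is irrelevant to the pileup and
#' density statistics downstream, only lengths matter.
#'
#' @param size_spec Named numeric vector: genome label -> length in bp.
#' @param gc_fraction Target GC proportion, strictly between 0 and 1.
#' @param seed Integer seed; the result is reproducible for a fixed seed.
#' @return A [genome_set()].
#' @export
synthesize_genomes <- function(size_spec, gc_fraction = 0.5, seed = 1) {
  if (is.null(names(size_spec)) || any(!nzchar(names(size_spec))))
    stop("size_spec must be a named vector of lengths")
  if (anyDuplicated(names(size_spec))) stop("duplicate genome labels")
  if (any(size_spec <= 0)) stop("genome lengths must be positive")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  set.seed(seed)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  seqs <- vapply(size_spec, function(n) {
    paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  genome_set(seqs)
}

#' Draw a ground-truth SNP list
#'
#' Allocates `n_sites` unique substitution sites across the genomes
#' proportionally to genome length (largest-remainder rounding), places them
#' uniformly at random, and draws each alternate base uniformly from the
#' three non-reference bases.
#'
#' @param genomes A [genome_set()].
#' @param n_sites Number of truth sites to plant (<= total size).
#' @param seed Integer seed.
#' @return A data frame with columns `genome_id`, `position` (1-based),
#'   `ref`, `alt`, sorted by genome and position.
#' @export
draw_snp_truth <- function(genomes, n_sites, seed = 1) {
  stopifnot(inherits(genomes, "genome_set"))
  if (n_sites < 0) stop("n_sites must be non-negative")
  total <- total_size(genomes)
  if (n_sites > total) stop("n_sites exceeds total genome size")
  empty <- data.frame(genome_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (n_sites == 0L) return(empty)
  set.seed(seed)

  # largest-remainder allocation keeps per-genome SNP density uniform
  quota <- n_sites * genomes$lengths / total
  alloc <- floor(quota)
  short <- n_sites - sum(alloc)
  if (short > 0) {
    extra <- order(quota - alloc, decreasing = TRUE)[seq_len(short)]
    alloc[extra] <- alloc[extra] + 1L
  }

  out <- lapply(names(genomes$seq), function(g) {
    k <- alloc[[g]]
    if (k == 0L) return(empty)
    pos <- sort(sample.int(genomes$lengths[[g]], k))
    ref <- substring(genomes$seq[[g]], pos, pos)
    alt <- other_base(ref, sample.int(3L, k, replace = TRUE))
    data.frame(genome_id = g, position = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Apply a truth list to a genome set
#'
#' Replaces the reference base with the alternate base at every truth site,
#' producing the mutated genome set used as the read-simulation template.
#' Errors if any record's `ref` does not match the genome, which signals an
#' inconsistent truth list.
#'
#' @param genomes A [genome_set()].
#' @param truth Truth data frame from [draw_snp_truth()].
#' @return The mutated [genome_set()]; lengths are unchanged and the mutated
#'   set differs from the input at exactly the truth positions.
#' @export
apply_snps <- function(genomes, truth) {
  stopifnot(inherits(genomes, "genome_set"))
  if (nrow(truth) == 0L) return(genomes)
  if (anyDuplicated(truth[c("genome_id", "position")]))
    stop("duplicate truth positions")
  seqs <- genomes$seq
  for (g in unique(truth$genome_id)) {
    if (!g %in% names(seqs)) stop("truth refers to unknown genome: ", g)
    tg <- truth[truth$genome_id == g, ]
    if (any(tg$position < 1L | tg$position > genomes$lengths[[g]]))
      stop("truth position outside genome ", g)
    raw <- charToRaw(seqs[[g]])
    cur <- rawToChar(raw[tg$position], multiple = TRUE)
    if (!all(cur == tg$ref))
      stop("ref-base mismatch in truth list for genome ", g)
    if (any(tg$ref == tg$alt)) stop("truth alt equals ref in genome ", g)
    raw[tg$position] <- charToRaw(paste(tg$alt, collapse = ""))
    seqs[[g]] <- rawToChar(raw)
  }
  genome_set(seqs)
}

#' Write / read a genome set as FASTA
#'
#' Plain FASTA wrapped at 70 columns; the round trip is lossless. Reading
#' validates the strict `{A,C,G,T}` alphabet.
#'
#' @param genomes A [genome_set()].
#' @param path File path.
#' @return `read_fasta()` returns a [genome_set()]; `write_fasta()` returns
#'   `path` invisibly.
#' @export
write_fasta <- function(genomes, path) {
  stopifnot(inherits(genomes, "genome_set"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genomes$seq),
                              filepath = path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_set(seqs)
}

#' Write / read a SNP truth list as TSV
#'
#' Tab-separated with a single `#`-prefixed header line and columns
#' `genome_id`, `position` (1-based), `ref`, `alt`.
#'
#' @param truth Truth data frame.
#' @param path File path.
#' @export
write_snp_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#genome_id\tposition\tref\talt", con)
  if (nrow(truth) > 0)
    writeLines(paste(truth$genome_id, truth$position, truth$ref, truth$alt,
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_snp_truth
#' @export
read_snp_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(genome_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) stop("malformed truth line")
  data.frame(genome_id = vapply(parts, `[`, "", 1L),
             position  = as.integer(vapply(parts, `[`, "", 2L)),
             ref       = vapply(parts, `[`, "", 3L),
             alt       = vapply(parts, `[`, "", 4L),
             stringsAsFactors = FALSE)
}
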