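#' Sequencing error model
#'
#' Per-base substitution, insertion and deletion probabilities for the read
#' simulator. Defaults reproduce the benchmark's simulation settings:
#' substitution rate 0.002, insertion and deletion rates 2e-5.
#'
#' @param snprate Per-base substitution (miscall) probability.
#' @param insrate Per-base insertion probability.
#' @param delrate Per-base deletion probability.
#' @return An object of class `error_model`.
#' @export
error_model <- function(snprate = 0.002, insrate = 2e-5, delrate = 2e-5) {
  rates <- c(snprate, insrate, delrate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1)
    stop("error rates must lie in [0,1) and sum to < 1")
  structure(list(snprate = snprate, insrate = insrate, delrate = delrate),
            class = "error_model")
}

#' Map a target fold-coverage to a read count
#'
#' The canonical mapping is `round(depth * total_size / read_length)` single
#' reads. For the full five-genome benchmark set at 75 bp this reproduces the
#' conventional 1M/2M/4M/8M read counts for 5x/10x/20x/40x within the
#' rounding those figures carry.
#'
#' @param depth Target fold-coverage (> 0).
#' @param genomes A [genome_set()] or a numeric total size in bp.
#' @param read_length Read length in bp (> 0).
#' @return Number of single reads (mates count individually).
#' @export
depth_to_read_count <- function(depth, genomes, read_length = 75) {
  if (depth <= 0) stop("depth must be positive")
  if (read_length <= 0) stop("read length must be positive")
  total <- if (inherits(genomes, "genome_set")) total_size(genomes)
           else as.numeric(genomes)
  round(depth * total / read_length)
}

#' Simulate paired-end reads from a (mutated) genome set
#'
#' Fragments are placed uniformly on a genome chosen proportionally to
#' length; mate 1 reads the fragment start on the plus strand, mate 2 the
#' reverse complement of the fragment end. Substitution errors replace a base
#' with a uniformly chosen different base; insertions and deletions edit the
#' read sequence in place, shifting the remainder of the read relative to the
#' reference. Each read's name encodes its true origin
#' (`r<pair>:<genome>:<start>:<strand>`), so downstream pileups can place
#' reads without alignment.
#'
#' Base qualities follow a constant-plus-noise profile: correctly read bases
#' draw from `N(qual_mean, qual_sd)` (default mean Q37), while miscalled and
#' inserted bases draw from the low `N(err_qual_mean, err_qual_sd)` profile
#' (default mean Q7), emulating the strong association between Illumina
#' miscalls and very low quality scores; under the default Q13 pileup floor
#' of [build_pileup()] almost all miscalled bases are then excluded from
#' pileups, as they are in real mpileup-based pipelines. Qualities are
#' clamped to `[2, 40]`.
#'
#' @param genomes Mutated [genome_set()] to read from.
#' @param n_reads Total number of single reads (rounded up to full pairs).
#' @param read_length Read length in bp.
#' @param error An [error_model()].
#' @param fragment_mean,fragment_sd Fragment-size distribution (bp).
#' @param qual_mean,qual_sd Quality profile of correct bases (Phred).
#' @param err_qual_mean,err_qual_sd Quality profile of erroneous bases.
#' @param seed Integer seed; identical seeds give identical reads.
#' @return A data frame of class `sim_reads` with columns `name`,
#'   `genome_id`, `start` (1-based on the reference), `strand`, `mate`,
#'   `seq`, `qual` (Phred+33 string), ordered pair-major (mate 1 then mate 2
#'   of each pair).
#' @export
simulate_reads <- function(genomes, n_reads, read_length = 75,
                           error = error_model(),
                           fragment_mean = 300, fragment_sd = 30,
                           qual_mean = 37, qual_sd = 2,
                           err_qual_mean = 7, err_qual_sd = 2,
                           seed = 1) {
  stopifnot(inherits(genomes, "genome_set"), inherits(error, "error_model"))
  if (n_reads <= 0) stop("n_reads must be positive")
  if (read_length <= 0) stop("read length must be positive")
  if (any(genomes$lengths < read_length))
    stop("genome shorter than the read length")
  set.seed(seed)
  L <- as.integer(read_length)
  n_pairs <- ceiling(n_reads / 2)

  # pairs per genome, proportional to genome length
  alloc <- as.vector(stats::rmultinom(1, n_pairs,
                                      genomes$lengths / total_size(genomes)))
  names(alloc) <- names(genomes$seq)

  pair_offset <- 0L
  per_genome <- lapply(names(genomes$seq), function(g) {
    m <- alloc[[g]]
    if (m == 0L) return(NULL)
    glen <- genomes$lengths[[g]]
    gseq <- genomes$seq[[g]]
    frag <- pmin(glen, pmax(L, round(rnorm(m, fragment_mean, fragment_sd))))
    start1 <- 1L + floor(runif(m) * (glen - frag + 1))
    end <- start1 + frag - 1L
    start2 <- end - L + 1L
    seq1 <- substring(gseq, start1, start1 + L - 1L)
    seq2 <- revcomp(substring(gseq, start2, end))
    ids <- pair_offset + seq_len(m)
    pair_offset <<- pair_offset + m
    df <- data.frame(
      pair = rep(ids, each = 2L),
      genome_id = g,
      start = as.integer(rbind(start1, start2)),
      strand = rep(c("+", "-"), m),
      mate = rep(1:2, m),
      seq = as.character(rbind(seq1, seq2)),
      stringsAsFactors = FALSE)
    df
  })
  reads <- do.call(rbind, per_genome)
  n <- nrow(reads)

  # base qualities: one long string sliced into per-read strings
  q <- pmax(2L, pmin(40L, as.integer(round(rnorm(n * L, qual_mean, qual_sd)))))
  qual_big <- rawToChar(as.raw(q + 33L))
  reads$qual <- substring(qual_big, seq.int(1L, by = L, length.out = n),
                          seq.int(L, by = L, length.out = n))

  reads <- apply_read_errors(reads, L, error, err_qual_mean, err_qual_sd,
                             genomes)
  reads$name <- sprintf("r%d:%s:%d:%s", reads$pair, reads$genome_id,
                        reads$start, reads$strand)
  reads$pair <- NULL
  reads <- reads[c("name", "genome_id", "start", "strand", "mate",
                   "seq", "qual")]
  rownames(reads) <- NULL
  class(reads) <- c("sim_reads", "data.frame")
  reads
}

# Edits read sequences/qualities in the sequenced orientation: first indels
# (which shift the rest of the read), then substitutions. Error bases get
# qualities from the low profile.
apply_read_errors <- function(reads, L, error, err_qual_mean, err_qual_sd,
                              genomes) {
  n <- nrow(reads)
  total <- n * L
  qchar <- function(k) {
    q <- pmax(2L, pmin(40L, as.integer(round(rnorm(k, err_qual_mean,
                                                   err_qual_sd)))))
    rawToChar(as.raw(q + 33L), multiple = TRUE)
  }

  # --- indels (rare; per-event loop) ---
  n_ins <- rbinom(1L, total, error$insrate)
  n_del <- rbinom(1L, total, error$delrate)
  if (n_ins + n_del > 0) {
    ev <- data.frame(
      kind = rep(c("ins", "del"), c(n_ins, n_del)),
      at = sample.int(total, n_ins + n_del),
      stringsAsFactors = FALSE)
    ev$read <- (ev$at - 1L) %/% L + 1L
    ev$off <- (ev$at - 1L) %% L + 1L
    dels_so_far <- integer(n)
    for (i in seq_len(nrow(ev))) {
      r <- ev$read[i]; j <- ev$off[i]
      s <- reads$seq[r]; qs <- reads$qual[r]
      if (ev$kind[i] == "ins") {
        nb <- sample(BASES, 1L)
        reads$seq[r] <- paste0(substr(s, 1L, j - 1L), nb,
                               substr(s, j, L - 1L))
        reads$qual[r] <- paste0(substr(qs, 1L, j - 1L), qchar(1L),
                                substr(qs, j, L - 1L))
      } else {
        dels_so_far[r] <- dels_so_far[r] + 1L
        ext <- template_extension(reads$genome_id[r], reads$start[r],
                                  reads$strand[r], L, dels_so_far[r], genomes)
        reads$seq[r] <- paste0(substr(s, 1L, j - 1L),
                               substr(s, j + 1L, L), ext)
        reads$qual[r] <- paste0(substr(qs, 1L, j - 1L),
                                substr(qs, j + 1L, L), qchar(1L))
      }
    }
  }

  # --- substitutions (vectorized passes; one pass per error rank within a
  # read so repeated edits to the same read are not lost) ---
  n_sub <- rbinom(1L, total, error$snprate)
  if (n_sub > 0) {
    at <- sample.int(total, n_sub)
    r <- (at - 1L) %/% L + 1L
    j <- (at - 1L) %% L + 1L
    rank <- stats::ave(seq_along(r), r, FUN = seq_along)
    for (k in seq_len(max(rank))) {
      sel <- rank == k
      rs <- r[sel]; js <- j[sel]
      s <- reads$seq[rs]
      cur <- substr(s, js, js)
      nb <- other_base(cur, sample.int(3L, length(rs), replace = TRUE))
      substr(s, js, js) <- nb
      reads$seq[rs] <- s
      qs <- reads$qual[rs]
      substr(qs, js, js) <- paste0(qchar(length(rs)))
      reads$qual[rs] <- qs
    }
  }
  reads
}

# Reference base that continues a read's template after a deletion, in the
# sequencing direction; falls back to a random base at genome edges.
template_extension <- function(genome_id, start, strand, L, n_del, genomes) {
  gseq <- genomes$seq[[genome_id]]
  glen <- genomes$lengths[[genome_id]]
  if (strand == "+") {
    p <- start + L - 1L + n_del
    if (p > glen) return(sample(BASES, 1L))
    substring(gseq, p, p)
  } else {
    p <- start - n_del
    if (p < 1L) return(sample(BASES, 1L))
    revcomp(substring(gseq, p, p))
  }
}

#' Parse read-name origin encoding
#'
#' Decodes `r<pair>:<genome>:<start>:<strand>` names back to their origin
#' tuples.
#'
#' @param names Character vector of read names (an optional `/1` or `/2`
#'   mate suffix is stripped).
#' @return Data frame with columns `genome_id`, `start`, `strand`.
#' @export
parse_read_names <- function(names) {
  names <- sub("/[12]$", "", names)
  parts <- strsplit(names, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) stop("unparseable read name")
  data.frame(genome_id = vapply(parts, `[`, "", 2L),
             start = as.integer(vapply(parts, `[`, "", 3L)),
             strand = vapply(parts, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Write / read simulated paired reads as FASTQ
#'
#' Standard 4-line FASTQ, one file per mate, `/1` and `/2` name suffixes.
#' The round trip is lossless.
#'
#' @param reads A `sim_reads` data frame.
#' @param path1,path2 Output FASTQ paths for mates 1 and 2.
#' @return `read_fastq()` returns a `sim_reads` data frame (pair-major
#'   order); `write_fastq()` returns the paths invisibly.
#' @export
write_fastq <- function(reads, path1, path2) {
  for (m in 1:2) {
    sel <- reads[reads$mate == m, ]
    path <- if (m == 1) path1 else path2
    if (nrow(sel) == 0L) {
      file.create(path)
      next
    }
    ss <- Biostrings::DNAStringSet(sel$seq)
    names(ss) <- paste0(sel$name, "/", m)
    Biostrings::writeXStringSet(ss, filepath = path, format = "fastq",
                                qualities = Biostrings::BStringSet(sel$qual))
  }
  invisible(c(path1, path2))
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path1, path2) {
  rd <- function(path, mate) {
    if (!file.exists(path)) stop("no such file: ", path)
    ss <- if (file.size(path) == 0L) Biostrings::DNAStringSet() else
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE)
    if (length(ss) == 0L)
      return(data.frame(name = character(), genome_id = character(),
                        start = integer(), strand = character(),
                        mate = integer(), seq = character(),
                        qual = character(), stringsAsFactors = FALSE))
    nm <- names(ss)
    if (any(!endsWith(nm, paste0("/", mate))))
      stop("mate suffix mismatch in ", path)
    org <- parse_read_names(nm)
    data.frame(name = sub("/[12]$", "", nm),
               genome_id = org$genome_id, start = org$start,
               strand = org$strand, mate = mate,
               seq = as.character(ss),
               qual = as.character(S4Vectors::mcols(ss)$qualities),
               stringsAsFactors = FALSE)
  }
  r1 <- rd(path1, 1L)
  r2 <- rd(path2, 2L)
  if (nrow(r1) != nrow(r2)) stop("desynchronized mate files")
  pair_of <- function(nm) sub(":.*$", "", nm)
  if (nrow(r1) && any(pair_of(r1$name) != pair_of(r2$name)))
    stop("desynchronized mate files")
  out <- rbind(r1, r2)
  if (nrow(r1)) {
    ord <- order(rep(seq_len(nrow(r1)), 2L), rep(1:2, each = nrow(r1)))
    out <- out[ord, ]
  }
  rownames(out) <- NULL
  class(out) <- c("sim_reads", "data.frame")
  out
}
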