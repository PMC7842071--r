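#' Build per-position pileups from origin-placed reads
#'
#' Stacks every read at the reference position encoded in its name, without
#' alignment (reads carry their true origin). Bases below `min_base_qual`
#' are excluded from the pileup, mirroring the default base-quality floor of
#' standard mpileup engines (Q13).
#'
#' A read that suffered an indel sequencing error carries a tail that is
#' shifted relative to the reference and would stack as a run of
#' high-quality mismatches. A gapped aligner absorbs or soft-clips such
#' tails; since placement here is by true origin, `clip_tails = TRUE`
#' (default) emulates that by clipping each read from the first position
#' where at least 4 of the following 8 bases mismatch the reference.
#' Isolated mismatches (true SNPs, miscalls) never trigger the rule. With
#' `clip_tails = FALSE` post-indel bases are stacked naively by offset.
#'
#' @param reads A `sim_reads` data frame (from [simulate_reads()] or
#'   [read_fastq()]).
#' @param reference The original (unmutated) [genome_set()].
#' @param min_base_qual Minimum Phred base quality for a base to enter the
#'   pileup.
#' @param clip_tails Soft-clip dense-mismatch read tails (see Details).
#' @return An object of class `pileup`: per genome a `4 x length` base-count
#'   matrix (rows A,C,G,T) and a matching quality-sum matrix.
#' @export
build_pileup <- function(reads, reference, min_base_qual = 13,
                         clip_tails = TRUE) {
  stopifnot(inherits(reference, "genome_set"))
  req <- c("genome_id", "start", "strand", "seq", "qual")
  if (!all(req %in% names(reads))) stop("reads are missing required columns")
  if (!all(reads$genome_id %in% names(reference$seq)))
    stop("read origin refers to unknown genome")
  per_genome <- lapply(names(reference$seq), function(g) {
    sel <- reads$genome_id == g
    glen <- reference$lengths[[g]]
    if (!any(sel)) {
      return(list(counts = matrix(0L, 4, glen),
                  qualsum = matrix(0, 4, glen)))
    }
    seqs <- reads$seq[sel]
    quals <- reads$qual[sel]
    minus <- reads$strand[sel] == "-"
    if (any(minus)) {
      # orient minus-strand reads to the reference strand
      seqs[minus] <- revcomp(seqs[minus])
      quals[minus] <- vapply(quals[minus], function(q)
        paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""),
        character(1), USE.NAMES = FALSE)
    }
    pileup_accumulate(as.integer(reads$start[sel]), seqs, quals,
                      reference$seq[[g]], as.integer(min_base_qual),
                      isTRUE(clip_tails))
  })
  names(per_genome) <- names(reference$seq)
  structure(list(genomes = per_genome, min_base_qual = min_base_qual),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup over", length(x$genomes), "genome(s), base-quality floor Q",
      x$min_base_qual, "\n")
  for (g in names(x$genomes)) {
    d <- colSums(x$genomes[[g]]$counts)
    cat(sprintf("  %s: %d covered positions, mean depth %.2f\n",
                g, sum(d > 0), mean(d[d > 0])))
  }
  invisible(x)
}

#' Extract pileup columns as a data frame
#'
#' Columns with zero depth are omitted.
#'
#' @param pileup A [build_pileup()] result.
#' @param genome_id Optional single genome to restrict to.
#' @return Data frame with `genome_id`, `position`, `depth`, per-base counts
#'   `A`, `C`, `G`, `T` and per-base quality sums `qA`..`qT`.
#' @export
pileup_columns <- function(pileup, genome_id = NULL) {
  stopifnot(inherits(pileup, "pileup"))
  gs <- if (is.null(genome_id)) names(pileup$genomes) else genome_id
  out <- lapply(gs, function(g) {
    cnt <- pileup$genomes[[g]]$counts
    qs <- pileup$genomes[[g]]$qualsum
    depth <- colSums(cnt)
    keep <- which(depth > 0)
    data.frame(genome_id = rep(g, length(keep)), position = keep,
               depth = depth[keep],
               A = cnt[1, keep], C = cnt[2, keep],
               G = cnt[3, keep], T = cnt[4, keep],
               qA = qs[1, keep], qC = qs[2, keep],
               qG = qs[3, keep], qT = qs[4, keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Caller threshold configuration
#'
#' Threshold semantics of the reimplemented pileup SNP caller. Defaults
#' follow the real-data settings (minimum depth 10, at least 2 supporting
#' reads, minimum mean base quality 15, minimum alternate-allele fraction
#' 0.2). Use [benchmark_config()] for the permissive benchmark settings.
#'
#' @param min_coverage Minimum site depth.
#' @param min_reads2 Minimum number of alternate-supporting reads.
#' @param min_avg_qual Minimum mean base quality at the site.
#' @param min_var_freq Minimum alternate-allele fraction.
#' @param qual_scope `"alt"` (default): `min_avg_qual` applies to the mean
#'   quality of alternate-supporting bases; `"column"`: to the whole-column
#'   mean.
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(min_coverage = 10, min_reads2 = 2,
                          min_avg_qual = 15, min_var_freq = 0.2,
                          qual_scope = c("alt", "column")) {
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  if (min_reads2 < 1) stop("min_reads2 must be >= 1")
  if (min_var_freq <= 0 || min_var_freq > 1)
    stop("min_var_freq must be in (0, 1]")
  structure(list(min_coverage = min_coverage, min_reads2 = min_reads2,
                 min_avg_qual = min_avg_qual, min_var_freq = min_var_freq,
                 qual_scope = match.arg(qual_scope)),
            class = "caller_config")
}

#' @rdname caller_config
#' @export
benchmark_config <- function() {
  caller_config(min_coverage = 1, min_reads2 = 1, min_avg_qual = 1,
                min_var_freq = 0.2)
}

#' Call SNPs from a pileup
#'
#' At every column the candidate alternate is the most frequent non-reference
#' base, with ties broken by the fixed base order A < C < G < T. A call is
#' emitted iff depth >= `min_coverage`, alternate reads >= `min_reads2`,
#' alternate fraction >= `min_var_freq`, and the mean quality of the
#' alternate-supporting bases (or the whole column, see `qual_scope`) is
#' >= `min_avg_qual`. Only substitutions are emitted; indels are never
#' called.
#'
#' @param pileup A [build_pileup()] result.
#' @param reference The original [genome_set()].
#' @param config A [caller_config()].
#' @return A data frame of class `variant_calls` with columns `genome_id`,
#'   `position`, `ref`, `alt`, `depth`, `alt_reads`, `alt_freq`,
#'   `mean_qual`, sorted by genome and position.
#' @export
call_snps <- function(pileup, reference, config = caller_config()) {
  stopifnot(inherits(pileup, "pileup"), inherits(reference, "genome_set"),
            inherits(config, "caller_config"))
  out <- lapply(names(pileup$genomes), function(g) {
    cnt <- pileup$genomes[[g]]$counts
    qs <- pileup$genomes[[g]]$qualsum
    glen <- ncol(cnt)
    depth <- colSums(cnt)
    refid <- base_ids(reference$seq[[g]])
    # mask the reference base, then take the most frequent remaining base;
    # max.col with ties.method "first" realizes the A<C<G<T tie-break
    nonref <- cnt
    nonref[cbind(refid, seq_len(glen))] <- -1L
    alt_id <- max.col(t(nonref), ties.method = "first")
    sel <- cbind(alt_id, seq_len(glen))
    alt_reads <- nonref[sel]
    mean_qual <- if (config$qual_scope == "alt") {
      ifelse(alt_reads > 0, qs[sel] / alt_reads, 0)
    } else {
      ifelse(depth > 0, colSums(qs) / depth, 0)
    }
    keep <- which(alt_reads >= config$min_reads2 &
                    depth >= config$min_coverage &
                    alt_reads >= config$min_var_freq * depth &
                    mean_qual >= config$min_avg_qual)
    data.frame(genome_id = rep(g, length(keep)), position = keep,
               ref = BASES[refid[keep]], alt = BASES[alt_id[keep]],
               depth = depth[keep], alt_reads = alt_reads[keep],
               alt_freq = alt_reads[keep] / depth[keep],
               mean_qual = mean_qual[keep],
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

#' Write / read SNP calls as VCF 4.2
#'
#' A fixed single-sample-free VCF 4.2 subset with INFO keys `DP` (depth),
#' `AD` (alternate reads), `AF` (alternate fraction, 4 decimals) and `MQS`
#' (mean base quality of alternate reads, 2 decimals). The round trip is
#' lossless to those precisions.
#'
#' @param calls A `variant_calls` data frame.
#' @param reference The [genome_set()] the calls refer to (for contig
#'   headers).
#' @param path Output path.
#' @export
write_vcf <- function(calls, reference, path) {
  stopifnot(inherits(reference, "genome_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(reference$seq),
                       reference$lengths),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
               "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele frequency\">",
               "##INFO=<ID=MQS,Number=1,Type=Float,Description=\"Mean alt base quality\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0) {
    info <- sprintf("DP=%d;AD=%d;AF=%.4f;MQS=%.2f", calls$depth,
                    calls$alt_reads, calls$alt_freq, calls$mean_qual)
    writeLines(paste(calls$genome_id, calls$position, ".", calls$ref,
                     calls$alt, ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  empty <- data.frame(genome_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_reads = integer(),
                      alt_freq = numeric(), mean_qual = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("variant_calls", "data.frame")
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 8L)) stop("malformed VCF line")
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  if (anyNA(pos) || any(pos < 1L)) stop("invalid VCF coordinate")
  info <- vapply(parts, `[`, "", 8L)
  grab <- function(key, cast) {
    v <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", info, perl = TRUE)
    cast(v)
  }
  out <- data.frame(genome_id = vapply(parts, `[`, "", 1L),
                    position = pos,
                    ref = vapply(parts, `[`, "", 4L),
                    alt = vapply(parts, `[`, "", 5L),
                    depth = grab("DP", as.integer),
                    alt_reads = grab("AD", as.integer),
                    alt_freq = grab("AF", as.numeric),
                    mean_qual = grab("MQS", as.numeric),
                    stringsAsFactors = FALSE)
  if (any(out$ref == out$alt)) stop("VCF record with ALT equal to REF")
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Write a pileup as an mpileup-like TSV
#'
#' One row per covered position: genome, position, reference base, depth and
#' A/C/G/T counts, with a `#`-prefixed header line.
#'
#' @param pileup A [build_pileup()] result.
#' @param reference The [genome_set()].
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, reference, path) {
  df <- pileup_columns(pileup)
  ref <- vapply(seq_len(nrow(df)), function(i)
    substring(reference$seq[[df$genome_id[i]]], df$position[i],
              df$position[i]), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#genome_id\tposition\tref\tdepth\tA\tC\tG\tT", con)
  writeLines(paste(df$genome_id, df$position, ref, df$depth,
                   df$A, df$C, df$G, df$T, sep = "\t"), con)
  invisible(path)
}
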