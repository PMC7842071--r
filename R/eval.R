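#' Classify SNP calls against a ground-truth list
#'
#' Taxonomy: a call at a truth site with the truth alternate base is a
#' *match*; at a truth site with a different alternate base a *mismatch*; at
#' a non-truth site a *false positive*; truth sites with no call are *false
#' negatives*. `match + mismatch + false_negative == all_true` and
#' `all_identified == match + mismatch + false_positive` hold by
#' construction.
#'
#' @param calls A `variant_calls` data frame (unique per genome/position).
#' @param truth Truth data frame from [draw_snp_truth()].
#' @return An object of class `eval_counts` with fields `match`, `mismatch`,
#'   `false_positive`, `false_negative`, `all_true`, `all_identified`.
#' @export
classify_calls <- function(calls, truth) {
  ck <- paste(calls$genome_id, calls$position)
  tk <- paste(truth$genome_id, truth$position)
  if (anyDuplicated(ck)) stop("duplicate call positions")
  if (anyDuplicated(tk)) stop("duplicate truth positions")
  hit <- match(ck, tk)
  at_truth <- !is.na(hit)
  n_match <- sum(at_truth & calls$alt == truth$alt[hit])
  n_mismatch <- sum(at_truth) - n_match
  n_fp <- sum(!at_truth)
  n_fn <- nrow(truth) - sum(at_truth)
  structure(list(match = n_match, mismatch = n_mismatch,
                 false_positive = n_fp, false_negative = n_fn,
                 all_true = nrow(truth), all_identified = nrow(calls)),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf(paste0("eval_counts: match %d, mismatch %d, FP %d, FN %d ",
                     "(all true %d, all identified %d)\n"),
              x$match, x$mismatch, x$false_positive, x$false_negative,
              x$all_true, x$all_identified))
  invisible(x)
}

#' Sensitivity: percent of true SNPs recovered with the correct base
#'
#' `100 * match / all_true`, reported to one decimal.
#'
#' @param counts An `eval_counts` object (or a list with `match` and
#'   `all_true`).
#' @return Percent, rounded to one decimal.
#' @export
sensitivity <- function(counts) {
  if (counts$all_true == 0) stop("no true SNPs: sensitivity undefined")
  round(100 * counts$match / counts$all_true, 1)
}

#' Selectivity: one minus the error fraction over the true-SNP count
#'
#' `100 * (1 - (false_positive + mismatch) / all_true)`, to one decimal.
#' Note the denominator is the number of *true* SNPs, not the number of
#' identified SNPs - an unusual convention, kept because it is the one under
#' which the published benchmark values reconcile (e.g. 1 - 52/10,786 =
#' 99.5%).
#'
#' @param counts An `eval_counts` object.
#' @return Percent, rounded to one decimal (may be negative if errors exceed
#'   the truth count).
#' @export
selectivity <- function(counts) {
  if (counts$all_true == 0) stop("no true SNPs: selectivity undefined")
  round(100 * (1 - (counts$false_positive + counts$mismatch) /
                 counts$all_true), 1)
}

#' SNP coverage: identified SNPs per reference base pair, as a percent
#'
#' `100 * all_identified / total_size`, reported to three decimals.
#'
#' @param all_identified Number of SNPs identified by the caller.
#' @param genomes A [genome_set()] or a numeric total size in bp.
#' @return Percent, rounded to three decimals.
#' @export
snp_coverage <- function(all_identified, genomes) {
  total <- if (inherits(genomes, "genome_set")) total_size(genomes)
           else as.numeric(genomes)
  if (total <= 0) stop("total genome size must be positive")
  round(100 * all_identified / total, 3)
}

#' Full evaluation report for one caller run
#'
#' @param calls A `variant_calls` data frame.
#' @param truth Truth data frame.
#' @param genomes The reference [genome_set()] (SNP-coverage denominator).
#' @param caller_label,depth_label Labels carried into the report.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(calls, truth, genomes, caller_label = "caller",
                        depth_label = "") {
  counts <- classify_calls(calls, truth)
  structure(list(counts = counts,
                 sensitivity = sensitivity(counts),
                 selectivity = selectivity(counts),
                 snp_coverage = snp_coverage(counts$all_identified, genomes),
                 caller_label = caller_label, depth_label = depth_label),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s %s: sensitivity %.1f%%, selectivity %.1f%%, SNP coverage %.3f%%\n",
              x$caller_label, x$depth_label, x$sensitivity, x$selectivity,
              x$snp_coverage))
  print(x$counts)
  invisible(x)
}

#' Tabulate evaluation reports across caller runs
#'
#' One row per run, mirroring the benchmark-table layout: labels, the four
#' classification counts, the number of identified SNPs, and the three
#' metrics.
#'
#' @param runs A list of runs, each a list with elements `caller_label`,
#'   `depth_label` and `calls`.
#' @param truth Truth data frame.
#' @param genomes Reference [genome_set()].
#' @param path Optional TSV output path (written with a `#` header line).
#' @return Data frame of class `benchmark_report`.
#' @export
benchmark_report <- function(runs, truth, genomes, path = NULL) {
  rows <- lapply(runs, function(r) {
    rep_ <- eval_report(r$calls, truth, genomes,
                        caller_label = r$caller_label %||% "caller",
                        depth_label = r$depth_label %||% "")
    data.frame(caller = rep_$caller_label, depth = rep_$depth_label,
               match = rep_$counts$match, mismatch = rep_$counts$mismatch,
               false_positive = rep_$counts$false_positive,
               false_negative = rep_$counts$false_negative,
               all_snps = rep_$counts$all_identified,
               snp_coverage = rep_$snp_coverage,
               sensitivity = rep_$sensitivity,
               selectivity = rep_$selectivity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  class(out) <- c("benchmark_report", "data.frame")
  out
}

#' Plot sensitivity and selectivity against sequencing depth
#'
#' @param x A `benchmark_report`.
#' @param ... Passed to [graphics::matplot()].
#' @method plot benchmark_report
#' @export
plot.benchmark_report <- function(x, ...) {
  depth <- as.numeric(sub("x$", "", x$depth))
  graphics::matplot(depth, cbind(x$sensitivity, x$selectivity),
                    type = "b", pch = c(1, 2), lty = 1,
                    xlab = "sequencing depth (x)", ylab = "percent", ...)
  graphics::legend("bottomright", c("sensitivity", "selectivity"),
                   pch = c(1, 2), lty = 1, col = 1:2, bty = "n")
  invisible(x)
}

#' Per-season SNP totals and per-sample averages
#'
#' Aggregates per-sample SNP counts by season: total SNPs, number of
#' samples, and the average SNPs per sample (`round(total / n)`,
#' round-half-even).
#'
#' @param snp_counts Named numeric vector of per-sample SNP counts (names
#'   are sample ids).
#' @param meta Sample metadata data frame with `sample_id` and `season`.
#' @return Data frame with one row per season: `season`, `n_samples`,
#'   `total_snps`, `mean_snps`.
#' @export
season_snp_totals <- function(snp_counts, meta) {
  season <- meta$season[match(names(snp_counts), meta$sample_id)]
  if (anyNA(season)) stop("sample id missing from metadata")
  tot <- tapply(snp_counts, season, sum)
  n <- tapply(snp_counts, season, length)
  data.frame(season = names(tot), n_samples = as.integer(n),
             total_snps = as.numeric(tot),
             mean_snps = round(as.numeric(tot) / as.integer(n)),
             stringsAsFactors = FALSE, row.names = NULL)
}
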