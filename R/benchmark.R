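#' Benchmark configuration
#'
#' All tunables of the simulate / correct / evaluate pipeline in one
#' validated object. A single `seed` governs every stochastic stage through
#' derived per-stage sub-seeds, so a run is reproducible end to end.
#'
#' @param n_genes,isoform_range,exon_count_range,exon_length_range,minor_abundance
#'   see [simulate_genes()].
#' @param depth,mismatch_rate,insert_rate,delete_rate,full_length_fraction
#'   see [simulate_reads()].
#' @param params correction parameters ([correction_params()]); the
#'   windowed run uses them as given, the baseline run with
#'   `identity_threshold = 0`.
#' @param raw_threshold,corrected_threshold,margin_min,map_threshold,band
#'   evaluation thresholds (see [assign_isoforms()],
#'   [compute_read_metrics()]).
#' @param seed master seed.
#' @return list of class `isocorr_config`.
#' @export
benchmark_config <- function(n_genes = 100L, isoform_range = c(2L, 2L),
                             exon_count_range = c(5L, 7L),
                             exon_length_range = c(150L, 300L),
                             minor_abundance = 0.2, depth = 30L,
                             mismatch_rate = 0.04, insert_rate = 0.05,
                             delete_rate = 0.04, full_length_fraction = 0.85,
                             params = correction_params(),
                             raw_threshold = 0.30, corrected_threshold = 0.10,
                             margin_min = 20, map_threshold = 0.35,
                             band = 200L, seed = 1L) {
  stopifnot(inherits(params, "isocorr_params"))
  stopifnot(seed == floor(seed), abs(seed) < 2^30)
  structure(list(n_genes = as.integer(n_genes),
                 isoform_range = as.integer(isoform_range),
                 exon_count_range = as.integer(exon_count_range),
                 exon_length_range = as.integer(exon_length_range),
                 minor_abundance = minor_abundance,
                 depth = as.integer(depth), mismatch_rate = mismatch_rate,
                 insert_rate = insert_rate, delete_rate = delete_rate,
                 full_length_fraction = full_length_fraction,
                 params = params, raw_threshold = raw_threshold,
                 corrected_threshold = corrected_threshold,
                 margin_min = margin_min, map_threshold = map_threshold,
                 band = as.integer(band), seed = as.integer(seed)),
            class = "isocorr_config")
}

#' Run the paired windowed-vs-baseline benchmark
#'
#' Simulates genes and reads, corrects the read set twice (windowed mode
#' and the windowing-disabled baseline), evaluates both against the
#' simulator truth, and returns paired reports: read metrics, isoform
#' retention and a per-bin loss comparison. When `out_dir` is given, the
#' reports are written as tab-separated files with a commented header
#' recording every parameter and the seed.
#'
#' @param config an [benchmark_config()] object.
#' @param out_dir optional report directory (created if missing).
#' @param progress passed to [correct_reads()].
#' @return an `isocorr_benchmark` object: list with `genes`, `sim`,
#'   `windowed`/`baseline` corrections, `metrics` (two-row tibble),
#'   `retention_windowed`/`retention_baseline`, and `loss_comparison`
#'   (per-bin losses of both modes). Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
run_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                          progress = 0L) {
  stopifnot(inherits(config, "isocorr_config"))
  genes <- simulate_genes(config$n_genes, config$isoform_range,
                          config$exon_count_range, config$exon_length_range,
                          config$minor_abundance, seed = config$seed + 1L)
  sim <- simulate_reads(genes, config$depth, config$mismatch_rate,
                        config$insert_rate, config$delete_rate,
                        config$full_length_fraction, seed = config$seed + 2L)
  p_win <- config$params
  p_base <- config$params
  p_base$identity_threshold <- 0
  p_base$baseline <- TRUE
  both <- correct_reads_multi(sim$reads, list(p_win, p_base),
                              progress = progress)
  cw <- both[[1]]
  cb <- both[[2]]
  metrics <- dplyr::bind_rows(
    windowed = compute_read_metrics(sim$reads, cw$corrected, genes, sim$truth,
                                    config$map_threshold, config$band),
    baseline = compute_read_metrics(sim$reads, cb$corrected, genes, sim$truth,
                                    config$map_threshold, config$band),
    .id = "mode")
  raw_asg <- assign_isoforms(sim$reads, genes, sim$truth,
                             config$raw_threshold, config$margin_min,
                             config$band)
  rw <- isoform_retention(sim$reads, cw$corrected, genes, sim$truth,
                          config$raw_threshold, config$corrected_threshold,
                          config$margin_min, config$band,
                          raw_assignments = raw_asg)
  rb <- isoform_retention(sim$reads, cb$corrected, genes, sim$truth,
                          config$raw_threshold, config$corrected_threshold,
                          config$margin_min, config$band,
                          raw_assignments = raw_asg)
  loss <- dplyr::bind_rows(windowed = rw$by_coverage,
                           baseline = rb$by_coverage, .id = "mode")
  out <- structure(list(config = config, genes = genes, sim = sim,
                        windowed = cw, baseline = cb, metrics = metrics,
                        retention_windowed = rw, retention_baseline = rb,
                        loss_comparison = loss),
                   class = "isocorr_benchmark")
  if (!is.null(out_dir)) write_benchmark_reports(out, out_dir)
  out
}

write_benchmark_reports <- function(bench, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- format_params_header(bench$config$params, seed = bench$config$seed)
  wr <- function(tbl, name) {
    path <- file.path(out_dir, name)
    writeLines(hdr, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  wr(bench$metrics, "metrics.tsv")
  wr(dplyr::bind_rows(windowed = bench$retention_windowed$per_gene,
                      baseline = bench$retention_baseline$per_gene,
                      .id = "mode"), "retention.tsv")
  wr(bench$loss_comparison, "loss_by_coverage.tsv")
  wr(glance(bench), "summary.tsv")
  invisible(out_dir)
}

#' @export
print.isocorr_benchmark <- function(x, ...) {
  g <- glance(x)
  cat("<isocorr_benchmark>\n")
  cat(sprintf("  genes: %d, reads: %d\n", x$config$n_genes, nrow(x$sim$reads)))
  cat(sprintf("  error rate: windowed %.3f%%, baseline %.3f%%\n",
              100 * g$error_rate_windowed, 100 * g$error_rate_baseline))
  cat(sprintf("  isoforms lost: windowed %d, baseline %d\n",
              g$lost_windowed, g$lost_baseline))
  invisible(x)
}

#' @describeIn run_benchmark per-bin loss table for both modes.
#' @param x an `isocorr_benchmark` object.
#' @param ... unused.
#' @export
tidy.isocorr_benchmark <- function(x, ...) x$loss_comparison

#' @describeIn run_benchmark one-row summary comparing the two modes.
#' @export
glance.isocorr_benchmark <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n_reads = nrow(x$sim$reads),
    n_corrected_windowed = m$n_read[m$mode == "windowed"],
    n_corrected_baseline = m$n_read[m$mode == "baseline"],
    error_rate_windowed = m$error_rate[m$mode == "windowed"],
    error_rate_baseline = m$error_rate[m$mode == "baseline"],
    lost_windowed = sum(x$retention_windowed$isoforms$lost),
    lost_baseline = sum(x$retention_baseline$isoforms$lost))
}

#' @describeIn run_benchmark grouped per-bin loss bars, windowed vs
#'   baseline.
#' @param object an `isocorr_benchmark` object.
#' @export
autoplot.isocorr_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$loss_comparison,
                  ggplot2::aes(x = .data$bin, y = .data$n_lost,
                               fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "relative coverage bin (upper edge)",
                  y = "isoforms lost",
                  title = "Isoform loss by relative coverage") +
    ggplot2::theme_minimal()
}
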