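#' Infer a directed regulatory network from an expression profile
#'
#' The high-level entry point running the full supervised pipeline:
#' \enumerate{
#'   \item pairwise statistics for all `n(n-1)/2` gene pairs
#'     ([pair_stats()]): binned mutual information, Pearson correlation
#'     with exact P-value, associativity measure;
#'   \item P-value threshold calibration on the fixed ladder
#'     ([adapt_p_threshold()]) when `p_threshold = "adapt"` — datasets
#'     whose significant fraction cannot cover the authentic-group band
#'     get a lifted cut;
#'   \item centroid-initialised threshold iteration under knowledge
#'     constraints ([moco_solve()]), partitioning pairs into authentic /
#'     questionable / unauthentic groups;
#'   \item per-pair cross-spectral phase calls ([cross_spectrum()],
#'     [call_direction()]) under the gain threshold;
#'   \item network assembly ([build_network()]).
#' }
#'
#' @param profile An [expression_profile] with at least two genes.
#' @param bins Mutual-information histogram bins; `NULL` for the
#'   cube-root default of [pair_stats()].
#' @param weights Associativity weights; `"centroid"` (default) or
#'   `c(w1, w2)`.
#' @param p_threshold `"adapt"` (default) to calibrate on the ladder, or
#'   a fixed numeric cut.
#' @param min_candidate_fraction Significant-pair fraction the ladder
#'   must reach; defaults to the lower edge of `target_fraction`, since
#'   authentic pairs are a subset of the significant ones.
#' @param target_fraction Authentic-group fraction band (default
#'   `c(0.30, 0.45)`).
#' @param delta_mi,delta_cc Threshold increments (default 0.005).
#' @param gain_threshold Transfer-gain constraint for direction calling
#'   (default 0.3).
#' @param zero_phase_tol Zero-phase tolerance in radians (default
#'   `pi/36`).
#' @param coherence_min Coherence reliability floor for direction calls
#'   (default 0.9, see [call_direction()]).
#' @param knowledge A [knowledge_constraints()] object or `NULL`.
#' @param max_iter Threshold-iteration cap.
#' @return An object of class `phasenet_fit`: list with `stats`,
#'   `result` (the `moco_result`), `calls` (named list of phase calls for
#'   every pair), `network`, `p_threshold`, `centroids` and `params`.
#' @examples
#' sim <- simulate_expression(planted_network(n_genes = 8, n_edges = 5,
#'                                            seed = 7))
#' fit <- infer_network(sim$profile)
#' fit
#' @export
infer_network <- function(profile, bins = NULL, weights = "centroid",
                          p_threshold = "adapt",
                          min_candidate_fraction = NULL,
                          target_fraction = c(0.30, 0.45),
                          delta_mi = 0.005, delta_cc = 0.005,
                          gain_threshold = 0.3,
                          zero_phase_tol = pi / 36, coherence_min = 0.9,
                          knowledge = NULL, max_iter = 10000L) {
  stopifnot(inherits(profile, "expression_profile"))
  if (is.null(knowledge))
    knowledge <- knowledge_constraints(gain_threshold = gain_threshold)

  stats <- pair_stats(profile, bins = bins, weights = weights)
  cent <- attr(stats, "centroids")

  if (identical(p_threshold, "adapt")) {
    if (is.null(min_candidate_fraction))
      min_candidate_fraction <- target_fraction[1L]
    p_th <- adapt_p_threshold(stats, min_candidate_fraction)
  } else {
    p_th <- as.numeric(p_threshold)
  }
  init <- thresholds(cent$mi, min(1, cent$cor), p_th = p_th,
                     delta_mi = delta_mi, delta_cc = delta_cc)

  result <- moco_solve(stats, init = init, knowledge = knowledge,
                       target_fraction = target_fraction,
                       max_iter = max_iter)

  calls <- all_phase_calls(profile, stats,
                           gain_threshold = knowledge$gain_threshold,
                           zero_phase_tol = zero_phase_tol,
                           coherence_min = coherence_min)
  network <- build_network(result$partition, calls, stats,
                           all_genes = profile$gene_ids)

  structure(list(profile = profile, stats = stats, result = result,
                 calls = calls, network = network,
                 p_threshold = p_th, centroids = cent,
                 params = list(bins = attr(stats, "bins"),
                               weights = attr(stats, "weights"),
                               target_fraction = target_fraction,
                               delta_mi = delta_mi, delta_cc = delta_cc,
                               gain_threshold = knowledge$gain_threshold,
                               zero_phase_tol = zero_phase_tol,
                               coherence_min = coherence_min)),
            class = "phasenet_fit")
}

# One phase call per pair of the statistics table; pairs whose spectrum
# is degenerate (constant series) fall back to an absent-field
# undirected call.
all_phase_calls <- function(profile, stats, gain_threshold,
                            zero_phase_tol, coherence_min = 0.9) {
  calls <- vector("list", nrow(stats))
  names(calls) <- stats$pair_id
  for (k in seq_len(nrow(stats))) {
    a <- profile$values[stats$gene_a[k], ]
    b <- profile$values[stats$gene_b[k], ]
    calls[[k]] <- tryCatch(
      call_direction(cross_spectrum(a, b), gain_threshold,
                     zero_phase_tol, coherence_min),
      error = function(e) undirected_call())
  }
  calls
}

#' @export
print.phasenet_fit <- function(x, ...) {
  part <- x$result$partition
  cat("Directed regulatory network inference\n")
  cat(sprintf("  %d genes, %d time points, %d pair candidates\n",
              length(x$profile$gene_ids),
              length(x$profile$time_points_h), nrow(x$stats)))
  cat(sprintf("  centroids: MI %.4f bits, |r| %.4f; P threshold %.3g\n",
              x$centroids$mi, x$centroids$cor, x$p_threshold))
  cat(sprintf("  thresholds after %d iterations (%s): MI %.4f, |r| %.4f\n",
              part$iterations, part$status,
              part$thresholds_used$mi_th, part$thresholds_used$cc_th))
  cat(sprintf("  partition: %d authentic / %d questionable / %d unauthentic\n",
              length(part$apgs), length(part$qpgs), length(part$upgs)))
  print(x$network)
  invisible(x)
}

#' @export
summary.phasenet_fit <- function(object, ...) {
  print(object)
  deg <- degree_summary(object$network)
  cat(sprintf("  mean total degree: %.3f\n",
              attr(deg, "mean_total_degree")))
  invisible(list(degrees = deg,
                 constraint_report = object$result$constraint_report,
                 history = object$result$partition$history))
}

#' @export
plot.phasenet_fit <- function(x, ...) {
  plot(x$network, ...)
}

#' Score a fit against a planted ground truth
#'
#' For simulation studies: the fraction of planted edges whose unordered
#' pair was recovered into the authentic group (`recall`), and, among
#' recovered pairs with a directed call, the fraction oriented toward the
#' planted target (`orientation_accuracy`).
#'
#' @param fit A `phasenet_fit`.
#' @param truth Data frame with columns `source`, `target` (the planted
#'   edges, as returned by [simulate_expression()]).
#' @return List with `recall`, `orientation_accuracy`, `n_planted`,
#'   `n_recovered`, `n_directed`.
#' @export
score_recovery <- function(fit, truth) {
  stopifnot(inherits(fit, "phasenet_fit"))
  truth_key <- paste(pmin(truth$source, truth$target),
                     pmax(truth$source, truth$target), sep = "|")
  apgs <- fit$result$partition$apgs
  recovered <- truth_key %in% apgs
  d <- fit$network$directed_edges
  dir_key <- paste(d$source, d$target, sep = ">")
  truth_dir <- paste(truth$source, truth$target, sep = ">")
  has_dir <- recovered & (truth_key %in% paste(
    pmin(d$source, d$target), pmax(d$source, d$target), sep = "|"))
  correct <- truth_dir %in% dir_key
  list(recall = mean(recovered),
       orientation_accuracy = if (any(has_dir))
         sum(correct & has_dir) / sum(has_dir) else NA_real_,
       n_planted = length(truth_key),
       n_recovered = sum(recovered),
       n_directed = sum(has_dir))
}

#' Run the inference pipeline from a configuration
#'
#' Batch interface over [infer_network()]: reads a YAML configuration (or
#' takes an equivalent named list), averages replicate input tables, runs
#' the pipeline, and writes the full output bundle — pair statistics,
#' partition, phase calls, network files (one set per gain threshold),
#' and a run log recording centroids, every threshold iteration and the
#' constraint report.
#'
#' Recognised configuration keys (all optional except `input`):
#' `input` (path or list of replicate paths), `out_dir` (default
#' `"phasenet_out"`), `bins`, `weights`, `p_threshold` (number or
#' `"adapt"`), `min_candidate_fraction`, `band` (two numbers),
#' `delta_mi`, `delta_cc`, `gain_thresholds` (one or more numbers),
#' `zero_phase_tol`, `knowledge` (path, see [read_knowledge()]), `seed`.
#'
#' @param config Path to a YAML file or a named list.
#' @return Invisibly, a named list of `phasenet_fit` objects, one per
#'   gain threshold.
#' @export
run_infer <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$input)) stop("config needs an 'input' path", call. = FALSE)
  out_dir <- cfg$out_dir %||% "phasenet_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))

  paths <- unlist(cfg$input)
  profiles <- lapply(paths, read_expression_table)
  profile <- if (length(profiles) > 1L) average_replicates(profiles)
             else profiles[[1L]]

  knowledge_path <- cfg$knowledge
  gains <- as.numeric(cfg$gain_thresholds %||% 0.3)
  band <- as.numeric(cfg$band %||% c(0.30, 0.45))

  log_lines <- c(sprintf("phasenet run: %d genes x %d time points",
                         length(profile$gene_ids),
                         length(profile$time_points_h)),
                 paste("inputs:", paste(paths, collapse = ", ")))
  fits <- list()
  for (g in gains) {
    knowledge <- if (!is.null(knowledge_path))
      read_knowledge(knowledge_path, gain_threshold = g)
    else knowledge_constraints(gain_threshold = g)
    fit <- infer_network(
      profile,
      bins = cfg$bins %||% NULL,
      weights = cfg$weights %||% "centroid",
      p_threshold = cfg$p_threshold %||% "adapt",
      min_candidate_fraction = cfg$min_candidate_fraction %||% NULL,
      target_fraction = band,
      delta_mi = cfg$delta_mi %||% 0.005,
      delta_cc = cfg$delta_cc %||% 0.005,
      zero_phase_tol = cfg$zero_phase_tol %||% (pi / 36),
      coherence_min = cfg$coherence_min %||% 0.9,
      knowledge = knowledge)
    tag <- sub("\\.?0+$", "", sprintf("g%.4f", g))
    fits[[tag]] <- fit

    export_network(fit$network,
                   file.path(out_dir, paste0("network_", tag, ".tsv")),
                   "edge-table")
    export_network(fit$network,
                   file.path(out_dir, paste0("network_", tag, ".sif")),
                   "sif")
    export_network(fit$network,
                   file.path(out_dir, paste0("network_", tag, ".graphml")),
                   "graphml")

    part <- fit$result$partition
    log_lines <- c(
      log_lines, "",
      sprintf("gain threshold %.4g:", g),
      sprintf("  centroids: MI %.6f, |r| %.6f", fit$centroids$mi,
              fit$centroids$cor),
      sprintf("  P threshold: %.4g", fit$p_threshold),
      sprintf("  PGHC status: %s after %d iterations", part$status,
              part$iterations),
      "  iteration trace (iteration, mi_th, cc_th, apgs, qpgs, upgs):",
      sprintf("    %d\t%.6f\t%.6f\t%d\t%d\t%d",
              part$history$iteration, part$history$mi_th,
              part$history$cc_th, part$history$apgs, part$history$qpgs,
              part$history$upgs),
      "  constraint report:",
      sprintf("    %s: %s %s", fit$result$constraint_report$constraint,
              ifelse(fit$result$constraint_report$pass, "pass", "FAIL"),
              fit$result$constraint_report$detail))
  }

  first <- fits[[1L]]
  write_pair_stats(first$stats, file.path(out_dir, "pair_stats.tsv"))
  write_partition(first$result$partition,
                  file.path(out_dir, "partition.tsv"))
  write_phase_calls(first$calls, first$stats,
                    file.path(out_dir, "phase_calls.tsv"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-pair phase calls as a delimited table
#'
#' @param calls Named list of phase calls (as in a `phasenet_fit`).
#' @param stats The matching `pair_stats` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_calls <- function(calls, stats, path) {
  stats <- as_pair_stats(stats)
  header <- paste(c("gene_a", "gene_b", "direction", "dominant_frequency",
                    "phase_rad", "gain", "coherence"), collapse = "\t")
  rows <- vapply(seq_len(nrow(stats)), function(i) {
    cl <- calls[[stats$pair_id[i]]]
    paste(c(stats$gene_a[i], stats$gene_b[i], cl$direction,
            fmt_num(c(cl$dominant_frequency, cl$phase_rad, cl$gain,
                      cl$coherence))), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
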