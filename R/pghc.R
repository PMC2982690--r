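#' Threshold set for the pairwise hierarchy criterion
#'
#' Bundles the mutual-information threshold (bits), the correlation-
#' magnitude threshold, the P-value cut, and the per-iteration increments
#' used by [pghc_iterate()]. Thresholds are conventionally initialised at
#' the metric centroids (see [centroids()]).
#'
#' @param mi_th Mutual-information threshold, `>= 0` (bits).
#' @param cc_th Correlation-magnitude threshold in `[0, 1]`.
#' @param p_th P-value threshold in `(0, 1]`; default 0.05.
#' @param delta_mi,delta_cc Positive per-iteration increments; default
#'   0.005 each.
#' @return An object of class `pghc_thresholds`.
#' @export
thresholds <- function(mi_th, cc_th, p_th = 0.05,
                       delta_mi = 0.005, delta_cc = 0.005) {
  stopifnot(is.finite(mi_th), is.finite(cc_th), is.finite(p_th),
            is.finite(delta_mi), is.finite(delta_cc))
  if (mi_th < 0) stop("mi_th must be >= 0", call. = FALSE)
  if (cc_th < 0 || cc_th > 1) stop("cc_th must lie in [0, 1]", call. = FALSE)
  if (p_th <= 0 || p_th > 1) stop("p_th must lie in (0, 1]", call. = FALSE)
  if (delta_mi <= 0 || delta_cc <= 0)
    stop("increments must be positive", call. = FALSE)
  structure(list(mi_th = mi_th, cc_th = cc_th, p_th = p_th,
                 delta_mi = delta_mi, delta_cc = delta_cc),
            class = "pghc_thresholds")
}

#' @export
print.pghc_thresholds <- function(x, ...) {
  cat(sprintf(
    "PGHC thresholds: MI >= %.4g bits, |r| >= %.4g, P <= %.4g (deltas %.3g / %.3g)\n",
    x$mi_th, x$cc_th, x$p_th, x$delta_mi, x$delta_cc))
  invisible(x)
}

#' Classify gene pairs into authentic / questionable / unauthentic groups
#'
#' One pass of the pairwise hierarchy rule at fixed thresholds:
#' \describe{
#'   \item{APGs (authentic)}{`mi >= mi_th` and `|r| >= cc_th` and
#'     `p <= p_th` — both metrics clear their thresholds and the
#'     correlation is significant.}
#'   \item{QPGs (questionable)}{exactly one side holds: MI clears its
#'     threshold but the correlation criterion (`|r| >= cc_th` with
#'     `p <= p_th`) fails, or vice versa.}
#'   \item{UPGs (unauthentic)}{neither side holds.}
#' }
#' Comparisons are closed (`>=`, `<=`), so thresholds of `(0, 0, 1)` place
#' every pair in the authentic group.
#'
#' @param stats A `pair_stats` data frame (see [pair_stats()]).
#' @param th A [thresholds()] object.
#' @return An object of class `pghc_partition`: list with character-vector
#'   members `apgs`, `qpgs`, `upgs` (pair ids), `thresholds_used`,
#'   `iterations = 0`, `status = "classified"`.
#' @export
classify_once <- function(stats, th) {
  stats <- as_pair_stats(stats)
  stopifnot(inherits(th, "pghc_thresholds"))
  if (!nrow(stats)) stop("empty pair-statistics collection", call. = FALSE)
  mi_ok <- stats$mi_bits >= th$mi_th
  cc_ok <- abs(stats$pearson_r) >= th$cc_th & stats$p_value <= th$p_th
  apg <- mi_ok & cc_ok
  qpg <- xor(mi_ok, cc_ok)
  partition(apgs = stats$pair_id[apg],
            qpgs = stats$pair_id[qpg],
            upgs = stats$pair_id[!apg & !qpg],
            thresholds_used = th, iterations = 0L,
            status = "classified")
}

partition <- function(apgs, qpgs, upgs, thresholds_used, iterations,
                      status, history = NULL, forced = character(0)) {
  structure(list(apgs = apgs, qpgs = qpgs, upgs = upgs,
                 thresholds_used = thresholds_used,
                 iterations = iterations, status = status,
                 history = history, forced = forced),
            class = "pghc_partition")
}

#' @export
print.pghc_partition <- function(x, ...) {
  n <- length(x$apgs) + length(x$qpgs) + length(x$upgs)
  cat(sprintf(
    "PGHC partition of %d pairs: %d authentic, %d questionable, %d unauthentic\n",
    n, length(x$apgs), length(x$qpgs), length(x$upgs)))
  print(x$thresholds_used)
  cat("iterations: ", x$iterations, " (", x$status, ")\n", sep = "")
  invisible(x)
}

#' Iterate the pairwise hierarchy criterion from centroid thresholds
#'
#' Starting from the initial thresholds (the metric centroids unless
#' given), repeatedly reclassifies the pairs, lowering both the MI and the
#' correlation threshold by their increments while the authentic fraction
#' is below the target band and questionable pairs remain, and raising
#' both while the fraction overshoots the band. The loop stops when the
#' fraction lands in the band, when thresholds hit the boundary of their
#' domain, when the questionable pool is exhausted, when a threshold state
#' repeats (band narrower than the step), or at the iteration cap; in the
#' non-converged cases the partition closest to the band is returned with
#' a warning. The P-value threshold is held fixed throughout (see
#' [adapt_p_threshold()] for its calibration).
#'
#' @param stats A `pair_stats` data frame.
#' @param init A [thresholds()] object; default: centroids of `stats` with
#'   default increments and `p_th = 0.05`.
#' @param target_fraction Length-2 numeric, the acceptable band for
#'   `|APGs| / n_pairs`; default `c(0.30, 0.45)`.
#' @param max_iter Iteration cap (default 10000).
#' @return A `pghc_partition` whose `history` data frame records the
#'   thresholds and group sizes at every iteration and whose `status` is
#'   one of `"converged"`, `"boundary"`, `"exhausted"`, `"cycle"`,
#'   `"cap"`.
#' @export
pghc_iterate <- function(stats, init = NULL,
                         target_fraction = c(0.30, 0.45),
                         max_iter = 10000L) {
  stats <- as_pair_stats(stats)
  if (!nrow(stats)) stop("empty pair-statistics collection", call. = FALSE)
  band <- as.numeric(target_fraction)
  if (length(band) != 2L || !(band[1L] < band[2L]) ||
      band[1L] <= 0 || band[2L] > 1)
    stop("target_fraction must be an interval inside (0, 1]", call. = FALSE)
  if (is.null(init)) {
    cent <- centroids(stats)
    init <- thresholds(cent$mi, min(1, cent$cor))
  }
  stopifnot(inherits(init, "pghc_thresholds"))

  n_pairs <- nrow(stats)
  mi_ceiling <- max(stats$mi_bits) + init$delta_mi
  th <- init
  iter <- 0L
  visited <- character(0)
  best <- NULL; best_dist <- Inf
  hist_rows <- list()
  status <- "cap"

  repeat {
    part <- classify_once(stats, th)
    frac <- length(part$apgs) / n_pairs
    hist_rows[[length(hist_rows) + 1L]] <-
      data.frame(iteration = iter, mi_th = th$mi_th, cc_th = th$cc_th,
                 apgs = length(part$apgs), qpgs = length(part$qpgs),
                 upgs = length(part$upgs), apg_fraction = frac)
    dist <- max(band[1L] - frac, frac - band[2L], 0)
    if (dist < best_dist) { best <- part; best_dist <- dist }

    if (frac >= band[1L] && frac <= band[2L]) { status <- "converged"; break }
    key <- sprintf("%.9f|%.9f", th$mi_th, th$cc_th)
    if (key %in% visited) { status <- "cycle"; break }
    visited <- c(visited, key)
    if (iter >= max_iter) { status <- "cap"; break }

    if (frac < band[1L]) {
      if (!length(part$qpgs)) { status <- "exhausted"; break }
      if (th$mi_th <= 0 && th$cc_th <= 0) { status <- "boundary"; break }
      th <- thresholds(max(0, th$mi_th - th$delta_mi),
                       max(0, th$cc_th - th$delta_cc),
                       th$p_th, th$delta_mi, th$delta_cc)
    } else {
      if (th$mi_th >= mi_ceiling && th$cc_th >= 1) {
        status <- "boundary"; break
      }
      th <- thresholds(min(mi_ceiling, th$mi_th + th$delta_mi),
                       min(1, th$cc_th + th$delta_cc),
                       th$p_th, th$delta_mi, th$delta_cc)
    }
    iter <- iter + 1L
  }

  final <- if (status %in% c("converged", "boundary", "exhausted")) part
           else best
  if (status != "converged")
    warning("PGHC iteration did not reach the target band (status: ",
            status, "); returning the partition closest to it",
            call. = FALSE)
  partition(final$apgs, final$qpgs, final$upgs,
            thresholds_used = final$thresholds_used,
            iterations = iter, status = status,
            history = do.call(rbind, hist_rows))
}

#' Rank questionable pairs for promotion
#'
#' Orders questionable pairs by decreasing associativity measure, ties by
#' increasing P-value, then lexicographic pair id — the order in which the
#' best questionable candidates would be promoted into the authentic group
#' when thresholds are set too high. The order is total and stable.
#'
#' @param stats A `pair_stats` data frame.
#' @param qpg_ids Character vector of pair ids to rank; default: all rows
#'   of `stats`. Ids absent from `stats` are an error.
#' @return Character vector of pair ids, best candidate first.
#' @export
rank_qpgs <- function(stats, qpg_ids = NULL) {
  stats <- as_pair_stats(stats)
  if (is.null(qpg_ids)) qpg_ids <- stats$pair_id
  if (!length(qpg_ids)) return(character(0))
  missing <- setdiff(qpg_ids, stats$pair_id)
  if (length(missing))
    stop("pair id not in statistics: '", missing[1L], "'", call. = FALSE)
  sub <- stats[stats$pair_id %in% qpg_ids, , drop = FALSE]
  sub$pair_id[order(-sub$am, sub$p_value, sub$pair_id)]
}

#' Calibrate the P-value threshold on a fixed ladder
#'
#' Short series with weak significance can leave too few pairs below the
#' conventional 0.05 cut to build any network. This returns the smallest
#' rung of the fixed ladder 0.05, 0.1, 0.2, ..., 0.9, 1.0 under which at
#' least `min_candidate_fraction` of the pairs are significant; the top
#' rung 1.0 always satisfies.
#'
#' @param stats A `pair_stats` data frame.
#' @param min_candidate_fraction Required fraction of pairs with
#'   `p <= p_th`, in `(0, 1)`.
#' @return A single P-value threshold from the ladder.
#' @export
adapt_p_threshold <- function(stats, min_candidate_fraction) {
  stats <- as_pair_stats(stats)
  if (!nrow(stats)) stop("empty pair-statistics collection", call. = FALSE)
  f <- as.numeric(min_candidate_fraction)
  if (!is.finite(f) || f <= 0 || f >= 1)
    stop("min_candidate_fraction must lie in (0, 1)", call. = FALSE)
  ladder <- c(0.05, seq(0.1, 1, by = 0.1))
  for (rung in ladder) {
    if (mean(stats$p_value <= rung) >= f) return(rung)
  }
  1
}

#' Write a partition as a delimited table
#'
#' One row per pair with its group label (`APG`, `QPG`, `UPG`).
#'
#' @param part A `pghc_partition`.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path, delimiter = "\t") {
  stopifnot(inherits(part, "pghc_partition"))
  ids <- c(part$apgs, part$qpgs, part$upgs)
  grp <- rep(c("APG", "QPG", "UPG"),
             c(length(part$apgs), length(part$qpgs), length(part$upgs)))
  ord <- order(ids)
  writeLines(c(paste("pair_id", "group", sep = delimiter),
               paste(ids[ord], grp[ord], sep = delimiter)), path)
  invisible(path)
}
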