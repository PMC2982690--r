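#' Pearson correlation with exact significance
#'
#' Product-moment correlation `r = cov(x, y) / (sd(x) sd(y))` with a
#' two-sided P-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, under
#' the null of no correlation.
#'
#' @param x,y Numeric vectors of equal length `>= 3`, neither constant.
#' @return A list with components `r` and `p`.
#' @export
pearson_with_pvalue <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx * dx); syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r * r))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Binned mutual information of two series
#'
#' Mutual information `I = sum p(x,y) log_b[p(x,y) / (p1(x) p2(y))]` over a
#' `bins x bins` equal-width joint histogram of the two series, in bits for
#' the default base 2. Cells with zero joint mass contribute nothing. A
#' constant series occupies a single bin and yields `I = 0`.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @param bins Number of equal-width bins per axis (`>= 2`).
#' @param base Logarithm base; 2 (bits) by default.
#' @return Non-negative mutual information.
#' @export
mutual_information <- function(x, y, bins, base = 2) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("bins must be >= 2", call. = FALSE)

  ix <- equal_width_bin(x, bins)
  iy <- equal_width_bin(y, bins)
  joint <- matrix(tabulate(ix + bins * (iy - 1L), nbins = bins * bins),
                  bins, bins) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- which(joint > 0, arr.ind = TRUE)
  pj <- joint[nz]
  mi <- sum(pj * log(pj / (px[nz[, 1L]] * py[nz[, 2L]]), base = base))
  max(mi, 0)
}

equal_width_bin <- function(v, bins) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(rep(1L, length(v)))
  i <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmin.int(as.integer(i), bins)
}

#' Associativity measure of a gene pair
#'
#' Projects weighted mutual information and correlation magnitude onto
#' orthogonal axes of a plane: the associativity measure is the Euclidean
#' norm `am = sqrt((w1 mi)^2 + (w2 |cor|)^2)` and `alpha` is the angle of
#' the point from the MI axis, in `[0, pi/2]`. Weights of `1/centroid`
#' (see [pair_stats()]) put both axes on a mean of one, levelling
#' asymmetric metric distributions. By convention `alpha = 0` for the zero
#' vector and `alpha = pi/2` when `mi = 0` with `|cor| > 0`.
#'
#' @param mi Non-negative mutual information (bits).
#' @param cor Correlation coefficient in `[-1, 1]`; its magnitude is used.
#' @param w1,w2 Positive weights for the MI and correlation axes.
#' @return A list with components `am` and `alpha` (radians).
#' @export
associativity_measure <- function(mi, cor, w1 = 1, w2 = 1) {
  if (any(mi < 0)) stop("mutual information must be non-negative",
                        call. = FALSE)
  if (w1 <= 0 || w2 <= 0) stop("weights must be positive", call. = FALSE)
  a <- w1 * mi
  b <- w2 * abs(cor)
  am <- sqrt(a * a + b * b)
  alpha <- ifelse(am == 0, 0, atan2(b, a))
  list(am = am, alpha = alpha)
}

#' Pairwise statistics for all gene pairs of a profile
#'
#' Computes, for each of the `n(n-1)/2` unordered gene pairs of a profile,
#' the binned mutual information (bits), the Pearson correlation with its
#' two-sided P-value, and the associativity measure with its angle. Pairs
#' are identified by `gene_a < gene_b` lexicographically and by the id
#' `"gene_a|gene_b"`.
#'
#' @param profile An [expression_profile] with at least two genes.
#' @param bins Histogram bins per axis for mutual information; default is
#'   the cube-root rule `max(2, ceiling(T^(1/3)))` for `T` time points
#'   (3 bins at `T = 14`). Joint histograms square the cell count, so the
#'   per-axis rule must stay well below the Sturges count used for
#'   univariate histograms: at 14 samples a 5x5 grid leaves the estimator
#'   bias, roughly `(bins - 1)^2 / (2 T ln 2)` bits, larger than the
#'   dependence signal itself.
#' @param weights Either the string `"centroid"` (default), giving weights
#'   `1/mi_centroid` and `1/cor_centroid` computed over all pairs, or a
#'   numeric vector `c(w1, w2)` of positive weights.
#' @return A data frame of class `pair_stats` with columns `pair_id`,
#'   `gene_a`, `gene_b`, `mi_bits`, `pearson_r`, `p_value`, `am`, `alpha`,
#'   and attributes `centroids` (list with `mi`, `cor`), `weights`, `bins`.
#' @export
pair_stats <- function(profile, bins = NULL, weights = "centroid") {
  stopifnot(inherits(profile, "expression_profile"))
  n <- length(profile$gene_ids)
  if (n < 2L)
    stop("pairwise statistics need at least 2 genes", call. = FALSE)
  if (is.null(bins))
    bins <- max(2L,
                as.integer(ceiling(length(profile$time_points_h)^(1 / 3))))

  idx <- utils::combn(n, 2L)
  m <- ncol(idx)
  ga <- character(m); gb <- character(m)
  mi <- numeric(m); r <- numeric(m); p <- numeric(m)
  for (k in seq_len(m)) {
    i <- idx[1L, k]; j <- idx[2L, k]
    a <- profile$gene_ids[i]; b <- profile$gene_ids[j]
    if (a > b) { tmp <- i; i <- j; j <- tmp; tmp <- a; a <- b; b <- tmp }
    ga[k] <- a; gb[k] <- b
    x <- profile$values[i, ]; y <- profile$values[j, ]
    mi[k] <- mutual_information(x, y, bins = bins)
    pr <- pearson_with_pvalue(x, y)
    r[k] <- pr$r; p[k] <- pr$p
  }

  cent <- list(mi = mean(mi), cor = mean(abs(r)))
  if (identical(weights, "centroid")) {
    w1 <- if (cent$mi > 0) 1 / cent$mi else 1
    w2 <- if (cent$cor > 0) 1 / cent$cor else 1
  } else {
    w <- as.numeric(weights)
    if (length(w) != 2L || any(!is.finite(w)) || any(w <= 0))
      stop("weights must be \"centroid\" or two positive numbers",
           call. = FALSE)
    w1 <- w[1L]; w2 <- w[2L]
  }
  amres <- associativity_measure(mi, r, w1, w2)

  out <- data.frame(pair_id = paste(ga, gb, sep = "|"),
                    gene_a = ga, gene_b = gb,
                    mi_bits = mi, pearson_r = r, p_value = p,
                    am = amres$am, alpha = amres$alpha,
                    stringsAsFactors = FALSE)
  ord <- order(out$pair_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "centroids") <- cent
  attr(out, "weights") <- c(w1 = w1, w2 = w2)
  attr(out, "bins") <- bins
  class(out) <- c("pair_stats", "data.frame")
  out
}

#' Metric centroids of a pair-statistics collection
#'
#' Arithmetic means of the mutual information and of the correlation
#' magnitude across all pairs; these centroids initialise the thresholding
#' iteration (see [pghc_iterate()]) and define the default associativity
#' weights.
#'
#' @param stats A `pair_stats` data frame (see [pair_stats()]).
#' @return A list with components `mi` and `cor`.
#' @export
centroids <- function(stats) {
  stats <- as_pair_stats(stats)
  if (!nrow(stats)) stop("empty pair-statistics collection", call. = FALSE)
  list(mi = mean(stats$mi_bits), cor = mean(abs(stats$pearson_r)))
}

as_pair_stats <- function(stats) {
  need <- c("pair_id", "gene_a", "gene_b", "mi_bits", "pearson_r",
            "p_value", "am", "alpha")
  if (!is.data.frame(stats) || !all(need %in% names(stats)))
    stop("expected a pair_stats data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(stats$pair_id))
    stop("duplicate pair id: '",
         stats$pair_id[duplicated(stats$pair_id)][1L], "'", call. = FALSE)
  stats
}

#' Write pair statistics as a delimited table
#'
#' @param stats A `pair_stats` data frame.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_pair_stats <- function(stats, path, delimiter = "\t") {
  stats <- as_pair_stats(stats)
  cols <- c("gene_a", "gene_b", "mi_bits", "pearson_r", "p_value",
            "am", "alpha")
  header <- paste(cols, collapse = delimiter)
  rows <- vapply(seq_len(nrow(stats)), function(i) {
    paste(c(stats$gene_a[i], stats$gene_b[i],
            fmt_num(unlist(stats[i, cols[-(1:2)]]))),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
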