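#' Specify a planted regulatory network for simulation
#'
#' Defines a ground-truthed generative regime emulating short,
#' synchronised microarray time series: a sparse set of lag-coupled gene
#' pairs (each target driven by one upstream gene after an integer-sample
#' delay) embedded among periodically expressed driver genes and
#' noise-only independent genes. The default regime — 24 genes, 14 time
#' points, 20 edges, noise SD 0.2 — mirrors the scale of a two-colour
#' cell-cycle experiment sampled every 30 minutes.
#'
#' When `edges` is `NULL` the structure is a small forest of regulator
#' hubs, each driving a distinct set of targets after a delay — the
#' hub-dominated out-degree profile typical of transcriptional networks.
#' Lags are drawn from `lag_choices` (samples) and couplings uniformly
#' from `coupling_range`. User-supplied `edges` may form arbitrary
#' single-parent DAGs (chains included).
#'
#' @param n_genes Number of genes (default 24).
#' @param time_points Number of equally spaced samples (default 14).
#' @param n_edges Number of planted regulatory edges (default 20); at
#'   most `n_genes - 1` under the single-parent constraint and at most
#'   half the pair count (edge density <= 0.5).
#' @param noise_sd Gaussian noise SD added to every gene (default 0.2).
#' @param seed Integer RNG seed (default 42).
#' @param lag_choices Integer sample lags to draw from; the default, one
#'   sampling interval (30 min on the default grid), is the scale of a
#'   transcriptional cascade delay. Every lag must be below
#'   `time_points / 2`.
#' @param period_range Range (samples) of the driver sinusoid periods;
#'   the default 8-12 samples is a 4-6 h cycle at 30-min sampling,
#'   i.e. 1-2 cycles across a 14-point series.
#' @param coupling_range Range of coupling coefficients in `(0, 1]`
#'   (default `c(0.7, 1)`).
#' @param edges Optional data frame with columns `source`, `target`,
#'   `lag`, `coupling` overriding the random structure.
#' @return An object of class `planted_network`.
#' @export
planted_network <- function(n_genes = 24, time_points = 14, n_edges = 20,
                            noise_sd = 0.2, seed = 42,
                            lag_choices = 1L,
                            period_range = c(8, 12),
                            coupling_range = c(0.7, 1),
                            edges = NULL) {
  n_genes <- as.integer(n_genes); time_points <- as.integer(time_points)
  if (n_genes < 2L) stop("need at least 2 genes", call. = FALSE)
  if (time_points < 6L)
    stop("need at least 6 time points for spectral estimation",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(lag_choices < 1L) || any(lag_choices >= time_points / 2))
    stop("lags must be positive and below time_points / 2", call. = FALSE)
  if (any(coupling_range <= 0) || any(coupling_range > 1))
    stop("couplings must lie in (0, 1]", call. = FALSE)
  genes <- sprintf("G%02d", seq_len(n_genes))

  if (is.null(edges)) {
    n_edges <- as.integer(n_edges)
    if (n_edges > n_genes - 1L)
      stop("at most n_genes - 1 edges under the single-parent constraint",
           call. = FALSE)
    # a few regulator hubs each driving a distinct target set (depth 1):
    # the hub-dominated out-degree profile typical of transcriptional
    # networks, and a regime where a target's only upstream noise is its
    # regulator's own measurement noise
    n_reg <- max(1L, as.integer(ceiling(n_edges / 5)))
    if (n_edges > n_genes - n_reg)
      stop("too many edges: need n_edges regulators + targets within ",
           "n_genes", call. = FALSE)
    edges <- with_seed(seed, {
      perm <- sample(genes)
      regulators <- perm[seq_len(n_reg)]
      targets <- perm[n_reg + seq_len(n_edges)]
      data.frame(
        source = sample(rep_len(regulators, n_edges)),
        target = targets,
        lag = sample(as.integer(lag_choices), n_edges, replace = TRUE),
        coupling = stats::runif(n_edges, coupling_range[1L],
                                coupling_range[2L]),
        stringsAsFactors = FALSE)
    })
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    need <- c("source", "target", "lag", "coupling")
    if (!all(need %in% names(edges)))
      stop("edges needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    edges <- edges[, need]
    if (!all(edges$source %in% genes) || !all(edges$target %in% genes))
      stop("edge endpoints must be among the generated gene ids (",
           genes[1L], " .. ", genes[n_genes], ")", call. = FALSE)
    if (anyDuplicated(edges$target))
      stop("each target may have only one planted regulator",
           call. = FALSE)
  }
  if (any(edges$source == edges$target))
    stop("self-edges are not allowed", call. = FALSE)
  if (any(edges$lag >= time_points / 2))
    stop("lag too large: must be below time_points / 2", call. = FALSE)
  if (nrow(edges) > 0.5 * n_genes * (n_genes - 1) / 2)
    stop("edge density above 0.5", call. = FALSE)

  structure(list(n_genes = n_genes, time_points = time_points,
                 genes = genes, edges = edges, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 period_range = as.numeric(period_range)),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf(
    "Planted network: %d genes x %d time points, %d lag-coupled edges, noise SD %.3g, seed %d\n",
    x$n_genes, x$time_points, nrow(x$edges), x$noise_sd, x$seed))
  invisible(x)
}

# Run code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate expression data from a planted network
#'
#' Driver genes (no planted regulator, at least one planted edge out, or
#' transitively upstream) are sums of one or two random-phase sinusoids
#' at cell-cycle-like periods plus Gaussian noise; each planted target is
#' `coupling * (regulator delayed by lag samples) + noise`; genes in no
#' planted edge are noise-only. Signals are built on a grid extended
#' backwards by the maximum cumulative lag so delayed copies are exact —
#' with coupling 1 and zero noise a target is exactly its delayed source.
#' Identical seeds give bit-identical output.
#'
#' @param planted A [planted_network()].
#' @return List with `profile` (an [expression_profile] on a 30-minute
#'   grid) and `truth` (the planted edge table: `source`, `target`,
#'   `lag`, `coupling`).
#' @export
simulate_expression <- function(planted) {
  stopifnot(inherits(planted, "planted_network"))
  n <- planted$n_genes
  T_ <- planted$time_points
  genes <- planted$genes
  edges <- planted$edges

  parent <- stats::setNames(rep(NA_character_, n), genes)
  lag <- stats::setNames(rep(0L, n), genes)
  coupling <- stats::setNames(rep(NA_real_, n), genes)
  if (nrow(edges)) {
    parent[edges$target] <- edges$source
    lag[edges$target] <- as.integer(edges$lag)
    coupling[edges$target] <- edges$coupling
  }
  depth <- stats::setNames(integer(n), genes)
  for (g in genes) {
    d <- 0L; cur <- g; guard <- 0L
    while (!is.na(parent[cur])) {
      d <- d + lag[cur]; cur <- parent[cur]
      guard <- guard + 1L
      if (guard > n) stop("cycle in planted edges", call. = FALSE)
    }
    depth[g] <- d
  }
  pad <- max(depth)
  Text <- T_ + pad

  vals <- with_seed(planted$seed, {
    ext <- matrix(NA_real_, n, Text, dimnames = list(genes, NULL))
    t_ext <- seq_len(Text)
    in_edge <- genes %in% c(edges$source, edges$target)
    roots <- genes[is.na(parent)]
    for (g in roots) {
      if (in_edge[match(g, genes)]) {
        p1 <- stats::runif(1, planted$period_range[1L],
                           planted$period_range[2L])
        sig <- sin(2 * pi * t_ext / p1 + stats::runif(1, 0, 2 * pi))
        if (stats::runif(1) < 0.5) {
          p2 <- p1 / 2
          sig <- sig + 0.4 * sin(2 * pi * t_ext / p2 +
                                   stats::runif(1, 0, 2 * pi))
        }
      } else {
        sig <- 0  # independent gene: noise only
      }
      ext[g, ] <- sig + stats::rnorm(Text, sd = planted$noise_sd)
    }
    remaining <- genes[!is.na(parent)]
    while (length(remaining)) {
      ready <- remaining[!(parent[remaining] %in% remaining)]
      if (!length(ready))
        stop("cycle in planted edges", call. = FALSE)
      for (g in ready) {
        k <- lag[g]
        src <- ext[parent[g], ]
        delayed <- c(rep(NA_real_, k), src)[seq_len(Text)]
        ext[g, ] <- coupling[g] * delayed +
          stats::rnorm(Text, sd = planted$noise_sd)
      }
      remaining <- setdiff(remaining, ready)
    }
    ext[, (pad + 1L):Text, drop = FALSE]
  })

  time_h <- (seq_len(T_) - 1L) * 0.5
  list(profile = expression_profile(genes, time_h, vals),
       truth = edges)
}
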