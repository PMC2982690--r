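# Fixtures built in code: small profiles, signal generators, and random
# pair-statistics collections used across the suite.

# noise-only expression profile on a 30-min grid
random_profile <- function(n_genes = 6, n_time = 14, seed = 1) {
  set.seed(seed)
  expression_profile(sprintf("G%02d", seq_len(n_genes)),
                     (seq_len(n_time) - 1) * 0.5,
                     matrix(rnorm(n_genes * n_time), n_genes, n_time))
}

# a sampled sinusoid and its k-sample delayed copy (exact, via the
# analytic form evaluated at shifted times)
delayed_sine_pair <- function(T_ = 14, period = 8, k = 1) {
  t <- seq_len(T_) - 1
  list(a = sin(2 * pi * t / period),
       b = sin(2 * pi * (t - k) / period))
}

# synthetic pair-statistics table with valid columns and random metrics
random_stats <- function(n_pairs = 50, seed = 1) {
  set.seed(seed)
  n_genes <- ceiling((1 + sqrt(1 + 8 * n_pairs)) / 2)
  genes <- sprintf("G%02d", seq_len(n_genes))
  idx <- utils::combn(n_genes, 2)[, seq_len(n_pairs), drop = FALSE]
  ga <- genes[idx[1, ]]; gb <- genes[idx[2, ]]
  mi <- runif(n_pairs, 0, 2)
  r <- runif(n_pairs, -1, 1)
  am <- associativity_measure(mi, r, 1, 1)
  out <- data.frame(pair_id = paste(ga, gb, sep = "|"),
                    gene_a = ga, gene_b = gb,
                    mi_bits = mi, pearson_r = r,
                    p_value = runif(n_pairs),
                    am = am$am, alpha = am$alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_stats", "data.frame")
  out
}

# independent rule-table oracle for the three-way classification
classify_oracle <- function(stats, th) {
  grp <- character(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    mi_ok <- stats$mi_bits[i] >= th$mi_th
    cc_ok <- abs(stats$pearson_r[i]) >= th$cc_th &&
      stats$p_value[i] <= th$p_th
    grp[i] <- if (mi_ok && cc_ok) "APG"
              else if (mi_ok || cc_ok) "QPG"
              else "UPG"
  }
  split(stats$pair_id, factor(grp, levels = c("APG", "QPG", "UPG")))
}

# brute-force histogram MI: explicit counting loops over all cells
mi_oracle <- function(x, y, bins, base = 2) {
  n <- length(x)
  bin1 <- function(v) {
    lo <- min(v); hi <- max(v)
    out <- integer(length(v))
    for (i in seq_along(v)) {
      if (hi == lo) { out[i] <- 1L; next }
      j <- floor((v[i] - lo) / (hi - lo) * bins) + 1
      out[i] <- as.integer(min(j, bins))
    }
    out
  }
  bx <- bin1(x); by <- bin1(y)
  mi <- 0
  for (ix in seq_len(bins)) {
    for (iy in seq_len(bins)) {
      nxy <- 0; nx <- 0; ny <- 0
      for (i in seq_len(n)) {
        if (bx[i] == ix && by[i] == iy) nxy <- nxy + 1
        if (bx[i] == ix) nx <- nx + 1
        if (by[i] == iy) ny <- ny + 1
      }
      if (nxy > 0)
        mi <- mi + (nxy / n) * log((nxy / n) / ((nx / n) * (ny / n)),
                                   base = base)
    }
  }
  mi
}

write_profile_text <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
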