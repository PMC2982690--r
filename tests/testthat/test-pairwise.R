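test_that("pearson matches the direct formula and cor.test significance", {
  # exact linear and anti-linear dependence
  expect_equal(pearson_with_pvalue(1:4, c(2, 4, 6, 8))$r, 1)
  expect_equal(pearson_with_pvalue(1:4, c(4, 3, 2, 1))$r, -1)

  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(14); y <- rnorm(14)
    got <- pearson_with_pvalue(x, y)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$r, r_oracle, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("pearson is invariant under positive affine maps of either input", {
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    ref <- pearson_with_pvalue(x, y)
    a <- runif(1, 0.1, 5); c <- rnorm(1)
    got <- pearson_with_pvalue(a * x + c, y)
    expect_equal(got$r, ref$r, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
  }
})

test_that("pearson rejects degenerate input", {
  expect_error(pearson_with_pvalue(c(1, 1, 1, 1), rnorm(4)), "constant")
  expect_error(pearson_with_pvalue(1:2, 1:2), "at least 3")
})

test_that("mutual information matches a brute-force cell-sum oracle", {
  set.seed(13)
  for (i in 1:300) {
    x <- rnorm(14); y <- rnorm(14)
    bins <- sample(2:6, 1)
    expect_equal(mutual_information(x, y, bins),
                 mi_oracle(x, y, bins), tolerance = 1e-12)
  }
})

test_that("mutual information hits its closed-form anchors", {
  # identical signals, two equally filled bins -> exactly 1 bit
  x <- c(rep(0, 7), rep(10, 7))
  expect_equal(mutual_information(x, x, bins = 2), 1)
  # product-form joint histogram -> exactly 0
  x <- c(0, 0, 10, 10)
  y <- c(0, 10, 0, 10)
  expect_equal(mutual_information(x, y, bins = 2), 0)
  expect_error(mutual_information(rnorm(5), rnorm(5), bins = 1), "bins")
})

test_that("mutual information is symmetric and bounded by self-information", {
  set.seed(14)
  for (i in 1:50) {
    x <- rnorm(14); y <- rnorm(14)
    bins <- sample(2:5, 1)
    expect_equal(mutual_information(x, y, bins),
                 mutual_information(y, x, bins), tolerance = 1e-12)
    self <- mutual_information(x, x, bins)
    # self-MI equals the histogram entropy of x
    px <- tabulate(phasenet:::equal_width_bin(x, bins), bins) / 14
    px <- px[px > 0]
    expect_equal(self, -sum(px * log2(px)), tolerance = 1e-12)
    expect_lte(mutual_information(x, y, bins), self + 1e-12)
  }
})

test_that("associativity measure is the weighted Euclidean projection", {
  # 3-4-5 right triangle
  am <- associativity_measure(0.3, 0.4, 1, 1)
  expect_equal(am$am, 0.5, tolerance = 1e-12)
  expect_equal(am$alpha, atan2(4, 3), tolerance = 1e-12)
  # zero vector convention
  z <- associativity_measure(0, 0, 1, 1)
  expect_equal(z$am, 0)
  expect_equal(z$alpha, 0)
  # pure-correlation limit
  expect_equal(associativity_measure(0, 0.5, 2, 2)$alpha, pi / 2)
  expect_error(associativity_measure(-0.1, 0, 1, 1), "non-negative")

  set.seed(15)
  for (i in 1:100) {
    mi <- runif(1, 0, 3); r <- runif(1, -1, 1)
    w1 <- runif(1, 0.1, 4); w2 <- runif(1, 0.1, 4)
    got <- associativity_measure(mi, r, w1, w2)
    expect_equal(got$am^2, (w1 * mi)^2 + (w2 * r)^2, tolerance = 1e-12)
    # homogeneity: scaling both weights by k scales am by k
    k <- runif(1, 0.5, 3)
    expect_equal(associativity_measure(mi, r, k * w1, k * w2)$am,
                 k * got$am, tolerance = 1e-12)
    expect_gte(got$alpha, 0); expect_lte(got$alpha, pi / 2)
  }
})

test_that("all-pairs statistics enumerate n(n-1)/2 ordered unique pairs", {
  for (n in c(2, 5, 8)) {
    st <- pair_stats(random_profile(n_genes = n, seed = n))
    expect_identical(nrow(st), as.integer(n * (n - 1) / 2))
    expect_false(anyDuplicated(st$pair_id) > 0)
    expect_true(all(st$gene_a < st$gene_b))
    expect_true(all(st$mi_bits >= 0))
    expect_true(all(abs(st$pearson_r) <= 1))
    expect_true(all(st$p_value >= 0 & st$p_value <= 1))
  }
})

test_that("centroid weighting normalises both metric axes to mean one", {
  st <- pair_stats(random_profile(n_genes = 6, seed = 4))
  cent <- centroids(st)
  w <- attr(st, "weights")
  expect_equal(unname(w["w1"]), 1 / cent$mi, tolerance = 1e-12)
  expect_equal(unname(w["w2"]), 1 / cent$cor, tolerance = 1e-12)
  expect_equal(mean(st$mi_bits * w["w1"]), 1, tolerance = 1e-12)
  expect_equal(mean(abs(st$pearson_r) * w["w2"]), 1, tolerance = 1e-12)
  # explicit numeric weights pass through
  st2 <- pair_stats(random_profile(n_genes = 6, seed = 4),
                    weights = c(2, 3))
  expect_equal(st2$am,
               sqrt((2 * st2$mi_bits)^2 + (3 * abs(st2$pearson_r))^2),
               tolerance = 1e-12)
})

test_that("centroids are brute-force means of MI and |r|", {
  st <- random_stats(40, seed = 6)
  cent <- centroids(st)
  expect_equal(cent$mi, sum(st$mi_bits) / 40, tolerance = 1e-12)
  expect_equal(cent$cor, sum(abs(st$pearson_r)) / 40, tolerance = 1e-12)
  # single pair: absolute value of r
  one <- st[1, ]; one$mi_bits <- 0.6; one$pearson_r <- -0.4
  cent1 <- centroids(one)
  expect_equal(cent1$mi, 0.6)
  expect_equal(cent1$cor, 0.4)
  expect_error(centroids(st[0, ]), "empty")
})

test_that("pair statistics export as a delimited table", {
  st <- pair_stats(random_profile(n_genes = 5, seed = 8))
  path <- tempfile(fileext = ".tsv")
  write_pair_stats(st, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), nrow(st))
  expect_equal(tab$mi_bits, st$mi_bits, tolerance = 1e-12)
})
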