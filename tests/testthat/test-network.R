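make_fit_pieces <- function(n_genes = 8, seed = 51) {
  sim <- simulate_expression(planted_network(n_genes = n_genes,
                                             n_edges = n_genes - 2,
                                             seed = seed))
  st <- pair_stats(sim$profile)
  part <- pghc_iterate(st, target_fraction = c(0.2, 0.5))
  calls <- phasenet:::all_phase_calls(sim$profile, st, 0.3, pi / 36)
  list(profile = sim$profile, stats = st, part = part, calls = calls)
}

test_that("network assembly respects partition, calls and the handshake lemma", {
  pc <- make_fit_pieces()
  net <- build_network(pc$part, pc$calls, pc$stats,
                       all_genes = pc$profile$gene_ids)
  n_edges <- nrow(net$directed_edges) + nrow(net$undirected_edges)
  expect_identical(n_edges, length(pc$part$apgs))
  expect_setequal(net$nodes, pc$profile$gene_ids)
  deg <- degree_summary(net)
  expect_identical(sum(deg$total_degree), 2L * n_edges)
  expect_identical(sum(deg$in_degree), nrow(net$directed_edges))
  expect_identical(sum(deg$out_degree), nrow(net$directed_edges))
  expect_equal(attr(deg, "mean_total_degree"),
               2 * n_edges / length(net$nodes))
})

test_that("edge orientation follows the lead-lag convention", {
  pc <- make_fit_pieces(seed = 52)
  net <- build_network(pc$part, pc$calls, pc$stats,
                       all_genes = pc$profile$gene_ids)
  for (i in seq_len(nrow(net$directed_edges))) {
    e <- net$directed_edges[i, ]
    id <- paste(min(e$source, e$target), max(e$source, e$target),
                sep = "|")
    cl <- pc$calls[[id]]
    # lagging call: lexicographic first gene leads -> it is the source
    if (cl$direction == "lagging") {
      expect_identical(e$source, min(e$source, e$target))
    } else {
      expect_identical(e$source, max(e$source, e$target))
    }
  }
})

test_that("reversing every call reverses every directed edge and no more", {
  pc <- make_fit_pieces(seed = 53)
  flipped <- lapply(pc$calls, function(cl) {
    if (cl$direction == "leading") cl$direction <- "lagging"
    else if (cl$direction == "lagging") cl$direction <- "leading"
    cl
  })
  net <- build_network(pc$part, pc$calls, pc$stats,
                       all_genes = pc$profile$gene_ids)
  rev <- build_network(pc$part, flipped, pc$stats,
                       all_genes = pc$profile$gene_ids)
  expect_identical(nrow(net$directed_edges), nrow(rev$directed_edges))
  expect_setequal(paste(net$directed_edges$source,
                        net$directed_edges$target),
                  paste(rev$directed_edges$target,
                        rev$directed_edges$source))
  expect_identical(net$undirected_edges$gene_a,
                   rev$undirected_edges$gene_a)
})

test_that("empty partitions yield isolate-only networks", {
  pc <- make_fit_pieces(seed = 54)
  empty <- phasenet:::partition(character(0), character(0),
                                pc$stats$pair_id,
                                thresholds_used = thresholds(9, 1, 0.01),
                                iterations = 0L, status = "classified")
  net <- build_network(empty, pc$calls, pc$stats,
                       all_genes = pc$profile$gene_ids)
  expect_identical(nrow(net$directed_edges), 0L)
  expect_identical(nrow(net$undirected_edges), 0L)
  expect_setequal(net$nodes, pc$profile$gene_ids)
  deg <- degree_summary(net)
  expect_true(all(deg$total_degree == 0L))
})

test_that("genes in no authentic pair remain as isolated nodes", {
  pc <- make_fit_pieces(seed = 55)
  # restrict authentic pairs to those avoiding the first gene entirely
  g1 <- pc$profile$gene_ids[1]
  keep <- pc$part$apgs[!grepl(g1, pc$part$apgs, fixed = TRUE)]
  part <- phasenet:::partition(keep, character(0),
                               setdiff(pc$stats$pair_id, keep),
                               thresholds_used = pc$part$thresholds_used,
                               iterations = 0L, status = "classified")
  net <- build_network(part, pc$calls, pc$stats,
                       all_genes = pc$profile$gene_ids)
  expect_true(g1 %in% net$nodes)
  deg <- degree_summary(net)
  expect_identical(deg$total_degree[deg$gene == g1], 0L)
})

test_that("a missing phase call for an authentic pair is an error", {
  pc <- make_fit_pieces(seed = 56)
  calls <- pc$calls
  calls[[pc$part$apgs[1]]] <- NULL
  expect_error(build_network(pc$part, calls, pc$stats,
                             all_genes = pc$profile$gene_ids),
               "no phase call")
})

test_that("edge-table export round-trips byte-identically", {
  pc <- make_fit_pieces(seed = 57)
  net <- build_network(pc$part, pc$calls, pc$stats,
                       all_genes = pc$profile$gene_ids)
  p1 <- tempfile(fileext = ".tsv")
  export_network(net, p1, "edge-table")
  back <- import_edge_table(p1)
  p2 <- tempfile(fileext = ".tsv")
  export_network(back, p2, "edge-table")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("SIF and GraphML exports carry the expected structure", {
  pc <- make_fit_pieces(seed = 58)
  net <- build_network(pc$part, pc$calls, pc$stats,
                       all_genes = pc$profile$gene_ids)
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_identical(sum(grepl("\tactivates-lead\t", lines)),
                   nrow(net$directed_edges))
  expect_identical(sum(grepl("\tassociates\t", lines)),
                   nrow(net$undirected_edges))

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), length(net$nodes),
               ignore_attr = TRUE)
  expect_equal(igraph::gsize(g),
               nrow(net$directed_edges) + nrow(net$undirected_edges),
               ignore_attr = TRUE)
  expect_true("am" %in% igraph::edge_attr_names(g))

  expect_error(export_network(net, tempfile(), "dot"), "arg")

  # empty network: valid (empty) documents per format
  empty <- phasenet:::regulatory_network(
    character(0),
    net$directed_edges[0, ], net$undirected_edges[0, ])
  for (fmt in c("edge-table", "sif", "graphml")) {
    f <- tempfile()
    expect_silent(export_network(empty, f, fmt))
    expect_true(file.exists(f))
  }
})

test_that("self-edges and duplicate pairs are rejected at construction", {
  d <- data.frame(source = "A", target = "A", am = 1, phase_rad = 0.1,
                  gain = 1, provenance = "threshold")
  u0 <- data.frame(gene_a = character(0), gene_b = character(0),
                   am = numeric(0), provenance = character(0))
  expect_error(phasenet:::regulatory_network("A", d, u0), "self-edges")
  d2 <- data.frame(source = c("A", "B"), target = c("B", "A"),
                   am = 1, phase_rad = 0.1, gain = 1,
                   provenance = "threshold")
  expect_error(phasenet:::regulatory_network(c("A", "B"), d2, u0),
               "duplicate edge")
})
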