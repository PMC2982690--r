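#' Assemble the directed regulatory network
#'
#' Turns the authentic pairs of a partition into network edges using the
#' per-pair phase calls: a `lagging` call (second gene lags the first)
#' orients the edge `gene_a -> gene_b` — the regulator is the earlier
#' signal — a `leading` call orients `gene_b -> gene_a`, and an
#' `undirected` call keeps the pair as an undirected association edge.
#' All input genes remain nodes, so genes in no authentic pair appear as
#' isolates.
#'
#' @param partition A `pghc_partition` (or the `partition` of a
#'   `moco_result`); pairs promoted by forced knowledge carry provenance
#'   `"forced"`, the rest `"threshold"`.
#' @param calls Named list of [call_direction()] results, one per
#'   authentic pair id (missing calls are an error).
#' @param stats The `pair_stats` data frame the partition was built from.
#' @param all_genes Character vector of every gene in the study; defaults
#'   to the genes appearing in `stats`.
#' @return An object of class `regulatory_network`: list with `nodes`
#'   (character), `directed_edges` (data frame `source`, `target`, `am`,
#'   `phase_rad`, `gain`, `provenance`) and `undirected_edges` (data
#'   frame `gene_a`, `gene_b`, `am`, `provenance`).
#' @export
build_network <- function(partition, calls, stats, all_genes = NULL) {
  if (inherits(partition, "moco_result")) partition <- partition$partition
  stopifnot(inherits(partition, "pghc_partition"))
  stats <- as_pair_stats(stats)
  if (is.null(all_genes))
    all_genes <- sort(unique(c(stats$gene_a, stats$gene_b)))

  apgs <- partition$apgs
  missing <- setdiff(apgs, names(calls))
  if (length(missing))
    stop("no phase call for authentic pair '", missing[1L], "'",
         call. = FALSE)
  row_of <- match(apgs, stats$pair_id)
  if (anyNA(row_of))
    stop("authentic pair absent from statistics: '",
         apgs[is.na(row_of)][1L], "'", call. = FALSE)

  dir_rows <- list(); und_rows <- list()
  for (k in seq_along(apgs)) {
    id <- apgs[k]
    st <- stats[row_of[k], ]
    call <- calls[[id]]
    prov <- if (id %in% partition$forced) "forced" else "threshold"
    if (call$direction == "lagging") {
      dir_rows[[length(dir_rows) + 1L]] <- data.frame(
        source = st$gene_a, target = st$gene_b, am = st$am,
        phase_rad = call$phase_rad, gain = call$gain, provenance = prov,
        stringsAsFactors = FALSE)
    } else if (call$direction == "leading") {
      dir_rows[[length(dir_rows) + 1L]] <- data.frame(
        source = st$gene_b, target = st$gene_a, am = st$am,
        phase_rad = call$phase_rad, gain = call$gain, provenance = prov,
        stringsAsFactors = FALSE)
    } else {
      und_rows[[length(und_rows) + 1L]] <- data.frame(
        gene_a = st$gene_a, gene_b = st$gene_b, am = st$am,
        provenance = prov, stringsAsFactors = FALSE)
    }
  }
  directed <- if (length(dir_rows)) do.call(rbind, dir_rows) else
    data.frame(source = character(0), target = character(0),
               am = numeric(0), phase_rad = numeric(0), gain = numeric(0),
               provenance = character(0), stringsAsFactors = FALSE)
  undirected <- if (length(und_rows)) do.call(rbind, und_rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               am = numeric(0), provenance = character(0),
               stringsAsFactors = FALSE)

  regulatory_network(all_genes, directed, undirected)
}

regulatory_network <- function(nodes, directed_edges, undirected_edges) {
  nodes <- as.character(nodes)
  ends <- c(directed_edges$source, directed_edges$target,
            undirected_edges$gene_a, undirected_edges$gene_b)
  stray <- setdiff(ends, nodes)
  if (length(stray))
    stop("edge endpoint is not a node: '", stray[1L], "'", call. = FALSE)
  if (any(directed_edges$source == directed_edges$target) ||
      any(undirected_edges$gene_a == undirected_edges$gene_b))
    stop("self-edges are not allowed", call. = FALSE)
  keys <- c(paste(pmin(directed_edges$source, directed_edges$target),
                  pmax(directed_edges$source, directed_edges$target),
                  sep = "|"),
            paste(pmin(undirected_edges$gene_a, undirected_edges$gene_b),
                  pmax(undirected_edges$gene_a, undirected_edges$gene_b),
                  sep = "|"))
  if (anyDuplicated(keys))
    stop("duplicate edge for pair '", keys[duplicated(keys)][1L], "'",
         call. = FALSE)
  structure(list(nodes = nodes,
                 directed_edges = directed_edges,
                 undirected_edges = undirected_edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  iso <- sum(!x$nodes %in% c(x$directed_edges$source,
                             x$directed_edges$target,
                             x$undirected_edges$gene_a,
                             x$undirected_edges$gene_b))
  cat(sprintf(
    "Regulatory network: %d nodes (%d isolated), %d directed and %d undirected edges\n",
    length(x$nodes), iso, nrow(x$directed_edges),
    nrow(x$undirected_edges)))
  invisible(x)
}

#' @export
summary.regulatory_network <- function(object, ...) {
  deg <- degree_summary(object)
  cat(sprintf("Mean total degree: %.3f\n",
              attr(deg, "mean_total_degree")))
  print(object)
  invisible(deg)
}

#' Plot a regulatory network
#'
#' Renders the network with igraph; directed edges carry arrows,
#' undirected association edges do not.
#'
#' @param x A `regulatory_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.regulatory_network <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(
    g, edge.arrow.mode = ifelse(igraph::E(g)$directed == 1, 2, 0), ...)
  invisible(x)
}

as_igraph <- function(net) {
  d <- net$directed_edges
  u <- net$undirected_edges
  edges <- rbind(
    data.frame(from = d$source, to = d$target,
               directed = rep(1L, nrow(d)),
               am = d$am, phase_rad = d$phase_rad, gain = d$gain,
               provenance = d$provenance, stringsAsFactors = FALSE),
    data.frame(from = u$gene_a, to = u$gene_b,
               directed = rep(0L, nrow(u)),
               am = u$am, phase_rad = rep(NA_real_, nrow(u)),
               gain = rep(NA_real_, nrow(u)),
               provenance = u$provenance, stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Per-node degree summary
#'
#' Exact in-, out- and undirected-degree counts per node; the mean total
#' degree (in + out + undirected) over all nodes, isolates included, is
#' attached as attribute `mean_total_degree`.
#'
#' @param network A `regulatory_network`.
#' @return Data frame with columns `gene`, `in_degree`, `out_degree`,
#'   `undirected_degree`, `total_degree`.
#' @export
degree_summary <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  nodes <- network$nodes
  cnt <- function(x) as.integer(table(factor(x, levels = nodes)))
  out <- data.frame(
    gene = nodes,
    in_degree = cnt(network$directed_edges$target),
    out_degree = cnt(network$directed_edges$source),
    undirected_degree = cnt(c(network$undirected_edges$gene_a,
                              network$undirected_edges$gene_b)),
    stringsAsFactors = FALSE)
  out$total_degree <- out$in_degree + out$out_degree +
    out$undirected_degree
  attr(out, "mean_total_degree") <-
    if (nrow(out)) mean(out$total_degree) else NA_real_
  out
}

#' Export a regulatory network
#'
#' Writes the network in one of three formats:
#' \describe{
#'   \item{`edge-table`}{delimited text with columns `source`, `target`,
#'     `directed` (1/0), `am`, `phase_rad`, `gain`, `provenance`;
#'     re-importable via [import_edge_table()] with a byte-identical
#'     re-export.}
#'   \item{`sif`}{simple interaction format, relation `activates-lead`
#'     for directed edges and `associates` for undirected ones; isolated
#'     nodes appear as bare node lines.}
#'   \item{`graphml`}{via [igraph::write_graph()], with `directed`, `am`,
#'     `phase_rad`, `gain` and `provenance` as edge attributes.}
#' }
#'
#' @param network A `regulatory_network`.
#' @param path Output path.
#' @param format One of `"edge-table"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("edge-table", "sif", "graphml")) {
  stopifnot(inherits(network, "regulatory_network"))
  format <- match.arg(format)
  d <- network$directed_edges
  u <- network$undirected_edges
  if (format == "edge-table") {
    header <- paste(c("source", "target", "directed", "am", "phase_rad",
                      "gain", "provenance"), collapse = "\t")
    rows <- character(0)
    if (nrow(d))
      rows <- c(rows, vapply(seq_len(nrow(d)), function(i)
        paste(c(d$source[i], d$target[i], "1",
                fmt_num(c(d$am[i], d$phase_rad[i], d$gain[i])),
                d$provenance[i]), collapse = "\t"), character(1)))
    if (nrow(u))
      rows <- c(rows, vapply(seq_len(nrow(u)), function(i)
        paste(c(u$gene_a[i], u$gene_b[i], "0",
                fmt_num(c(u$am[i], NA_real_, NA_real_)),
                u$provenance[i]), collapse = "\t"), character(1)))
    writeLines(c(header, rows), path)
  } else if (format == "sif") {
    lines <- character(0)
    if (nrow(d))
      lines <- c(lines, paste(d$source, "activates-lead", d$target,
                              sep = "\t"))
    if (nrow(u))
      lines <- c(lines, paste(u$gene_a, "associates", u$gene_b,
                              sep = "\t"))
    iso <- setdiff(network$nodes,
                   c(d$source, d$target, u$gene_a, u$gene_b))
    writeLines(c(lines, iso), path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Import a regulatory network from an edge table
#'
#' Reads a table written by [export_network()] with
#' `format = "edge-table"`. The node set is the union of edge endpoints
#' (isolates are not representable in an edge list).
#'
#' @param path Path to the edge table.
#' @return A `regulatory_network`.
#' @export
import_edge_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA")
  need <- c("source", "target", "directed", "am", "phase_rad", "gain",
            "provenance")
  if (!all(need %in% names(tab)))
    stop("edge table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- tab[tab$directed == 1, , drop = FALSE]
  u <- tab[tab$directed == 0, , drop = FALSE]
  regulatory_network(
    nodes = sort(unique(c(tab$source, tab$target))),
    directed_edges = data.frame(
      source = d$source, target = d$target, am = d$am,
      phase_rad = d$phase_rad, gain = d$gain, provenance = d$provenance,
      stringsAsFactors = FALSE),
    undirected_edges = data.frame(
      gene_a = u$source, gene_b = u$target, am = u$am,
      provenance = u$provenance, stringsAsFactors = FALSE))
}
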