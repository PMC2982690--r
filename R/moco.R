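#' Prior-knowledge constraints for network reconstruction
#'
#' Acquired biological knowledge enters the combinatorial optimization as
#' hard constraints: `forced` edges (directed source -> target pairs that
#' must appear in the network regardless of thresholds) and `forbidden`
#' pairs (unordered pairs that may never be authentic), plus the transfer-
#' gain constraint applied at direction calling. The forced and forbidden
#' sets must be disjoint on the underlying unordered pairs.
#'
#' @param forced Two-column matrix or data frame of directed
#'   (source, target) gene pairs, or `NULL`.
#' @param forbidden Two-column matrix or data frame of unordered gene
#'   pairs, or `NULL`.
#' @param gain_threshold Non-negative transfer-gain constraint (default
#'   0.3).
#' @return An object of class `knowledge_constraints`.
#' @export
knowledge_constraints <- function(forced = NULL, forbidden = NULL,
                                  gain_threshold = 0.3) {
  forced <- normalize_edge_input(forced)
  forbidden <- normalize_edge_input(forbidden)
  if (gain_threshold < 0)
    stop("gain_threshold must be >= 0", call. = FALSE)
  fk <- unordered_key(forced); bk <- unordered_key(forbidden)
  clash <- intersect(fk, bk)
  if (length(clash))
    stop("pair both forced and forbidden: '", clash[1L], "'", call. = FALSE)
  structure(list(forced = forced, forbidden = forbidden,
                 gain_threshold = gain_threshold),
            class = "knowledge_constraints")
}

normalize_edge_input <- function(x) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x)))
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(x) < 2L) stop("edge input needs two columns", call. = FALSE)
  out <- data.frame(from = as.character(x[[1L]]),
                    to = as.character(x[[2L]]), stringsAsFactors = FALSE)
  if (any(out$from == out$to))
    stop("self-pair in knowledge input: '",
         out$from[out$from == out$to][1L], "'", call. = FALSE)
  out
}

unordered_key <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "|")
}

#' Read knowledge constraints from a delimited file
#'
#' Expects three delimited columns: a directive (`force` or `forbid`), and
#' the two gene ids (source then target for `force`; order irrelevant for
#' `forbid`). Lines starting with `#` are ignored.
#'
#' @param path Path to the constraint file.
#' @param gain_threshold Gain constraint stored alongside the lists.
#' @param delimiter Field delimiter; auto-detected (tab vs comma) if NULL.
#' @return A [knowledge_constraints()] object.
#' @export
read_knowledge <- function(path, gain_threshold = 0.3, delimiter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (is.null(delimiter))
    delimiter <- if (any(grepl("\t", lines))) "\t" else ","
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("knowledge line ", bad[1L], " does not have 3 fields",
         call. = FALSE)
  directive <- tolower(trimws(vapply(parts, `[`, character(1), 1L)))
  a <- trimws(vapply(parts, `[`, character(1), 2L))
  b <- trimws(vapply(parts, `[`, character(1), 3L))
  unknown <- setdiff(directive, c("force", "forbid"))
  if (length(unknown))
    stop("unknown directive '", unknown[1L], "'", call. = FALSE)
  knowledge_constraints(
    forced = if (any(directive == "force"))
      data.frame(from = a[directive == "force"],
                 to = b[directive == "force"]) else NULL,
    forbidden = if (any(directive == "forbid"))
      data.frame(from = a[directive == "forbid"],
                 to = b[directive == "forbid"]) else NULL,
    gain_threshold = gain_threshold)
}

#' Solve the constrained partition problem
#'
#' Runs the threshold iteration ([pghc_iterate()]) and then imposes the
#' knowledge constraints on the resulting partition: forbidden pairs are
#' demoted from the authentic group to the unauthentic group, and forced
#' pairs are promoted into the authentic group from wherever they sit,
#' flagged with forced provenance. The two objectives — an authentic group
#' inside the target band, then the largest unauthentic group compatible
#' with it — are realized lexicographically: the monotone threshold walk
#' stops at the first (hence highest-threshold, hence largest-UPG) state
#' inside the band. With empty knowledge the result equals the plain
#' iteration.
#'
#' @param stats A `pair_stats` data frame.
#' @param init Initial [thresholds()]; `NULL` for centroid initialisation.
#' @param knowledge A [knowledge_constraints()] object.
#' @param target_fraction Authentic-fraction band, as in [pghc_iterate()].
#' @param max_iter Iteration cap.
#' @return An object of class `moco_result`: list with `partition` (a
#'   `pghc_partition` whose `forced` field lists promoted pair ids),
#'   `objective_values` (list `apg_size`, `upg_size`) and
#'   `constraint_report` (see [check_constraints()]).
#' @export
moco_solve <- function(stats, init = NULL,
                       knowledge = knowledge_constraints(),
                       target_fraction = c(0.30, 0.45),
                       max_iter = 10000L) {
  stats <- as_pair_stats(stats)
  stopifnot(inherits(knowledge, "knowledge_constraints"))
  universe <- stats$pair_id

  forced_ids <- unordered_key(knowledge$forced)
  missing_f <- setdiff(forced_ids, universe)
  if (length(missing_f))
    stop("forced pair not in the pair universe: '", missing_f[1L], "'",
         call. = FALSE)
  forbidden_ids <- unordered_key(knowledge$forbidden)
  missing_b <- setdiff(forbidden_ids, universe)
  if (length(missing_b))
    stop("forbidden pair not in the pair universe: '", missing_b[1L], "'",
         call. = FALSE)

  part <- pghc_iterate(stats, init = init,
                       target_fraction = target_fraction,
                       max_iter = max_iter)

  apgs <- part$apgs; qpgs <- part$qpgs; upgs <- part$upgs
  demote <- intersect(apgs, forbidden_ids)
  apgs <- setdiff(apgs, demote)
  upgs <- union(upgs, demote)
  promote <- setdiff(forced_ids, apgs)
  qpgs <- setdiff(qpgs, promote)
  upgs <- setdiff(upgs, promote)
  apgs <- union(apgs, promote)

  final <- partition(apgs, qpgs, upgs,
                     thresholds_used = part$thresholds_used,
                     iterations = part$iterations, status = part$status,
                     history = part$history, forced = promote)
  res <- structure(list(partition = final,
                        objective_values = list(
                          apg_size = length(apgs),
                          upg_size = length(upgs)),
                        constraint_report = NULL,
                        knowledge = knowledge,
                        n_pairs = length(universe)),
                   class = "moco_result")
  res$constraint_report <- check_constraints(res, knowledge)
  res
}

#' @export
print.moco_result <- function(x, ...) {
  cat("Constrained partition result\n")
  print(x$partition)
  rep <- x$constraint_report
  cat(sum(rep$pass), "of", nrow(rep), "constraint checks passed\n")
  invisible(x)
}

#' Verify the constraint set of a partition result
#'
#' Recomputes every structural and knowledge constraint on a result:
#' non-negative group sizes, conservation of the pair total, absence of
#' forbidden pairs from the authentic group, and presence of forced pairs
#' in it. Failures are reported, never thrown.
#'
#' @param result A `moco_result` (or a list with a `partition` and
#'   `n_pairs`).
#' @param knowledge A [knowledge_constraints()] object.
#' @return Data frame with columns `constraint`, `pass`, `detail`.
#' @export
check_constraints <- function(result, knowledge) {
  part <- result$partition
  sizes <- c(apg = length(part$apgs), qpg = length(part$qpgs),
             upg = length(part$upgs))
  total <- result$n_pairs
  forced_ids <- unordered_key(knowledge$forced)
  forbidden_ids <- unordered_key(knowledge$forbidden)
  bad_forbidden <- intersect(forbidden_ids, part$apgs)
  missing_forced <- setdiff(forced_ids, part$apgs)
  all_ids <- c(part$apgs, part$qpgs, part$upgs)
  data.frame(
    constraint = c("non-negative group sizes", "fixed pair total",
                   "groups disjoint", "forbidden pairs not authentic",
                   "forced pairs authentic"),
    pass = c(all(sizes >= 0),
             sum(sizes) == total,
             !anyDuplicated(all_ids),
             length(bad_forbidden) == 0L,
             length(missing_forced) == 0L),
    detail = c(paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
               sprintf("%d of %d", sum(sizes), total),
               if (anyDuplicated(all_ids))
                 paste("duplicated:", all_ids[duplicated(all_ids)][1L])
               else "",
               if (length(bad_forbidden))
                 paste("violations:", paste(bad_forbidden, collapse = " "))
               else "",
               if (length(missing_forced))
                 paste("missing:", paste(missing_forced, collapse = " "))
               else ""),
    stringsAsFactors = FALSE)
}
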