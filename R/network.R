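# Levenshtein-distance clonotype similarity graphs and six global metrics.

#' Levenshtein edit distance between sequences
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions (unit costs). Vectorized over both arguments; with two
#' vectors, returns the full distance matrix.
#'
#' @param a,b character vectors.
#' @return integer matrix of distances (`length(a)` x `length(b)`).
#' @export
levenshtein <- function(a, b) {
  adist(a, b, costs = c(insertions = 1, deletions = 1, substitutions = 1))
}

#' Build the Levenshtein-distance clonotype graph
#'
#' Nodes are unique CDR3 strings; an undirected edge joins two distinct
#' sequences iff their Levenshtein distance is between 1 and `max_dist`.
#' Candidate pairs are pruned by length difference (|len(a) - len(b)| >
#' max_dist implies LD > max_dist), an exact optimization: the edge set
#' equals the all-pairs construction.
#'
#' @param seqs character vector of unique sequences.
#' @param max_dist maximum edit distance for an edge (default 3).
#' @return an object of class `"clonotype_graph"`: list with `graph`
#'   (an igraph), `seqs`, and `max_dist`.
#' @export
build_ld_graph <- function(seqs, max_dist = 3) {
  if (max_dist < 1) abort("max_dist must be >= 1")
  if (anyDuplicated(seqs)) abort("sequences must be unique")
  seqs <- as.character(seqs)
  n <- length(seqs)
  lens <- nchar(seqs)
  # group by length; only compare length bands within max_dist
  by_len <- split(seq_len(n), lens)
  ulen <- as.integer(names(by_len))
  edges <- list()
  for (i in seq_along(ulen)) {
    for (j in i:length(ulen)) {
      if (ulen[j] - ulen[i] > max_dist) next
      ia <- by_len[[i]]; ib <- by_len[[j]]
      d <- adist(seqs[ia], seqs[ib])
      hit <- which(d >= 1 & d <= max_dist, arr.ind = TRUE)
      if (i == j && nrow(hit)) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit)) {
        edges[[length(edges) + 1]] <- cbind(ia[hit[, 1]], ib[hit[, 2]])
      }
    }
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), ncol = 2)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- seqs
  if (nrow(em)) g <- igraph::add_edges(g, t(em))
  structure(list(graph = g, seqs = seqs, max_dist = max_dist),
            class = "clonotype_graph")
}

#' @export
print.clonotype_graph <- function(x, ...) {
  cat(sprintf("<clonotype_graph> %d nodes, %d edges (LD <= %d)\n",
              length(x$seqs), igraph::ecount(x$graph), x$max_dist))
  invisible(x)
}

#' Edge list of a clonotype graph as a tibble
#' @param x a `clonotype_graph`.
#' @param ... unused.
#' @return tibble with columns `from`, `to` (sequences).
#' @export
tidy.clonotype_graph <- function(x, ...) {
  el <- igraph::as_edgelist(x$graph, names = TRUE)
  tibble(from = el[, 1], to = el[, 2])
}

#' Six global network metrics of a clonotype graph
#'
#' * `avg_degree`: 2|E|/|V|.
#' * `density`: 2|E|/(|V|(|V|-1)).
#' * `avg_clustering`: mean over nodes of the local clustering coefficient
#'   (triangles through the node over deg(deg-1)/2; 0 for degree < 2).
#' * `global_efficiency`: mean over node pairs of 1/d(u, v), disconnected
#'   pairs contributing 0.
#' * `local_efficiency`: mean over nodes of the global efficiency of the
#'   subgraph induced on the node's neighbours (0 for degree < 2).
#' * `assortativity`: Pearson correlation of degrees across edge endpoints
#'   (Newman's degree assortativity); NA when degree variance is zero.
#'
#' @param g a `clonotype_graph` or an igraph.
#' @return one-row tibble with the six metrics.
#' @export
network_metrics <- function(g) {
  ig <- if (inherits(g, "clonotype_graph")) g$graph else g
  nv <- igraph::vcount(ig)
  if (nv < 2) abort("network metrics undefined for graphs with < 2 nodes")
  ne <- igraph::ecount(ig)
  local_cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  local_cc[is.nan(local_cc)] <- 0
  tibble(
    assortativity = suppressWarnings(igraph::assortativity_degree(ig)),
    avg_degree = 2 * ne / nv,
    avg_clustering = mean(local_cc),
    density = 2 * ne / (nv * (nv - 1)),
    local_efficiency = if (ne == 0) 0 else igraph::average_local_efficiency(ig),
    global_efficiency = if (ne == 0) 0 else igraph::global_efficiency(ig)
  )
}

#' Network metrics of a repertoire across downsampled sizes
#'
#' Downsamples the repertoire to each size in clonotype mode (frequency
#' information removed), builds the LD graph and computes the six global
#' metrics. Sizes exceeding the clonal volume are skipped with a warning.
#'
#' @param rep a [repertoire()].
#' @param sizes integer vector of clonotype counts.
#' @param max_dist edge threshold (default 3).
#' @param seed integer seed; one derived stream per size.
#' @return tibble with one row per achieved size.
#' @export
network_summary <- function(rep, sizes, max_dist = 3, seed = 1L) {
  rows <- list()
  for (s in sizes) {
    ds <- downsample(rep, s, mode = "clonotypes",
                     seed = derive_seed(seed, attr(rep, "study_id"),
                                        attr(rep, "individual_id"),
                                        rep_locus(rep), "net", s))
    if (is.null(ds)) next
    g <- build_ld_graph(ds$junction_aa, max_dist)
    rows[[length(rows) + 1]] <- bind_cols(tibble(size = s), network_metrics(g))
  }
  bind_rows(rows)
}
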