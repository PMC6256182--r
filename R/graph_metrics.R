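#' @importFrom igraph vcount ecount
NULL

# accept an ortho_graph or a plain igraph; metrics never see hermits
.as_igraph <- function(graph) {
  if (inherits(graph, "ortho_graph")) return(graph$graph)
  if (inherits(graph, "igraph")) return(graph)
  stop("expected an ortho_graph or igraph object")
}

#' Mean degree of a network
#'
#' The mean number of neighbours per word, `2 |E| / |V|`.
#'
#' @param graph an `ortho_graph` or `igraph` object.
#' @return a real number.
#' @export
mean_degree <- function(graph) {
  ig <- .as_igraph(graph)
  if (igraph::vcount(ig) == 0L)
    stop("mean degree is undefined for an empty graph")
  2 * igraph::ecount(ig) / igraph::vcount(ig)
}

#' Degree distribution of a network
#'
#' Relative frequency of each observed degree over the non-hermit nodes;
#' only observed degrees appear, so the values sum to 1 and, for an
#' orthographic graph, degree 0 never appears.
#'
#' @param graph an `ortho_graph` or `igraph` object.
#' @return named numeric vector: names are degrees, values are relative
#'   frequencies.
#' @export
degree_distribution <- function(graph) {
  ig <- .as_igraph(graph)
  if (igraph::vcount(ig) == 0L)
    stop("degree distribution is undefined for an empty graph")
  tab <- table(igraph::degree(ig))
  stats::setNames(as.numeric(tab) / igraph::vcount(ig), names(tab))
}

#' Local clustering coefficient of a node
#'
#' `C_i = 2 T_i / (k_i (k_i - 1))`, where `T_i` is the number of edges among
#' the node's neighbours: the probability that two neighbours of the node
#' are themselves neighbours.  Undefined (NA) for nodes of degree below 2.
#'
#' @param graph an `ortho_graph` or `igraph` object.
#' @param node a vertex name (or index).
#' @return a real in `[0, 1]`, or `NA` when the degree is below 2.
#' @export
local_clustering <- function(graph, node) {
  ig <- .as_igraph(graph)
  if (is.character(node) && !(node %in% igraph::V(ig)$name))
    stop("unknown node: ", node)
  val <- unname(igraph::transitivity(ig, type = "local", vids = node,
                                     isolates = "NaN"))
  ifelse(is.nan(val), NA_real_, val)
}

#' Average clustering coefficient of a network
#'
#' Arithmetic mean of the local clustering coefficients.  By default nodes
#' of degree below 2, where the coefficient is undefined, are excluded from
#' the average; `count_undefined_as_zero = TRUE` counts them as 0 instead.
#'
#' @param graph an `ortho_graph` or `igraph` object.
#' @param count_undefined_as_zero include degree-<2 nodes as zeros.
#' @return a real in `[0, 1]`.
#' @export
average_clustering <- function(graph, count_undefined_as_zero = FALSE) {
  ig <- .as_igraph(graph)
  if (igraph::vcount(ig) == 0L)
    stop("clustering is undefined for an empty graph")
  cl <- igraph::transitivity(ig, type = "local", isolates = "NaN")
  if (count_undefined_as_zero) {
    cl[is.nan(cl)] <- 0
    return(mean(cl))
  }
  cl <- cl[!is.nan(cl)]
  if (length(cl) == 0L)
    stop("no node has degree >= 2; clustering is undefined under the ",
         "exclusion policy")
  mean(cl)
}

# finite positive shortest-path lengths from a set of source vertices
.sampled_distances <- function(ig, n_sources) {
  n_sources <- as.integer(n_sources)
  if (n_sources > igraph::vcount(ig))
    stop("n_sources exceeds the number of nodes")
  src <- sample(igraph::vcount(ig), n_sources)
  d <- igraph::distances(ig, v = src)
  d[is.finite(d) & d > 0]
}

#' Average shortest-path length
#'
#' Mean shortest-path length over ordered pairs of distinct, mutually
#' reachable nodes; unreachable pairs are excluded, so the measure is finite
#' even when the graph is disconnected after hermit removal.  `"exact"` mode
#' runs a breadth-first search from every node; `"sampled"` mode pools the
#' path lengths of all pairs reachable from `n_sources` uniformly drawn
#' source nodes (a ratio estimator of the exact value; exactly unbiased when
#' every node reaches the same number of others).  Sampling uses R's global
#' RNG stream.
#'
#' @param graph an `ortho_graph` or `igraph` object with >= 2 nodes.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_sources number of BFS sources in sampled mode.
#' @return a real >= 1.
#' @export
average_path_length <- function(graph, mode = c("exact", "sampled"),
                                n_sources = 1000L) {
  ig <- .as_igraph(graph)
  mode <- match.arg(mode)
  if (igraph::vcount(ig) < 2L)
    stop("average path length needs at least 2 nodes")
  if (mode == "exact")
    return(igraph::mean_distance(ig, directed = FALSE, unconnected = TRUE))
  mean(.sampled_distances(ig, n_sources))
}

#' Network diameter
#'
#' The maximum finite shortest-path length: the largest distance within any
#' connected component.  In `"sampled"` mode the maximum over BFS trees from
#' `n_sources` random sources is returned; this is a lower bound on the true
#' diameter and is flagged with attribute `lower_bound = TRUE`.
#'
#' @inheritParams average_path_length
#' @return an integer (with attribute `lower_bound` in sampled mode).
#' @export
graph_diameter <- function(graph, mode = c("exact", "sampled"),
                           n_sources = 1000L) {
  ig <- .as_igraph(graph)
  mode <- match.arg(mode)
  if (igraph::vcount(ig) < 2L)
    stop("diameter needs at least 2 nodes")
  if (mode == "exact")
    return(as.integer(igraph::diameter(ig, directed = FALSE,
                                       unconnected = TRUE)))
  d <- as.integer(max(.sampled_distances(ig, n_sources)))
  attr(d, "lower_bound") <- TRUE
  d
}

#' Compute all network measures for one lexicon
#'
#' Fills the full per-lexicon record: lexicon size, non-hermit node count
#' `n`, mean degree, degree distribution, average path length `L`, diameter
#' `D`, clustering coefficient `C`, and hermit statistics (hermit proportion
#' is hermits over all types).  Path-based measures use exact breadth-first
#' search when `n` is at most `exact_threshold` (default 5000) and BFS
#' sampling from `n_sources` sources above it; `path_mode` can force either.
#'
#' @param lexicon a [virtual_lexicon()] or a character vector of word types.
#' @param graph optional pre-built [build_neighbor_graph()] result for the
#'   same types; built on the fly when omitted.
#' @param path_mode `"auto"`, `"exact"` or `"sampled"`.
#' @param n_sources BFS sources in sampled mode.
#' @param clustering_policy `"exclude"` drops degree-<2 nodes from `C`
#'   (the default), `"zero"` counts them as 0.
#' @param seed optional integer seed for the sampled path mode.
#' @param exact_threshold node count up to which `"auto"` uses exact paths.
#' @return a `network_measures` record (a list; `NA` fields where a measure
#'   is undefined, e.g. on an all-hermit lexicon).
#' @export
compute_all_measures <- function(lexicon, graph = NULL,
                                 path_mode = c("auto", "exact", "sampled"),
                                 n_sources = 1000L,
                                 clustering_policy = c("exclude", "zero"),
                                 seed = NULL,
                                 exact_threshold = 5000L) {
  path_mode <- match.arg(path_mode)
  clustering_policy <- match.arg(clustering_policy)
  if (inherits(lexicon, "virtual_lexicon")) {
    types <- lexicon$types
    participant <- lexicon$participant_id
    grade <- lexicon$grade_label
  } else {
    types <- as.character(lexicon)
    participant <- NA_integer_
    grade <- NA_character_
  }
  if (is.null(graph)) graph <- build_neighbor_graph(types)
  stopifnot(inherits(graph, "ortho_graph"))
  if (graph$lexicon_size != length(types))
    stop("graph was not built from this lexicon")

  n <- length(graph$nodes)
  hermit_count <- length(graph$hermits)
  lexicon_size <- graph$lexicon_size
  if (path_mode == "auto")
    path_mode <- if (n <= exact_threshold) "exact" else "sampled"
  if (!is.null(seed)) set.seed(seed)

  if (n == 0L) {
    return(structure(list(participant = participant, grade = grade,
                          lexicon_size = lexicon_size, n = 0L,
                          mean_degree = NA_real_,
                          degree_distribution = NULL,
                          avg_path_length = NA_real_, diameter = NA_integer_,
                          clustering = NA_real_, hermit_count = hermit_count,
                          hermit_proportion = hermit_count / lexicon_size,
                          path_length_mode = path_mode),
                     class = "network_measures"))
  }

  pk <- degree_distribution(graph)
  clustering <- tryCatch(
    average_clustering(graph, clustering_policy == "zero"),
    error = function(e) NA_real_)
  if (n >= 2L) {
    ns <- min(n_sources, n)
    L <- average_path_length(graph, path_mode, ns)
    D <- graph_diameter(graph, path_mode, ns)
  } else {
    L <- NA_real_
    D <- NA_integer_
  }
  structure(list(participant = participant, grade = grade,
                 lexicon_size = lexicon_size, n = n,
                 mean_degree = mean_degree(graph),
                 degree_distribution = pk,
                 avg_path_length = L, diameter = as.integer(D),
                 clustering = clustering, hermit_count = hermit_count,
                 hermit_proportion = hermit_count / lexicon_size,
                 path_length_mode = path_mode),
            class = "network_measures")
}

#' @export
print.network_measures <- function(x, ...) {
  cat("network measures",
      if (!is.na(x$participant))
        paste0("(participant ", x$participant, ", grade ", x$grade, ")"),
      "\n  lexicon size:", x$lexicon_size, " n:", x$n,
      " hermits:", x$hermit_count,
      sprintf("(%.1f%%)", 100 * x$hermit_proportion),
      "\n  <k>:", format(x$mean_degree, digits = 4),
      " L:", format(x$avg_path_length, digits = 4),
      " D:", x$diameter,
      " C:", format(x$clustering, digits = 4),
      paste0("[", x$path_length_mode, "]"), "\n")
  invisible(x)
}
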