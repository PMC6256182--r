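#' Levenshtein distance between word types
#'
#' Standard unit-cost edit distance (substitutions, insertions, deletions; no
#' transpositions), computed over Unicode code points after NFC
#' normalisation, so composed and decomposed umlauts count as one symbol.
#' Comparison is case-sensitive.
#'
#' @param a,b character vectors, recycled elementwise.
#' @return integer vector of distances.
#' @export
levenshtein_distance <- function(a, b) {
  a <- stringi::stri_trans_nfc(as.character(a))
  b <- stringi::stri_trans_nfc(as.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n))
    out[i] <- as.integer(utils::adist(a[i], b[i], useBytes = FALSE))
  out
}

# all unordered index pairs that share a key; keys sorted bytewise (radix)
# for locale independence
.pairs_from_groups <- function(ids, keys) {
  o <- order(keys, method = "radix")
  k <- keys[o]
  id <- ids[o]
  r <- rle(k)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  big <- which(r$lengths >= 2L)
  if (length(big) == 0L)
    return(matrix(integer(0), ncol = 2L))
  do.call(rbind, lapply(big, function(bk) {
    g <- id[starts[bk]:ends[bk]]
    t(utils::combn(g, 2L))
  }))
}

#' Build the Levenshtein-1 orthographic neighbour graph
#'
#' Connects two word types iff their Levenshtein distance is exactly 1.  The
#' graph is simple and undirected; types with no neighbour are set aside as
#' lexical hermits rather than kept as isolated vertices.
#'
#' Edges are found through an index, never by all-pairs distance computation:
#' same-length pairs differing by one substitution share a single-position
#' wildcard key, and pairs at length difference 1 are matched by looking up
#' every single-deletion variant of each word among the input types.  The
#' naive shortcut of matching shared deletion variants is avoided because it
#' admits transpositions (e.g. "ab"/"ba"), which are distance 2.  The result
#' is independent of input order.
#'
#' @param types character vector of unique, non-empty word types.
#' @return an `ortho_graph`: a list with `nodes` (types with at least one
#'   neighbour), `hermits`, `edges` (two-column character matrix,
#'   lexicographically ordered within and across rows), `lexicon_size`, and
#'   `graph` (the [igraph::graph_from_data_frame()] over the non-hermit
#'   nodes).
#' @export
build_neighbor_graph <- function(types) {
  types <- stringi::stri_trans_nfc(as.character(types))
  if (length(types) == 0L)
    return(.ortho_graph(character(0), character(0),
                        matrix(character(0), ncol = 2L), 0L))
  if (any(is.na(types) | types == ""))
    stop("word types must be non-empty strings")
  if (anyDuplicated(types))
    stop("word types must be unique after NFC normalization")

  lens <- stringi::stri_length(types)
  idx <- rep.int(seq_along(types), lens)
  pos <- sequence(lens)
  w <- types[idx]
  pre <- stringi::stri_sub(w, 1L, pos - 1L)
  post <- stringi::stri_sub(w, pos + 1L)

  # substitution edges: same wildcard bucket => same length, one differing
  # position, so distance exactly 1
  sub_pairs <- .pairs_from_groups(idx, stringi::stri_join(pre, "\x1f", post))

  # insertion/deletion edges: a single-deletion variant that is itself a type
  del_variant <- stringi::stri_join(pre, post)
  hit <- match(del_variant, types)
  keep <- which(!is.na(hit))
  del_pairs <- cbind(idx[keep], hit[keep])

  pairs <- rbind(sub_pairs, del_pairs)
  if (nrow(pairs) > 0L) {
    a <- pmin(pairs[, 1L], pairs[, 2L])
    b <- pmax(pairs[, 1L], pairs[, 2L])
    dup <- duplicated(a * (length(types) + 1) + b)
    a <- a[!dup]
    b <- b[!dup]
    ea <- types[a]
    eb <- types[b]
    swap <- ea > eb
    tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
    o <- order(ea, eb, method = "radix")
    edges <- cbind(ea[o], eb[o])
  } else {
    edges <- matrix(character(0), ncol = 2L)
  }
  connected <- unique(c(edges))
  hermits <- setdiff(types, connected)
  nodes <- types[types %in% connected]
  .ortho_graph(nodes, hermits, edges, length(types))
}

.ortho_graph <- function(nodes, hermits, edges, lexicon_size) {
  g <- if (length(nodes) > 0L) {
    igraph::graph_from_data_frame(
      data.frame(from = edges[, 1L], to = edges[, 2L],
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = sort(nodes), stringsAsFactors = FALSE))
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }
  structure(list(nodes = nodes, hermits = hermits, edges = edges,
                 lexicon_size = as.integer(lexicon_size), graph = g),
            class = "ortho_graph")
}

#' @export
print.ortho_graph <- function(x, ...) {
  cat("orthographic neighbour graph:", length(x$nodes), "connected nodes,",
      nrow(x$edges), "edges,", length(x$hermits), "hermits (of",
      x$lexicon_size, "types)\n")
  invisible(x)
}

#' Adjacency list of an orthographic graph
#'
#' @param graph an [build_neighbor_graph()] result.
#' @return named list mapping each non-hermit node to the character vector
#'   of its neighbours.
#' @export
adjacency_list <- function(graph) {
  stopifnot(inherits(graph, "ortho_graph"))
  al <- igraph::as_adj_list(graph$graph)
  lapply(stats::setNames(al, igraph::V(graph$graph)$name),
         function(vs) igraph::V(graph$graph)$name[as.integer(vs)])
}

#' Ego network of a word type
#'
#' The subgraph induced on all types within Levenshtein distance
#' `max_distance` of a focus word; edges still require pairwise distance
#' exactly 1.  The focus word's local clustering coefficient within the full
#' source set is reported alongside (NA when its degree is below 2).
#'
#' @param graph_source character vector of word types containing `focus`.
#' @param focus the focus word type.
#' @param max_distance maximum Levenshtein distance from the focus (>= 1).
#' @return an `ego_network`: list with the induced `ortho_graph` (`graph`),
#'   `focus`, `distances` (named integer vector from the focus), and
#'   `focus_clustering`.
#' @export
ego_network <- function(graph_source, focus, max_distance = 2L) {
  graph_source <- stringi::stri_trans_nfc(as.character(graph_source))
  focus <- stringi::stri_trans_nfc(as.character(focus))
  stopifnot(length(focus) == 1L, max_distance >= 1L)
  if (!focus %in% graph_source)
    stop("focus word \"", focus, "\" is not in the source set")
  d <- as.integer(utils::adist(focus, graph_source, useBytes = FALSE))
  keep <- graph_source[d <= max_distance]
  sub <- build_neighbor_graph(keep)
  cl <- if (focus %in% sub$nodes) local_clustering(sub, focus) else NA_real_
  structure(list(graph = sub, focus = focus,
                 distances = stats::setNames(d[d <= max_distance], keep),
                 focus_clustering = cl),
            class = "ego_network")
}

#' @export
print.ego_network <- function(x, ...) {
  cat("ego network of \"", x$focus, "\": ", length(x$graph$nodes) +
        length(x$graph$hermits), " types within distance ",
      max(x$distances), "; focus clustering ",
      format(x$focus_clustering, digits = 3), "\n", sep = "")
  invisible(x)
}
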