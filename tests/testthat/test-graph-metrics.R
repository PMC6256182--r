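test_that("mean degree and degree distribution match closed forms", {
  triangle <- igraph::make_full_graph(3)
  expect_equal(mean_degree(triangle), 2)
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(mean_degree(path3), 4 / 3)
  expect_equal(mean_degree(igraph::make_full_graph(5)), 4)
  star <- igraph::make_star(4, mode = "undirected")
  pk <- degree_distribution(star)
  expect_equal(pk, c("1" = 0.75, "3" = 0.25))
  ring <- igraph::make_ring(6)
  expect_equal(degree_distribution(ring), c("2" = 1))
  # counts recovered from relative frequencies are whole numbers
  counts <- pk * igraph::vcount(star)
  expect_equal(counts, round(counts))
  expect_error(mean_degree(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("local clustering follows C_i = 2 T_i / (k_i (k_i - 1))", {
  triangle <- igraph::make_full_graph(3)
  expect_equal(local_clustering(triangle, 1), 1)
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  expect_equal(local_clustering(star, 1), 0)     # no edges among leaves
  expect_true(is.na(local_clustering(star, 2)))  # degree-1: undefined
  og <- build_neighbor_graph(c("hat", "hot", "hate"))
  expect_equal(local_clustering(og, "hat"), 0)
  expect_error(local_clustering(og, "cat"), "unknown node")
})

test_that("average clustering honours both undefined-node policies", {
  expect_equal(average_clustering(igraph::make_full_graph(4)), 1)
  expect_equal(average_clustering(igraph::make_ring(5)), 0)
  # triangle plus pendant: defined nodes give {1, 1, 1/3}
  tp <- igraph::make_graph(~ a - b, b - c, c - a, a - d)
  expect_equal(average_clustering(tp), 7 / 9)
  expect_equal(average_clustering(tp, count_undefined_as_zero = TRUE), 7 / 12)
  # matching: all degrees 1, undefined everywhere under the default policy
  m2 <- igraph::make_graph(~ a - b, c - d)
  expect_error(average_clustering(m2), "undefined")
  expect_equal(average_clustering(m2, count_undefined_as_zero = TRUE), 0)
})

test_that("path length and diameter match closed forms and conventions", {
  path4 <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(average_path_length(path4), 5 / 3)
  expect_equal(graph_diameter(path4), 3L)
  # unreachable pairs are excluded, not infinite
  m2 <- igraph::make_graph(~ a - b, c - d)
  expect_equal(average_path_length(m2), 1)
  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  expect_equal(graph_diameter(two_tri), 1L)
  for (n in c(4, 7, 12)) {
    expect_equal(graph_diameter(igraph::make_ring(n)), as.integer(floor(n / 2)))
    pn <- igraph::make_ring(n, circular = FALSE)
    expect_equal(average_path_length(pn), (n + 1) / 3)
    expect_equal(graph_diameter(pn), n - 1L)
  }
})

test_that("exact L, D and C agree with Floyd-Warshall and triangle oracles", {
  set.seed(20)
  for (i in 1:6) {
    ig <- random_test_graph(sample(20:100, 1), stats::runif(1, 0.03, 0.1))
    if (igraph::ecount(ig) == 0) next
    adj <- adj_of(ig)
    expect_equal(average_path_length(ig), oracle_avg_path_length(adj))
    expect_equal(graph_diameter(ig), as.integer(oracle_diameter(adj)))
    if (any(rowSums(adj) >= 2))
      expect_equal(average_clustering(ig), oracle_avg_clustering(adj))
  }
})

test_that("sampled path estimates track the exact values", {
  set.seed(21)
  errs <- vapply(1:10, function(i) {
    ig <- random_test_graph(200, 0.03)
    exact <- average_path_length(ig)
    sampled <- average_path_length(ig, mode = "sampled", n_sources = 50)
    d_exact <- graph_diameter(ig)
    d_sampled <- graph_diameter(ig, mode = "sampled", n_sources = 50)
    expect_lte(d_sampled, d_exact)            # sampled D is a lower bound
    expect_true(isTRUE(attr(d_sampled, "lower_bound")))
    abs(sampled - exact) / exact
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
  ig <- random_test_graph(50, 0.1)
  expect_error(average_path_length(ig, mode = "sampled", n_sources = 51),
               "n_sources")
})

test_that("compute_all_measures reproduces the hand-enumerated record", {
  lex <- virtual_lexicon(1L, "1", c("hat", "hot", "hate", "zzz"),
                         stats::setNames(rep("1", 4),
                                         c("hat", "hot", "hate", "zzz")))
  m <- compute_all_measures(lex)
  expect_identical(m$lexicon_size, 4L)
  expect_identical(m$n, 3L)
  expect_identical(m$hermit_count, 1L)
  expect_equal(m$hermit_proportion, 0.25)
  expect_equal(m$mean_degree, 4 / 3)
  expect_equal(m$clustering, 0)   # only "hat" has degree 2; hot-hate absent
  expect_equal(m$avg_path_length, 4 / 3)
  expect_identical(m$diameter, 2L)
  expect_identical(m$path_length_mode, "exact")
  # invariants of the record
  pk <- m$degree_distribution
  expect_equal(sum(pk), 1, tolerance = 1e-9)
  expect_equal(sum(as.numeric(names(pk)) * pk), m$mean_degree,
               tolerance = 1e-9)
  expect_identical(m$n + m$hermit_count, m$lexicon_size)
  expect_false("0" %in% names(pk))
})

test_that("all-hermit lexicons yield undefined measures, not errors", {
  m <- compute_all_measures(c("aaa", "zzz", "qqq"))
  expect_identical(m$n, 0L)
  expect_true(is.na(m$mean_degree) && is.na(m$avg_path_length) &&
                is.na(m$clustering))
  expect_equal(m$hermit_proportion, 1)
})

test_that("sampled-mode records are reproducible from their seed", {
  cp <- generate_corpus(corpus_gen_config(n_types = 1500, seed = 23))
  types <- sample_initial_lexicon(cp, 900, 1, base_seed = 23)$types
  g <- build_neighbor_graph(types)
  m1 <- compute_all_measures(types, g, path_mode = "sampled", n_sources = 40,
                             seed = 99)
  m2 <- compute_all_measures(types, g, path_mode = "sampled", n_sources = 40,
                             seed = 99)
  expect_identical(m1, m2)
  expect_identical(m1$path_length_mode, "sampled")
})

test_that("growing lexicons gain neighbours and lose clustering", {
  d <- small_demo_cohort(seed = 9, n_types = 2000, n_participants = 4)
  md <- matrix(NA_real_, 4, 3)
  cc <- matrix(NA_real_, 4, 3)
  for (p in 1:4) for (g in 1:3) {
    gr <- build_neighbor_graph(d$cohort$lexicons[[p]][[g]]$types)
    md[p, g] <- mean_degree(gr)
    cc[p, g] <- average_clustering(gr)
  }
  expect_true(all(diff(colMeans(md)) >= 0))
  expect_true(all(diff(colMeans(cc)[-1]) <= 0))
})
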