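test_that("edge-list loading simplifies and reports cleanup counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tB", "B\tA", "A\tA", "A\tC"), f)
  net <- load_edge_list(f)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(net), 2)
  el <- igraph::as_edgelist(net)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("A B", "A C"))
  rep <- net$cleanup_report
  expect_equal(rep$raw_rows, 4)
  expect_equal(rep$loops_dropped, 1)
  expect_equal(rep$duplicates_collapsed, 1)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tB", f2)
  net2 <- load_edge_list(f2)
  expect_equal(igraph::vcount(net2), 2)
  expect_equal(igraph::ecount(net2), 1)
})

test_that("SIF format and malformed/empty files are handled", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B", "B pp C"), f)
  net <- load_edge_list(f, format = "sif")
  expect_equal(igraph::ecount(net), 2)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "brokenrow"), f2)
  expect_error(load_edge_list(f2), "line 2")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only a comment", f3)
  expect_error(load_edge_list(f3), "empty")
})

test_that("simplified edge count matches a set-based dedup oracle", {
  set.seed(11)
  ids <- sprintf("p%02d", 1:25)
  from <- sample(ids, 300, replace = TRUE)
  to <- sample(ids, 300, replace = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(from, to, sep = "\t"), f)
  net <- load_edge_list(f)
  # oracle: set of canonical unordered non-loop pairs
  keep <- from != to
  expected <- unique(paste(pmin(from[keep], to[keep]),
                           pmax(from[keep], to[keep])))
  expect_equal(igraph::ecount(net), length(expected))
})

test_that("loading is idempotent under re-serialisation", {
  net <- random_fixture_graph(15, 0.3, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), f)
  net2 <- load_edge_list(f)
  canon <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(canon(net2), canon(net))
})

test_that("ID mapping renames, drops unmapped nodes and re-simplifies", {
  m <- function(...) {
    p <- list(...)
    data.frame(source = names(p), target = unlist(p),
               stringsAsFactors = FALSE)
  }
  net <- interaction_network("A", "B")
  out <- apply_id_mapping(net, m(A = "X", B = "Y"))
  expect_setequal(igraph::V(out)$name, c("X", "Y"))
  expect_equal(igraph::ecount(out), 1)

  net2 <- interaction_network(c("A", "B"), c("B", "C"))
  out2 <- apply_id_mapping(net2, m(A = "X", C = "X", B = "Y"))
  expect_setequal(igraph::V(out2)$name, c("X", "Y"))
  expect_equal(igraph::ecount(out2), 1)

  out3 <- apply_id_mapping(net, m(A = "X"))
  expect_identical(igraph::V(out3)$name, "X")
  expect_equal(igraph::ecount(out3), 0)
  expect_identical(out3$mapping_report$untranslated, "B")
})

test_that("mapping collisions follow the policy and are logged", {
  net <- interaction_network("A", "B")
  mapping <- data.frame(source = c("A", "A", "B"),
                        target = c("Z", "X", "Y"),
                        stringsAsFactors = FALSE)
  out <- apply_id_mapping(net, mapping)
  expect_setequal(igraph::V(out)$name, c("X", "Y"))
  expect_identical(out$mapping_report$collisions$A, "Z")
  expect_error(apply_id_mapping(net, mapping, collision_policy = "error"),
               "ambiguous")
})

test_that("mapping never increases node or edge counts", {
  set.seed(21)
  for (rep in 1:10) {
    net <- random_fixture_graph(20, 0.2, seed = 100 + rep)
    ids <- igraph::V(net)$name
    src <- sample(ids, 15)
    mapping <- data.frame(source = src,
                          target = sample(sprintf("u%02d", 1:8), 15,
                                          replace = TRUE),
                          stringsAsFactors = FALSE)
    out <- apply_id_mapping(net, mapping)
    expect_lte(igraph::vcount(out), igraph::vcount(net))
    expect_lte(igraph::ecount(out), igraph::ecount(net))
  }
})

test_that("giant component selection and tie-breaking are deterministic", {
  # components of sizes 5, 3, 1
  net <- interaction_network(
    c("a1", "a2", "a3", "a4", "b1", "b2"),
    c("a2", "a3", "a4", "a5", "b2", "b3"),
    isolated = "z1")
  gc <- giant_component(net)
  expect_setequal(igraph::V(gc)$name, c("a1", "a2", "a3", "a4", "a5"))
  expect_true(igraph::is_connected(gc))

  # connected network is returned whole
  ring <- interaction_network(c("x", "y", "z"), c("y", "z", "x"))
  expect_equal(igraph::vcount(giant_component(ring)), 3)

  # equal-size tie: the component holding the smallest node ID wins
  tie <- interaction_network(c("m1", "a1"), c("m2", "a2"))
  expect_setequal(igraph::V(giant_component(tie))$name, c("a1", "a2"))

  expect_error(giant_component(interaction_network(character(0), character(0))),
               "empty")
})

test_that("random node deletion is exact, seeded and uniform", {
  net <- random_fixture_graph(10, 0.4, seed = 3)
  out <- random_node_deletion(net, 0.5, rng_seed = 9)
  expect_equal(igraph::vcount(out), 5)
  out2 <- random_node_deletion(net, 0.5, rng_seed = 9)
  expect_identical(sort(igraph::V(out2)$name), sort(igraph::V(out)$name))
  expect_error(random_node_deletion(net, 1.5, 1), "fraction")
  expect_error(random_node_deletion(net, 0, 1), "fraction")

  # each node should survive in about half of many replicates
  big <- random_fixture_graph(100, 0.05, seed = 4)
  ids <- sort(igraph::V(big)$name)
  survive <- setNames(numeric(length(ids)), ids)
  n_rep <- 400
  for (s in seq_len(n_rep)) {
    kept <- igraph::V(random_node_deletion(big, 0.5, rng_seed = s))$name
    survive[kept] <- survive[kept] + 1
  }
  rate <- survive / n_rep
  # binomial(400, 0.5): +-5 sd band
  expect_true(all(abs(rate - 0.5) < 5 * sqrt(0.25 / n_rep)))
})
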