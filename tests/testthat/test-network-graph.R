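test_that("threshold objects validate their ranges", {
  th <- network_thresholds()
  expect_equal(th$r_min, 0.5)
  expect_equal(th$p_max, 0.1)
  expect_equal(th$n_min, 4L)
  expect_true(th$drop_negative)
  expect_error(network_thresholds(r_min = -0.1), "r_min")
  expect_error(network_thresholds(p_max = 0), "p_max")
  expect_error(network_thresholds(p_max = 1.5), "p_max")
  expect_error(network_thresholds(n_min = 1), "n_min")
})

test_that("edge filtering reproduces the enumerated fixture exactly", {
  edges <- filter_edges(boundary_fixture(), network_thresholds())
  got <- paste(edges$region_a, edges$region_b, sep = "-")
  expect_identical(sort(got),
                   sort(c("ACC-PL", "ACC-IL", "BLA-NRe", "NRe-vCA1")))
  # lexicographic deterministic ordering, smaller code first
  expect_identical(got, sort(got, method = "radix"))
  dropped <- attr(edges, "dropped")
  expect_equal(nrow(dropped) + nrow(edges), 120)
  neg <- dropped[dropped$region_a == "ACC" & dropped$region_b == "RSP", ]
  expect_match(neg$dropped_reason, "negative")

  # n_min = 5 reproduces the strictly-greater-than-4 reading
  strict <- filter_edges(boundary_fixture(),
                         network_thresholds(n_min = 5))
  got5 <- paste(strict$region_a, strict$region_b, sep = "-")
  expect_identical(sort(got5), sort(c("ACC-IL", "BLA-NRe", "NRe-vCA1")))
})

test_that("filtering is idempotent and monotone in thresholds", {
  th <- network_thresholds()
  edges <- filter_edges(boundary_fixture(), th)
  again <- filter_edges(transform(as.data.frame(edges), excluded = FALSE), th)
  expect_equal(as.data.frame(again)[names(edges)], as.data.frame(edges),
               ignore_attr = TRUE)

  set.seed(303)
  for (i in 1:20) {
    tab <- make_pair_table(r = round(runif(120, -1, 1), 3),
                           p = round(runif(120), 3),
                           n_pairs = sample(2:9, 120, replace = TRUE))
    tab$excluded <- tab$n_pairs < 4
    base <- filter_edges(tab, network_thresholds())
    stricter_r <- filter_edges(tab, network_thresholds(r_min = 0.7))
    stricter_p <- filter_edges(tab, network_thresholds(p_max = 0.05))
    key <- function(e) paste(e$region_a, e$region_b)
    expect_true(all(key(stricter_r) %in% key(base)))
    expect_true(all(key(stricter_p) %in% key(base)))
  }
})

test_that("networks carry all 16 nodes, weights and opacity", {
  fold <- make_fold_table("recall", fold = 2)
  edges <- filter_edges(boundary_fixture(), network_thresholds())
  net <- build_network(edges, fold, "recall")
  expect_equal(igraph::vcount(net), 16)
  expect_equal(igraph::ecount(net), 4)
  expect_equal(igraph::V(net)$fold_change, rep(2, 16))
  expect_equal(sort(unique(igraph::V(net)$division)),
               sort(unique(brain_regions()$division)))

  # opacity: linear rescaling of r from [r_min, 1] to [0, 1]
  eattr <- igraph::as_data_frame(net, "edges")
  expect_equal(eattr$opacity, (eattr$r - 0.5) / 0.5, tolerance = 1e-12)
  boundary <- eattr[eattr$r == 0.5, ]
  expect_equal(boundary$opacity, 0)

  # no surviving edges: 16 isolated nodes
  empty <- filter_edges(make_pair_table(r = 0, p = 1), network_thresholds())
  net0 <- build_network(empty, fold, "recall")
  expect_equal(igraph::ecount(net0), 0)
  expect_equal(igraph::vcount(net0), 16)

  # undefined fold changes become weight 1, flagged
  fold_u <- make_fold_table("recall", fold = NA_real_, undefined = TRUE)
  netu <- build_network(empty, fold_u, "recall")
  expect_equal(igraph::V(netu)$fold_change, rep(1, 16))
  expect_true(all(igraph::V(netu)$weight_flagged))

  # home-cage network: all node weights exactly 1
  nethc <- build_network(filter_edges(make_pair_table(), network_thresholds()),
                         make_fold_table("home_cage", fold = 1), "home_cage")
  expect_equal(igraph::V(nethc)$fold_change, rep(1, 16))

  expect_error(build_network(edges, fold[-1, ], "recall"), "lacks region")
})

test_that("degree ranking counts incident edges and reports ties", {
  fold <- make_fold_table("recall")
  empty <- filter_edges(make_pair_table(), network_thresholds())
  rk0 <- degree_ranking(build_network(empty, fold, "recall"))
  expect_true(all(rk0$degree == 0))
  expect_true(all(rk0$rank == 1))
  expect_true(all(rk0$tied))

  # star: NRe connected to 5 regions, nothing else
  tab <- make_pair_table()
  for (sp in c("ACC", "PL", "BLA", "vCA1", "vCA3")) {
    tab <- set_pair(tab, "NRe", sp, r = 0.9, p = 0.001, n_pairs = 6L)
  }
  rk <- degree_ranking(build_network(filter_edges(tab, network_thresholds()),
                                     fold, "recall"))
  expect_equal(rk$region[1], "NRe")
  expect_equal(rk$degree[1], 5)
  expect_equal(rk$rank[1], 1)
  expect_false(rk$tied[1])
  expect_true(all(rk$degree[rk$region %in% c("ACC", "PL", "BLA", "vCA1",
                                             "vCA3")] == 1))
  # lexicographic order inside the degree-1 tie
  tied <- rk$region[rk$degree == 1]
  expect_identical(tied, sort(tied, method = "radix"))
})

test_that("graph exports round-trip through GraphML", {
  fold <- make_fold_table("recall", fold = seq(0.5, 2, length.out = 16))
  edges <- filter_edges(boundary_fixture(), network_thresholds())
  net <- build_network(edges, fold, "recall")
  gml <- tempfile(fileext = ".graphml")
  etsv <- tempfile(fileext = ".tsv")
  ntsv <- tempfile(fileext = ".tsv")
  write_network(net, etsv, ntsv, gml)

  back <- read_network(gml)
  expect_equal(sort(igraph::V(back)$name), sort(igraph::V(net)$name))
  expect_equal(igraph::V(back)$fold_change[order(igraph::V(back)$name)],
               igraph::V(net)$fold_change[order(igraph::V(net)$name)],
               tolerance = 1e-9)
  eb <- igraph::as_data_frame(back, "edges")
  en <- igraph::as_data_frame(net, "edges")
  ord <- function(d) d[order(d$from, d$to), c("from", "to", "r", "p",
                                              "n_pairs", "opacity")]
  expect_equal(ord(eb), ord(en), tolerance = 1e-9, ignore_attr = TRUE)

  nodes <- utils::read.table(ntsv, header = TRUE, sep = "\t")
  expect_equal(nrow(nodes), 16)
  expect_equal(sum(nodes$degree), 2 * igraph::ecount(net))
  etab <- utils::read.table(etsv, header = TRUE, sep = "\t")
  expect_equal(nrow(etab), igraph::ecount(net))
})
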