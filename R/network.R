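#' Edge-filter thresholds for connectivity networks
#'
#' The default thresholds keep only the strongest positive correlations:
#' `r >= 0.5`, two-sided `p <= 0.1`, at least 4 complete pairs, negative
#' correlations never drawn. All three comparisons are inclusive. The
#' pair-count threshold is configurable (`n_min = 5` reproduces the
#' strictly-greater-than-4 reading).
#'
#' @param r_min Minimum correlation coefficient, in `[0, 1]` (default 0.5).
#' @param p_max Maximum p-value, in `(0, 1]` (default 0.1).
#' @param n_min Minimum complete-pair count, `>= 2`, inclusive (default 4).
#' @param drop_negative Drop edges with `r <= 0` (default `TRUE`).
#' @return A validated list of class `"network_thresholds"`.
#' @export
network_thresholds <- function(r_min = 0.5, p_max = 0.1, n_min = 4L,
                               drop_negative = TRUE) {
  stopifnot_scalar_number(r_min, "r_min", lower = 0, upper = 1)
  stopifnot_scalar_number(p_max, "p_max", upper = 1)
  if (p_max <= 0) stop("`p_max` must be in (0, 1]", call. = FALSE)
  stopifnot_scalar_number(n_min, "n_min", lower = 2)
  if (!is.logical(drop_negative) || length(drop_negative) != 1L ||
      is.na(drop_negative)) {
    stop("`drop_negative` must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(r_min = r_min, p_max = p_max, n_min = as.integer(n_min),
         drop_negative = drop_negative),
    class = "network_thresholds"
  )
}

#' Filter correlation pairs into network edges
#'
#' Applies the conjunction of edge criteria to a group's correlation
#' matrix: not excluded upstream, `n_pairs >= n_min`, `p <= p_max`,
#' `r >= r_min`, and `r > 0` when negatives are dropped. Surviving edges
#' are returned in deterministic order (lexicographic by region code, the
#' smaller code first). Dropped pairs are retained in the `"dropped"`
#' attribute with a `dropped_reason` for audit; they carry no weight
#' downstream. An empty edge list is a valid result.
#'
#' @param cm A `correlation_matrix` (or a data frame with columns
#'   `region_a`, `region_b`, `r`, `p`, `n_pairs`, `excluded`).
#' @param thresholds A [network_thresholds()] object.
#' @return Data frame of class `"edge_list"` with columns `group`,
#'   `region_a`, `region_b`, `r`, `p`, `n_pairs`; attributes `thresholds`
#'   and `dropped`.
#' @export
filter_edges <- function(cm, thresholds = network_thresholds()) {
  stopifnot(inherits(thresholds, "network_thresholds"))
  need <- c("region_a", "region_b", "r", "p", "n_pairs", "excluded")
  missing_cols <- setdiff(need, names(cm))
  if (length(missing_cols)) {
    stop("correlation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cm <- as.data.frame(cm)
  if (is.null(cm$group)) cm$group <- NA_character_

  # lexicographic normal form: smaller code first, rows sorted (a, b)
  swap <- cm$region_a > cm$region_b
  tmp <- cm$region_a[swap]
  cm$region_a[swap] <- cm$region_b[swap]
  cm$region_b[swap] <- tmp

  reason <- rep(NA_character_, nrow(cm))
  reason[is.na(reason) & cm$excluded] <- "excluded upstream"
  reason[is.na(reason) & cm$n_pairs < thresholds$n_min] <-
    sprintf("n_pairs < %d", thresholds$n_min)
  reason[is.na(reason) & is.na(cm$r)] <- "undefined correlation"
  reason[is.na(reason) & thresholds$drop_negative & cm$r <= 0] <-
    "negative or zero correlation"
  reason[is.na(reason) & cm$r < thresholds$r_min] <-
    sprintf("r < %s", format(thresholds$r_min))
  reason[is.na(reason) & cm$p > thresholds$p_max] <-
    sprintf("p > %s", format(thresholds$p_max))

  keep <- is.na(reason)
  cols <- c("group", "region_a", "region_b", "r", "p", "n_pairs")
  edges <- cm[keep, cols]
  edges <- edges[order(edges$region_a, edges$region_b, method = "radix"), ]
  rownames(edges) <- NULL
  dropped <- cm[!keep, cols]
  dropped$dropped_reason <- reason[!keep]
  dropped <- dropped[order(dropped$region_a, dropped$region_b,
                           method = "radix"), ]
  rownames(dropped) <- NULL

  structure(edges, class = c("edge_list", "data.frame"),
            thresholds = thresholds, dropped = dropped)
}

#' Build a functional-connectivity network
#'
#' Assembles the thresholded graph for one group: all 16 regions as nodes
#' (isolated nodes included), node weight equal to the group's fold-change
#' over the home-cage baseline (undefined fold changes become weight 1
#' with `weight_flagged = TRUE`), and the filtered correlations as edges.
#' Each edge carries `r`, `p`, `n_pairs` and an `opacity` attribute, the
#' linear rescaling of `r` from `[r_min, 1]` to `[0, 1]` used for line
#' transparency (stronger correlations darker).
#'
#' @param edges An `edge_list` from [filter_edges()].
#' @param fold A fold-change table from [fold_changes()].
#' @param group Group label of the network.
#' @return An `igraph` graph with graph attributes `group` and the applied
#'   thresholds.
#' @export
build_network <- function(edges, fold, group) {
  thresholds <- attr(edges, "thresholds") %||% network_thresholds()
  reg <- brain_regions()
  fc <- fold[fold$group == group, ]
  if (!all(reg$region %in% fc$region)) {
    stop("fold-change table lacks region(s) for group ", group, ": ",
         paste(setdiff(reg$region, fc$region), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(c(edges$region_a, edges$region_b)), fc$region)
  if (length(unknown)) {
    stop("edge references region(s) absent from fold changes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  idx <- match(reg$region, fc$region)
  weight <- fc$fold_change[idx]
  flagged <- fc$undefined[idx] | is.na(weight)
  weight[is.na(weight)] <- 1

  vertices <- data.frame(
    name = reg$region,
    division = reg$division,
    fold_change = weight,
    weight_flagged = flagged,
    stringsAsFactors = FALSE
  )
  edf <- as.data.frame(edges)[, c("region_a", "region_b", "r", "p", "n_pairs")]
  if (nrow(edf)) {
    span <- max(1 - thresholds$r_min, .Machine$double.eps)
    edf$opacity <- pmin(1, pmax(0, (edf$r - thresholds$r_min) / span))
  } else {
    edf$opacity <- numeric(0)
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "group", group)
  g <- igraph::set_graph_attr(g, "r_min", thresholds$r_min)
  g <- igraph::set_graph_attr(g, "p_max", thresholds$p_max)
  g <- igraph::set_graph_attr(g, "n_min", thresholds$n_min)
  g
}

#' Degree ranking of network nodes
#'
#' Number of incident edges per region, sorted by degree descending with
#' lexicographic region order inside ties. Ties are reported explicitly:
#' competition ranking (`rank`) assigns tied nodes the same (smallest)
#' rank, and `tied` marks nodes sharing their degree with another node.
#' The top-ranked node(s) are the network's hub candidates.
#'
#' @param network An `igraph` graph from [build_network()].
#' @return Data frame: `region`, `degree`, `rank`, `tied`.
#' @export
degree_ranking <- function(network) {
  deg <- igraph::degree(network)
  out <- data.frame(region = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$region, method = "radix"), ]
  rownames(out) <- NULL
  out$rank <- as.integer(sapply(out$degree, function(d) {
    1L + sum(out$degree > d) # competition ranking: ties share the top rank
  }))
  out$tied <- duplicated(out$degree) | duplicated(out$degree, fromLast = TRUE)
  out
}

#' Export a network
#'
#' Writes the canonical artifacts of one group's network: an edge-list TSV
#' (`group`, `region_a`, `region_b`, `r`, `p`, `n_pairs`, `opacity`), a
#' node table TSV (`region`, `division`, `fold_change`, `degree`) and a
#' GraphML file.
#'
#' @param network An `igraph` graph from [build_network()].
#' @param edge_path,node_path,graphml_path Output paths (`NULL` skips).
#' @return Invisibly, a character vector of the files written.
#' @export
write_network <- function(network, edge_path = NULL, node_path = NULL,
                          graphml_path = NULL) {
  written <- character()
  group <- igraph::graph_attr(network, "group")
  if (!is.null(edge_path)) {
    edf <- igraph::as_data_frame(network, what = "edges")
    names(edf)[1:2] <- c("region_a", "region_b")
    edf <- cbind(group = group, edf)
    utils::write.table(edf, edge_path, sep = infer_sep(edge_path),
                       quote = FALSE, row.names = FALSE)
    written <- c(written, edge_path)
  }
  if (!is.null(node_path)) {
    vdf <- igraph::as_data_frame(network, what = "vertices")
    names(vdf)[1] <- "region"
    vdf$degree <- as.integer(igraph::degree(network))
    utils::write.table(
      vdf[c("region", "division", "fold_change", "degree")],
      node_path, sep = infer_sep(node_path), quote = FALSE, row.names = FALSE)
    written <- c(written, node_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(network, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}

#' Read a network back from GraphML
#'
#' @param graphml_path Path written by [write_network()].
#' @return An `igraph` graph.
#' @export
read_network <- function(graphml_path) {
  igraph::read_graph(graphml_path, format = "graphml")
}

division_palette <- c(cortex = "#4C72B0", thalamus = "#DD8452",
                      amygdala = "#C44E52", hippocampus = "#55A868")

#' Plot a connectivity network
#'
#' Deterministic rendering of the thresholded network: nodes colored by
#' brain subdivision, node area proportional to fold-change over home
#' cage, edge darkness proportional to the opacity attribute (i.e. to r).
#' The force-directed layout uses a fixed seed, so the picture is
#' reproducible; the edge list, not the figure, is the canonical output.
#'
#' @param network An `igraph` graph from [build_network()].
#' @param file Optional PNG path.
#' @param layout_seed Seed for the layout (default 1).
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_network <- function(network, file = NULL, layout_seed = 1L) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 120)
    on.exit(grDevices::dev.off())
  }
  lay <- with_local_seed(layout_seed,
                         igraph::layout_with_fr(network))
  op <- igraph::V(network)$fold_change
  vcol <- division_palette[igraph::V(network)$division]
  ecol <- if (igraph::ecount(network)) {
    grDevices::gray(1 - igraph::E(network)$opacity)
  } else {
    NULL
  }
  igraph::plot.igraph(
    network, layout = lay,
    vertex.size = 8 * sqrt(pmax(op, 0.25)),
    vertex.color = vcol, vertex.label.color = "black",
    vertex.label.cex = 0.8, edge.color = ecol, edge.width = 3,
    main = paste("Connectivity network:",
                 igraph::graph_attr(network, "group"))
  )
  invisible(file)
}
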