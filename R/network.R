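#' Default mapping from A-group identifiers to structural classes
#'
#' The overview network colours X-group nodes by the structural class of
#' their architecture (A) level: all-alpha in blue, all-beta in red,
#' alpha+beta in yellow, alpha/beta in green, mixed in yellow-green, others
#' in cyan. Colours are categorical attribute strings so renderers choose
#' the palette. The default table covers the numeric A-group codes used by
#' the synthetic benchmark; supply your own named vector for a real
#' classification.
#'
#' @return Named character vector mapping A-group id to class name.
#' @export
default_aclass_map <- function() {
  c("1" = "all-alpha", "2" = "all-beta", "3" = "alpha+beta",
    "4" = "alpha/beta", "5" = "mixed", "6" = "other")
}

.class_colors <- c("all-alpha" = "blue", "all-beta" = "red",
                   "alpha+beta" = "yellow", "alpha/beta" = "green",
                   "mixed" = "yellow-green", "other" = "cyan",
                   "unknown" = "gray")

#' Build the X-group overview network
#'
#' One node per X-group present in the bridge table, coloured by structural
#' class; one edge per unordered X-group pair sharing at least one
#' representative bridging theme. An edge is `solid` when at least one
#' representative pair uses the local (Smith-Waterman) theme alignment with
#' more than 20 aligned residues, `dashed` otherwise. Parallel instances
#' collapse into a single edge carrying a count and the theme ids.
#'
#' @param bridge_table Bridge table data.frame (from [detect_bridges()] or
#'   [read_bridges()]).
#' @param classification Named classification label vector (used to find
#'   the A-group of each X-group).
#' @param aclass_map Named vector mapping A-group id to structural class
#'   (default [default_aclass_map()]); unmapped A-groups are coloured
#'   `gray` with a warning.
#' @return Object of class `theme_network` (level `"overview"`) wrapping an
#'   igraph graph.
#' @export
build_overview <- function(bridge_table, classification,
                           aclass_map = default_aclass_map()) {
  if (nrow(bridge_table) == 0) stop("bridge table is empty")
  xg <- sort(unique(c(bridge_table$xgroup_a, bridge_table$xgroup_b)))
  # A-group of each X-group, via any domain classified into it
  x_of_label <- xgroup_of(classification)
  a_of_label <- agroup_of(classification)
  agrp <- vapply(xg, function(x) {
    hit <- which(x_of_label == x)
    if (length(hit)) a_of_label[hit[1]] else NA_character_
  }, "")
  cls <- unname(aclass_map[agrp])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("X-group(s) with unknown structural class coloured gray: ",
            paste(xg[unknown], collapse = ", "))
    cls[unknown] <- "unknown"
  }
  nodes <- data.frame(name = xg, label = xg, aclass = agrp,
                      class_group = cls,
                      color_group = unname(.class_colors[cls]),
                      stringsAsFactors = FALSE)
  ekey <- apply(cbind(bridge_table$xgroup_a, bridge_table$xgroup_b), 1,
                function(r) paste(sort(r), collapse = "|"))
  solid_cand <- bridge_table$mode == "local" & bridge_table$n_aligned > 20
  agg <- lapply(sort(unique(ekey)), function(k) {
    idx <- which(ekey == k)
    ends <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(from = ends[1], to = ends[2],
               style = if (any(solid_cand[idx])) "solid" else "dashed",
               count = length(idx),
               themes = paste(sort(unique(bridge_table$theme_id[idx])),
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, agg)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, level = "overview"), class = "theme_network")
}

#' Build the nested (domain-level) network for one X-group pair
#'
#' A bipartite graph whose nodes are the domains of the two X-groups and
#' whose edges connect domain pairs sharing a theme variation; edges carry
#' the alignment statistics, nodes carry their full classification with the
#' below-X levels (H.T.F) as a border attribute.
#'
#' @param bridge_table Bridge table data.frame.
#' @param xgroup_pair Character vector of the two X-group ids.
#' @param classification Named classification label vector.
#' @return Object of class `theme_network` (level `"nested"`).
#' @export
build_nested <- function(bridge_table, xgroup_pair, classification) {
  stopifnot(length(xgroup_pair) == 2)
  pair <- sort(as.character(xgroup_pair))
  ekey <- apply(cbind(bridge_table$xgroup_a, bridge_table$xgroup_b), 1,
                function(r) paste(sort(r), collapse = "|"))
  idx <- which(ekey == paste(pair, collapse = "|"))
  if (length(idx) == 0) {
    stop("X-group pair ", paste(pair, collapse = "/"),
         " not present in the bridge table; available pairs: ",
         paste(sort(unique(ekey)), collapse = ", "))
  }
  sub <- bridge_table[idx, , drop = FALSE]
  doms <- sort(unique(c(sub$domain_a, sub$domain_b)))
  xg <- xgroup_of(classification[doms])
  label <- unname(classification[doms])
  htf <- vapply(strsplit(label, ".", fixed = TRUE), function(f)
    paste(f[-(1:2)], collapse = "."), "")
  nodes <- data.frame(name = doms, xgroup = unname(xg),
                      classification = label, border = htf,
                      side = ifelse(xg == pair[1], 1L, 2L),
                      type = xg == pair[1],
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = sub$domain_a, to = sub$domain_b,
                      theme_id = sub$theme_id, mode = sub$mode,
                      score = sub$score, n_aligned = sub$n_aligned,
                      pct_identity = sub$pct_identity,
                      pct_similarity = sub$pct_similarity,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, edges$theme_id), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, level = "nested", xgroup_pair = pair),
            class = "theme_network")
}

#' @export
print.theme_network <- function(x, ...) {
  cat("<theme_network> level=", x$level, ": ",
      igraph::vcount(x$graph), " node(s), ",
      igraph::ecount(x$graph), " edge(s)\n", sep = "")
  invisible(x)
}

#' Export a theme network to GraphML or SIF
#'
#' GraphML preserves all node and edge attributes. SIF carries the topology
#' (`node1 <TAB> theme <TAB> node2`) with node and edge attributes written
#' to a sidecar TSV at `<path>.attrs.tsv`. Node and edge ordering is
#' deterministic (sorted ids), so repeated exports are byte-identical.
#'
#' @param network A `theme_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return The output path, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  g <- network$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    lines <- paste(el[, 1], "theme", el[, 2], sep = "\t")
    writeLines(lines, path)
    ed <- igraph::as_data_frame(g, what = "edges")
    nd <- igraph::as_data_frame(g, what = "vertices")
    attr_path <- paste0(path, ".attrs.tsv")
    con <- file(attr_path, "w")
    writeLines("# edge attributes", con)
    write.table(ed, con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines("# node attributes", con)
    write.table(nd, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}
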