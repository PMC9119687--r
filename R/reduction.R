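#' Merge eligibility of two adjacent nodes
#'
#' Two neighboring nodes may be merged during graph reduction when both
#' are non-kinase proteins, share the same differential-expression
#' category, and belong to the same biological-process cluster.  Nodes
#' without a cluster assignment are treated as their own singleton cluster
#' and are therefore never eligible.
#'
#' @param g A `cancer_graph` of original (non-virtual) nodes.
#' @param clusters Tibble `gene_id`, `cluster`.
#' @param u,v Gene ids of two adjacent nodes (vectorised).
#' @return Logical vector.
#' @export
merge_eligible <- function(g, clusters, u, v) {
  nodes <- g$nodes
  iu <- match(u, nodes$gene_id)
  iv <- match(v, nodes$gene_id)
  if (anyNA(iu) || anyNA(iv)) stop("unknown node id", call. = FALSE)
  cl <- node_clusters(nodes$gene_id, clusters)
  !nodes$is_kinase[iu] & !nodes$is_kinase[iv] &
    nodes$dge[iu] == nodes$dge[iv] & cl[iu] == cl[iv] &
    !startsWith(cl[iu], ".singleton.")
}

# Cluster label per node; unassigned nodes get a unique singleton label.
node_clusters <- function(gene_ids, clusters) {
  cl <- as.character(clusters$cluster[match(gene_ids, clusters$gene_id)])
  miss <- is.na(cl)
  cl[miss] <- paste0(".singleton.", gene_ids[miss])
  cl
}

#' Partition the graph into merge groups
#'
#' The merge groups are the connected components of the eligibility
#' subgraph: nodes are the graph's non-kinase proteins and edges are the
#' adjacent pairs for which [merge_eligible()] holds.  Kinases and
#' ineligible nodes form singleton groups.  The result is maximal and
#' deterministic.
#'
#' @inheritParams merge_eligible
#' @return Tibble `gene_id`, `group` (integer id; groups numbered in node
#'   order).
#' @export
find_merge_groups <- function(g, clusters) {
  nodes <- g$nodes
  ids <- nodes$gene_id
  cl <- node_clusters(ids, clusters)
  e <- g$edges
  if (nrow(e) > 0L) {
    iu <- match(e$from, ids)
    iv <- match(e$to, ids)
    elig <- !nodes$is_kinase[iu] & !nodes$is_kinase[iv] &
      !nodes$is_virtual[iu] & !nodes$is_virtual[iv] &
      nodes$dge[iu] == nodes$dge[iv] & cl[iu] == cl[iv]
    e <- e[elig, ]
  }
  ig <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(ig)$membership[ids]
  tibble::tibble(gene_id = ids, group = as.integer(comp))
}

#' Merge one group of nodes into a virtual node
#'
#' Produces the virtual node replacing `members` and the rewired incident
#' edges.  Numeric annotations (DGA scores, pIC50) are the median over the
#' group, with absent values entering the median as 0 (matching the
#' feature-encoding convention); a resulting 0 is stored as absent.  The
#' shared DGE category is carried over.  Edges from the group to each
#' outside node are collapsed into a single edge weighted by the median of
#' the collapsed weights; within-group edges are dropped.  Medians of
#' even-sized sets are the mean of the two middle values.
#'
#' @param g A `cancer_graph`.
#' @param members Character vector of gene ids, length >= 2, all
#'   non-kinase, sharing one DGE category.
#' @param virtual_id Identifier for the new node.
#' @return List with `node` (one-row tibble) and `edges` (tibble `from` =
#'   `virtual_id`, `to` = outside node, `weight`).
#' @export
merge_group <- function(g, members, virtual_id = paste(members, collapse = "+")) {
  stopifnot(length(members) >= 2L)
  nodes <- g$nodes[match(members, g$nodes$gene_id), ]
  if (anyNA(nodes$gene_id)) stop("unknown member id", call. = FALSE)
  if (any(nodes$is_kinase)) {
    stop("merge group must not contain kinase nodes", call. = FALSE)
  }
  if (length(unique(nodes$dge)) != 1L) {
    stop("merge group must share one DGE category", call. = FALSE)
  }
  med0 <- function(v) {
    m <- stats::median(ifelse(is.na(v), 0, v))
    if (m == 0) NA_real_ else m
  }
  node <- tibble::tibble(
    gene_id = virtual_id, is_kinase = FALSE, dge = nodes$dge[1],
    dga_disease = med0(nodes$dga_disease),
    dga_disgenet = med0(nodes$dga_disgenet),
    pic50 = med0(nodes$pic50), is_virtual = TRUE,
    members = list(unlist(nodes$members, use.names = FALSE))
  )
  e <- g$edges
  inc <- (e$from %in% members) | (e$to %in% members)
  e <- e[inc, ]
  internal <- (e$from %in% members) & (e$to %in% members)
  e <- e[!internal, ]
  outside <- ifelse(e$from %in% members, e$to, e$from)
  edges <- tibble::tibble(from = virtual_id, to = outside,
                          weight = e$weight) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = stats::median(.data$weight), .groups = "drop")
  list(node = node, edges = edges)
}

#' Reduce a cancer graph by merging biologically coherent node groups
#'
#' One pass of knowledge-driven coarsening: [find_merge_groups()]
#' partitions the nodes, every non-singleton group is replaced by a single
#' virtual node (annotated with group medians, see [merge_group()]), and
#' edges incident to a group are collapsed to median-weight edges between
#' the surviving nodes.  Virtual nodes are never re-merged, so the
#' operation is idempotent.  On cancer-specific networks — where only
#' about 2% of proteins are kinases and kinases are excluded from merging
#' — this step shrinks the graph substantially while strictly increasing
#' the kinase-node fraction whenever any merge occurs.
#'
#' @inheritParams merge_eligible
#' @return List with `graph` (the reduced `cancer_graph`; label, tissue
#'   and instance identifiers unchanged; feature matrix recomputed) and
#'   `map` (a `reduction_map`: the group partition plus before/after
#'   statistics).
#' @export
reduce_graph <- function(g, clusters) {
  groups <- find_merge_groups(g, clusters)
  sizes <- table(groups$group)
  non_singleton <- as.integer(names(sizes)[sizes > 1L])

  ids <- g$nodes$gene_id
  new_id <- ids
  virtual_ids <- character(0)
  for (k in seq_along(non_singleton)) {
    grp <- non_singleton[k]
    mem <- groups$gene_id[groups$group == grp]
    vid <- paste0("virtual_", k, ":", paste(mem, collapse = "+"))
    virtual_ids[k] <- vid
    new_id[ids %in% mem] <- vid
  }
  map_to <- stats::setNames(new_id, ids)

  merged <- vector("list", length(non_singleton))
  for (k in seq_along(non_singleton)) {
    mem <- groups$gene_id[groups$group == non_singleton[k]]
    merged[[k]] <- merge_group(g, mem, virtual_ids[k])$node
  }
  keep <- g$nodes[!ids %in% groups$gene_id[groups$group %in% non_singleton], ]
  nodes <- dplyr::bind_rows(keep, dplyr::bind_rows(merged))

  e <- g$edges
  if (nrow(e) > 0L) {
    ef <- unname(map_to[e$from])
    et <- unname(map_to[e$to])
    keep_e <- ef != et
    edges <- tibble::tibble(from = pmin(ef[keep_e], et[keep_e]),
                            to = pmax(ef[keep_e], et[keep_e]),
                            weight = e$weight[keep_e]) |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(weight = stats::median(.data$weight),
                       .groups = "drop")
  } else {
    edges <- e
  }

  reduced <- cancer_graph(nodes, edges, cell_line = g$cell_line,
                          drug = g$drug, tissue = g$tissue,
                          label = g$label, validate = FALSE)
  map <- structure(
    list(groups = groups, assignment = map_to,
         stats = tibble::tibble(
           nodes_before = nrow(g$nodes), nodes_after = nrow(reduced$nodes),
           edges_before = nrow(g$edges), edges_after = nrow(reduced$edges),
           kinase_fraction_before = mean(g$nodes$is_kinase),
           kinase_fraction_after = mean(reduced$nodes$is_kinase))),
    class = "reduction_map")
  list(graph = reduced, map = map)
}

#' Summarise a graph reduction
#'
#' @param map A `reduction_map` from [reduce_graph()].
#' @return One-row tibble with node/edge counts before and after, percent
#'   reductions, and kinase-node fractions before and after.
#' @export
reduction_stats <- function(map) {
  s <- map$stats
  dplyr::mutate(
    s,
    node_reduction_pct = 100 * (1 - .data$nodes_after / .data$nodes_before),
    edge_reduction_pct = if (s$edges_before > 0)
      100 * (1 - s$edges_after / s$edges_before) else 0
  )
}

#' @export
print.reduction_map <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<reduction_map> %d -> %d nodes, %d -> %d edges, kinase fraction %.3f -> %.3f\n",
              s$nodes_before, s$nodes_after, s$edges_before, s$edges_after,
              s$kinase_fraction_before, s$kinase_fraction_after))
  invisible(x)
}
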