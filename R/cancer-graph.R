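#' Construct a cancer-specific (cell line, drug) graph
#'
#' A `cancer_graph` holds one annotated protein-protein interaction
#' subnetwork for a single cell line treated with a single drug.  Nodes are
#' proteins (or, after reduction, virtual nodes standing for a merged group
#' of proteins) annotated with differential expression category, disease
#' association scores, and the drug's pIC50 where the protein is an
#' inhibited kinase.  Edges are undirected, carry the STRING-style
#' confidence score (0-1000) as weight, and contain no self-loops or
#' duplicates.
#'
#' @param nodes Tibble with columns `gene_id`, `is_kinase` (logical), `dge`
#'   (one of `"up"`, `"down"`, `"normal"`), `dga_disease` (score in
#'   \[1, 10\] or `NA`), `dga_disgenet` (score in \[0.01, 1\] or `NA`),
#'   `pic50` (`NA` unless the drug inhibits this kinase at or above the
#'   retained threshold), `is_virtual` (logical), and `members`
#'   (list-column of original gene ids; singleton for non-virtual nodes).
#'   Missing annotation columns are filled with defaults.
#' @param edges Tibble with columns `from`, `to` (gene ids) and `weight`.
#' @param cell_line,drug Identifiers of the instance.
#' @param tissue Tissue-of-origin group label used for grouped
#'   cross-validation.
#' @param label Integer 1 (cytotoxic response, positive class), 0
#'   (cytostatic, negative class), or `NA` for unlabeled graphs.
#' @param validate Run [validate_cancer_graph()] (default `TRUE`).
#' @return A `cancer_graph` object with the node feature matrix `X`
#'   computed by [encode_features()].
#' @export
cancer_graph <- function(nodes, edges, cell_line = NA_character_,
                         drug = NA_character_, tissue = NA_character_,
                         label = NA_integer_, validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  if (!"is_kinase" %in% names(nodes)) nodes$is_kinase <- FALSE
  if (!"dge" %in% names(nodes)) nodes$dge <- "normal"
  if (!"dga_disease" %in% names(nodes)) nodes$dga_disease <- NA_real_
  if (!"dga_disgenet" %in% names(nodes)) nodes$dga_disgenet <- NA_real_
  if (!"pic50" %in% names(nodes)) nodes$pic50 <- NA_real_
  if (!"is_virtual" %in% names(nodes)) nodes$is_virtual <- FALSE
  if (!"members" %in% names(nodes)) nodes$members <- as.list(nodes$gene_id)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric())
  }
  g <- structure(
    list(nodes = nodes, edges = edges,
         cell_line = cell_line, drug = drug, tissue = tissue,
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         X = NULL),
    class = "cancer_graph"
  )
  g$X <- encode_features(nodes)
  if (validate) validate_cancer_graph(g)
  g
}

#' Validate a cancer graph
#'
#' Checks the structural invariants: unique node ids; edges reference
#' known nodes, are free of self-loops and (undirected) duplicates; score
#' ranges; virtual nodes have more than one member and are never kinases;
#' the feature matrix has one row per node.
#'
#' @param g A `cancer_graph`.
#' @param min_confidence If non-`NULL`, additionally require every edge
#'   weight to be at least this value.
#' @return `g`, invisibly.  Errors on the first violated invariant.
#' @export
validate_cancer_graph <- function(g, min_confidence = NULL) {
  nodes <- g$nodes
  edges <- g$edges
  if (anyDuplicated(nodes$gene_id)) stop("duplicate node ids", call. = FALSE)
  if (!all(nodes$dge %in% c("up", "down", "normal"))) {
    stop("unknown DGE category", call. = FALSE)
  }
  # Range checks apply to original nodes; virtual nodes carry group
  # medians taken with absent-as-0, which may fall below the raw minima.
  orig <- !nodes$is_virtual
  dd <- nodes$dga_disease[orig]
  if (any(!is.na(dd) & (dd < 1 | dd > 10))) {
    stop("dga_disease outside [1,10]", call. = FALSE)
  }
  dn <- nodes$dga_disgenet[orig]
  if (any(!is.na(dn) & (dn < 0.01 | dn > 1))) {
    stop("dga_disgenet outside [0.01,1]", call. = FALSE)
  }
  n_members <- lengths(nodes$members)
  if (!all(nodes$is_virtual == (n_members > 1L))) {
    stop("is_virtual must hold exactly for nodes with >1 member",
         call. = FALSE)
  }
  if (any(nodes$is_virtual & nodes$is_kinase)) {
    stop("virtual nodes can never be kinases", call. = FALSE)
  }
  if (nrow(edges) > 0L) {
    if (any(edges$from == edges$to)) stop("self-loop edge", call. = FALSE)
    ok <- edges$from %in% nodes$gene_id & edges$to %in% nodes$gene_id
    if (!all(ok)) stop("edge references unknown node", call. = FALSE)
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("parallel edges", call. = FALSE)
    if (!is.null(min_confidence) && any(edges$weight < min_confidence)) {
      stop("edge weight below the confidence threshold", call. = FALSE)
    }
  }
  if (!is.null(g$X) && nrow(g$X) != nrow(nodes)) {
    stop("feature matrix row count differs from node count", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.cancer_graph <- function(x, ...) {
  cat(sprintf("<cancer_graph> %s + %s (%s)\n",
              x$cell_line, x$drug, x$tissue))
  cat(sprintf("  %d nodes (%d kinase, %d virtual), %d edges, label = %s\n",
              nrow(x$nodes), sum(x$nodes$is_kinase),
              sum(x$nodes$is_virtual), nrow(x$edges),
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Encode node annotations as the fixed 7-dimensional feature matrix
#'
#' Each node is represented by a length-7 vector:
#' a one-hot encoding of the DGE category (`up`, `down`, `normal`), the
#' DISEASE association score divided by 10, the DisGeNET score as-is
#' (both already in \[0, 1\] after scaling), the pIC50 divided by 10, and
#' the kinase indicator.  Absent annotations contribute 0 — an
#' unannotated, normally expressed non-kinase carries no information
#' beyond its `normal` bit, which also guarantees that no feature row is
#' all-zero (keeping cosine similarities in the attention layer
#' well-defined).
#'
#' @param nodes A node tibble (see [cancer_graph()]) or a `cancer_graph`.
#' @return Numeric matrix with one row per node and columns
#'   `dge_up`, `dge_down`, `dge_normal`, `dga_disease`, `dga_disgenet`,
#'   `pic50`, `is_kinase`.
#' @export
encode_features <- function(nodes) {
  if (inherits(nodes, "cancer_graph")) nodes <- nodes$nodes
  dge <- nodes$dge
  bad <- setdiff(unique(dge), c("up", "down", "normal"))
  if (length(bad) > 0L) {
    stop("unknown DGE category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  zero_na <- function(v) ifelse(is.na(v), 0, v)
  X <- cbind(
    dge_up       = as.numeric(dge == "up"),
    dge_down     = as.numeric(dge == "down"),
    dge_normal   = as.numeric(dge == "normal"),
    dga_disease  = zero_na(nodes$dga_disease) / 10,
    dga_disgenet = zero_na(nodes$dga_disgenet),
    pic50        = zero_na(nodes$pic50) / 10,
    is_kinase    = as.numeric(nodes$is_kinase)
  )
  rownames(X) <- nodes$gene_id
  X
}

graph_format_version <- "1.0"

#' Write a cancer graph to a plain-text archive
#'
#' The archive is a directory holding three diffable files: `nodes.tsv`
#' (annotations, with the `members` list serialised as a comma-joined
#' string), `edges.tsv`, and `meta.json` (instance identifiers, tissue,
#' label, and a format version).  [read_graph()] restores the graph
#' losslessly.
#'
#' @param g A validated `cancer_graph`.
#' @param path Directory to write (created, or overwritten if it already
#'   holds an archive).
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  validate_cancer_graph(g)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  nodes <- g$nodes
  nodes$members <- vapply(nodes$members, paste, character(1), collapse = ",")
  readr::write_tsv(nodes, file.path(path, "nodes.tsv"), progress = FALSE)
  readr::write_tsv(g$edges, file.path(path, "edges.tsv"), progress = FALSE)
  meta <- list(format_version = graph_format_version,
               cell_line = g$cell_line, drug = g$drug, tissue = g$tissue,
               label = g$label)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA)
  invisible(path)
}

#' Read a cancer graph archive written by [write_graph()]
#'
#' @param path Archive directory.
#' @return The restored `cancer_graph`.
#' @export
read_graph <- function(path) {
  files <- file.path(path, c("nodes.tsv", "edges.tsv", "meta.json"))
  if (!dir.exists(path) || !all(file.exists(files))) {
    stop("not a graph archive (missing files): ", path, call. = FALSE)
  }
  meta <- tryCatch(jsonlite::read_json(files[3]),
                   error = function(e) stop("corrupt graph metadata: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  if (is.null(meta$format_version) ||
      !identical(meta$format_version, graph_format_version)) {
    stop("graph archive format version mismatch (expected ",
         graph_format_version, ")", call. = FALSE)
  }
  col_spec <- readr::cols(
    gene_id = readr::col_character(), is_kinase = readr::col_logical(),
    dge = readr::col_character(), dga_disease = readr::col_double(),
    dga_disgenet = readr::col_double(), pic50 = readr::col_double(),
    is_virtual = readr::col_logical(), members = readr::col_character()
  )
  nodes <- tryCatch(
    suppressWarnings(readr::read_tsv(files[1], col_types = col_spec,
                                     progress = FALSE)),
    error = function(e) stop("corrupt node table: ", conditionMessage(e),
                             call. = FALSE))
  required <- c("gene_id", "is_kinase", "dge", "dga_disease",
                "dga_disgenet", "pic50", "is_virtual", "members")
  if (!all(required %in% names(nodes))) {
    stop("graph archive node table is truncated or malformed",
         call. = FALSE)
  }
  nodes$members <- strsplit(nodes$members, ",", fixed = TRUE)
  edges <- readr::read_tsv(
    files[2],
    col_types = readr::cols(from = readr::col_character(),
                            to = readr::col_character(),
                            weight = readr::col_double()),
    progress = FALSE)
  cancer_graph(nodes, edges,
               cell_line = meta$cell_line %||% NA_character_,
               drug = meta$drug %||% NA_character_,
               tissue = meta$tissue %||% NA_character_,
               label = if (is.null(meta$label)) NA_integer_
                       else as.integer(meta$label))
}

#' Adjacency matrix of a cancer graph
#'
#' @param g A `cancer_graph`.
#' @param weighted Return confidence scores instead of 0/1.
#' @return Symmetric numeric matrix in node order, zero diagonal.
#' @export
graph_adjacency <- function(g, weighted = FALSE) {
  ids <- g$nodes$gene_id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(g$edges) > 0L) {
    i <- match(g$edges$from, ids)
    j <- match(g$edges$to, ids)
    w <- if (weighted) g$edges$weight else 1
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}
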