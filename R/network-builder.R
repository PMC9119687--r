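#' Configuration for graph assembly
#'
#' @param min_confidence Inclusive PPI confidence threshold; edges scoring
#'   at least this value are retained (STRING convention, default 500).
#' @param min_pic50 Minimum pIC50 for a kinase-inhibition annotation to be
#'   kept.  The default 6.3 corresponds to an IC50 of 500 nM
#'   (\eqn{-\log_{10}(500\times 10^{-9}) \approx 6.3}).
#' @param disease_mapping Optional tibble with columns `cell_line` and
#'   `disease` mapping each cell line to the disease term used for DGA
#'   lookup.  When `NULL`, the cell-line identifier itself is used as the
#'   disease key.
#' @return A `build_config` list.
#' @export
build_config <- function(min_confidence = 500, min_pic50 = 6.3,
                         disease_mapping = NULL) {
  stopifnot(min_confidence >= 0, min_pic50 > 0)
  if (!is.null(disease_mapping)) {
    disease_mapping <- tibble::as_tibble(disease_mapping)
    stopifnot(all(c("cell_line", "disease") %in% names(disease_mapping)))
  }
  structure(list(min_confidence = min_confidence, min_pic50 = min_pic50,
                 disease_mapping = disease_mapping),
            class = "build_config")
}

#' pIC50 equivalent of an IC50 concentration
#'
#' Converts a half-maximal inhibitory concentration to the negative log10
#' molar scale used to filter kinase-inhibition annotations; 500 nM maps
#' to about 6.3.
#'
#' @param ic50_nM IC50 in nanomolar.
#' @return pIC50 (\eqn{-\log_{10}} of the molar concentration).
#' @export
pic50_from_ic50_nM <- function(ic50_nM) {
  -log10(ic50_nM * 1e-9)
}

#' Build the confidence-filtered PPI network
#'
#' Keeps every interaction whose confidence score is at least
#' `min_confidence` (inclusive: a score of exactly 500 passes the default
#' filter), drops self-pairs, and collapses duplicate or reversed pairs
#' keeping the maximum score.
#'
#' @param ppi_edges Tibble with columns `protein_a`, `protein_b`, `score`.
#' @param min_confidence Inclusive threshold (default 500).
#' @return Tibble `from`, `to`, `weight` with `from < to` lexicographically.
#' @export
build_ppi_network <- function(ppi_edges, min_confidence = 500) {
  e <- tibble::as_tibble(ppi_edges)
  e <- e[e$protein_a != e$protein_b & e$score >= min_confidence, ]
  if (nrow(e) == 0L) {
    stop("no PPI edge passes the confidence threshold ", min_confidence,
         "; network is empty", call. = FALSE)
  }
  tibble::tibble(from = pmin(e$protein_a, e$protein_b),
                 to = pmax(e$protein_a, e$protein_b),
                 weight = e$score) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop")
}

#' Label (cell line, drug) instances from growth-rate records
#'
#' Applies the sign rule for growth-rate inhibition: a negative maximal GR
#' value means the drug kills cells faster than they divide (cytotoxic,
#' positive class 1); a positive or zero value means growth arrest at most
#' (cytostatic, negative class 0).  Records are rejected when GR50 is
#' infinite or when a (cell line, drug) pair carries multiple GR50
#' measurements.
#'
#' @param gr Tibble with columns `cell_line`, `drug`, `gr50`, `gr_max`,
#'   `tissue`.
#' @return Tibble with one row per input record: the input columns plus
#'   `accepted` (logical), `label` (1/0, `NA` when rejected), and `reason`
#'   (`NA` when accepted).
#' @export
label_from_gr <- function(gr) {
  gr <- tibble::as_tibble(gr)
  if (nrow(gr) == 0L) {
    return(dplyr::mutate(gr, accepted = logical(0), label = integer(0),
                         reason = character(0)))
  }
  if (!is.numeric(gr$gr_max) || anyNA(gr$gr_max)) {
    stop("gr_max must be numeric and non-missing", call. = FALSE)
  }
  key <- paste(gr$cell_line, gr$drug, sep = "\r")
  multi <- key %in% key[duplicated(key)]
  inf50 <- is.infinite(gr$gr50)
  reason <- dplyr::case_when(
    multi ~ "multiple GR50 values for this cell line-drug pair",
    inf50 ~ "infinite GR50",
    !is.finite(gr$gr_max) ~ "non-finite GRmax",
    TRUE ~ NA_character_
  )
  accepted <- is.na(reason)
  gr$accepted <- accepted
  gr$label <- ifelse(accepted, as.integer(gr$gr_max < 0), NA_integer_)
  gr$reason <- reason
  gr
}

#' Assemble the annotated graph for one (cell line, drug) combination
#'
#' Annotates every protein in the confidence-filtered PPI network with the
#' cell line's DGE category (defaulting to `normal` when unreported), the
#' DGA scores of the mapped disease term (DISEASE and DisGeNET kept as
#' separate annotations), and the drug's pIC50 when it meets
#' `config$min_pic50` (taking the maximum over multiple measurements for
#' one kinase-drug pair).  Kinase status is taken from membership in the
#' KIP table (a protein with any recorded inhibition profile is a kinase).
#' The graph label comes from the accepted GR record.
#'
#' @param cell_line,drug Instance identifiers.
#' @param tables Validated [read_omics_tables()] output.
#' @param config A [build_config()].
#' @param ppi Optional pre-built PPI edge tibble from
#'   [build_ppi_network()]; computed from `tables$ppi` when `NULL`.
#' @return A labeled `cancer_graph`.
#' @export
build_instance <- function(cell_line, drug, tables, config = build_config(),
                           ppi = NULL) {
  gr <- label_from_gr(tables$gr)
  rec <- gr[gr$cell_line == cell_line & gr$drug == drug, ]
  if (nrow(rec) == 0L || !any(rec$accepted)) {
    stop("no accepted growth-rate record for ", cell_line, " + ", drug,
         call. = FALSE)
  }
  rec <- rec[rec$accepted, ][1, ]
  if (is.null(ppi)) {
    ppi <- build_ppi_network(tables$ppi, config$min_confidence)
  }
  nodes <- annotate_nodes(unique(c(ppi$from, ppi$to)), cell_line, drug,
                          tables, config)
  cancer_graph(nodes, ppi, cell_line = cell_line, drug = drug,
               tissue = rec$tissue, label = rec$label)
}

annotate_nodes <- function(gene_ids, cell_line, drug, tables, config) {
  nodes <- tibble::tibble(gene_id = sort(gene_ids))

  kinases <- unique(tables$kip$gene_id)
  nodes$is_kinase <- nodes$gene_id %in% kinases

  dge <- tables$dge[tables$dge$cell_line == cell_line, c("gene_id", "category")]
  nodes$dge <- dge$category[match(nodes$gene_id, dge$gene_id)]
  nodes$dge[is.na(nodes$dge)] <- "normal"

  disease <- cell_line
  if (!is.null(config$disease_mapping)) {
    m <- config$disease_mapping
    hit <- match(cell_line, m$cell_line)
    if (!is.na(hit)) disease <- m$disease[hit]
  }
  dga <- tables$dga[tables$dga$disease == disease, ]
  dis <- dga[dga$source == "DISEASE", ]
  dgn <- dga[dga$source == "DisGeNET", ]
  nodes$dga_disease <- dis$score[match(nodes$gene_id, dis$gene_id)]
  nodes$dga_disgenet <- dgn$score[match(nodes$gene_id, dgn$gene_id)]

  kip <- tables$kip[tables$kip$drug == drug &
                      tables$kip$pic50 >= config$min_pic50, ]
  if (nrow(kip) > 0L) {
    kip <- dplyr::summarise(dplyr::group_by(kip, .data$gene_id),
                            pic50 = max(.data$pic50), .groups = "drop")
  }
  nodes$pic50 <- kip$pic50[match(nodes$gene_id, kip$gene_id)]
  nodes$pic50[!nodes$is_kinase] <- NA_real_

  nodes$is_virtual <- FALSE
  nodes$members <- as.list(nodes$gene_id)
  nodes
}

#' Build every accepted (cell line, drug) graph from the omics tables
#'
#' Applies [label_from_gr()] to the GR table, builds one annotated graph
#' per accepted record via [build_instance()], and reports every rejected
#' record with the rule that rejected it.
#'
#' @param tables Validated [read_omics_tables()] output.
#' @param config A [build_config()].
#' @param quiet Suppress the progress message.
#' @return List with elements `graphs` (list of `cancer_graph`) and
#'   `rejections` (tibble `cell_line`, `drug`, `reason`).
#' @export
build_dataset <- function(tables, config = build_config(), quiet = TRUE) {
  gr <- label_from_gr(tables$gr)
  rejections <- gr[!gr$accepted, c("cell_line", "drug", "reason")]
  rejections <- dplyr::distinct(rejections)
  accepted <- gr[gr$accepted, ]
  if (nrow(accepted) == 0L) {
    return(list(graphs = list(), rejections = rejections))
  }
  ppi <- build_ppi_network(tables$ppi, config$min_confidence)
  graphs <- vector("list", nrow(accepted))
  for (k in seq_len(nrow(accepted))) {
    nodes <- annotate_nodes(unique(c(ppi$from, ppi$to)),
                            accepted$cell_line[k], accepted$drug[k],
                            tables, config)
    graphs[[k]] <- cancer_graph(nodes, ppi,
                                cell_line = accepted$cell_line[k],
                                drug = accepted$drug[k],
                                tissue = accepted$tissue[k],
                                label = accepted$label[k],
                                validate = FALSE)
  }
  if (!quiet) {
    message(sprintf("built %d graphs (%d positive, %d negative), %d rejections",
                    length(graphs), sum(accepted$label == 1L),
                    sum(accepted$label == 0L), nrow(rejections)))
  }
  list(graphs = graphs, rejections = rejections)
}
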