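#' Column schemas for the six omics input tables
#'
#' The pipeline consumes six tab-separated tables: a STRING-style
#' protein-protein interaction (PPI) edge list, a categorical differential
#' gene expression (DGE) table, a disease-gene association (DGA) score
#' table, a kinase-inhibitor profiling (KIP) table of pIC50 values, a
#' growth-rate (GR) response table, and a gene-to-biological-process
#' cluster table.  `omics_schemas()` returns the declared column names and
#' types for each, which `read_omics_tables()` enforces.
#'
#' @return A named list with one character vector of column names per table
#'   (`ppi`, `dge`, `dga`, `kip`, `gr`, `go_clusters`).
#' @export
omics_schemas <- function() {
  list(
    ppi         = c("protein_a", "protein_b", "score"),
    dge         = c("gene_id", "cell_line", "category"),
    dga         = c("disease", "gene_id", "score", "source"),
    kip         = c("drug", "gene_id", "pic50"),
    gr          = c("cell_line", "drug", "gr50", "gr_max", "tissue"),
    go_clusters = c("gene_id", "cluster")
  )
}

#' Read and validate the six omics input tables
#'
#' Reads the TSV files named in `paths`, checks each header against
#' [omics_schemas()], and validates value ranges: PPI confidence scores in
#' \[0, 1000\], DGE categories in \{up, down, normal\}, DISEASE-source DGA
#' scores in \[1, 10\], DisGeNET-source DGA scores in \[0.01, 1\], and
#' non-empty identifiers throughout.  Validation failures are reported with
#' the offending table, column, and row index.
#'
#' @param paths Named list or character vector with elements `ppi`, `dge`,
#'   `dga`, `kip`, `gr`, `go_clusters` giving file locations.  Any table
#'   may instead be supplied directly as a data frame.
#' @return An `omics_tables` object: a named list of validated tibbles.
#' @export
read_omics_tables <- function(paths) {
  schemas <- omics_schemas()
  missing <- setdiff(names(schemas), names(paths))
  if (length(missing) > 0L) {
    stop("missing input table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tables <- lapply(names(schemas), function(nm) {
    x <- paths[[nm]]
    tbl <- if (is.data.frame(x)) {
      tibble::as_tibble(x)
    } else {
      if (!file.exists(x)) stop("file not found for table '", nm, "': ", x,
                                call. = FALSE)
      readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
    }
    check_schema(tbl, schemas[[nm]], nm)
    tbl[schemas[[nm]]]
  })
  names(tables) <- names(schemas)
  out <- validate_omics_tables(tables)
  if (nrow(out$gr) == 0L) {
    warning("growth-rate table is empty: no (cell line, drug) instances",
            call. = FALSE)
  }
  out
}

check_schema <- function(tbl, cols, name) {
  absent <- setdiff(cols, names(tbl))
  if (length(absent) > 0L) {
    stop("table '", name, "' is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

#' Validate omics tables already held in memory
#'
#' Applies the same range and identifier checks as [read_omics_tables()]
#' to a named list of data frames.
#'
#' @param tables Named list with elements `ppi`, `dge`, `dga`, `kip`, `gr`,
#'   `go_clusters`.
#' @return The validated `omics_tables` object.
#' @export
validate_omics_tables <- function(tables) {
  schemas <- omics_schemas()
  for (nm in names(schemas)) {
    check_schema(tables[[nm]], schemas[[nm]], nm)
    tables[[nm]] <- tibble::as_tibble(tables[[nm]])[schemas[[nm]]]
  }

  fail <- function(table, column, rows, msg) {
    stop(sprintf("table '%s', column '%s', row(s) %s: %s", table, column,
                 paste(utils::head(rows, 5L), collapse = ", "), msg),
         call. = FALSE)
  }
  check_ids <- function(tbl, nm, cols) {
    for (cl in cols) {
      v <- tbl[[cl]]
      bad <- which(is.na(v) | !nzchar(as.character(v)))
      if (length(bad) > 0L) fail(nm, cl, bad, "empty identifier")
    }
  }

  ppi <- tables$ppi
  check_ids(ppi, "ppi", c("protein_a", "protein_b"))
  bad <- which(!is.finite(ppi$score) | ppi$score < 0 | ppi$score > 1000)
  if (length(bad) > 0L) {
    fail("ppi", "score", bad, "confidence score outside [0, 1000]")
  }

  dge <- tables$dge
  check_ids(dge, "dge", c("gene_id", "cell_line"))
  bad <- which(!dge$category %in% c("up", "down", "normal"))
  if (length(bad) > 0L) {
    fail("dge", "category", bad,
         "category must be one of 'up', 'down', 'normal'")
  }

  dga <- tables$dga
  check_ids(dga, "dga", c("disease", "gene_id"))
  bad <- which(!dga$source %in% c("DISEASE", "DisGeNET"))
  if (length(bad) > 0L) {
    fail("dga", "source", bad, "source must be 'DISEASE' or 'DisGeNET'")
  }
  is_dis <- dga$source == "DISEASE"
  bad <- which(is_dis & (!is.finite(dga$score) | dga$score < 1 | dga$score > 10))
  if (length(bad) > 0L) {
    fail("dga", "score", bad, "DISEASE score outside range [1,10]")
  }
  bad <- which(!is_dis &
                 (!is.finite(dga$score) | dga$score < 0.01 | dga$score > 1))
  if (length(bad) > 0L) {
    fail("dga", "score", bad, "DisGeNET score outside range [0.01,1]")
  }

  kip <- tables$kip
  check_ids(kip, "kip", c("drug", "gene_id"))
  bad <- which(!is.finite(kip$pic50) | kip$pic50 <= 0)
  if (length(bad) > 0L) fail("kip", "pic50", bad, "pIC50 must be positive")

  gr <- tables$gr
  check_ids(gr, "gr", c("cell_line", "drug", "tissue"))
  bad <- which(is.na(gr$gr_max))
  if (length(bad) > 0L) fail("gr", "gr_max", bad, "GRmax must be numeric")

  check_ids(tables$go_clusters, "go_clusters", c("gene_id", "cluster"))

  structure(tables, class = c("omics_tables", "list"))
}

#' @export
print.omics_tables <- function(x, ...) {
  cat("<omics_tables>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write omics tables to a directory of TSV files
#'
#' @param tables An `omics_tables` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_omics_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(omics_schemas())) {
    readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Locate omics TSV tables in a directory
#'
#' Companion to [write_omics_tables()]: returns the named path list that
#' [read_omics_tables()] expects, assuming files `<table>.tsv` in `dir`.
#'
#' @param dir Directory containing `ppi.tsv`, `dge.tsv`, ...
#' @return Named list of file paths.
#' @export
omics_table_paths <- function(dir) {
  nms <- names(omics_schemas())
  stats::setNames(as.list(file.path(dir, paste0(nms, ".tsv"))), nms)
}
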