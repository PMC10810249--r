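#' Read an expression table with class labels
#'
#' Loads a gene/probe-by-sample log2 expression matrix from either a plain
#' delimited file (first column = probe or gene id, header row = sample ids)
#' or a GEO Series Matrix text file (the block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`). Labels come
#' from a sidecar table (`sample_id<TAB>label[<TAB>batch]`) or, for the GEO
#' format, from a `!Sample_characteristics_ch1` line containing the class
#' tokens.
#'
#' @param path path to the expression file.
#' @param format `"delimited"` or `"geo_series_matrix"`.
#' @param labels_path optional path to the sidecar label table (no header).
#' @param sep field separator for delimited files (default tab).
#' @param positive label value for the positive (cancer) class.
#' @param negative label value for the negative (normal) class; only used to
#'   recognise characteristics lines in the GEO format.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, format = c("delimited", "geo_series_matrix"),
                                  labels_path = NULL, sep = "\t",
                                  positive = "cancer", negative = "normal") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    hdr <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]][-1]
    hdr <- gsub("^\"|\"$", "", hdr)
    if (anyDuplicated(hdr))
      stop("duplicate sample column: ", hdr[duplicated(hdr)][1])
    tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                             row.names = NULL, stringsAsFactors = FALSE,
                             comment.char = "", quote = "\"")
    ids <- as.character(tab[[1]])
    mat <- tab[, -1, drop = FALSE]
    colnames(mat) <- hdr
    for (j in seq_along(mat)) {
      v <- mat[[j]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
        stop("non-numeric value in column '", colnames(mat)[j],
             "', row '", ids[bad], "'")
      }
    }
    values <- as.matrix(mat)
    rownames(values) <- ids
    labs <- NULL
    batch <- NULL
  } else {
    lines <- readLines(path)
    b <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    e <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(b) != 1 || length(e) != 1 || e <= b + 1)
      stop("no series matrix table found in ", path)
    hdr <- gsub("^\"|\"$", "", strsplit(lines[b + 1], "\t", fixed = TRUE)[[1]][-1])
    if (anyDuplicated(hdr))
      stop("duplicate sample column: ", hdr[duplicated(hdr)][1])
    tab <- utils::read.table(text = lines[(b + 1):(e - 1)], header = TRUE,
                             sep = "\t", check.names = FALSE, quote = "\"",
                             stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    rownames(values) <- ids
    colnames(values) <- hdr
    if (!is.numeric(values)) stop("non-numeric value in series matrix table")
    labs <- NULL
    batch <- NULL
    ch <- grep("^!Sample_characteristics_ch1", lines, value = TRUE)
    for (line in ch) {
      fields <- gsub("^\"|\"$", "", strsplit(line, "\t")[[1]][-1])
      low <- tolower(fields)
      hit <- grepl(tolower(positive), low, fixed = TRUE) |
             grepl(tolower(negative), low, fixed = TRUE)
      if (all(hit) && length(fields) == ncol(values)) {
        labs <- ifelse(grepl(tolower(positive), low, fixed = TRUE), positive, negative)
        break
      }
    }
  }
  if (!is.null(labels_path)) {
    side <- utils::read.table(labels_path, header = FALSE, sep = sep,
                              stringsAsFactors = FALSE)
    if (ncol(side) < 2) stop("label table needs at least two columns")
    idx <- match(colnames(values), as.character(side[[1]]))
    if (anyNA(idx))
      stop("labels missing for samples: ",
           paste(colnames(values)[is.na(idx)][1:3], collapse = ", "))
    labs <- as.character(side[[2]])[idx]
    if (ncol(side) >= 3) batch <- as.character(side[[3]])[idx]
  }
  if (is.null(labs))
    stop("no labels: supply 'labels_path' or a characteristics line with class tokens")
  expression_matrix(values, labs, batch = batch, positive = positive)
}

#' Write an ExpressionMatrix and its label sidecar
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path for the expression table (tab-delimited).
#' @param labels_path optional output path for the label sidecar.
#' @param id_column name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, labels_path = NULL, id_column = "gene") {
  df <- data.frame(id = rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    side <- data.frame(colnames(m$values), as.character(m$labels))
    if (!is.null(m$batch)) side[[3]] <- as.character(m$batch)
    utils::write.table(side, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Probe-to-gene-symbol map
#'
#' @param probe_id character vector of probe ids (each at most once).
#' @param gene_symbol character vector of gene symbols; `NA` or `""` marks an
#'   unmapped probe.
#' @return a `ProbeMap` data frame.
#' @export
probe_map <- function(probe_id, gene_symbol) {
  probe_id <- as.character(probe_id)
  gene_symbol <- as.character(gene_symbol)
  if (length(probe_id) != length(gene_symbol))
    stop("probe_id and gene_symbol lengths differ")
  if (anyDuplicated(probe_id))
    stop("probe appears more than once: ", probe_id[duplicated(probe_id)][1])
  structure(data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       stringsAsFactors = FALSE),
            class = c("ProbeMap", "data.frame"))
}

#' Collapse probe-level rows to gene symbols
#'
#' Probes sharing a gene symbol are averaged per sample (arithmetic mean of
#' their log2 values); probes with no symbol are dropped with a warning
#' listing how many were removed. Output genes are ordered lexicographically
#' by symbol for reproducibility.
#'
#' @param m probe-level `ExpressionMatrix`.
#' @param pm a [probe_map()]. Probes absent from the map are treated as
#'   unmapped.
#' @return gene-level `ExpressionMatrix`.
#' @export
collapse_probes <- function(m, pm) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(pm, "ProbeMap"))
  sym <- pm$gene_symbol[match(rownames(m$values), pm$probe_id)]
  sym[sym == ""] <- NA_character_
  unmapped <- is.na(sym)
  if (any(unmapped))
    warning(sum(unmapped), " probe(s) had no gene symbol and were removed")
  if (all(unmapped)) stop("no probe could be mapped to a gene symbol")
  v <- m$values[!unmapped, , drop = FALSE]
  g <- sym[!unmapped]
  collapsed <- rowsum(v, group = g) / as.vector(table(g)[sort(unique(g))])
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  expression_matrix(collapsed, as.character(m$labels),
                    batch = if (is.null(m$batch)) NULL else as.character(m$batch),
                    positive = m$positive)
}

#' Drop unexpressed / uninformative gene rows
#'
#' Post-RMA log2 data contain no literal zeros, so "unexpressed across all
#' samples" needs an operational definition. Two modes are provided:
#' `"variance"` (default) removes rows constant across samples;
#' `"threshold"` removes rows whose values are all below the detection
#' threshold `tau`.
#'
#' @param m an `ExpressionMatrix`.
#' @param mode `"variance"` or `"threshold"`.
#' @param tau detection threshold (log2 units), used in threshold mode;
#'   must be non-negative.
#' @return the filtered `ExpressionMatrix`; row order preserved. The number
#'   of removed rows is reported via `message()`.
#' @export
filter_unexpressed <- function(m, mode = c("variance", "threshold"), tau = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "ExpressionMatrix"), tau >= 0)
  if (mode == "variance") {
    rv <- apply(m$values, 1, stats::var)
    keep <- rv > 0
  } else {
    keep <- apply(m$values, 1, function(x) any(x >= tau))
  }
  if (!any(keep)) stop("all rows removed by filter_unexpressed (mode=", mode, ")")
  message("filter_unexpressed: removed ", sum(!keep), " of ", length(keep),
          " rows (mode=", mode, ")")
  em_subset(m, genes = which(keep))
}
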