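#' Export a clustering in the Java TreeView dialect (CDT + GTR + ATR)
#'
#' Writes the tab-separated clustered-data table (CDT) with GID/AID
#' columns, the row dendrogram (GTR) and the column dendrogram (ATR) in the
#' format produced by the classic Cluster 3.0 program and read by Java
#' TreeView. Tree node rows are NODE, child, child, score; the score is
#' \code{1 - merge height}, i.e. the similarity at which the pair merged
#' (the Pearson correlation itself under the default correlation
#' distance). Rows and columns of the CDT appear in dendrogram leaf order.
#'
#' @param clustering result of \code{\link{hierarchical_cluster}}.
#' @param basename output path without extension; \code{.cdt},
#'   \code{.gtr}, \code{.atr} are appended.
#' @return invisibly, the three file paths.
#' @export
export_treeview <- function(clustering, basename) {
  stopifnot(inherits(clustering, "ihc_clustering"))
  m <- clustering$matrix
  rows <- clustering$rows
  cols <- clustering$cols
  gid <- function(i) sprintf("GENE%dX", i - 1L)
  aid <- function(j) sprintf("ARRY%dX", j - 1L)

  write_tree <- function(hc, leaf_name, prefix, path) {
    n <- length(hc$order)
    node_name <- function(id) {
      # hclust merge convention: negative = leaf index, positive = node row
      if (id < 0) leaf_name(-id) else sprintf("NODE%dX", id)
    }
    lines <- vapply(seq_len(n - 1L), function(i) {
      paste(sprintf("NODE%dX", i),
            node_name(hc$merge[i, 1]),
            node_name(hc$merge[i, 2]),
            format(1 - hc$height[i], digits = 10),
            sep = "\t")
    }, character(1))
    writeLines(lines, path)
  }

  gtr_path <- paste0(basename, ".gtr")
  atr_path <- paste0(basename, ".atr")
  cdt_path <- paste0(basename, ".cdt")
  write_tree(rows, gid, "GENE", gtr_path)
  write_tree(cols, aid, "ARRY", atr_path)

  ro <- rows$order
  co <- cols$order
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT",
                    colnames(m)[co]), collapse = "\t")
  aid_row <- paste(c("AID", "", "", "", aid(co)), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "", rep("1", length(co))),
                   collapse = "\t")
  data_rows <- vapply(ro, function(i) {
    paste(c(gid(i), rownames(m)[i], rownames(m)[i], "1",
            format(m[i, co], digits = 10, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, aid_row, eweight, data_rows), cdt_path)
  invisible(c(cdt = cdt_path, gtr = gtr_path, atr = atr_path))
}

#' Read the data matrix back from a CDT file
#'
#' Inverse of the CDT part of \code{\link{export_treeview}}: returns the
#' matrix with rows and columns restored (in CDT order, i.e. dendrogram
#' leaf order).
#'
#' @param path a .cdt file.
#' @return numeric matrix with dimnames.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "AID\t") &
                !startsWith(lines, "EWEIGHT\t")][-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  vals <- t(vapply(parts, function(p) as.numeric(p[-(1:4)]),
                   numeric(length(header) - 4L)))
  rownames(vals) <- vapply(parts, `[`, character(1), 2L)
  colnames(vals) <- header[-(1:4)]
  vals
}

#' Clustered heatmap of the standardized feature matrix
#'
#' Convenience wrapper around \code{\link[pheatmap]{pheatmap}} using the
#' package's dendrograms, with a white-to-red palette (higher value, more
#' intense red).
#'
#' @param clustering result of \code{\link{hierarchical_cluster}}.
#' @param path optional PNG path; when NULL, plots to the active device.
#' @param ... passed to \code{pheatmap}.
#' @export
plot_heatmap <- function(clustering, path = NULL, ...) {
  stopifnot(inherits(clustering, "ihc_clustering"))
  pal <- grDevices::colorRampPalette(c("white", "#FFB0B0", "red",
                                       "#7F0000"))(100)
  args <- list(mat = clustering$matrix,
               cluster_rows = clustering$rows,
               cluster_cols = clustering$cols,
               color = pal, ...)
  if (!is.null(path)) {
    args$filename <- path
  }
  do.call(pheatmap::pheatmap, args)
}
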