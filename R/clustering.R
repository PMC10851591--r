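#' Standardize a patient feature table into a clustering matrix
#'
#' The 12 parameters mix 8-bit intensities, area fractions and a ratio, so
#' each column is z-scored (sample SD, denominator n - 1) before
#' clustering. Constant columns cannot be scaled; they are set to 0 and
#' listed in the \code{constant_columns} attribute.
#'
#' @param features per-patient feature data.frame (from
#'   \code{\link{aggregate_patients}} or a feature TSV) with a
#'   \code{patient} column and the 12 parameter columns.
#' @return numeric matrix, patients in rows (rownames = patient ids),
#'   parameters in columns, with attribute \code{constant_columns}.
#' @export
standardize <- function(features) {
  fn <- feature_names()
  missing <- setdiff(fn, names(features))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(features) < 2L)
    stop("need at least 2 patients to standardize", call. = FALSE)
  m <- as.matrix(features[, fn])
  rownames(m) <- if ("patient" %in% names(features)) features$patient
                 else as.character(seq_len(nrow(features)))
  sds <- apply(m, 2L, stats::sd)
  constant <- sds == 0 | is.na(sds)
  z <- scale(m)
  z[, constant] <- 0
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "constant_columns") <- fn[constant]
  z
}

# 1 - Pearson correlation between rows, as a dist object
correlation_dist <- function(m) {
  r <- stats::cor(t(m))
  r[is.na(r)] <- 0  # rows with zero variance: treat as uncorrelated
  stats::as.dist(1 - r)
}

# 1 - uncentered correlation (cosine similarity) between rows. Unlike the
# centered version this keeps the overall level of a profile, so
# uniformly-low and uniformly-high patients are far apart.
uncentered_dist <- function(m) {
  norms <- sqrt(rowSums(m^2))
  norms[norms == 0] <- 1
  s <- (m / norms) %*% t(m / norms)
  s[s > 1] <- 1; s[s < -1] <- -1
  stats::as.dist(1 - s)
}

#' Two-dimensional hierarchical clustering of the feature matrix
#'
#' Agglomerative clustering of both patients (rows) and parameters
#' (columns), with average linkage by default. The default distance is
#' uncentered correlation distance (1 - cosine similarity), the default
#' similarity of the classic gene-expression clustering tools whose file
#' format this package exports: on z-scored features it separates
#' uniformly-low from uniformly-high profiles, which centered Pearson
#' correlation is blind to (it removes each profile's mean). Centered
#' Pearson ("correlation") and Euclidean distance remain available.
#'
#' @param matrix standardized matrix from \code{\link{standardize}}.
#' @param distance "uncentered", "correlation" or "euclidean".
#' @param linkage any method accepted by \code{\link[stats]{hclust}}
#'   (default "average").
#' @return list with \code{rows} and \code{cols} (\code{hclust} objects),
#'   and the \code{matrix}, \code{distance} and \code{linkage} used.
#' @export
hierarchical_cluster <- function(matrix, distance = c("uncentered",
                                                      "correlation",
                                                      "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  if (any(!is.finite(matrix)))
    stop("feature matrix contains non-finite values", call. = FALSE)
  dfun <- switch(distance,
                 uncentered = uncentered_dist,
                 correlation = correlation_dist,
                 euclidean = function(m) stats::dist(m))
  structure(list(rows = stats::hclust(dfun(matrix), method = linkage),
                 cols = stats::hclust(dfun(t(matrix)), method = linkage),
                 matrix = matrix, distance = distance, linkage = linkage),
            class = "ihc_clustering")
}

#' Cut the patient dendrogram into k groups
#'
#' Groups are renumbered 1..k in dendrogram leaf order (the order they
#' appear in a plotted tree, left to right), so group numbering is
#' reproducible and independent of input row order.
#'
#' @param clustering result of \code{\link{hierarchical_cluster}} (or a
#'   bare \code{hclust} object over patients).
#' @param k number of groups, between 1 and the number of patients.
#' @return named integer vector of group labels in 1..k.
#' @export
cut_groups <- function(clustering, k = 4) {
  hc <- if (inherits(clustering, "ihc_clustering")) clustering$rows
        else clustering
  n <- length(hc$order)
  if (k < 1 || k > n) stop("k must lie in [1, n]", call. = FALSE)
  raw <- stats::cutree(hc, k = k)
  stats::setNames(match(raw, unique(raw[hc$order])), names(raw))
}

#' Label each patient group with an expression phenotype
#'
#' The rule operates on the group means of two discriminating z-scored
#' parameters: the extracellular area fraction (\code{pct_area_extra}) and
#' the intracellular/extracellular area ratio (\code{intra_extra_ratio}).
#' A group is \emph{intracellular} when only the ratio mean exceeds
#' \code{tau}, \emph{extracellular} when only the extracellular-area mean
#' does, \emph{both} when both do, and \emph{low} otherwise.
#'
#' @param groups integer group labels from \code{\link{cut_groups}}.
#' @param matrix the standardized matrix the groups were cut from.
#' @param tau z-score threshold for calling a parameter elevated
#'   (default 0.5).
#' @return named character vector: phenotype per group ("1", "2", ...).
#' @export
label_phenotypes <- function(groups, matrix, tau = 0.5) {
  ks <- sort(unique(groups))
  pheno <- vapply(ks, function(g) {
    rows <- names(groups)[groups == g]
    z_extra <- mean(matrix[rows, "pct_area_extra"])
    z_ratio <- mean(matrix[rows, "intra_extra_ratio"])
    if (z_ratio > tau && z_extra > tau) "both"
    else if (z_ratio > tau) "intracellular"
    else if (z_extra > tau) "extracellular"
    else "low"
  }, character(1))
  stats::setNames(pheno, as.character(ks))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the expectation under random
#' labeling.
#'
#' @param a,b label vectors of equal length (any label type).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length",
                                   call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
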