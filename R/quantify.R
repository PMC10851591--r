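#' Threshold configuration for dual-threshold quantification
#'
#' The low threshold delimits total specific staining, the high threshold
#' the high-density staining that is operationally treated as intracellular.
#' One configuration is applied to every image of a project so that areas
#' and intensities stay comparable between images.
#'
#' @param low,high integers in [0, 255], \code{low <= high}.
#' @param tissue_threshold integer in [0, 255] used for tissue segmentation
#'   on the original RGB image.
#' @return object of class \code{threshold_config}.
#' @export
threshold_config <- function(low, high, tissue_threshold = 220) {
  for (v in list(low, high, tissue_threshold)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 255)
      stop("thresholds must be scalars in [0, 255]", call. = FALSE)
  }
  if (low > high)
    stop("low threshold must not exceed high threshold", call. = FALSE)
  structure(list(low = as.integer(low), high = as.integer(high),
                 tissue_threshold = as.integer(tissue_threshold)),
            class = "threshold_config")
}

#' Apply the low/high threshold pair to a DAB map
#'
#' @param dab a \code{dab_map}.
#' @param cfg a \code{\link{threshold_config}}.
#' @return list of logical matrices \code{T} (tissue), \code{L}
#'   (total stained: tissue with intensity >= low) and \code{H}
#'   (high-density: tissue with intensity >= high). By construction
#'   \code{H} is a subset of \code{L}, itself a subset of \code{T}.
#' @export
apply_thresholds <- function(dab, cfg) {
  stopifnot(inherits(dab, "dab_map"), inherits(cfg, "threshold_config"))
  T_ <- dab$tissue
  L <- T_ & (dab$intensity >= cfg$low)
  H <- T_ & (dab$intensity >= cfg$high)
  structure(list(T = T_, L = L, H = H), class = "segmentation_masks")
}

#' Names of the 12 per-image staining parameters, in canonical table order
#' @export
feature_names <- function() {
  c("mean_dab_total", "mode_dab_total", "median_dab_total", "pct_area_total",
    "mean_intra", "mode_intra", "median_intra", "pct_area_intra",
    "pct_area_extra", "mean_intensity_tissue", "mean_intensity_intra_tissue",
    "intra_extra_ratio")
}

# histogram mode of an integer vector on the 0..255 grid; smallest value
# wins ties so the statistic is deterministic
intensity_mode <- function(v) {
  if (length(v) == 0L) return(0)
  tab <- tabulate(v + 1L, nbins = 256L)
  which.max(tab) - 1
}

#' Compute the 12 per-image staining parameters
#'
#' Intensity statistics (mean, mode, median) are taken over the total-stain
#' mask \code{L} and the high-density mask \code{H}. Area fractions are
#' relative to the tissue-covered area \code{T}:
#' \itemize{
#'   \item \code{pct_area_total = |L| / |T|}
#'   \item \code{pct_area_intra = |H| / |T|}
#'   \item \code{pct_area_extra = (|L| - |H|) / |T|}
#' }
#' \code{mean_intensity_tissue} and \code{mean_intensity_intra_tissue}
#' average intensity over all of \code{T}, counting pixels outside
#' \code{L} (respectively \code{H}) as 0, which makes them sensitive to both
#' staining level and stained area. \code{intra_extra_ratio} is
#' \code{|H| / (|L| - |H|)}; when the extracellular area is empty the
#' denominator is floored at one pixel and the result flagged
#' (\code{ratio_flagged}), so downstream clustering always receives a
#' finite value. Statistics of an empty mask are 0 by convention.
#'
#' @param masks output of \code{\link{apply_thresholds}}.
#' @param dab the \code{dab_map} the masks came from.
#' @return one-row data.frame with the columns of \code{\link{feature_names}}
#'   plus a logical \code{ratio_flagged}.
#' @export
compute_image_features <- function(masks, dab) {
  stopifnot(inherits(masks, "segmentation_masks"), inherits(dab, "dab_map"))
  nT <- sum(masks$T)
  if (nT == 0L) stop("no tissue detected in image", call. = FALSE)
  nL <- sum(masks$L)
  nH <- sum(masks$H)
  vL <- dab$intensity[masks$L]
  vH <- dab$intensity[masks$H]

  mask_stats <- function(v) {
    if (length(v) == 0L) c(mean = 0, mode = 0, median = 0)
    else c(mean = mean(v), mode = intensity_mode(v),
           median = stats::median(v))
  }
  sL <- mask_stats(vL)
  sH <- mask_stats(vH)

  n_extra <- nL - nH
  flagged <- n_extra == 0L
  ratio <- nH / max(n_extra, 1L)

  data.frame(
    mean_dab_total = sL[["mean"]],
    mode_dab_total = sL[["mode"]],
    median_dab_total = sL[["median"]],
    pct_area_total = nL / nT,
    mean_intra = sH[["mean"]],
    mode_intra = sH[["mode"]],
    median_intra = sH[["median"]],
    pct_area_intra = nH / nT,
    pct_area_extra = n_extra / nT,
    mean_intensity_tissue = sum(vL) / nT,
    mean_intensity_intra_tissue = sum(vH) / nT,
    intra_extra_ratio = ratio,
    ratio_flagged = flagged
  )
}

#' Quantify one image end to end
#'
#' Convenience wrapper: RGB array in, one feature row out.
#'
#' @param image numeric \code{H x W x 3} array in [0, 255].
#' @param cfg a \code{\link{threshold_config}}.
#' @param model a \code{\link{stain_model}}.
#' @param c_max saturation concentration for the 8-bit DAB scale.
#' @return one-row data.frame of features.
#' @export
quantify_image <- function(image, cfg, model = stain_model(), c_max = 2.0) {
  dm <- dab_map(image, model, c_max, cfg$tissue_threshold)
  compute_image_features(apply_thresholds(dm, cfg), dm)
}

#' Aggregate per-image features into per-patient features
#'
#' Each parameter is the arithmetic mean over the patient's images
#' (three per patient in a standard project).
#'
#' @param features data.frame with a \code{patient} column, the 12 feature
#'   columns and optionally \code{ratio_flagged}.
#' @return data.frame with one row per patient: \code{patient},
#'   \code{n_images}, the 12 averaged parameters, and \code{ratio_flagged}
#'   (TRUE if any contributing image was flagged).
#' @export
aggregate_patients <- function(features) {
  if (nrow(features) == 0L) stop("no image features to aggregate",
                                 call. = FALSE)
  if (!"patient" %in% names(features))
    stop("features must carry a 'patient' column", call. = FALSE)
  fn <- feature_names()
  missing <- setdiff(fn, names(features))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  split_rows <- split(features, features$patient)
  out <- lapply(split_rows, function(d) {
    row <- as.data.frame(as.list(colMeans(d[fn])))
    row$patient <- d$patient[1]
    row$n_images <- nrow(d)
    row$ratio_flagged <- if ("ratio_flagged" %in% names(d))
      any(d$ratio_flagged) else FALSE
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("patient", "n_images", fn, "ratio_flagged")]
}

#' Write / read a feature table as tab-separated values
#'
#' Column order is fixed: identifiers first, then the 12 parameters in the
#' order of \code{\link{feature_names}}.
#'
#' @param features data.frame of per-image or per-patient features.
#' @param path destination TSV.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
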