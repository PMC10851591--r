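#' Stain model for hematoxylin + DAB colour deconvolution
#'
#' A stain model holds one optical-density (OD) vector per stain and the
#' matching unmixing matrix. Brightfield stains mix additively in OD space
#' (Beer-Lambert), so an RGB pixel converted to OD is a non-negative linear
#' combination of the stain vectors; inverting that mixture recovers the
#' per-stain concentrations.
#'
#' The default vectors are the widely used Ruifrok-Johnston H-DAB values.
#' The third ("residual") vector is the normalized cross product of the two
#' stain vectors so that the matrix is always invertible.
#'
#' @param hematoxylin,dab numeric length-3 per-channel OD vectors; they are
#'   normalized to unit Euclidean length internally.
#' @param residual optional third vector; defaults to the cross product of
#'   the first two, normalized.
#' @return An object of class \code{stain_model} with components
#'   \code{stains} (3 x 3 matrix, one stain per row, unit rows) and
#'   \code{unmix} (its inverse).
#' @examples
#' m <- stain_model()
#' m$stains %*% m$unmix  # identity
#' @export
stain_model <- function(hematoxylin = c(0.650, 0.704, 0.286),
                        dab = c(0.269, 0.568, 0.778),
                        residual = NULL) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("stain vector has (near) zero norm", call. = FALSE)
    v / n
  }
  h <- unit(as.numeric(hematoxylin))
  d <- unit(as.numeric(dab))
  if (is.null(residual)) {
    residual <- c(h[2] * d[3] - h[3] * d[2],
                  h[3] * d[1] - h[1] * d[3],
                  h[1] * d[2] - h[2] * d[1])
    if (sqrt(sum(residual^2)) < 1e-6)
      stop("stain vectors are collinear; the stain matrix is singular",
           call. = FALSE)
  }
  r <- unit(as.numeric(residual))
  stains <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(stains) <- c("red", "green", "blue")
  if (abs(det(stains)) < 1e-6) {
    stop("stain vectors are collinear; the stain matrix is singular",
         call. = FALSE)
  }
  structure(list(stains = stains, unmix = solve(stains)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("Stain model (rows are unit OD vectors):\n")
  print(round(x$stains, 4))
  invisible(x)
}

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert transform channelwise:
#' \code{OD = -log10((I + 1) / 255)}, with the +1 offset guarding against
#' \code{log(0)} at fully absorbing pixels. The tiny negative value this
#' yields at I = 255 is clipped to 0 so that OD is always non-negative.
#'
#' @param image numeric array \code{H x W x 3} with channel intensities in
#'   [0, 255] (integers; fractional values are accepted and used as-is).
#' @return numeric array \code{H x W x 3} of non-negative optical densities.
#' @export
rgb_to_od <- function(image) {
  check_rgb(image)
  od <- -log10((image + 1) / 255)
  od[od < 0] <- 0
  od
}

check_rgb <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("RGB intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Unmix an optical-density image into per-stain concentration maps
#'
#' Multiplies each pixel's OD vector by the model's unmixing matrix.
#' Negative concentrations (pixels falling below the stain plane because of
#' noise) are clipped to 0.
#'
#' @param od numeric array \code{H x W x 3} of optical densities.
#' @param model a \code{\link{stain_model}}.
#' @return named list of \code{H x W} concentration matrices, one per stain.
#' @export
separate_stains <- function(od, model = stain_model()) {
  if (!inherits(model, "stain_model")) stop("model must be a stain_model",
                                            call. = FALSE)
  d <- dim(od)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("expected an H x W x 3 optical-density array", call. = FALSE)
  }
  flat <- matrix(od, ncol = 3L)           # pixels x channels
  conc <- flat %*% model$unmix            # pixels x stains
  conc[conc < 0] <- 0
  out <- lapply(seq_len(3L), function(j) matrix(conc[, j], d[1], d[2]))
  names(out) <- rownames(model$stains)
  out
}

#' Scale a DAB concentration map to an inverted 8-bit intensity image
#'
#' Concentrations are mapped linearly onto [0, 255] with saturation at
#' \code{c_max}: \code{intensity = round(255 * min(c, c_max) / c_max)} with
#' round-half-up, so 0 means no DAB and 255 means concentration at or above
#' \code{c_max}. Using one \code{c_max} for every image of a project keeps
#' intensities comparable across images, mirroring stack-based analysis.
#'
#' @param dab_concentration non-negative numeric matrix.
#' @param c_max positive scalar; concentration mapped to 255. Default 2.0 OD.
#' @return integer matrix with values in 0..255.
#' @export
dab_intensity_map <- function(dab_concentration, c_max = 2.0) {
  if (!is.numeric(c_max) || length(c_max) != 1L || is.na(c_max) || c_max <= 0)
    stop("c_max must be a positive scalar", call. = FALSE)
  if (min(dab_concentration) < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  x <- pmin(dab_concentration, c_max)
  m <- round_half_up(255 * x / c_max)
  storage.mode(m) <- "integer"
  m
}

# round-half-up at a given number of decimal digits (round() in R is
# round-half-even, which would make 8-bit conversion depend on parity)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Segment tissue from bright background
#'
#' A pixel is tissue when the mean of its three channels falls below
#' \code{tissue_threshold}: stained tissue absorbs light while the empty
#' slide stays near white.
#'
#' @param image numeric array \code{H x W x 3} in [0, 255].
#' @param tissue_threshold scalar in [0, 255].
#' @return logical \code{H x W} matrix, TRUE for tissue.
#' @export
tissue_mask <- function(image, tissue_threshold = 220) {
  check_rgb(image)
  if (tissue_threshold < 0 || tissue_threshold > 255)
    stop("tissue_threshold must lie in [0, 255]", call. = FALSE)
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  lum < tissue_threshold
}

#' Full DAB-detection stage: RGB image to inverted DAB map plus tissue mask
#'
#' Chains OD conversion, stain separation, 8-bit scaling of the DAB channel
#' and tissue segmentation. The result is the working object all
#' quantification consumes.
#'
#' @inheritParams rgb_to_od
#' @inheritParams dab_intensity_map
#' @inheritParams tissue_mask
#' @param model a \code{\link{stain_model}}.
#' @return A \code{dab_map}: list with integer matrix \code{intensity}
#'   (0..255, higher = more DAB) and logical matrix \code{tissue}.
#' @export
dab_map <- function(image, model = stain_model(), c_max = 2.0,
                    tissue_threshold = 220) {
  conc <- separate_stains(rgb_to_od(image), model)
  new_dab_map(dab_intensity_map(conc$dab, c_max),
              tissue_mask(image, tissue_threshold))
}

#' Construct a DAB map from an intensity matrix and a tissue mask
#'
#' @param intensity integer matrix with values in 0..255.
#' @param tissue logical matrix of the same shape.
#' @return object of class \code{dab_map}.
#' @export
new_dab_map <- function(intensity, tissue) {
  if (!identical(dim(intensity), dim(tissue)))
    stop("intensity and tissue mask must have identical shape", call. = FALSE)
  if (min(intensity) < 0 || max(intensity) > 255)
    stop("DAB intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(intensity) <- "integer"
  structure(list(intensity = intensity, tissue = as.matrix(tissue)),
            class = "dab_map")
}

#' @export
print.dab_map <- function(x, ...) {
  cat(sprintf("DAB map %d x %d, tissue fraction %.3f, median DAB %d\n",
              nrow(x$intensity), ncol(x$intensity), mean(x$tissue),
              stats::median(x$intensity[x$tissue])))
  invisible(x)
}
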