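#' Archetype specifications for synthetic hematoxylin + DAB lung images
#'
#' Each archetype mirrors one of the four expression phenotypes the pipeline
#' is designed to separate: \emph{extracellular}-dominant, general
#' \emph{low}, \emph{intracellular}-dominant, and \emph{both}. An archetype
#' fixes the target tissue coverage, the fractions of tissue carrying
#' diffuse (extracellular) and punctate high-density (intracellular) DAB,
#' and the optical densities of the stains.
#'
#' Default fractions are chosen so that the four phenotypes are separated in
#' the three discriminating parameters (total stained area, intracellular
#' area, intracellular/extracellular ratio) the way the four observed
#' phenotype groups are: the extracellular archetype has a large diffuse
#' area with little punctate stain, the intracellular archetype the
#' converse, the "both" archetype is high in both (and therefore also in
#' the ratio), and "low" is weak in everything.
#'
#' @param name one of "extracellular", "low", "intracellular", "both".
#' @param tissue_fraction target fraction of the frame covered by tissue.
#' @param extra_fraction,intra_fraction target fractions of the tissue area
#'   carrying extracellular / intracellular DAB (disjoint regions).
#' @param od_hematoxylin hematoxylin OD applied to all tissue.
#' @param od_extra,od_intra DAB OD of the extracellular and intracellular
#'   compartments; must satisfy \code{od_intra > od_extra > 0}.
#' @param noise_sd standard deviation of Gaussian per-channel OD noise.
#' @return object of class \code{archetype_spec}.
#' @export
archetype_spec <- function(name = c("extracellular", "low", "intracellular",
                                    "both"),
                           tissue_fraction = 0.55,
                           extra_fraction = NULL, intra_fraction = NULL,
                           od_hematoxylin = 0.4, od_extra = 0.6,
                           od_intra = 1.2, noise_sd = 0.05) {
  name <- match.arg(name)
  defaults <- list(
    extracellular = c(extra = 0.40, intra = 0.03),
    low           = c(extra = 0.06, intra = 0.01),
    intracellular = c(extra = 0.05, intra = 0.09),
    both          = c(extra = 0.30, intra = 0.42)
  )[[name]]
  if (is.null(extra_fraction)) extra_fraction <- defaults[["extra"]]
  if (is.null(intra_fraction)) intra_fraction <- defaults[["intra"]]
  stopifnot(tissue_fraction > 0, tissue_fraction <= 1,
            extra_fraction >= 0, intra_fraction >= 0,
            extra_fraction + intra_fraction <= 1)
  if (!(od_intra > od_extra && od_extra > 0))
    stop("need od_intra > od_extra > 0", call. = FALSE)
  structure(list(name = name, tissue_fraction = tissue_fraction,
                 extra_fraction = extra_fraction,
                 intra_fraction = intra_fraction,
                 od_hematoxylin = od_hematoxylin, od_extra = od_extra,
                 od_intra = od_intra, noise_sd = noise_sd),
            class = "archetype_spec")
}

#' All four default archetypes
#' @return named list of \code{\link{archetype_spec}} objects.
#' @export
default_archetypes <- function() {
  nm <- c("extracellular", "low", "intracellular", "both")
  stats::setNames(lapply(nm, archetype_spec), nm)
}

#' Thresholds calibrated to the simulator's optical densities
#'
#' On the 8-bit DAB scale with saturation \code{c_max}, the extracellular
#' and intracellular compartments of a spec land at
#' \code{255 * od / c_max}. The low threshold is set halfway between zero
#' and the extracellular level, the high threshold halfway between the two
#' compartment levels, which keeps both several noise standard deviations
#' away from either class.
#'
#' @param spec an \code{\link{archetype_spec}} (any archetype; the ODs are
#'   shared across the default archetypes).
#' @param c_max saturation concentration of the 8-bit scale.
#' @param tissue_threshold passed through to the returned config.
#' @return a \code{\link{threshold_config}}.
#' @export
calibrate_thresholds <- function(spec = archetype_spec("low"), c_max = 2.0,
                                 tissue_threshold = 220) {
  lev_extra <- 255 * spec$od_extra / c_max
  lev_intra <- 255 * spec$od_intra / c_max
  threshold_config(low = round_half_up(lev_extra / 2),
                   high = round_half_up((lev_extra + lev_intra) / 2),
                   tissue_threshold = tissue_threshold)
}

# smooth Gaussian random field; separable blur via FFT-free convolution
smooth_field <- function(shape, correlation_length) {
  field <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  half <- max(1L, ceiling(2 * correlation_length))
  k <- stats::dnorm(seq(-half, half), sd = correlation_length)
  k <- k / sum(k)
  pad_conv <- function(m, kern) {
    # convolve each column with replicated-edge padding
    h <- length(kern) %/% 2L
    n <- nrow(m)
    padded <- rbind(m[rep(1L, h), , drop = FALSE], m,
                    m[rep(n, h), , drop = FALSE])
    out <- apply(padded, 2L, function(col)
      stats::filter(col, kern, sides = 2L))
    out[(h + 1L):(h + n), , drop = FALSE]
  }
  field <- pad_conv(field, k)
  t(pad_conv(t(field), k))
}

#' Generate a lacy tissue mask
#'
#' Thresholds a smoothed Gaussian random field at the porosity quantile, so
#' the tissue fraction equals \code{1 - porosity} up to the granularity of
#' one pixel. The correlation length sets the scale of the airspace
#' "holes", emulating sectioned parenchyma.
#'
#' @param shape integer c(height, width).
#' @param porosity fraction of the frame left as background, in [0, 1).
#' @param correlation_length smoothing scale in pixels.
#' @param seed integer seed; generation is fully reproducible.
#' @return logical matrix, TRUE for tissue.
#' @export
generate_tissue <- function(shape, porosity = 0.45, correlation_length = 6,
                            seed = 1L) {
  if (length(shape) != 2L || any(shape < 8L))
    stop("shape must be c(height, width) with both >= 8", call. = FALSE)
  if (porosity < 0 || porosity >= 1)
    stop("porosity must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  if (porosity == 0) return(matrix(TRUE, shape[1], shape[2]))
  f <- smooth_field(shape, correlation_length)
  f >= stats::quantile(f, porosity, names = FALSE)
}

# disk offsets as an integer matrix of (dr, dc)
disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, ])
}

#' Place extracellular and intracellular staining inside a tissue mask
#'
#' Intracellular staining is modeled as cell-scale disks (radius 3-8 px)
#' dropped at random tissue locations until the requested fraction of
#' tissue is covered; the final disk is trimmed so the recorded fraction is
#' exact to the pixel. Extracellular staining is a smooth blob field over
#' the remaining tissue, thresholded at the quantile that yields the
#' requested fraction exactly. The two masks are disjoint and both lie
#' inside the tissue.
#'
#' @param tissue logical tissue mask.
#' @param spec an \code{\link{archetype_spec}}.
#' @param seed integer seed.
#' @return object of class \code{synthetic_truth}: list with masks
#'   \code{tissue}, \code{extra}, \code{intra}, the exact achieved
#'   \code{fractions} (tissue of frame, extra of tissue, intra of tissue),
#'   the \code{seed} and the \code{archetype} name.
#' @export
place_staining <- function(tissue, spec, seed = 1L) {
  stopifnot(inherits(spec, "archetype_spec"))
  set.seed(seed)
  n_tissue <- sum(tissue)
  if (n_tissue == 0L) stop("tissue mask is empty", call. = FALSE)
  n_intra_target <- round_half_up(spec$intra_fraction * n_tissue)
  n_extra_target <- round_half_up(spec$extra_fraction * n_tissue)
  if (n_intra_target + n_extra_target > n_tissue)
    stop("requested stain fractions exceed available tissue", call. = FALSE)

  nr <- nrow(tissue); nc <- ncol(tissue)
  intra <- matrix(FALSE, nr, nc)
  tissue_idx <- which(tissue)
  # drop disks until the target pixel count is reached, then trim the excess
  while (sum(intra) < n_intra_target) {
    ctr <- tissue_idx[sample.int(length(tissue_idx), 1L)]
    r <- sample(3:8, 1L)
    rc <- arrayInd(ctr, dim(tissue))
    off <- disk_offsets(r)
    rr <- rc[1] + off[, 1]; cc <- rc[2] + off[, 2]
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    px <- cbind(rr[keep], cc[keep])
    px <- px[tissue[px], , drop = FALSE]
    new <- px[!intra[px], , drop = FALSE]
    overshoot <- sum(intra) + nrow(new) - n_intra_target
    if (overshoot > 0)
      new <- new[seq_len(nrow(new) - overshoot), , drop = FALSE]
    intra[new] <- TRUE
  }

  extra <- matrix(FALSE, nr, nc)
  if (n_extra_target > 0) {
    avail <- tissue & !intra
    f <- smooth_field(c(nr, nc), correlation_length = 8)
    vals <- f[avail]
    cut <- sort(vals, decreasing = TRUE)[n_extra_target]
    sel <- avail & (f >= cut)
    # resolve ties at the cut value so the count is exact
    excess <- sum(sel) - n_extra_target
    if (excess > 0) {
      tie_idx <- which(sel & (f == cut))
      sel[tie_idx[seq_len(excess)]] <- FALSE
    }
    extra <- sel
  }

  structure(list(
    tissue = tissue, extra = extra, intra = intra,
    fractions = c(tissue = n_tissue / (nr * nc),
                  extra = sum(extra) / n_tissue,
                  intra = sum(intra) / n_tissue),
    seed = seed, archetype = spec$name
  ), class = "synthetic_truth")
}

#' Render a synthetic RGB brightfield image from ground truth
#'
#' Beer-Lambert forward model, the exact inverse of the detection stage:
#' every tissue pixel carries the hematoxylin OD, stained compartments add
#' the DAB OD of their region, per-channel OD is
#' \code{concentration x stain vector} summed over stains, optionally
#' perturbed by Gaussian OD noise, and transmitted intensity is
#' \code{round(255 * 10^-OD) - 1} clipped to [0, 255]. The -1 offset is
#' the exact counterpart of the +1 guard in \code{\link{rgb_to_od}}, so a
#' noise-free render/unmix round trip is limited only by 8-bit
#' quantization. Background is near white.
#'
#' @param truth a \code{synthetic_truth}.
#' @param spec the \code{\link{archetype_spec}} that produced it.
#' @param model the shared \code{\link{stain_model}}.
#' @param noise logical; add Gaussian OD noise of sd \code{spec$noise_sd}.
#' @param seed integer seed for the noise.
#' @return numeric \code{H x W x 3} array in [0, 255].
#' @export
render_image <- function(truth, spec, model = stain_model(), noise = TRUE,
                         seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(spec, "archetype_spec"))
  set.seed(seed)
  nr <- nrow(truth$tissue); nc <- ncol(truth$tissue)
  c_h <- ifelse(truth$tissue, spec$od_hematoxylin, 0)
  c_d <- ifelse(truth$intra, spec$od_intra,
                ifelse(truth$extra, spec$od_extra, 0))
  od <- outer(c_h, model$stains["hematoxylin", ]) +
        outer(c_d, model$stains["dab", ])
  if (noise && spec$noise_sd > 0)
    od <- od + stats::rnorm(length(od), sd = spec$noise_sd)
  img <- round_half_up(255 * 10^(-od)) - 1
  img[img > 255] <- 255
  img[img < 0] <- 0
  img
}

# truncated-normal draw by resampling; bounds are generous so this
# terminates quickly
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate a synthetic clinical table for a four-archetype cohort
#'
#' Covariates follow the structure of a neonatal autopsy cohort:
#' gestational age (GA) in weeks (truncated normal within 21-41), birth
#' weight increasing with GA, postnatal age (PNA) at death drawn from three
#' bins (< 1 day, 1-7 days, > 7 days) with the cohort's bin rates, sex,
#' preterm status (GA < 37), and antenatal/postnatal steroid flags.
#' Optionally a planted GA deficit \code{ga_effect} is applied to patients
#' of the high-intracellular archetypes (intracellular, both) who died at
#' PNA 1-7 days, emulating a postnatal-age-dependent association between
#' prematurity and intracellular staining.
#'
#' @param n_per_archetype patients per archetype.
#' @param seed integer seed.
#' @param ga_mean,ga_sd baseline GA distribution (weeks).
#' @param ga_effect GA shift (weeks, usually negative) planted in
#'   high-intracellular patients of the 1-7 day PNA bin; 0 disables it.
#' @param pna_bin_probs probabilities of the three PNA bins.
#' @return data.frame with columns patient, archetype, ga_weeks,
#'   birth_weight_g, pna_days, pma_weeks, sex, preterm,
#'   antenatal_steroids, postnatal_steroids.
#' @export
generate_clinical <- function(n_per_archetype = 20, seed = 1L,
                              ga_mean = 29, ga_sd = 2.5, ga_effect = 0,
                              pna_bin_probs = c(0.365, 0.41, 0.225)) {
  set.seed(seed)
  arch <- rep(c("extracellular", "low", "intracellular", "both"),
              each = n_per_archetype)
  n <- length(arch)
  bin <- sample.int(3L, n, replace = TRUE, prob = pna_bin_probs)
  pna <- numeric(n)
  pna[bin == 1L] <- stats::runif(sum(bin == 1L), 0, 1)
  pna[bin == 2L] <- stats::runif(sum(bin == 2L), 1, 7)
  pna[bin == 3L] <- pmin(8 + stats::rexp(sum(bin == 3L), rate = 1 / 40), 228)
  mu <- rep(ga_mean, n)
  planted <- arch %in% c("intracellular", "both") & bin == 2L
  mu[planted] <- mu[planted] + ga_effect
  ga <- round(rnorm_trunc(n, mu, ga_sd, 21, 41), 1)
  bw <- pmax(300, round(165 * ga - 3300 + stats::rnorm(n, 0, 350)))
  data.frame(
    patient = sprintf("P%03d", seq_len(n)),
    archetype = arch,
    ga_weeks = ga,
    birth_weight_g = bw,
    pna_days = round(pna, 2),
    pma_weeks = round(ga + pna / 7, 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.37, 0.63)),
    preterm = ga < 37,
    antenatal_steroids = stats::runif(n) < 0.148,
    postnatal_steroids = stats::runif(n) < 0.061,
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic cohort: images, ground truth and clinical data
#'
#' Every patient receives \code{images_per_patient} images drawn from their
#' archetype, with the stain fractions jittered by up to 10 percent
#' relative between images so that per-patient averaging is meaningful.
#' Each patient additionally carries an individual DAB density multiplier
#' (archetype-level mean times a small log-normal jitter) applied to both
#' DAB optical densities: stronger-expressing phenotypes deposit denser
#' chromogen, so staining-intensity parameters covary with the area
#' parameters across a cohort rather than being constant up to noise.
#'
#' @param n_per_archetype patients per archetype.
#' @param images_per_patient images per patient (3 in a standard project).
#' @param shape image size c(height, width).
#' @param archetypes named list of \code{\link{archetype_spec}}s.
#' @param model shared \code{\link{stain_model}}.
#' @param noise logical; render with OD noise.
#' @param seed master seed; all randomness derives from it.
#' @param ga_effect planted GA effect passed to
#'   \code{\link{generate_clinical}}.
#' @param od_scale_means named per-archetype means of the patient DAB
#'   density multiplier.
#' @param od_scale_sd log-scale SD of the per-patient multiplier jitter.
#' @param dir optional directory; when given, images are written as TIFF
#'   and the tables as TSV.
#' @return list with \code{images} (list of RGB arrays, named
#'   patient_image), \code{truth} (data.frame of exact per-image fractions),
#'   \code{clinical} (see \code{\link{generate_clinical}}), and
#'   \code{archetypes}.
#' @export
generate_cohort <- function(n_per_archetype = 20, images_per_patient = 3,
                            shape = c(160, 160),
                            archetypes = default_archetypes(),
                            model = stain_model(), noise = TRUE, seed = 1L,
                            ga_effect = 0,
                            od_scale_means = c(extracellular = 1.0,
                                               low = 0.9,
                                               intracellular = 1.1,
                                               both = 1.2),
                            od_scale_sd = 0.04, dir = NULL) {
  stopifnot(n_per_archetype >= 1)
  clinical <- generate_clinical(n_per_archetype, seed = seed,
                                ga_effect = ga_effect)
  images <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(clinical))) {
    spec0 <- archetypes[[clinical$archetype[i]]]
    set.seed((as.numeric(seed) * 524287 + i * 2039) %% 2147483647)
    od_scale <- od_scale_means[[clinical$archetype[i]]] *
      exp(stats::rnorm(1, 0, od_scale_sd))
    spec0$od_extra <- spec0$od_extra * od_scale
    spec0$od_intra <- spec0$od_intra * od_scale
    for (j in seq_len(images_per_patient)) {
      sub_seed <- (as.numeric(seed) * 131071 + i * 613 + j * 7) %% 2147483647
      set.seed(sub_seed)
      jit <- stats::runif(2, 0.9, 1.1)
      spec <- spec0
      spec$extra_fraction <- min(spec0$extra_fraction * jit[1], 0.95)
      spec$intra_fraction <- min(spec0$intra_fraction * jit[2],
                                 0.95 - spec$extra_fraction)
      tis <- generate_tissue(shape, porosity = 1 - spec$tissue_fraction,
                             seed = sub_seed + 1L)
      tr <- place_staining(tis, spec, seed = sub_seed + 2L)
      img <- render_image(tr, spec, model, noise = noise,
                          seed = sub_seed + 3L)
      key <- sprintf("%s_%d", clinical$patient[i], j)
      images[[key]] <- img
      truth_rows[[key]] <- data.frame(
        patient = clinical$patient[i], image = j,
        archetype = spec0$name,
        tissue_fraction = tr$fractions[["tissue"]],
        extra_fraction = tr$fractions[["extra"]],
        intra_fraction = tr$fractions[["intra"]]
      )
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  out <- list(images = images, truth = truth, clinical = clinical,
              archetypes = archetypes)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(images))
      write_rgb_image(images[[key]], file.path(dir, paste0(key, ".tiff")))
    utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
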