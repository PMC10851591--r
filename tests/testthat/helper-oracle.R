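# Independent reference implementations used as oracles, written as plain
# per-pixel loops so they share no code path with the package.

# naive 12-parameter reference: explicit loops over pixels
naive_features <- function(intensity, tissue, low, high) {
  nT <- 0L; nL <- 0L; nH <- 0L
  vL <- integer(0); vH <- integer(0)
  for (i in seq_len(nrow(intensity))) {
    for (j in seq_len(ncol(intensity))) {
      if (!tissue[i, j]) next
      nT <- nT + 1L
      v <- intensity[i, j]
      if (v >= low) { nL <- nL + 1L; vL <- c(vL, v) }
      if (v >= high) { nH <- nH + 1L; vH <- c(vH, v) }
    }
  }
  mode_of <- function(v) {
    if (length(v) == 0L) return(0)
    counts <- table(v)
    best <- max(counts)
    min(as.integer(names(counts)[counts == best]))
  }
  st <- function(v) {
    if (length(v) == 0L) c(0, 0, 0)
    else c(mean(v), mode_of(v), median(v))
  }
  sL <- st(vL); sH <- st(vH)
  list(
    mean_dab_total = sL[1], mode_dab_total = sL[2],
    median_dab_total = sL[3], pct_area_total = nL / nT,
    mean_intra = sH[1], mode_intra = sH[2], median_intra = sH[3],
    pct_area_intra = nH / nT, pct_area_extra = (nL - nH) / nT,
    mean_intensity_tissue = sum(vL) / nT,
    mean_intensity_intra_tissue = sum(vH) / nT,
    intra_extra_ratio = nH / max(nL - nH, 1L)
  )
}

random_dab_map <- function(n = 32, p_tissue = 0.8) {
  intensity <- matrix(sample(0:255, n * n, replace = TRUE), n, n)
  tissue <- matrix(runif(n * n) < p_tissue, n, n)
  if (!any(tissue)) tissue[1, 1] <- TRUE
  new_dab_map(intensity, tissue)
}

# uniform-colour RGB array
flat_rgb <- function(rgb, h = 4, w = 4) {
  arr <- array(0, dim = c(h, w, 3))
  for (k in 1:3) arr[, , k] <- rgb[k]
  arr
}

# archetype -> expression group number used in PNA stratification
archetype_groups <- function(clinical) {
  map <- c(extracellular = 1L, low = 2L, intracellular = 3L, both = 4L)
  stats::setNames(map[clinical$archetype], clinical$patient)
}

quantify_cohort <- function(cohort, cfg = calibrate_thresholds()) {
  feats <- do.call(rbind, lapply(names(cohort$images), function(k) {
    f <- quantify_image(cohort$images[[k]], cfg)
    f$patient <- sub("_[0-9]+$", "", k)
    f
  }))
  aggregate_patients(feats)
}
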