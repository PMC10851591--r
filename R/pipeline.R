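#' Read a project configuration from YAML
#'
#' A project config freezes every analysis choice — stain vectors,
#' thresholds, saturation concentration, clustering settings, output
#' locations and the seed — so a run is fully reproducible from the file.
#' Missing keys fall back to package defaults.
#'
#' @param path YAML file; see \code{\link{default_config}} for the keys.
#' @return list of class \code{project_config}.
#' @export
read_project_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

#' Default project configuration
#' @return list of class \code{project_config} with keys:
#'   \code{image_dir}, \code{clinical_path}, \code{output_dir},
#'   \code{stain_hematoxylin}, \code{stain_dab} (length-3 OD vectors),
#'   \code{low}, \code{high}, \code{tissue_threshold}, \code{c_max},
#'   \code{distance}, \code{linkage}, \code{k}, \code{tau},
#'   \code{seed}.
#' @export
default_config <- function() {
  m <- stain_model()
  cal <- calibrate_thresholds()
  structure(list(
    image_dir = ".", clinical_path = NULL, output_dir = "output",
    stain_hematoxylin = unname(m$stains["hematoxylin", ]),
    stain_dab = unname(m$stains["dab", ]),
    low = cal$low, high = cal$high,
    tissue_threshold = cal$tissue_threshold,
    c_max = 2.0,
    distance = "uncentered", linkage = "average", k = 4L, tau = 0.5,
    seed = 1L
  ), class = "project_config")
}

validate_config <- function(cfg) {
  threshold_config(cfg$low, cfg$high, cfg$tissue_threshold)  # range checks
  if (cfg$c_max <= 0) stop("c_max must be positive", call. = FALSE)
  if (cfg$k < 1) stop("k must be at least 1", call. = FALSE)
  class(cfg) <- "project_config"
  cfg
}

config_stain_model <- function(cfg) {
  stain_model(cfg$stain_hematoxylin, cfg$stain_dab)
}

config_thresholds <- function(cfg) {
  threshold_config(cfg$low, cfg$high, cfg$tissue_threshold)
}

# image files named <patient>_<index>.<ext>
parse_image_name <- function(files) {
  base <- tools::file_path_sans_ext(basename(files))
  patient <- sub("_[0-9]+$", "", base)
  index <- suppressWarnings(as.integer(sub("^.*_", "", base)))
  data.frame(file = files, patient = patient, image = index,
             stringsAsFactors = FALSE)
}

#' Quantify every image of a project
#'
#' Reads each image under \code{cfg$image_dir} (TIFF/PNG, named
#' \code{<patient>_<index>}), runs stain separation and dual-threshold
#' quantification, aggregates per patient, and writes
#' \code{image_features.tsv}, \code{patient_features.tsv} and a run
#' manifest. Images that fail (unreadable file, no tissue) are recorded in
#' the manifest with their error message, not silently dropped.
#'
#' @param cfg a \code{project_config}.
#' @return list with \code{image_features}, \code{patient_features} and
#'   \code{manifest} (per-image status data.frame).
#' @export
run_quantify <- function(cfg) {
  files <- sort(list.files(cfg$image_dir, pattern = "\\.(tiff?|png)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (length(files) == 0L)
    stop("no images found under ", cfg$image_dir, call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config_stain_model(cfg)
  thr <- config_thresholds(cfg)
  info <- parse_image_name(files)

  rows <- list(); status <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    res <- tryCatch({
      img <- read_rgb_image(info$file[i])
      feats <- quantify_image(img, thr, model, cfg$c_max)
      feats$patient <- info$patient[i]
      feats$image <- info$image[i]
      rows[[length(rows) + 1L]] <- feats
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    status[i] <- res
  }
  manifest <- data.frame(file = basename(info$file),
                         patient = info$patient, image = info$image,
                         status = status, stringsAsFactors = FALSE)
  if (length(rows) == 0L) stop("every image failed quantification",
                               call. = FALSE)
  image_features <- do.call(rbind, rows)
  id_cols <- c("patient", "image")
  image_features <- image_features[, c(id_cols,
                                       setdiff(names(image_features),
                                               id_cols))]
  patient_features <- aggregate_patients(image_features)

  write_feature_table(image_features,
                      file.path(cfg$output_dir, "image_features.tsv"))
  write_feature_table(patient_features,
                      file.path(cfg$output_dir, "patient_features.tsv"))
  manifest_out <- manifest
  utils::write.table(manifest_out,
                     file.path(cfg$output_dir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("version: %s",
                       as.character(utils::packageVersion("dabquant"))),
               sprintf("seed: %d", cfg$seed),
               sprintf("config_hash: %s",
                       config_hash(cfg))),
             file.path(cfg$output_dir, "run_manifest.txt"))
  list(image_features = image_features,
       patient_features = patient_features, manifest = manifest)
}

config_hash <- function(cfg) {
  # stable fingerprint of the frozen analysis choices; enough to detect a
  # config change between runs without a cryptographic dependency
  s <- paste(utils::capture.output(utils::str(unclass(cfg))),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %%
            .Machine$integer.max)
}

#' Cluster a patient feature table into phenotype groups
#'
#' Standardizes, clusters both dimensions, cuts the patient tree at
#' \code{cfg$k}, labels phenotypes, and writes the group-assignment TSV
#' plus CDT/GTR/ATR files (and a heatmap PNG when requested).
#'
#' @param cfg a \code{project_config}.
#' @param patient_features per-patient feature data.frame.
#' @param heatmap logical; also write \code{heatmap.png}.
#' @return list with \code{clustering}, \code{groups} (integer vector),
#'   \code{phenotypes} (per group) and \code{assignments} (data.frame).
#' @export
run_cluster <- function(cfg, patient_features, heatmap = FALSE) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  z <- standardize(patient_features)
  cl <- hierarchical_cluster(z, distance = cfg$distance,
                             linkage = cfg$linkage)
  groups <- cut_groups(cl, k = cfg$k)
  phen <- label_phenotypes(groups, z, tau = cfg$tau)
  assignments <- data.frame(patient = names(groups),
                            group = unname(groups),
                            phenotype = unname(phen[as.character(groups)]),
                            stringsAsFactors = FALSE)
  utils::write.table(assignments,
                     file.path(cfg$output_dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_treeview(cl, file.path(cfg$output_dir, "clustered"))
  if (heatmap) plot_heatmap(cl, file.path(cfg$output_dir, "heatmap.png"))
  list(clustering = cl, groups = groups, phenotypes = phen,
       assignments = assignments)
}

#' Group statistics, PNA stratification and cohort summary
#'
#' Produces the statistics report: Pearson correlations between the 12
#' parameters and the numeric clinical covariates, per-parameter one-way
#' ANOVA with Bonferroni pairwise tests across the expression groups, the
#' A-D postnatal-age stratification with the C-vs-D gestational-age
#' t-test, and the cohort demographic summary. Written as
#' \code{statistics.tsv} blocks plus a readable \code{statistics.txt}.
#'
#' @param cfg a \code{project_config}.
#' @param patient_features per-patient feature data.frame.
#' @param groups named group vector from \code{\link{run_cluster}}.
#' @param clinical clinical data.frame (see
#'   \code{\link{read_clinical_table}}).
#' @return list with \code{correlation}, \code{anova} (per parameter),
#'   \code{strata}, \code{cvd_ttest} and \code{summary}.
#' @export
run_stats <- function(cfg, patient_features, groups, clinical) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  unmatched <- setdiff(patient_features$patient, clinical$patient)
  if (length(unmatched))
    warning("patients without clinical record: ",
            paste(unmatched, collapse = ", "))
  merged <- merge(patient_features, clinical, by = "patient")

  clin_numeric <- intersect(c("ga_weeks", "birth_weight_g", "pna_days",
                              "pma_weeks"), names(merged))
  corr <- pearson_matrix(merged[, c(feature_names(), clin_numeric)])

  grp <- groups[merged$patient]
  anovas <- lapply(feature_names(), function(fn) {
    samples <- split(merged[[fn]], grp)
    samples <- samples[vapply(samples, length, 0L) >= 2L]
    if (length(samples) >= 3L) anova_bonferroni(samples) else NULL
  })
  names(anovas) <- feature_names()

  strata <- stratify_pna(groups, clinical)
  merged$stratum <- strata[merged$patient]
  cvd <- NULL
  if ("ga_weeks" %in% names(merged)) {
    ga_c <- merged$ga_weeks[merged$stratum == "C"]
    ga_d <- merged$ga_weeks[merged$stratum == "D"]
    if (length(ga_c) >= 2L && length(ga_d) >= 2L) cvd <- ttest(ga_c, ga_d)
  }
  summ <- cohort_summary(clinical)

  report <- c(
    "== Cohort summary ==",
    utils::capture.output(print(summ)),
    "",
    "== Pearson correlations flagged at |r| > 0.7 ==",
    utils::capture.output(print(which(corr$flagged, arr.ind = TRUE))),
    "",
    "== Group A-D stratification ==",
    utils::capture.output(print(table(strata))),
    "",
    "== Gestational age, Group C vs D (Student's t) ==",
    if (is.null(cvd)) "not estimable (fewer than 2 patients per stratum)"
    else sprintf("t = %.3f, df = %d, p = %.4g", cvd$t, round(cvd$df),
                 cvd$p)
  )
  writeLines(report, file.path(cfg$output_dir, "statistics.txt"))
  utils::write.table(summ, file.path(cfg$output_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(patient = names(strata),
                                stratum = unname(strata)),
                     file.path(cfg$output_dir, "strata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(corr$r, 4),
                     file.path(cfg$output_dir, "correlation_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  list(correlation = corr, anova = anovas, strata = strata,
       cvd_ttest = cvd, summary = summ)
}

#' Run the complete pipeline: quantify, cluster, statistics
#'
#' @param cfg a \code{project_config} whose \code{image_dir} holds the
#'   images and whose \code{clinical_path} points at the clinical TSV.
#' @return list with the results of the three stages.
#' @export
run_all <- function(cfg) {
  q <- run_quantify(cfg)
  cl <- run_cluster(cfg, q$patient_features)
  clinical <- read_clinical_table(cfg$clinical_path)
  st <- run_stats(cfg, q$patient_features, cl$groups, clinical)
  list(quantify = q, cluster = cl, stats = st)
}
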