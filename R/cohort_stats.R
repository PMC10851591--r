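#' Two-sample Student's t-test (pooled variance)
#'
#' Classical pooled-variance two-sided t-test, with explicit conventions
#' for the degenerate zero-variance cases: equal means give t = 0, p = 1;
#' unequal means with zero pooled variance are reported as p = 0 with a
#' \code{degenerate} flag. A Welch test is available via
#' \code{pooled = FALSE}.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param pooled use the pooled-variance (Student) statistic; FALSE gives
#'   Welch.
#' @return list with \code{t}, \code{df}, \code{p} and \code{degenerate}.
#' @export
ttest <- function(a, b, pooled = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    df <- length(a) + length(b) - 2L
    if (mean(a) == mean(b))
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  res <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, degenerate = FALSE)
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' Global one-way ANOVA F-test across k groups followed by all pairwise
#' pooled t-tests; each pairwise p-value is multiplied by the number of
#' pairs (Bonferroni) and capped at 1.
#'
#' @param samples list of numeric vectors (>= 3 groups, each n >= 2).
#' @return list with \code{F}, \code{df}, \code{p} and a data.frame
#'   \code{pairwise} (group_a, group_b, t, p_raw, p_adj).
#' @export
anova_bonferroni <- function(samples) {
  if (length(samples) < 3L) stop("need at least 3 groups", call. = FALSE)
  if (any(vapply(samples, function(x) sum(!is.na(x)), 0L) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  y <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)),
              levels = names(samples))
  fit <- stats::anova(stats::lm(y ~ g))
  pairs <- utils::combn(names(samples), 2L)
  n_pairs <- ncol(pairs)
  pw <- apply(pairs, 2L, function(p) {
    tt <- ttest(samples[[p[1]]], samples[[p[2]]])
    c(t = tt$t, p_raw = tt$p)
  })
  pairwise <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                         t = pw["t", ], p_raw = pw["p_raw", ],
                         p_adj = pmin(pw["p_raw", ] * n_pairs, 1))
  list(F = fit$`F value`[1], df = fit$Df, p = fit$`Pr(>F)`[1],
       pairwise = pairwise)
}

#' Pairwise Pearson correlation matrix with high-correlation flags
#'
#' Correlations are computed on pairwise-complete observations; cells with
#' fewer than 3 complete pairs, or involving a constant column, are
#' reported as NA. Off-diagonal cells with |r| > \code{flag_threshold} are
#' flagged.
#'
#' @param data numeric data.frame or matrix (columns = variables).
#' @param flag_threshold absolute correlation above which a pair is
#'   flagged (default 0.7).
#' @return list with \code{r} (symmetric matrix, unit diagonal) and
#'   \code{flagged} (logical matrix).
#' @export
pearson_matrix <- function(data, flag_threshold = 0.7) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("all columns must be numeric", call. = FALSE)
  p <- ncol(m)
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
  # blank out cells with insufficient support
  obs <- crossprod(!is.na(m))
  r[obs < 3L] <- NA
  diag(r) <- 1
  flagged <- !is.na(r) & abs(r) > flag_threshold
  diag(flagged) <- FALSE
  list(r = r, flagged = flagged)
}

#' Stratify patients by phenotype pair and postnatal age at death
#'
#' The four expression groups are merged into a low-intracellular pair
#' (groups 1 and 2: extracellular-dominant and low) and a
#' high-intracellular pair (groups 3 and 4: intracellular-dominant and
#' both), then crossed with postnatal age (PNA) at death:
#' \itemize{
#'   \item A: low-intracellular pair, PNA < 1 day
#'   \item B: high-intracellular pair, PNA < 1 day
#'   \item C: low-intracellular pair, PNA 1-7 days
#'   \item D: high-intracellular pair, PNA 1-7 days
#' }
#' Patients who died after 7 days, or whose PNA is unknown, are excluded.
#' Day boundaries follow the reported binning: exactly 1 day and exactly
#' 7 days both fall in the 1-7 day bin.
#'
#' @param groups named integer vector of expression group labels (1..4),
#'   names are patient ids; alternatively a character vector of phenotype
#'   names ("extracellular", "low" = low pair; "intracellular", "both" =
#'   high pair).
#' @param clinical data.frame with \code{patient} and \code{pna_days}
#'   (NA = unknown).
#' @return named character vector mapping each patient to
#'   "A", "B", "C", "D" or "excluded".
#' @export
stratify_pna <- function(groups, clinical) {
  if (is.null(names(groups))) stop("groups must be named by patient id",
                                   call. = FALSE)
  high <- if (is.numeric(groups)) groups %in% c(3L, 4L)
          else groups %in% c("intracellular", "both")
  names(high) <- names(groups)
  pna <- stats::setNames(clinical$pna_days, clinical$patient)
  out <- vapply(names(groups), function(p) {
    x <- pna[[p]]
    if (is.null(x) || is.na(x) || x > 7) return("excluded")
    if (x < 1) { if (high[[p]]) "B" else "A" }
    else       { if (high[[p]]) "D" else "C" }
  }, character(1))
  out
}

#' Demographic and treatment summary of a clinical table
#'
#' Counts and percentages for sex, preterm/term status, postnatal-age
#' bins (< 1 day, 1-7 days, > 7 days) and steroid treatments. Percentages
#' are taken over the non-missing total of each variable and rounded
#' half-up: whole percent for demographics, one decimal for PNA bins and
#' treatment rates.
#'
#' @param clinical data.frame with columns \code{sex} ("F"/"M"),
#'   \code{preterm} (logical), \code{pna_days} (NA = unknown), and
#'   optionally \code{antenatal_steroids} / \code{postnatal_steroids}.
#' @return data.frame with columns variable, level, n, pct.
#' @export
cohort_summary <- function(clinical) {
  pct <- function(n, total, digits) {
    if (total == 0) 0 else round_half_up(100 * n / total, digits)
  }
  rows <- list()
  add <- function(variable, level, n, total, digits) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, n = n,
      pct = pct(n, total, digits))
  }
  if ("sex" %in% names(clinical)) {
    s <- clinical$sex[!is.na(clinical$sex)]
    add("sex", "female", sum(s == "F"), length(s), 0)
    add("sex", "male", sum(s == "M"), length(s), 0)
  }
  if ("preterm" %in% names(clinical)) {
    p <- clinical$preterm[!is.na(clinical$preterm)]
    add("maturity", "preterm", sum(p), length(p), 0)
    add("maturity", "term", sum(!p), length(p), 0)
  }
  if ("pna_days" %in% names(clinical)) {
    x <- clinical$pna_days[!is.na(clinical$pna_days)]
    add("pna_at_death", "<1 day", sum(x < 1), length(x), 1)
    add("pna_at_death", "1-7 days", sum(x >= 1 & x <= 7), length(x), 1)
    add("pna_at_death", ">7 days", sum(x > 7), length(x), 1)
  }
  for (tr in c("antenatal_steroids", "postnatal_steroids")) {
    if (tr %in% names(clinical)) {
      v <- clinical[[tr]][!is.na(clinical[[tr]])]
      add("treatment", tr, sum(v), length(v), 1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a clinical metadata table
#'
#' Tab-separated, one row per patient; the string in \code{na} (default
#' "NA") marks unknown values (typically unknown postnatal age).
#'
#' @param path TSV file with at least a \code{patient} column.
#' @param na missing-value token.
#' @return data.frame.
#' @export
read_clinical_table <- function(path, na = "NA") {
  utils::read.delim(path, na.strings = na, stringsAsFactors = FALSE)
}
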