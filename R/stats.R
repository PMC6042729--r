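# Study-level statistics: per-subject rates of change, exact Mann-Whitney
# group comparisons with Holm-Bonferroni familywise correction, Pearson
# correlations of imaging rates with clinical variables, and the
# standardised response mean (SRM).

#' Rate of change of a metric
#'
#' `(followup - baseline) / interval_years`, in metric units per year.
#'
#' @param baseline_value,followup_value Metric values.
#' @param interval_years Time to follow-up in years (> 0).
#' @return Rate of change (vectorized).
#' @export
rate_of_change <- function(baseline_value, followup_value, interval_years) {
  if (any(!is.finite(interval_years)) || any(interval_years <= 0))
    stop("interval_years must be > 0")
  (followup_value - baseline_value) / interval_years
}

#' Mann-Whitney U test (two-sided)
#'
#' U is reported as `min(U1, U2)` with midrank handling of ties. The p-value
#' is exact — computed from the full null distribution over all
#' `choose(n1+n2, n1)` group assignments — when `n1 + n2 <= 25` and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x_values,y_values Numeric samples, both nonempty.
#' @return List with `U`, `p`, `n1`, `n2`, `exact`.
#' @export
mann_whitney <- function(x_values, y_values) {
  x <- as.numeric(x_values[is.finite(x_values)])
  y <- as.numeric(y_values[is.finite(y_values)])
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (n1 + n2) <= 25L && !ties
  if (length(unique(c(x, y))) == 1L) {
    # completely tied samples: no evidence either way
    return(list(U = n1 * n2 / 2, p = 1, n1 = n1, n2 = n2, exact = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  u1 <- unname(wt$statistic)
  p <- wt$p.value
  if (is.na(p)) p <- 1   # degenerate tie structure under the normal approximation
  list(U = min(u1, n1 * n2 - u1), p = p, n1 = n1, n2 = n2, exact = use_exact)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and rejects `p_(i)` while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure. Flags are
#' returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Familywise error rate (default 0.05).
#' @return Logical rejection flags, same order as `p_values`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p, na.last = TRUE)
  reject <- logical(m)
  for (i in seq_len(m)) {
    pi <- p[ord[i]]
    if (is.na(pi) || pi > alpha / (m - i + 1)) break
    reject[ord[i]] <- TRUE
  }
  reject
}

#' Pearson correlation with t-based p-value
#'
#' @param x_values,y_values Numeric vectors, n >= 3, nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x_values, y_values) {
  keep <- is.finite(x_values) & is.finite(y_values)
  x <- x_values[keep]; y <- y_values[keep]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in a variable")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Standardised response mean
#'
#' `mean(change) / sd(change)` with the sample (n-1) standard deviation; the
#' conventional responsiveness index for change scores.
#'
#' @param change_scores Numeric vector of within-subject changes, n >= 2.
#' @return List with `srm`, `n`.
#' @export
srm <- function(change_scores) {
  ch <- change_scores[is.finite(change_scores)]
  if (length(ch) < 2L) stop("need at least 2 change scores")
  s <- stats::sd(ch)
  if (s == 0) stop("change scores are constant: SRM undefined")
  list(srm = mean(ch) / s, n = length(ch))
}

#' Assemble a long study table from per-subject metric tables
#'
#' @param metric_tables Nested list: `metric_tables[[subject_id]][[timepoint]]`
#'   is a [region_metrics_table()] data.frame, timepoints `baseline` /
#'   `followup`.
#' @param manifest Subject manifest data.frame.
#' @return Long data.frame: subject_id, group, timepoint, region, index,
#'   metric, value, interval_years.
#' @export
study_table <- function(metric_tables, manifest) {
  rows <- list()
  for (id in names(metric_tables)) {
    mrow <- manifest[manifest$subject_id == id, ]
    if (nrow(mrow) != 1L) stop("subject ", id, " missing from manifest")
    for (tp in c("baseline", "followup")) {
      tab <- metric_tables[[id]][[tp]]
      if (is.null(tab)) stop("subject ", id, " lacks timepoint ", tp)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, group = mrow$group, timepoint = tp,
        tab[c("region", "index", "metric", "value")],
        interval_years = mrow$interval_years, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.mw_family <- function(wide, manifest, alpha, iqr_type) {
  combos <- unique(wide[c("region", "index", "metric")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- wide$region == combos$region[i] & wide$index == combos$index[i] &
      wide$metric == combos$metric[i]
    d <- wide[sel, ]
    pat <- d$value[d$group == "patient"]
    con <- d$value[d$group == "control"]
    mw <- mann_whitney(pat, con)
    data.frame(region = combos$region[i], index = combos$index[i],
               metric = combos$metric[i],
               median_patient = stats::median(pat),
               iqr_patient = stats::IQR(pat, type = iqr_type),
               median_control = stats::median(con),
               iqr_control = stats::IQR(con, type = iqr_type),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$significant <- holm_bonferroni(res$p, alpha)
  res$family_size <- nrow(res)
  res
}

#' Run the full group analysis
#'
#' Reproduces the study's statistical design on a long study table:
#' \itemize{
#' \item baseline patient-vs-control Mann-Whitney comparisons of all
#'   region x index x metric combinations (one Holm-Bonferroni family);
#' \item the same comparisons on per-subject rates of change (a second
#'   family);
#' \item Pearson correlations of the rates of metrics whose rate comparison
#'   survived correction against CAG repeats, disease duration, and
#'   IACRS/ICARS rates of change, in patients (a third family);
#' \item SRM of the clinical scales and of the passing metrics (patients'
#'   raw change scores).
#' }
#'
#' @param st Long study table from [study_table()].
#' @param manifest Subject manifest data.frame.
#' @param alpha Familywise significance threshold (default 0.05).
#' @param iqr_type Quartile interpolation rule passed to [stats::IQR()]
#'   (default 7, the R default; the emulated study does not state its rule).
#' @return List with data.frames `baseline`, `rate`, `correlations`, `srm`,
#'   plus `alpha`.
#' @export
run_group_analysis <- function(st, manifest, alpha = 0.05, iqr_type = 7) {
  need <- c("subject_id", "group", "timepoint", "region", "index", "metric",
            "value", "interval_years")
  if (!all(need %in% names(st))) stop("study table lacks required columns")

  base <- st[st$timepoint == "baseline", ]
  fup <- st[st$timepoint == "followup", ]
  key <- function(d) paste(d$subject_id, d$region, d$index, d$metric, sep = "\r")
  fup <- fup[match(key(base), key(fup)), ]
  if (any(is.na(fup$value))) stop("incomplete study table: missing follow-up cells")
  rates <- base
  rates$value <- rate_of_change(base$value, fup$value, base$interval_years)

  baseline_res <- .mw_family(base, manifest, alpha, iqr_type)
  rate_res <- .mw_family(rates, manifest, alpha, iqr_type)

  pass <- rate_res[rate_res$significant, c("region", "index", "metric")]
  pat <- manifest[manifest$group == "patient", ]
  clin <- data.frame(
    subject_id = pat$subject_id,
    cag_repeats = pat$cag_repeats,
    disease_duration = pat$disease_duration_years,
    iacrs_rate = rate_of_change(pat$iacrs_baseline, pat$iacrs_followup, pat$interval_years),
    icars_rate = rate_of_change(pat$icars_baseline, pat$icars_followup, pat$interval_years),
    stringsAsFactors = FALSE)

  cor_rows <- list()
  srm_rows <- list()
  for (scale in c("iacrs", "icars")) {
    chg <- pat[[paste0(scale, "_followup")]] - pat[[paste0(scale, "_baseline")]]
    sr <- tryCatch(srm(chg), error = function(e) list(srm = NA_real_, n = sum(is.finite(chg))))
    srm_rows[[length(srm_rows) + 1L]] <- data.frame(
      name = toupper(scale), srm = sr$srm, n = sr$n, stringsAsFactors = FALSE)
  }
  if (nrow(pass) > 0L) {
    for (i in seq_len(nrow(pass))) {
      sel <- rates$region == pass$region[i] & rates$index == pass$index[i] &
        rates$metric == pass$metric[i] & rates$group == "patient"
      d <- rates[sel, c("subject_id", "value")]
      d <- d[match(clin$subject_id, d$subject_id), ]
      nm <- paste(pass$region[i], pass$index[i], pass$metric[i], sep = ".")
      for (cv in c("cag_repeats", "disease_duration", "iacrs_rate", "icars_rate")) {
        pc <- tryCatch(pearson_correlation(d$value, clin[[cv]]),
                       error = function(e) list(r = NA_real_, p = NA_real_, n = NA_integer_))
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          metric = nm, clinical = cv, r = pc$r, p = pc$p, n = pc$n,
          stringsAsFactors = FALSE)
      }
      selb <- base$region == pass$region[i] & base$index == pass$index[i] &
        base$metric == pass$metric[i] & base$group == "patient"
      bsel <- base[selb, ]
      fsel <- fup[selb, ]
      chg <- fsel$value - bsel$value
      sr <- tryCatch(srm(chg), error = function(e) list(srm = NA_real_, n = length(chg)))
      srm_rows[[length(srm_rows) + 1L]] <- data.frame(
        name = nm, srm = sr$srm, n = sr$n, stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(cor_rows)) {
    cr <- do.call(rbind, cor_rows)
    cr$significant <- holm_bonferroni(cr$p, alpha)
    cr$family_size <- nrow(cr)
    cr
  } else {
    data.frame(metric = character(), clinical = character(), r = numeric(),
               p = numeric(), n = integer(), significant = logical(),
               family_size = integer(), stringsAsFactors = FALSE)
  }

  list(baseline = baseline_res, rate = rate_res,
       correlations = correlations,
       srm = do.call(rbind, srm_rows),
       alpha = alpha)
}
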