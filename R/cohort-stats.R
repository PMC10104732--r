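#' SYNTAX risk grouping
#'
#' Partitions SYNTAX scores into the conventional tertile-style risk bands:
#' low `[0, 22]`, medium `[23, 32]`, high `>= 33`. Scores are defined on
#' integers; fractional inputs are rounded half-up before grouping.
#'
#' @param score Numeric vector of non-negative SYNTAX scores.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' syntax_group(c(0, 22, 23, 32, 33)) # low low medium medium high
#' @export
syntax_group <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score))) abort("`score` must be finite numeric.")
  if (any(score < 0)) abort("SYNTAX scores must be non-negative.")
  sc <- floor(score + 0.5) # round half-up
  cut(sc,
    breaks = c(-0.5, 22.5, 32.5, Inf),
    labels = c("low", "medium", "high")
  )
}

#' Vessel inclusion filter for score calculation
#'
#' Keeps vessels with diameter strictly greater than 1.5 mm and stenosis
#' strictly greater than 50% diameter reduction — both boundaries are
#' exclusive. Row order is preserved.
#'
#' @param vessels Data frame with numeric columns `diameter` (mm) and
#'   `stenosis` (percent, 0-100).
#' @param min_diameter,min_stenosis Exclusive lower bounds.
#' @return The included subset as a tibble.
#' @export
vessel_filter <- function(vessels, min_diameter = 1.5, min_stenosis = 50) {
  if (!is.data.frame(vessels) || !all(c("diameter", "stenosis") %in% names(vessels))) {
    abort("`vessels` must have `diameter` and `stenosis` columns.")
  }
  if (any(vessels$diameter <= 0)) abort("vessel diameters must be positive.")
  if (any(vessels$stenosis < 0 | vessels$stenosis > 100)) {
    abort("stenosis must be a percentage in [0, 100].")
  }
  dplyr::filter(
    as_tibble(vessels),
    .data$diameter > min_diameter, .data$stenosis > min_stenosis
  )
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson correlation between two variables, with the two-sided
#' p-value from the t distribution on `n - 2` degrees of freedom and a 95%
#' confidence interval via the Fisher z transform (as [stats::cor.test()]
#' computes them).
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`, finite, each with
#'   positive variance.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `statistic`, `p.value`, `n`.
#' @export
pearson_r <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 4L) abort("need n >= 4 observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("inputs must be finite.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("undefined correlation: a variable has zero variance.")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  tibble(
    estimate = unname(ct$estimate),
    conf.low = ct$conf.int[1],
    conf.high = ct$conf.int[2],
    statistic = unname(ct$statistic),
    p.value = ct$p.value,
    n = length(x)
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test): the ratio
#' of between-group to within-group mean squares, with the p-value from the
#' F distribution.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (factor or coercible), `>= 2` groups with
#'   `>= 2` values each.
#' @return One-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p.value`.
#' @export
anova_oneway <- function(values, groups) {
  if (length(values) != length(groups)) abort("`values` and `groups` lengths differ.")
  g <- factor(groups)
  if (nlevels(g) < 2L) abort("need at least 2 groups.")
  if (any(table(g) < 2L)) abort("every group needs at least 2 values.")
  if (stats::sd(values) == 0) abort("F undefined: all values identical across groups.")
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  tibble(
    statistic = unname(ft$statistic),
    df_between = unname(ft$parameter[1]),
    df_within = unname(ft$parameter[2]),
    p.value = ft$p.value
  )
}

#' Pearson chi-square test of independence
#'
#' Pearson's chi-square statistic on a two-way contingency table with
#' `(r - 1)(c - 1)` degrees of freedom, without continuity correction.
#'
#' @param table A matrix (or table) of non-negative counts with no zero
#'   row/column margin.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @export
chi_square <- function(table) {
  tb <- as.matrix(table)
  if (any(tb < 0)) abort("counts must be non-negative.")
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
    abort("zero marginal: every row and column needs a positive total.")
  }
  # chisq.test warns when expected counts are small; the asymptotic caveat is
  # documented here rather than surfaced on every call
  ct <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = ct$p.value
  )
}

#' Diagnostic performance of FFR predictions at a cutoff
#'
#' Dichotomises predicted FFR at the ischemia cutoff (positive = FFR `<=`
#' cutoff, conventionally 0.80), cross-tabulates against the reference
#' truth, and reports accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`.
#'
#' @param ffr Numeric vector of predicted FFR values.
#' @param truth Logical (or 0/1) vector: reference-standard ischemia.
#' @param cutoff Ischemia cutoff on FFR (default 0.80).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `cutoff`.
#' @export
diagnostic_metrics <- function(ffr, truth, cutoff = 0.80) {
  if (!length(ffr)) abort("empty input.")
  if (length(ffr) != length(truth)) abort("`ffr` and `truth` lengths differ.")
  truth <- as.logical(truth)
  if (any(is.na(truth)) || any(!is.finite(ffr))) abort("inputs must be finite/complete.")
  pos <- ffr <= cutoff
  tp <- sum(pos & truth)
  fp <- sum(pos & !truth)
  tn <- sum(!pos & !truth)
  fn <- sum(!pos & truth)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(ffr),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    cutoff = cutoff
  )
}

#' ROC curve and AUC
#'
#' Sweeps every unique score as a threshold (higher score = more positive;
#' pass `-ffr` or set `direction = "<"` for markers where low values
#' indicate disease), builds the ROC points, and integrates the AUC by the
#' trapezoidal rule — which equals the Mann-Whitney concordance probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or 0/1) class labels; both classes must occur.
#' @param direction `">"` (default): larger scores indicate the positive
#'   class; `"<"`: smaller scores do.
#' @return A `roc_result`: list with `roc` (tibble `threshold`, `tpr`,
#'   `fpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, direction = c(">", "<")) {
  direction <- match.arg(direction)
  if (length(scores) != length(labels)) abort("`scores` and `labels` lengths differ.")
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) abort("both classes must be present.")
  if (direction == "<") scores <- -scores
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  roc <- tibble(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  structure(list(roc = roc, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f over %d thresholds\n", x$auc, nrow(x$roc) - 1L))
  invisible(x)
}

#' Per-group event incidence with chi-square comparison
#'
#' Crude MACCE incidence per SYNTAX group over the follow-up window, with
#' the overall chi-square test of homogeneity and all pairwise group
#' contrasts. Pairwise p-values are reported unadjusted by default, as is
#' common in three-group clinical tables; set `adjust = "bonferroni"` for a
#' corrected version.
#'
#' @param cohort Data frame with an event flag and a grouping column (as
#'   from [simulate_cohort()]).
#' @param group,event Column names (strings) of the grouping factor and the
#'   logical event flag.
#' @param adjust `"none"` (default) or `"bonferroni"` for the pairwise
#'   p-values.
#' @return A list: `rates` (tibble `group`, `n`, `events`, `rate`),
#'   `overall` (chi-square tibble or `NULL` when degenerate), `pairwise`
#'   (tibble of contrasts), `degenerate` (logical: no events or a single
#'   event level).
#' @export
group_event_rates <- function(cohort, group = "syntax_group", event = "macce",
                              adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!all(c(group, event) %in% names(cohort))) {
    abort(sprintf("cohort must contain `%s` and `%s` columns.", group, event))
  }
  g <- factor(cohort[[group]])
  ev <- as.logical(cohort[[event]])
  if (any(table(g) == 0)) warn("empty group present.")
  rates <- tibble(
    group = levels(g),
    n = as.integer(table(g)),
    events = as.integer(tapply(ev, g, sum, default = 0L)),
  ) |> dplyr::mutate(rate = .data$events / .data$n)

  degenerate <- length(unique(ev)) < 2L
  overall <- NULL
  pairwise <- tibble(
    group1 = character(), group2 = character(),
    statistic = numeric(), p.value = numeric()
  )
  if (!degenerate) {
    overall <- chi_square(table(g, ev))
    combs <- utils::combn(levels(g), 2)
    pw <- purrr::map(seq_len(ncol(combs)), function(i) {
      sel <- g %in% combs[, i]
      tb <- table(droplevels(g[sel]), ev[sel])
      if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
        return(tibble(
          group1 = combs[1, i], group2 = combs[2, i],
          statistic = NA_real_, p.value = NA_real_
        ))
      }
      cs <- chi_square(tb)
      tibble(
        group1 = combs[1, i], group2 = combs[2, i],
        statistic = cs$statistic, p.value = cs$p.value
      )
    })
    pairwise <- dplyr::bind_rows(pw)
    if (adjust == "bonferroni") {
      pairwise$p.value <- stats::p.adjust(pairwise$p.value, method = "bonferroni")
    }
  }
  list(rates = rates, overall = overall, pairwise = pairwise, degenerate = degenerate)
}
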