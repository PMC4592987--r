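# muffle lm's "essentially perfect fit" warning; degenerate (zero-residual)
# series are already handled explicitly by the callers
.quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Low-expression filter
#'
#' A gene passes if its mean log10 FPKM across all samples exceeds the cutoff
#' (strict `>`). The default cutoff of -2 rejects extremely low-expressing
#' and undetected genes.
#'
#' @param tcm An absolute-scale [time_course_matrix()].
#' @param cutoff Cutoff on the gene's mean log10 FPKM (default -2).
#' @return Named logical vector, one entry per gene.
#' @export
expression_filter <- function(tcm, cutoff = -2) {
  stopifnot(inherits(tcm, "time_course_matrix"))
  if (tcm$scale != "absolute")
    stop("expression filter is undefined on t0-normalized data")
  rowMeans(tcm$values) > cutoff
}

#' One-way ANOVA of expression on time point
#'
#' Fixed-effects F-test with time point as the grouping factor, comparing
#' within-time-point variation against between-time-point variation. Genes
#' with a significant time effect (`p < alpha`, conventionally 0.05) are
#' rejected from the reference-gene pool; no multiple-testing adjustment is
#' applied across genes since the screen deliberately errs toward rejection.
#'
#' @param x Numeric series of log-expression values.
#' @param time Time point of each value (hours).
#' @return The F-test p-value. A series with zero total variance returns 1.
#' @export
anova_time <- function(x, time) {
  if (length(x) != length(time)) stop("`x` and `time` lengths differ")
  grp <- factor(time)
  if (nlevels(grp) < 2) stop("need at least 2 distinct time points")
  if (all(table(grp) < 2))
    stop("no replication at any time point; within-group variance undefined")
  if (stats::var(x) == 0) return(1)
  fit <- stats::lm(x ~ grp)
  # near-noiseless genes trip lm's perfect-fit warning; the F-test is still
  # well defined here (zero-variance series are handled above)
  tab <- .quiet_perfect_fit(stats::anova(fit))
  unname(tab[["Pr(>F)"]][1])
}

#' Linear regression of expression on time with prediction intervals
#'
#' Ordinary least squares of log10 FPKM on time over all replicate points,
#' plus a prediction (or confidence) interval for a new observation at each
#' distinct time point:
#' \deqn{\hat y_i \pm t_{(1+level)/2,\,n-2} \; s \sqrt{1 + 1/n + (t_i - \bar t)^2 / S_{tt}}}
#' (drop the leading 1 under the square root for the confidence variant).
#'
#' @param x Numeric series of log-expression values (>= 3 points).
#' @param time Time of each value in hours (>= 2 distinct values).
#' @param level Interval coverage (default 0.95).
#' @param interval `"prediction"` (default) or `"confidence"`.
#' @return An object of class `regression_fit`: `slope`, `intercept`,
#'   `sigma` (residual SD), `n`, `t_mean`, `S_tt`, `level`, `interval`, and
#'   `bounds`, a data frame with `time`, `fit`, `lower`, `upper` per distinct
#'   time point.
#' @export
fit_regression_pi <- function(x, time, level = 0.95,
                              interval = c("prediction", "confidence")) {
  interval <- match.arg(interval)
  if (length(x) != length(time)) stop("`x` and `time` lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 points (n - 2 residual df)")
  if (length(unique(time)) < 2) stop("need at least 2 distinct time points")
  if (!(level > 0 && level < 1)) stop("`level` must be in (0, 1)")
  fit <- stats::lm(x ~ time)
  s <- .quiet_perfect_fit(summary(fit))$sigma
  t_mean <- mean(time)
  S_tt <- sum((time - t_mean)^2)
  ti <- sort(unique(time))
  yhat <- stats::coef(fit)[1] + stats::coef(fit)[2] * ti
  extra <- if (interval == "prediction") 1 else 0
  half <- stats::qt((1 + level) / 2, df = n - 2) * s *
    sqrt(extra + 1 / n + (ti - t_mean)^2 / S_tt)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 sigma = s, n = n, t_mean = t_mean, S_tt = S_tt,
                 level = level, interval = interval,
                 bounds = data.frame(time = ti, fit = unname(yhat),
                                     lower = unname(yhat - half),
                                     upper = unname(yhat + half))),
            class = "regression_fit")
}

#' Prediction-interval ranking score (PIRS)
#'
#' Scores a gene's expression stability as the sum, over distinct time
#' points, of the absolute deviations of the regression prediction-interval
#' bounds from the gene's overall mean expression:
#' \deqn{PIRS = \sum_i \left( |U_i - m| + |L_i - m| \right)}
#' where `m` is the mean of all observed log values. Flat, low-noise genes
#' score near 0; lower is more stable. The alternative reading that sums the
#' interval widths `|U_i - L_i|` is available via `formula = "width"`.
#'
#' @param fit A [fit_regression_pi()] result.
#' @param x The observed log-expression values the fit was built from.
#' @param formula `"deviation"` (default, both bounds against the mean) or
#'   `"width"` (sum of interval widths).
#' @return A list: `pirs`, `mean_expr`, `bounds` (the fit's bounds with the
#'   per-time-point contribution attached).
#' @export
pirs_score <- function(fit, x, formula = c("deviation", "width")) {
  formula <- match.arg(formula)
  stopifnot(inherits(fit, "regression_fit"))
  m <- mean(x)
  b <- fit$bounds
  contrib <- if (formula == "deviation") abs(b$upper - m) + abs(b$lower - m)
             else abs(b$upper - b$lower)
  b$contribution <- contrib
  list(pirs = sum(contrib), mean_expr = m, bounds = b)
}

#' SD and relative-SD stability statistics
#'
#' The independent stability analysis: per-gene standard deviation of the log
#' values and its ratio to the absolute mean (RSD). Genes whose SD is at most
#' `sd_fraction` of the absolute mean log10 FPKM (default 0.5%) are flagged
#' as candidates.
#'
#' @param tcm An absolute-scale [time_course_matrix()].
#' @param sd_fraction Candidate threshold as a fraction of `|mean|`
#'   (default 0.005).
#' @return Data frame: `gene_id`, `mean_expr`, `sd`, `rsd` (`NA` when the
#'   mean is 0), `candidate`, `reason` (`NA` or `"zero mean"`).
#' @export
sd_rsd <- function(tcm, sd_fraction = 0.005) {
  stopifnot(inherits(tcm, "time_course_matrix"))
  if (tcm$scale != "absolute")
    stop("SD/RSD statistics are defined on the absolute scale")
  m <- rowMeans(tcm$values)
  s <- apply(tcm$values, 1, stats::sd)
  zero_mean <- m == 0
  rsd <- ifelse(zero_mean, NA_real_, s / abs(m))
  data.frame(gene_id = rownames(tcm$values), mean_expr = m, sd = s, rsd = rsd,
             candidate = !zero_mean & s <= sd_fraction * abs(m),
             reason = ifelse(zero_mean, "zero mean", NA_character_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-course SD/RSD candidate intersection
#'
#' Keeps genes flagged as SD candidates in the replicate-averaged course and
#' in at least one of the individual courses.
#'
#' @param courses List of absolute-scale [time_course_matrix()] objects, the
#'   individual courses.
#' @param averaged The averaged course.
#' @param sd_fraction Passed to [sd_rsd()].
#' @return Character vector of gene IDs (possibly empty).
#' @export
cross_course_candidates <- function(courses, averaged, sd_fraction = 0.005) {
  if (length(courses) < 1) stop("need at least one individual course")
  cand <- function(tcm) {
    tab <- sd_rsd(tcm, sd_fraction)
    tab$gene_id[tab$candidate]
  }
  avg_cand <- cand(averaged)
  indiv <- unique(unlist(lapply(courses, cand)))
  sort(intersect(avg_cand, indiv))
}

#' Jaccard similarity of two top-k ranked gene lists
#'
#' @param rank_a,rank_b Ordered gene-ID vectors (best first).
#' @param k Number of leading genes compared.
#' @return `|top-k(a) intersect top-k(b)| / |top-k(a) union top-k(b)|`.
#' @export
jaccard_topk <- function(rank_a, rank_b, k) {
  if (k <= 0) stop("`k` must be positive")
  if (k > min(length(rank_a), length(rank_b)))
    stop("`k` exceeds a ranking's length")
  a <- utils::head(rank_a, k)
  b <- utils::head(rank_b, k)
  length(intersect(a, b)) / length(union(a, b))
}

#' Top genes per expression quintile
#'
#' Splits genes into five equal-frequency bins by mean expression and
#' returns, from each bin, the `per_quintile` genes with the lowest PIRS, so
#' that the selected reference candidates span the expression range. Ties
#' (in expression at bin boundaries or in PIRS) are broken by gene ID.
#'
#' @param scores Data frame with columns `gene_id`, `mean_expr`, `pirs`
#'   (e.g. a [stability_report()] restricted to the genes to rank).
#' @param per_quintile Genes reported per quintile (default 2).
#' @param scale Scale of the dataset the scores came from; must be
#'   `"absolute"` — quintiles of expression are undefined for t0-normalized
#'   data, where a top-n overall report should be used instead.
#' @return Data frame: `gene_id`, `quintile` (1 = lowest expression),
#'   `mean_expr`, `pirs`, ordered by quintile then PIRS.
#' @export
quintile_report <- function(scores, per_quintile = 2, scale = "absolute") {
  if (scale != "absolute")
    stop("quintiles are undefined on a relative-scale dataset; report top-n overall")
  required <- c("gene_id", "mean_expr", "pirs")
  if (!all(required %in% names(scores)))
    stop("`scores` must have columns ", paste(required, collapse = ", "))
  n <- nrow(scores)
  if (n < 5) stop("need at least 5 genes to form quintiles")
  ord <- order(scores$mean_expr, scores$gene_id)
  # equal-frequency bins: first bins take the extra genes when n %% 5 != 0
  sizes <- rep(n %/% 5, 5) + c(rep(1, n %% 5), rep(0, 5 - n %% 5))
  bin <- rep(seq_len(5), times = sizes)
  out <- do.call(rbind, lapply(seq_len(5), function(q) {
    rows <- scores[ord[bin == q], , drop = FALSE]
    rows <- rows[order(rows$pirs, rows$gene_id), , drop = FALSE]
    rows <- utils::head(rows, per_quintile)
    cbind(quintile = rep(q, nrow(rows)), rows)
  }))
  rownames(out) <- NULL
  out[, c("gene_id", "quintile", "mean_expr", "pirs")]
}

#' Per-dataset stability report: ENCAS filters plus PIRS and SD/RSD
#'
#' Runs the full per-dataset chain on one course: the expression cutoff, the
#' rhythmicity rejection (from a supplied screen or imported calls), the
#' per-gene time-effect ANOVA, then PIRS scoring of every gene along with the
#' SD/RSD statistics. Genes surviving all three filters form the ENCAS set
#' ("expressing, noncircadian, ANOVA selected"); PIRS ranks are assigned
#' within that set. For courses without replicates the ANOVA filter is
#' skipped (within-group variance is undefined), and rhythmicity is skipped
#' when no calls are supplied — both skips are recorded in the result's
#' attributes.
#'
#' @param tcm A [time_course_matrix()].
#' @param rhythm Optional rhythmicity calls: a data frame with `gene_id` and
#'   `is_rhythmic` (from [jtk_screen()] or [read_rhythm_calls()]). `NULL`
#'   skips the filter (all genes pass).
#' @param cutoff Expression cutoff on mean log10 FPKM (default -2); ignored
#'   (with the filter skipped) on relative-scale data.
#' @param anova_alpha Rejection level for the time-effect ANOVA (default
#'   0.05, strict `<`; no across-gene adjustment).
#' @param level Prediction-interval coverage for PIRS (default 0.95).
#' @param pirs_formula Passed to [pirs_score()].
#' @return Data frame with one row per gene: `gene_id`, `mean_expr`, `pirs`,
#'   `sd`, `rsd`, `passes_expression`, `passes_rhythm`, `passes_anova`,
#'   `is_encas`, `pirs_rank` (within ENCAS genes; `NA` otherwise), `quintile`
#'   (equal-frequency expression bin over all genes; `NA` on relative-scale
#'   data). Attribute `skipped` names any skipped filters.
#' @export
stability_report <- function(tcm, rhythm = NULL, cutoff = -2,
                             anova_alpha = 0.05, level = 0.95,
                             pirs_formula = "deviation") {
  stopifnot(inherits(tcm, "time_course_matrix"))
  genes <- rownames(tcm$values)
  time <- tcm$samples$time
  skipped <- character(0)
  absolute <- tcm$scale == "absolute"

  if (absolute) {
    passes_expr <- expression_filter(tcm, cutoff)
  } else {
    passes_expr <- rep(TRUE, length(genes))
    skipped <- c(skipped, "expression (relative scale)")
  }

  if (is.null(rhythm)) {
    passes_rhythm <- rep(TRUE, length(genes))
    skipped <- c(skipped, "rhythmicity (no calls supplied)")
  } else {
    idx <- match(genes, rhythm$gene_id)
    passes_rhythm <- ifelse(is.na(idx), TRUE, !rhythm$is_rhythmic[idx])
  }

  replicated <- any(table(time) >= 2)
  if (replicated) {
    anova_p <- apply(tcm$values, 1, anova_time, time = time)
    passes_anova <- !(anova_p < anova_alpha)
  } else {
    passes_anova <- rep(TRUE, length(genes))
    skipped <- c(skipped, "anova (no replicates)")
  }

  pirs <- numeric(length(genes))
  mean_expr <- numeric(length(genes))
  for (g in seq_along(genes)) {
    fit <- fit_regression_pi(tcm$values[g, ], time, level = level)
    sc <- pirs_score(fit, tcm$values[g, ], formula = pirs_formula)
    pirs[g] <- sc$pirs
    mean_expr[g] <- sc$mean_expr
  }

  sdtab <- if (absolute) sd_rsd(tcm) else
    data.frame(sd = apply(tcm$values, 1, stats::sd), rsd = NA_real_)

  is_encas <- passes_expr & passes_rhythm & passes_anova
  rank_vec <- rep(NA_integer_, length(genes))
  enc <- which(is_encas)
  rank_vec[enc[order(pirs[enc], genes[enc])]] <- seq_along(enc)

  quint <- rep(NA_integer_, length(genes))
  if (absolute && length(genes) >= 5) {
    n <- length(genes)
    ord <- order(mean_expr, genes)
    sizes <- rep(n %/% 5, 5) + c(rep(1, n %% 5), rep(0, 5 - n %% 5))
    quint[ord] <- rep(seq_len(5), times = sizes)
  }

  out <- data.frame(gene_id = genes, mean_expr = mean_expr, pirs = pirs,
                    sd = sdtab$sd, rsd = sdtab$rsd,
                    passes_expression = passes_expr,
                    passes_rhythm = passes_rhythm,
                    passes_anova = passes_anova,
                    is_encas = is_encas, pirs_rank = rank_vec,
                    quintile = quint,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
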