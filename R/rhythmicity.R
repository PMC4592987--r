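#' Kendall concordance statistic S and tau-b
#'
#' The pairwise-concordance statistic underlying JTK-style rhythmicity tests:
#' `S` is the number of concordant minus discordant pairs between a series and
#' a reference waveform; `tau` is the tie-corrected (tau-b) normalization.
#'
#' @param x Numeric series.
#' @param ref Reference series of the same length.
#' @return A list with elements `S` (integer) and `tau` (in \[-1, 1\]; 0 when
#'   either series is entirely tied).
#' @examples
#' kendall_s(c(1, 2, 3), c(1, 2, 3))  # S = 3, tau = 1
#' @export
kendall_s <- function(x, ref) {
  if (length(x) != length(ref))
    stop("`x` and `ref` must have the same length")
  if (length(x) < 3) stop("need at least 3 observations")
  n <- length(x)
  idx <- .pair_index(n)
  dx <- sign(x[idx$j] - x[idx$i])
  dr <- sign(ref[idx$j] - ref[idx$i])
  S <- sum(dx * dr)
  n0 <- n * (n - 1) / 2
  tx <- table(x); tr <- table(ref)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(tr * (tr - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  tau <- if (denom == 0) 0 else S / denom
  list(S = as.integer(S), tau = tau)
}

# upper-triangle pair indices (i < j) for a series of length n
.pair_index <- function(n) {
  cmb <- utils::combn(n, 2)
  list(i = cmb[1, ], j = cmb[2, ])
}

# all permutations of 1..n as an n! x n integer matrix; used only for small n
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[row:(row + nrow(sub) - 1), ] <- as.integer(block)
    row <- row + nrow(sub)
  }
  out
}

# Cosine reference waveforms evaluated at each sample time. Replicates at the
# same time share the reference value, giving tied reference ranks.
.jtk_references <- function(time, periods, phases = NULL) {
  ut <- sort(unique(time))
  if (is.null(phases)) {
    step <- min(diff(ut))
    phases <- lapply(periods, function(p) seq(0, p - step / 2, by = step))
    phases <- lapply(seq_along(periods),
                     function(k) phases[[k]][phases[[k]] < periods[k]])
  } else {
    phases <- rep(list(phases), length(periods))
  }
  refs <- list()
  for (k in seq_along(periods)) {
    for (ph in phases[[k]]) {
      refs[[length(refs) + 1L]] <- list(
        period = periods[k], phase = ph,
        wave = cos(2 * pi * (time - ph) / periods[k]))
    }
  }
  refs
}

# Null distribution of |S| per reference and of max_j |S_j| under permutation
# of the observed values. Exact enumeration for n <= exact_limit, otherwise
# Monte-Carlo with n_perm draws from the current RNG stream.
.jtk_null <- function(values_sorted, ref_sign, idx, exact_limit, n_perm) {
  n <- length(values_sorted)
  m <- ncol(ref_sign)
  exact <- n <= exact_limit
  perms <- if (exact) .all_permutations(n) else NULL
  B <- if (exact) nrow(perms) else n_perm
  abs_S <- matrix(0L, B, m)
  for (b in seq_len(B)) {
    xv <- if (exact) values_sorted[perms[b, ]] else sample(values_sorted)
    dx <- sign(xv[idx$j] - xv[idx$i])
    abs_S[b, ] <- abs(as.integer(dx %*% ref_sign))
  }
  list(abs_S = abs_S, max_S = apply(abs_S, 1, max), exact = exact, B = B)
}

#' JTK-style rhythmicity test for one expression series
#'
#' Tests a gene's time course against phased cosine reference waveforms by
#' Kendall concordance, with an exact or Monte-Carlo permutation null. For
#' each candidate period and each phase on the sampling grid a cosine
#' reference is evaluated at every sample's time (replicates share the
#' reference value); the test statistic against each reference is `|S|`
#' (see [kendall_s()]). Per-reference tail probabilities come from permuting
#' the observed values: full enumeration when `n <= exact_limit`, otherwise
#' `n_perm` seeded Monte-Carlo permutations.
#'
#' Scanning several phases (and periods) multiplies the chance of a large
#' `|S|` under the null, so a within-gene correction is applied. The default,
#' `correction = "maxstat"`, uses the permutation distribution of
#' `max_j |S_j|` across all references, which is calibrated by construction
#' (empirical type-I error matches the nominal level). The alternative
#' `"bonferroni"` multiplies the smallest per-reference tail probability by
#' the number of references; it is conservative when references are
#' correlated, as phased cosines are.
#'
#' @param x Numeric series of log-expression values, one per sample.
#' @param time Sampling time in hours, one per sample (replicates repeat the
#'   time value).
#' @param periods Candidate periods in hours; default 22, the circadian
#'   period regime of *Neurospora crassa*.
#' @param exact_limit Largest `n` for which the permutation null is
#'   enumerated exactly (default 8; `8! = 40320` arrangements).
#' @param n_perm Monte-Carlo permutations when `n > exact_limit`.
#' @param correction `"maxstat"` (default) or `"bonferroni"`; see Details.
#' @return A list: `p_value`, `best_period`, `best_phase` (of the reference
#'   with the largest `|S|`), `S` (that largest `|S|`), `n_refs`.
#' @seealso [jtk_screen()] to test a whole matrix with a shared null.
#' @export
jtk_test <- function(x, time, periods = 22, exact_limit = 8, n_perm = 10000,
                     correction = c("maxstat", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(x) != length(time)) stop("`x` and `time` lengths differ")
  if (length(x) < 6) stop("need at least 6 samples for a rhythmicity test")
  if (any(!is.finite(x))) stop("non-finite expression values")
  refs <- .jtk_references(time, periods)
  idx <- .pair_index(length(x))
  ref_sign <- vapply(refs, function(r) sign(r$wave[idx$j] - r$wave[idx$i]),
                     numeric(length(idx$i)))
  null <- .jtk_null(sort(x), ref_sign, idx, exact_limit, n_perm)
  .jtk_pvalue(x, refs, ref_sign, idx, null, correction)
}

.jtk_pvalue <- function(x, refs, ref_sign, idx, null, correction) {
  dx <- sign(x[idx$j] - x[idx$i])
  S_obs <- abs(as.numeric(dx %*% ref_sign))
  m <- length(refs)
  tail_prob <- function(null_vals, obs) {
    if (null$exact) mean(null_vals >= obs)
    else (1 + sum(null_vals >= obs)) / (null$B + 1)
  }
  if (correction == "maxstat") {
    p <- tail_prob(null$max_S, max(S_obs))
  } else {
    p_each <- vapply(seq_len(m),
                     function(j) tail_prob(null$abs_S[, j], S_obs[j]),
                     numeric(1))
    p <- min(1, m * min(p_each))
  }
  best <- which.max(S_obs)
  list(p_value = p, best_period = refs[[best]]$period,
       best_phase = refs[[best]]$phase, S = S_obs[best], n_refs = m)
}

#' Screen a time-course matrix for rhythmic genes
#'
#' Runs [jtk_test()] on every gene of a course and applies
#' Benjamini-Hochberg correction across genes. The permutation null is
#' computed once per distinct tie pattern of the observed values and shared
#' across genes, so screening 1,000 genes costs little more than one test.
#'
#' @param tcm A [time_course_matrix()] (a single course, or pass `course` to
#'   subset).
#' @param course Optional course ID to restrict to.
#' @param alpha Significance level on the BH-adjusted q-value (strict `<`;
#'   default 0.05).
#' @inheritParams jtk_test
#' @return Data frame with one row per gene: `gene_id`, `p_value`, `q_value`,
#'   `best_period`, `best_phase`, `is_rhythmic` (`q_value < alpha`).
#' @export
jtk_screen <- function(tcm, course = NULL, periods = 22, alpha = 0.05,
                       exact_limit = 8, n_perm = 10000,
                       correction = c("maxstat", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(inherits(tcm, "time_course_matrix"))
  keep <- if (is.null(course)) rep(TRUE, ncol(tcm$values))
          else tcm$samples$course_id == course
  vals <- tcm$values[, keep, drop = FALSE]
  time <- tcm$samples$time[keep]
  if (ncol(vals) < 6) stop("need at least 6 samples for a rhythmicity screen")
  refs <- .jtk_references(time, periods)
  idx <- .pair_index(ncol(vals))
  ref_sign <- vapply(refs, function(r) sign(r$wave[idx$j] - r$wave[idx$i]),
                     numeric(length(idx$i)))
  cache <- new.env(parent = emptyenv())
  res <- lapply(seq_len(nrow(vals)), function(g) {
    x <- vals[g, ]
    if (any(!is.finite(x))) stop("non-finite values for gene ", rownames(vals)[g])
    sig <- paste(sort(table(x)), collapse = ",")
    if (is.null(cache[[sig]]))
      cache[[sig]] <- .jtk_null(sort(x), ref_sign, idx, exact_limit, n_perm)
    .jtk_pvalue(x, refs, ref_sign, idx, cache[[sig]], correction)
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  q <- bh_adjust(p)
  data.frame(gene_id = rownames(vals), p_value = p, q_value = q,
             best_period = vapply(res, `[[`, numeric(1), "best_period"),
             best_phase = vapply(res, `[[`, numeric(1), "best_phase"),
             is_rhythmic = q < alpha, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and returns BH q-values in the original order:
#' `q_(i) = min_(j >= i) p_(j) * m / j` over the sorted p-values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Import precomputed rhythmicity calls
#'
#' Reads a table of per-gene q-values (for instance, output of an external
#' JTK run) and flags rhythmic genes at a strict `q < alpha`.
#'
#' @param path TSV with columns `gene_id` and `q_value`; `p_value` optional.
#' @param alpha Significance level (default 0.05, strict `<`).
#' @return Data frame: `gene_id`, `p_value` (`NA` if absent from the file),
#'   `q_value`, `is_rhythmic`. Empty file with a header yields zero rows.
#' @export
read_rhythm_calls <- function(path, alpha = 0.05) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "q_value") %in% names(tab)))
    stop("rhythm-call file must have gene_id and q_value columns: ", path)
  data.frame(gene_id = as.character(tab$gene_id),
             p_value = if ("p_value" %in% names(tab)) tab$p_value
                       else rep(NA_real_, nrow(tab)),
             q_value = tab$q_value,
             is_rhythmic = tab$q_value < alpha,
             stringsAsFactors = FALSE)
}
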