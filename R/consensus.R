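#' Pareto front (nondominated set) under minimization
#'
#' A gene is on the front iff no other gene weakly dominates it: scores less
#' than or equal in every dataset and strictly less in at least one. Lower
#' scores are better throughout.
#'
#' @param scores Numeric matrix, genes in rows (row names = gene IDs),
#'   datasets in columns; no missing values.
#' @return Logical vector in row order: `TRUE` for nondominated genes. An
#'   empty matrix yields an empty vector; a single gene is on the front.
#' @export
pareto_front <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n == 0) return(logical(0))
  if (anyNA(scores)) stop("scores must not contain missing values")
  on_front <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(scores[j, ] <= scores[i, ]) && any(scores[j, ] < scores[i, ])) {
        on_front[i] <- FALSE
        break
      }
    }
  }
  names(on_front) <- rownames(scores)
  on_front
}

#' Min-max normalize per-dataset scores and sum across datasets
#'
#' Each dataset's scores are mapped to \[0, 1\] by min-max normalization (the
#' best gene in a dataset gets 0) and summed across datasets; lower summed
#' scores indicate genes consistently stable everywhere. A z-score variant is
#' available for scale-sensitivity checks.
#'
#' @param scores Numeric matrix, genes x datasets, no missing values; at
#'   least 2 genes.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return Data frame: `gene_id`, one `norm_<dataset>` column per dataset,
#'   `summed`, `on_pareto_front`; ordered by ascending `summed` (ties by gene
#'   ID).
#' @export
normalize_and_sum <- function(scores, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 genes to normalize")
  if (anyNA(scores)) stop("scores must not contain missing values")
  norm <- apply(scores, 2, function(col) {
    rng <- range(col)
    if (method == "minmax") {
      if (diff(rng) == 0) {
        warning("zero spread in a dataset; all scores normalized to 0")
        rep(0, length(col))
      } else (col - rng[1]) / diff(rng)
    } else {
      s <- stats::sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
    }
  })
  out <- data.frame(gene_id = rownames(scores), norm,
                    summed = rowSums(norm),
                    on_pareto_front = unname(pareto_front(scores)),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[seq_len(ncol(scores)) + 1L] <- paste0("norm_", colnames(scores))
  out[order(out$summed, out$gene_id), , drop = FALSE]
}

#' Final consensus candidates: pareto front intersected with top summed
#'
#' @param ms A [normalize_and_sum()] result.
#' @param top_n How many of the best summed-normalized genes to intersect
#'   with the pareto front (default 10).
#' @return Character vector of candidate gene IDs (sorted); empty, with a
#'   warning, when the front and the top-n set are disjoint.
#' @export
select_candidates <- function(ms, top_n = 10) {
  ord <- order(ms$summed, ms$gene_id)
  top <- ms$gene_id[utils::head(ord, top_n)]
  front <- ms$gene_id[ms$on_pareto_front]
  out <- sort(intersect(top, front))
  if (length(out) == 0)
    warning("pareto front and top-", top_n, " summed set are disjoint")
  out
}

#' Consensus ranking of PIRS scores across datasets
#'
#' Assembles the per-dataset PIRS scores of the genes scored in every
#' dataset (typically the ENCAS sets), computes the pareto front and the
#' summed min-max-normalized score, and intersects the front with the top-n
#' summed genes to produce the final reference-gene candidates. Genes missing
#' from any dataset are excluded (dominance is undefined on missing
#' coordinates) and reported separately.
#'
#' @param reports Named list of [stability_report()] data frames, one per
#'   dataset.
#' @param top_n Passed to [select_candidates()].
#' @param encas_only Use only each dataset's ENCAS genes (default `TRUE`).
#' @return A list of class `consensus_ranking`: `table` (the
#'   [normalize_and_sum()] frame with a `selected` column), `candidates`
#'   (character vector), `excluded` (genes not scored in every dataset).
#' @export
consensus_ranking <- function(reports, top_n = 10, encas_only = TRUE) {
  if (length(reports) < 1) stop("need at least one stability report")
  if (is.null(names(reports)) || any(names(reports) == ""))
    names(reports) <- paste0("dataset", seq_along(reports))
  pool <- lapply(reports, function(r) {
    if (encas_only) r[r$is_encas, c("gene_id", "pirs")]
    else r[, c("gene_id", "pirs")]
  })
  shared <- Reduce(intersect, lapply(pool, `[[`, "gene_id"))
  all_genes <- unique(unlist(lapply(pool, `[[`, "gene_id")))
  excluded <- sort(setdiff(all_genes, shared))
  if (length(shared) < 2)
    stop("fewer than 2 genes scored in every dataset; no consensus possible")
  shared <- sort(shared)
  scores <- vapply(pool, function(p) p$pirs[match(shared, p$gene_id)],
                   numeric(length(shared)))
  rownames(scores) <- shared
  ms <- normalize_and_sum(scores)
  candidates <- select_candidates(ms, top_n)
  ms$selected <- ms$gene_id %in% candidates
  structure(list(table = ms, candidates = candidates, excluded = excluded),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("consensus_ranking: %d genes scored in every dataset, %d on the pareto front\n",
              nrow(x$table), sum(x$table$on_pareto_front)))
  cat(sprintf("  candidates (%d): %s\n", length(x$candidates),
              paste(x$candidates, collapse = ", ")))
  if (length(x$excluded) > 0)
    cat(sprintf("  excluded (missing from a dataset): %d genes\n",
                length(x$excluded)))
  invisible(x)
}
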