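#' Three-fold replicate outlier rule
#'
#' Given three biological-replicate relative expression values (linear
#' scale), drops the single value that differs from BOTH others by more than
#' `fold` (ratio above `fold` or below `1/fold`). When no value, or more
#' than one value, satisfies the rule, all three are retained — at most one
#' replicate is ever removed, and the decision does not depend on input
#' order.
#'
#' @param values Numeric vector of length 3, strictly positive.
#' @param fold Fold-change threshold (default 3, strict `>`).
#' @return The retained values (length 3, or 2 with the outlier dropped),
#'   in input order.
#' @export
replicate_filter <- function(values, fold = 3) {
  if (length(values) != 3) stop("expected exactly 3 replicate values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("fold changes are undefined for non-positive values")
  differs <- function(a, b) {
    r <- a / b
    r > fold || r < 1 / fold
  }
  outlier <- vapply(1:3, function(i) {
    others <- values[-i]
    differs(values[i], others[1]) && differs(values[i], others[2])
  }, logical(1))
  if (sum(outlier) == 1) values[!outlier] else values
}

#' Convert Ct values to relative expression levels
#'
#' Helper for applying the fold-change replicate rule to Ct data: relative
#' level `2^-(ct - ref_ct)`, assuming perfect doubling per cycle.
#'
#' @param ct Numeric Ct values.
#' @param ref_ct Reference Ct subtracted before exponentiation (default 0,
#'   i.e. `2^-ct` up to a shared scale).
#' @return Relative expression on the linear scale.
#' @export
ct_to_relative <- function(ct, ref_ct = 0) 2^(-(ct - ref_ct))

#' Read a Ct table
#'
#' @param path TSV with columns `gene_id`, `primer_rank`, `replicate`, `ct`;
#'   an empty `ct` cell (or `NA`) marks an unreadable well (no
#'   amplification) — never a sentinel cycle number.
#' @return Data frame of class `ct_table` with `ct` numeric (`NA` =
#'   unreadable) and `readable` logical.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("gene_id", "primer_rank", "replicate", "ct")
  if (!all(required %in% names(tab)))
    stop("Ct table must have columns ", paste(required, collapse = ", "))
  ct_table(tab)
}

#' Construct/validate a Ct table
#'
#' @param tab Data frame with columns `gene_id`, `primer_rank`, `replicate`,
#'   `ct` (`NA` = unreadable).
#' @return The validated frame with class `ct_table` and a `readable`
#'   column.
#' @export
ct_table <- function(tab) {
  tab <- as.data.frame(tab)
  key <- paste(tab$gene_id, tab$primer_rank, tab$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene_id, primer_rank, replicate) rows in Ct table")
  bad <- !is.na(tab$ct) & (!is.finite(tab$ct) | tab$ct <= 0)
  if (any(bad))
    stop("readable Ct values must be finite and positive")
  tab$readable <- !is.na(tab$ct)
  class(tab) <- c("ct_table", "data.frame")
  tab
}

#' Summarize the Ct observations of one gene
#'
#' Mean Ct over all readable wells; SD only when three or more wells are
#' readable; a gene counts as detected when any readable well falls strictly
#' below the detection threshold.
#'
#' @param tab A [ct_table()].
#' @param gene Gene ID present in the table.
#' @param detect_threshold Detection cutoff in cycles (default 30,
#'   strict `<`).
#' @return A list: `gene_id`, `mean_ct` (`NA` if nothing readable), `sd_ct`
#'   (`NA` unless `n_readable >= 3`), `n_readable`, `detected`,
#'   `per_pair_ct` (named mean Ct per primer rank, readable wells only).
#' @export
summarize_gene_ct <- function(tab, gene, detect_threshold = 30) {
  stopifnot(inherits(tab, "ct_table"))
  rows <- tab[tab$gene_id == gene, , drop = FALSE]
  if (nrow(rows) == 0) stop("gene ", gene, " absent from the Ct table")
  ct <- rows$ct[rows$readable]
  n <- length(ct)
  per_pair <- tapply(rows$ct[rows$readable], rows$primer_rank[rows$readable],
                     mean)
  list(gene_id = gene,
       mean_ct = if (n > 0) mean(ct) else NA_real_,
       sd_ct = if (n >= 3) stats::sd(ct) else NA_real_,
       n_readable = n,
       detected = n > 0 && any(ct < detect_threshold),
       per_pair_ct = per_pair)
}

#' Summarize every gene of a Ct table
#'
#' @inheritParams summarize_gene_ct
#' @return Data frame: `gene_id`, `mean_ct`, `sd_ct`, `n_readable`,
#'   `detected`; one row per gene in first-appearance order.
#' @export
summarize_ct <- function(tab, detect_threshold = 30) {
  stopifnot(inherits(tab, "ct_table"))
  genes <- unique(tab$gene_id)
  rows <- lapply(genes, function(g) {
    s <- summarize_gene_ct(tab, g, detect_threshold)
    data.frame(gene_id = g, mean_ct = s$mean_ct, sd_ct = s$sd_ct,
               n_readable = s$n_readable, detected = s$detected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean primer penalty by detection status
#'
#' Compares the engine penalty of the primer pairs behind detected vs
#' undetected genes — the diagnostic linking primer quality to RT-PCR
#' success. Only pairs present in the Ct table (i.e. actually tested) are
#' averaged.
#'
#' @param summaries A [summarize_ct()] frame.
#' @param catalog A catalog pairs frame (see [build_catalog()]) with
#'   `gene_id`, `rank`, `pair_penalty`.
#' @param tab The [ct_table()] the summaries came from (identifies which
#'   pairs were tested).
#' @return A list: `mean_penalty_detected`, `mean_penalty_undetected`
#'   (either `NA`, with a warning, when its group is empty), `n_detected`,
#'   `n_undetected`.
#' @export
penalty_detection_summary <- function(summaries, catalog, tab) {
  stopifnot(inherits(tab, "ct_table"))
  tested <- unique(tab[, c("gene_id", "primer_rank")])
  pen <- catalog$pair_penalty[match(paste(tested$gene_id, tested$primer_rank),
                                    paste(catalog$gene_id, catalog$rank))]
  if (anyNA(pen))
    stop("tested primer pair(s) missing from the catalog: ",
         paste(utils::head(tested$gene_id[is.na(pen)]), collapse = ", "))
  detected <- summaries$detected[match(tested$gene_id, summaries$gene_id)]
  group_mean <- function(sel, label) {
    if (!any(sel)) {
      warning("no ", label, " genes; mean penalty undefined")
      NA_real_
    } else mean(pen[sel])
  }
  list(mean_penalty_detected = group_mean(detected, "detected"),
       mean_penalty_undetected = group_mean(!detected, "undetected"),
       n_detected = sum(unique(tested$gene_id) %in%
                          summaries$gene_id[summaries$detected]),
       n_undetected = sum(!unique(tested$gene_id) %in%
                            summaries$gene_id[summaries$detected]))
}
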