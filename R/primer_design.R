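# structured error for genes whose geometry cannot host a primer pair;
# build_catalog() catches this class and records the reason
.degenerate_region <- function(gene_id, reason) {
  stop(structure(class = c("refprimer_degenerate_region", "error", "condition"),
                 list(message = sprintf("%s: %s", gene_id, reason),
                      call = sys.call(-1), gene_id = gene_id, reason = reason)))
}

#' Select the primer design region for a gene model
#'
#' Applies the intron-aware region rules on the spliced transcript:
#' \itemize{
#'   \item mono-exonic genes: primers fall in the 3' tail window, between
#'     `tail_window` and `tail_margin` bp from the end of the gene;
#'   \item one intron: the amplicon must span the single exon-exon junction;
#'   \item two or more introns: the amplicon must span the last junction,
#'     earlier introns are ignored.
#' }
#' Spanning a junction means genomic DNA yields a larger (or no) product, so
#' RT-PCR signal can be attributed to spliced mRNA. Mono-exonic genes
#' shorter than the tail window use the whole sequence minus the 3' margin
#' and are flagged `short_gene`.
#'
#' @param g A `gene_model` from [load_annotation()].
#' @param tail_window,tail_margin Tail-window geometry in bp (defaults 500
#'   and 100): the search region for mono-exonic genes is
#'   `[len - tail_window, len - tail_margin)`.
#' @param span_flank Half-width in bp of the search region centered on the
#'   junction for intron-spanning modes (default 250, one maximal amplicon
#'   on each side).
#' @param min_flank Minimum spliced sequence on each side of the junction
#'   (primer plus margin; default 25). Shorter flanks raise a
#'   degenerate-region error that [build_catalog()] records as a design
#'   failure.
#' @return An object of class `design_region`: `gene_id`, `mode` (one of
#'   `"tail_window"`, `"span_single_intron"`, `"span_last_intron"`),
#'   `search_seq` (the spliced sequence), `included_range` (0-based
#'   half-open on `search_seq`), `junction_target` (0-based position, `NA`
#'   for tail mode), `short_gene`.
#' @export
select_region <- function(g, tail_window = 500, tail_margin = 100,
                          span_flank = 250, min_flank = 25) {
  stopifnot(inherits(g, "gene_model"))
  len <- nchar(g$spliced_seq)
  short_gene <- FALSE
  if (g$n_exons == 1) {
    if (len >= tail_window) {
      rng <- c(len - tail_window, len - tail_margin)
    } else {
      short_gene <- TRUE
      rng <- c(0, max(0, len - tail_margin))
    }
    if (diff(rng) < 100)
      .degenerate_region(g$gene_id, "tail window shorter than the minimum amplicon")
    mode <- "tail_window"
    junction <- NA_integer_
  } else {
    junction <- g$junctions[length(g$junctions)]
    mode <- if (g$n_exons == 2) "span_single_intron" else "span_last_intron"
    if (junction < min_flank)
      .degenerate_region(g$gene_id, "exons before the last junction too short for a primer")
    if (len - junction < min_flank)
      .degenerate_region(g$gene_id, "last exon too short for a primer")
    rng <- c(max(0, junction - span_flank), min(len, junction + span_flank))
  }
  structure(list(gene_id = g$gene_id, mode = mode, search_seq = g$spliced_seq,
                 included_range = as.integer(rng),
                 junction_target = as.integer(junction),
                 short_gene = short_gene),
            class = "design_region")
}

#' Design ranked primer pairs within a region
#'
#' Searches the region for acceptable left/right primers with the engine,
#' forms pairs meeting the amplicon-size window, the pair Tm-difference
#' limit, and (in span modes) junction containment, and returns up to
#' `n_pairs` mutually non-identical pairs sorted by ascending pair penalty
#' with ranks 1..k. All reported coordinates are 0-based on the spliced
#' transcript; `right_start` is the leftmost template base of the right
#' primer's binding site, whose sequence is the reverse complement of the
#' template there.
#'
#' @param r A [select_region()] result.
#' @param engine A [builtin_engine()].
#' @param n_pairs Maximum pairs returned (default 5).
#' @return Data frame with columns `gene_id`, `rank`, `left_seq`,
#'   `right_seq`, `left_start`, `right_start`, `left_len`, `right_len`,
#'   `amplicon_len`, `left_tm`, `right_tm`, `left_penalty`, `right_penalty`,
#'   `pair_penalty`, `spans_intron`, `mode`. Zero acceptable pairs yield an
#'   empty frame whose `reason` attribute explains the failure.
#' @export
design_pairs <- function(r, engine = builtin_engine(), n_pairs = 5) {
  stopifnot(inherits(r, "design_region"))
  if (!inherits(engine, "builtin_engine"))
    stop("only the builtin engine is supported by this binding; ",
         "see primer3_engine() for the external one")
  empty <- function(reason) {
    out <- design_pairs_empty_frame()
    attr(out, "reason") <- reason
    out
  }
  rng <- r$included_range
  chars <- strsplit(r$search_seq, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("non-ACGT character in the spliced sequence of ", r$gene_id)

  cums <- .thermo_cums(chars)
  cand <- list()
  for (L in engine$size_min:engine$size_max) {
    if (rng[2] - rng[1] < L) next
    starts <- seq.int(rng[1], rng[2] - L)
    cand[[length(cand) + 1L]] <- .window_scores(cums, starts, L, engine)
  }
  if (length(cand) == 0) return(empty("design region shorter than a primer"))
  cand <- do.call(rbind, cand)
  cand <- cand[cand$tm >= engine$tm_min & cand$tm <= engine$tm_max &
               cand$gc >= engine$gc_min & cand$gc <= engine$gc_max, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(empty("no acceptable primers"))
  # drop candidates with a self-complementarity run >= the threshold, found
  # by matching threshold-length k-mers of the region against their reverse
  # complements (equivalent to .max_comp_run on each window, but shared)
  rejected <- .self_comp_rejected(chars, rng, cand$start, cand$len,
                                  engine$self_comp_max)
  cand <- cand[!rejected, , drop = FALSE]
  if (nrow(cand) == 0) return(empty("no acceptable primers"))
  cand <- cand[order(cand$penalty, cand$start, cand$len), , drop = FALSE]
  cand$seq <- substring(r$search_seq, cand$start + 1L, cand$start + cand$len)

  # per-side pools: in span modes the left primer must start before the
  # junction and the right primer must end after it
  if (is.na(r$junction_target)) {
    il <- jr <- seq_len(nrow(cand))
  } else {
    il <- which(cand$start < r$junction_target)
    jr <- which(cand$start + cand$len > r$junction_target)
  }
  il <- utils::head(il, engine$max_candidates)
  jr <- utils::head(jr, engine$max_candidates)
  if (length(il) == 0 || length(jr) == 0)
    return(empty("no acceptable primers"))

  # pair search over pools of the K best candidates per side, escalating K
  # until the best n_pairs found are provably optimal (any unexamined pair
  # contains a candidate with penalty >= the K-th, so its pair penalty is
  # bounded below) or the pools are exhausted
  search_pairs <- function(K) {
    ilK <- utils::head(il, K); jrK <- utils::head(jr, K)
    li <- rep(ilK, times = length(jrK))
    ri <- rep(jrK, each = length(ilK))
    amp <- cand$start[ri] + cand$len[ri] - cand$start[li]
    ok <- amp >= engine$product_range[1] & amp <= engine$product_range[2] &
      abs(cand$tm[li] - cand$tm[ri]) <= engine$max_tm_diff
    if (!is.na(r$junction_target))
      ok <- ok & cand$start[li] < r$junction_target &
        (cand$start[ri] + cand$len[ri]) > r$junction_target
    list(li = li[ok], ri = ri[ok])
  }
  K <- 128L
  repeat {
    hit <- search_pairs(K)
    exhausted <- K >= max(length(il), length(jr))
    if (length(hit$li) >= n_pairs || exhausted) {
      if (length(hit$li) == 0) return(empty("no acceptable primer pairs"))
      pp <- cand$penalty[hit$li] + cand$penalty[hit$ri] +
        engine$w_diff * abs(cand$tm[hit$li] - cand$tm[hit$ri])
      worst_kept <- sort(pp)[min(n_pairs, length(pp))]
      bound <- cand$penalty[min(K, nrow(cand))] + min(cand$penalty)
      if (exhausted || worst_kept <= bound) break
    }
    K <- K * 4L
  }
  li <- hit$li; ri <- hit$ri
  pair_penalty <- cand$penalty[li] + cand$penalty[ri] +
    engine$w_diff * abs(cand$tm[li] - cand$tm[ri])
  ord <- utils::head(order(pair_penalty, cand$start[li], cand$start[ri]),
                     n_pairs)
  li_s <- li[ord]; ri_s <- ri[ord]
  data.frame(gene_id = r$gene_id, rank = seq_along(ord),
             left_seq = cand$seq[li_s],
             right_seq = vapply(cand$seq[ri_s], .revcomp, character(1),
                                USE.NAMES = FALSE),
             left_start = cand$start[li_s], right_start = cand$start[ri_s],
             left_len = cand$len[li_s], right_len = cand$len[ri_s],
             amplicon_len = as.integer(cand$start[ri_s] + cand$len[ri_s] -
                                         cand$start[li_s]),
             left_tm = cand$tm[li_s], right_tm = cand$tm[ri_s],
             left_penalty = cand$penalty[li_s],
             right_penalty = cand$penalty[ri_s],
             pair_penalty = pair_penalty[ord],
             spans_intron = !is.na(r$junction_target),
             mode = r$mode, stringsAsFactors = FALSE)
}

#' Build a genome-wide ranked primer catalog
#'
#' Runs [select_region()] and [design_pairs()] over every transcript of an
#' annotation and assembles the catalog: up to five ranked primer pairs per
#' transcript, with per-transcript pair counts and machine-readable failure
#' reasons for genes whose geometry or sequence defeats the search. Output
#' is deterministic for fixed inputs and engine parameters.
#'
#' @param fasta,gff3 Genome FASTA and GFF3 annotation paths.
#' @param engine A [builtin_engine()].
#' @param out_dir Optional directory; when given, writes `catalog.tsv`
#'   (0-based spliced-transcript coordinates, as documented in
#'   [design_pairs()]) and `catalog_summary.json` (counts, failures, engine
#'   parameters).
#' @param n_pairs Pairs requested per transcript (default 5).
#' @param ... Passed to [select_region()].
#' @return A list of class `primer_catalog`: `pairs` (the combined
#'   [design_pairs()] frame), `summary` (list: `attempted`, `with_pairs`,
#'   `with_full`, `failures` data frame of `gene_id`/`reason`, `engine`
#'   parameters), `models_skipped`.
#' @export
build_catalog <- function(fasta, gff3, engine = builtin_engine(),
                          out_dir = NULL, n_pairs = 5, ...) {
  models <- load_annotation(fasta, gff3)
  pairs <- list()
  failures <- list()
  for (m in models) {
    res <- tryCatch({
      region <- select_region(m, ...)
      design_pairs(region, engine, n_pairs)
    }, refprimer_degenerate_region = function(e) {
      out <- design_pairs_empty_frame()
      attr(out, "reason") <- e$reason
      out
    })
    if (nrow(res) == 0) {
      failures[[m$gene_id]] <- attr(res, "reason")
    } else {
      pairs[[m$gene_id]] <- res
    }
  }
  pairs_df <- if (length(pairs) > 0) do.call(rbind, pairs) else
    design_pairs_empty_frame()
  rownames(pairs_df) <- NULL
  counts <- table(factor(pairs_df$gene_id, levels = names(pairs)))
  summary <- list(
    attempted = length(models),
    with_pairs = length(pairs),
    with_full = sum(counts == n_pairs),
    failures = data.frame(gene_id = names(failures),
                          reason = unlist(failures, use.names = FALSE),
                          stringsAsFactors = FALSE),
    engine = unclass(engine))
  out <- structure(list(pairs = pairs_df, summary = summary,
                        models_skipped = attr(models, "skipped")),
                   class = "primer_catalog")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pairs_df, file.path(out_dir, "catalog.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "catalog_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

# the empty pairs frame with full schema (shared by build_catalog)
design_pairs_empty_frame <- function() {
  data.frame(gene_id = character(0), rank = integer(0),
             left_seq = character(0), right_seq = character(0),
             left_start = integer(0), right_start = integer(0),
             left_len = integer(0), right_len = integer(0),
             amplicon_len = integer(0), left_tm = numeric(0),
             right_tm = numeric(0), left_penalty = numeric(0),
             right_penalty = numeric(0), pair_penalty = numeric(0),
             spans_intron = logical(0), mode = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.primer_catalog <- function(x, ...) {
  s <- x$summary
  cat(sprintf("primer_catalog: %d transcripts attempted, %d with pairs, %d with the full set\n",
              s$attempted, s$with_pairs, s$with_full))
  if (nrow(s$failures) > 0)
    cat(sprintf("  failures: %d (%s)\n", nrow(s$failures),
                paste(unique(s$failures$reason), collapse = "; ")))
  invisible(x)
}
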