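# run expr under a fixed seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic expression time course
#'
#' Describes a simulated circadian (or induction) experiment: sampling grid,
#' replication, number of courses, and a table of gene classes with their
#' signal parameters. Every generated gene carries its ground-truth class.
#' Defaults mirror a replicated two-day circadian design: samples every 2 h
#' over 0-44 h, 2 replicates, 3 courses, and a mix of flat genes, 22-h
#' cosine cyclers, linear trenders, and low-expressed genes.
#'
#' @param n_genes Number of genes.
#' @param time_points Sampling times in hours.
#' @param replicates Biological replicates per time point (1 for
#'   induction-style series).
#' @param courses Number of independent courses sharing gene parameters but
#'   with independent noise.
#' @param classes Data frame with columns `class` (label), `prop`
#'   (proportions summing to 1), `sigma` (noise SD on log10 FPKM),
#'   `amplitude` (cosine, log10 units), `period` (h), `slope` (log10 units
#'   per h), `low` (logical: base expression drawn below the detection
#'   cutoff). Two optional logical columns support planted-reference
#'   constructions: `centered_noise` draws noise mean-centered within each
#'   time point, so a flat gene's between-time-point variance is exactly
#'   zero (its time-effect ANOVA is null by construction, not by chance);
#'   `opposed_gradient` scales the class's sigma by `2^j` over its genes
#'   `j = 0..k-1` in course 1 and by `2^(k-1-j)` in course 2 (courses beyond
#'   2 use the base sigma), so every pair of planted genes trades places
#'   between courses and the whole class is mutually nondominated across
#'   datasets by construction.
#' @param base_range Range of base log10 FPKM for non-low genes (default
#'   spans roughly the observed reference-gene range, 0.1 to 3.2).
#' @param low_range Range of base log10 FPKM for low-expressed genes.
#' @param seed Integer seed; identical specs give identical output.
#' @return A list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 200,
                                time_points = seq(0, 44, by = 2),
                                replicates = 2, courses = 3,
                                classes = NULL,
                                base_range = c(0.1, 3.2),
                                low_range = c(-4, -2.2),
                                seed = 1) {
  if (length(time_points) == 0) stop("empty time grid")
  if (is.null(classes))
    classes <- data.frame(
      class = c("flat", "cycler", "trender", "low_expressed"),
      prop = c(0.40, 0.30, 0.15, 0.15),
      sigma = c(0.2, 0.2, 0.2, 0.3),
      amplitude = c(0, 1, 0, 0),
      period = c(NA, 22, NA, NA),
      slope = c(0, 0, 0.02, 0),
      low = c(FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE)
  if (abs(sum(classes$prop) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  structure(list(n_genes = n_genes, time_points = time_points,
                 replicates = replicates, courses = courses,
                 classes = classes, base_range = base_range,
                 low_range = low_range, seed = seed),
            class = "expression_sim_spec")
}

#' Simulate expression time courses with known gene classes
#'
#' Generates log10-FPKM values as `base + class signal + Gaussian noise`:
#' cyclers follow a cosine at their period and phase, trenders a linear
#' drift, flat and low-expressed genes carry no signal. Gene parameters
#' (base, phase) are shared across courses; the noise is independent per
#' course. Output is bit-reproducible for a fixed spec.
#'
#' @param spec An [expression_sim_spec()].
#' @return A list: `courses` (named list of [time_course_matrix()], one per
#'   course) and `truth` (data frame: `gene_id`, `class`, `base`, `sigma`,
#'   `amplitude`, `period`, `phase`, `slope`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  .with_seed(spec$seed, {
    cls <- spec$classes
    n_per <- floor(spec$n_genes * cls$prop)
    short <- spec$n_genes - sum(n_per)
    if (short > 0) n_per[seq_len(short)] <- n_per[seq_len(short)] + 1L
    class_of <- rep(cls$class, times = n_per)
    gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
    row_of <- match(class_of, cls$class)
    base <- ifelse(cls$low[row_of],
                   stats::runif(spec$n_genes, spec$low_range[1], spec$low_range[2]),
                   stats::runif(spec$n_genes, spec$base_range[1], spec$base_range[2]))
    phase <- stats::runif(spec$n_genes, 0,
                          ifelse(is.na(cls$period[row_of]), 1, cls$period[row_of]))
    centered <- if ("centered_noise" %in% names(cls))
      cls$centered_noise[row_of] else rep(FALSE, spec$n_genes)
    opposed <- if ("opposed_gradient" %in% names(cls))
      cls$opposed_gradient[row_of] else rep(FALSE, spec$n_genes)
    gradient <- rep(1, spec$n_genes)   # per-gene multiplier, course 1 sense
    for (cl in unique(class_of[opposed])) {
      members <- which(class_of == cl)
      gradient[members] <- 2^(seq_along(members) - 1)
    }
    truth <- data.frame(gene_id = gene_ids, class = class_of, base = base,
                        sigma = cls$sigma[row_of],
                        amplitude = cls$amplitude[row_of],
                        period = cls$period[row_of], phase = phase,
                        slope = cls$slope[row_of], stringsAsFactors = FALSE)
    time <- rep(spec$time_points, each = spec$replicates)
    repl <- rep(seq_len(spec$replicates), times = length(spec$time_points))
    courses <- list()
    for (cr in seq_len(spec$courses)) {
      course_id <- paste0("course", cr)
      signal <- outer(seq_len(spec$n_genes), seq_along(time),
                      function(g, s) {
        per <- truth$period[g]
        cyc <- ifelse(is.na(per), 0,
                      truth$amplitude[g] * cos(2 * pi * (time[s] - truth$phase[g]) / per))
        truth$base[g] + cyc + truth$slope[g] * time[s]
      })
      sd_gene <- truth$sigma
      if (any(opposed)) {
        mult <- rep(1, spec$n_genes)
        if (cr == 1) mult[opposed] <- gradient[opposed]
        if (cr == 2) {
          for (cl in unique(class_of[opposed])) {
            members <- which(class_of == cl)
            mult[members] <- rev(gradient[members])
          }
        }
        sd_gene <- sd_gene * mult
      }
      noise <- matrix(stats::rnorm(length(signal), sd = sd_gene),
                      nrow = spec$n_genes)
      if (any(centered)) {
        # remove the within-time-point mean so centered genes have exactly
        # zero between-time-point variance around their signal
        for (tp in unique(time)) {
          cols <- which(time == tp)
          if (length(cols) < 2) next
          ctr <- noise[centered, cols, drop = FALSE]
          noise[centered, cols] <- ctr - rowMeans(ctr)
        }
      }
      vals <- signal + noise
      rownames(vals) <- gene_ids
      colnames(vals) <- sprintf("%s_t%02g_r%d", course_id, time, repl)
      meta <- data.frame(sample_id = colnames(vals), time = time,
                         replicate = repl, course_id = course_id,
                         stringsAsFactors = FALSE)
      courses[[course_id]] <- time_course_matrix(vals, meta)
    }
    list(courses = courses, truth = truth)
  })
}

# random DNA with a given GC fraction and no homopolymer longer than max_run
.random_seq <- function(n, gc = 0.5, max_run = 6) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(p), n, replace = TRUE, prob = p)
  repeat {
    r <- rle(x)
    bad <- which(r$lengths > max_run)
    if (length(bad) == 0) break
    ends <- cumsum(r$lengths)
    for (b in bad) {
      pos <- seq.int(ends[b] - r$lengths[b] + max_run + 1, ends[b])
      x[pos] <- sample(setdiff(names(p), r$values[b]), length(pos),
                       replace = TRUE)
    }
  }
  paste(x, collapse = "")
}

#' Specification for a synthetic annotated genome
#'
#' @param n_genes Number of genes.
#' @param exon_count_props Named proportions over exon counts `"1"`, `"2"`,
#'   `"3"` (mono-exonic, single-intron, multi-intron).
#' @param mono_len_range Spliced length range (bp) for mono-exonic genes;
#'   the default keeps them longer than the 500-bp tail window.
#' @param exon_len_range,last_exon_len_range,intron_len_range Length ranges
#'   (bp) for multi-exonic pieces; flanks around the last junction stay long
#'   enough for primers.
#' @param gc GC fraction of gene sequence (0.5 keeps every gene designable).
#' @param intergenic_range Spacing between genes on the contig (bp).
#' @param minus_strand_prop Proportion of genes placed on the minus strand.
#' @param seed Integer seed.
#' @return A list of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_genes = 50,
                            exon_count_props = c("1" = 0.4, "2" = 0.3, "3" = 0.3),
                            mono_len_range = c(1200, 2500),
                            exon_len_range = c(250, 600),
                            last_exon_len_range = c(250, 500),
                            intron_len_range = c(60, 200),
                            gc = 0.5,
                            intergenic_range = c(200, 500),
                            minus_strand_prop = 0.5,
                            seed = 1) {
  if (abs(sum(exon_count_props) - 1) > 1e-8)
    stop("exon-count proportions must sum to 1")
  if (exon_len_range[1] < 50 || last_exon_len_range[1] < 50)
    stop("exons must be at least 50 bp to host a primer")
  structure(list(n_genes = n_genes, exon_count_props = exon_count_props,
                 mono_len_range = mono_len_range,
                 exon_len_range = exon_len_range,
                 last_exon_len_range = last_exon_len_range,
                 intron_len_range = intron_len_range, gc = gc,
                 intergenic_range = intergenic_range,
                 minus_strand_prop = minus_strand_prop, seed = seed),
            class = "genome_sim_spec")
}

#' Simulate a genome FASTA and GFF3 with planted gene models
#'
#' Plants mono-exonic, two-exon and three-exon genes on both strands of one
#' contig, with sequence composition (GC near 50%, no homopolymers beyond
#' 6 bp) chosen so every gene is designable by the built-in engine. The
#' emitted files parse back to the planted models exactly.
#'
#' @param spec A [genome_sim_spec()].
#' @param out_dir Directory for `genome.fa` and `annotation.gff3`.
#' @return Invisibly, a list: `fasta`, `gff3` (paths) and `truth` (data
#'   frame: `gene_id`, `strand`, `n_exons`, `spliced_len`).
#' @export
simulate_genome <- function(spec, out_dir) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$seed, {
    runi <- function(rng) round(stats::runif(1, rng[1], rng[2]))
    n_exons_of <- sample(as.integer(names(spec$exon_count_props)),
                         spec$n_genes, replace = TRUE,
                         prob = spec$exon_count_props)
    seq_parts <- character(0)
    pos <- 0L  # 0-based cursor on the contig
    gff <- c("##gff-version 3")
    truth <- list()
    for (g in seq_len(spec$n_genes)) {
      gid <- sprintf("tx%03d", g)
      gap <- runi(spec$intergenic_range)
      seq_parts <- c(seq_parts, .random_seq(gap, gc = 0.5))
      pos <- pos + gap
      ne <- n_exons_of[g]
      if (ne == 1) {
        ex_lens <- runi(spec$mono_len_range)
        in_lens <- integer(0)
      } else {
        ex_lens <- c(vapply(seq_len(ne - 1),
                            function(i) runi(spec$exon_len_range), numeric(1)),
                     runi(spec$last_exon_len_range))
        in_lens <- vapply(seq_len(ne - 1),
                          function(i) runi(spec$intron_len_range), numeric(1))
      }
      strand <- if (stats::runif(1) < spec$minus_strand_prop) "-" else "+"
      ex_start <- integer(ne)
      cursor <- pos
      for (k in seq_len(ne)) {
        ex_start[k] <- cursor
        seq_parts <- c(seq_parts, .random_seq(ex_lens[k], gc = spec$gc))
        cursor <- cursor + ex_lens[k]
        if (k < ne) {
          seq_parts <- c(seq_parts, .random_seq(in_lens[k], gc = 0.4))
          cursor <- cursor + in_lens[k]
        }
      }
      ex_end <- ex_start + ex_lens
      span <- c(pos, cursor)
      pos <- cursor
      gff <- c(gff,
        sprintf("chr1\trefprimer-sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s_gene",
                span[1] + 1L, span[2], strand, gid),
        sprintf("chr1\trefprimer-sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s_gene",
                span[1] + 1L, span[2], strand, gid, gid),
        sprintf("chr1\trefprimer-sim\texon\t%d\t%d\t.\t%s\t.\tID=%s_exon%d;Parent=%s",
                ex_start + 1L, ex_end, strand, gid, seq_len(ne), gid))
      truth[[gid]] <- data.frame(gene_id = gid, strand = strand, n_exons = ne,
                                 spliced_len = sum(ex_lens),
                                 stringsAsFactors = FALSE)
    }
    seq_parts <- c(seq_parts, .random_seq(200, gc = 0.5))
    contig <- Biostrings::DNAStringSet(paste(seq_parts, collapse = ""))
    names(contig) <- "chr1"
    fasta <- file.path(out_dir, "genome.fa")
    gff3 <- file.path(out_dir, "annotation.gff3")
    Biostrings::writeXStringSet(contig, fasta)
    writeLines(gff, gff3)
    invisible(list(fasta = fasta, gff3 = gff3,
                   truth = do.call(rbind, c(truth, make.row.names = FALSE))))
  })
}

#' Simulate a Ct table from a primer catalog and expression levels
#'
#' Ct values follow the standard dilution relation
#' `ct = intercept - slope * log10(expression)` plus Gaussian noise; a well
#' drops out (unreadable) with probability increasing both in the pair's
#' penalty and in the amount by which its Ct exceeds a soft ceiling —
#' emulating weak primers and low-abundance targets failing to amplify.
#'
#' @param catalog Catalog pairs frame (`gene_id`, `rank`, `pair_penalty`).
#' @param log10_expr Named vector of log10 expression per gene (names =
#'   gene IDs; must cover the catalog's genes).
#' @param seed Integer seed.
#' @param replicates Wells per primer pair (default 3).
#' @param intercept,slope Calibration of the Ct relation; the default slope
#'   `log2(10) = 3.32` cycles per 10-fold expression assumes perfect
#'   efficiency.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param ct_ceiling Soft ceiling above which dropout risk grows (cycles).
#' @param lambda_penalty,lambda_ct Dropout rates per penalty unit and per
#'   cycle above the ceiling; dropout probability is
#'   `1 - exp(-(lambda_penalty * penalty + lambda_ct * max(0, ct - ceiling)))`.
#' @return A [ct_table()] with attribute `truth` (data frame: `gene_id`,
#'   `log10_expr`, `expected_ct`).
#' @export
simulate_ct <- function(catalog, log10_expr, seed = 1, replicates = 3,
                        intercept = 35, slope = log2(10), noise_sd = 0.15,
                        ct_ceiling = 30, lambda_penalty = 0.6,
                        lambda_ct = 0.35) {
  missing <- setdiff(unique(catalog$gene_id), names(log10_expr))
  if (length(missing) > 0)
    stop("no expression level for gene(s): ",
         paste(utils::head(missing), collapse = ", "))
  .with_seed(seed, {
    rows <- catalog[rep(seq_len(nrow(catalog)), each = replicates), ]
    repl <- rep(seq_len(replicates), times = nrow(catalog))
    expected <- intercept - slope * log10_expr[rows$gene_id]
    ct <- expected + stats::rnorm(nrow(rows), sd = noise_sd)
    p_drop <- 1 - exp(-(lambda_penalty * rows$pair_penalty +
                          lambda_ct * pmax(0, ct - ct_ceiling)))
    ct[stats::runif(nrow(rows)) < p_drop] <- NA_real_
    out <- ct_table(data.frame(gene_id = rows$gene_id,
                               primer_rank = rows$rank,
                               replicate = repl, ct = ct,
                               stringsAsFactors = FALSE))
    genes <- unique(catalog$gene_id)
    attr(out, "truth") <- data.frame(
      gene_id = genes, log10_expr = unname(log10_expr[genes]),
      expected_ct = unname(intercept - slope * log10_expr[genes]),
      stringsAsFactors = FALSE)
    out
  })
}
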