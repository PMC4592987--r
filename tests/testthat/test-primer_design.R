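test_that("region selection follows the intron-aware rules", {
  mk_model <- function(n_exons, exon_len = 600, last_len = 400,
                       total = 2000) {
    if (n_exons == 1) {
      seq <- strrep("ACGT", total / 4)
      exons <- cbind(start = 0, end = total)
      junctions <- integer(0)
    } else {
      lens <- c(rep(exon_len, n_exons - 1), last_len)
      seq <- strrep("ACGT", sum(lens) / 4)
      exons <- cbind(start = cumsum(c(0, lens[-n_exons])),
                     end = cumsum(lens))
      junctions <- as.integer(cumsum(lens)[-n_exons])
    }
    structure(list(gene_id = "toy", chrom = "c", strand = "+",
                   exons = exons, introns = NULL,
                   genomic_span = c(start = 0, end = nchar(seq)),
                   spliced_seq = seq, junctions = junctions,
                   n_exons = n_exons), class = "gene_model")
  }

  # mono-exonic 2000 bp: window [1500, 1900)
  r1 <- select_region(mk_model(1))
  expect_equal(r1$mode, "tail_window")
  expect_equal(r1$included_range, c(1500L, 1900L))
  expect_true(is.na(r1$junction_target))

  # 2-exon gene with exons 600 + 400: junction at 600
  r2 <- select_region(mk_model(2, exon_len = 600, last_len = 400))
  expect_equal(r2$mode, "span_single_intron")
  expect_equal(r2$junction_target, 600L)
  expect_true(r2$junction_target > r2$included_range[1] &&
                r2$junction_target < r2$included_range[2])

  # 4-exon gene: only the last junction is targeted
  r4 <- select_region(mk_model(4, exon_len = 600, last_len = 400))
  expect_equal(r4$mode, "span_last_intron")
  expect_equal(r4$junction_target, 1800L)

  # short mono-exonic gene: whole sequence minus the margin, flagged
  rs <- select_region(mk_model(1, total = 400))
  expect_true(rs$short_gene)
  expect_equal(rs$included_range, c(0L, 300L))

  # last exon too short for a primer: degenerate-region failure
  expect_error(select_region(mk_model(2, exon_len = 600, last_len = 12)),
               class = "refprimer_degenerate_region")
})

test_that("designed pairs respect size, uniqueness and rank ordering", {
  dir <- withr::local_tempdir()
  fx <- mono_exonic_fixture(dir, len = 2000, seed = 11)
  models <- load_annotation(fx$fasta, fx$gff3)
  r <- select_region(models[[1]])
  pairs <- design_pairs(r, builtin_engine())
  expect_equal(nrow(pairs), 5)
  expect_equal(pairs$rank, 1:5)
  expect_true(all(diff(pairs$pair_penalty) >= 0))
  expect_true(all(pairs$amplicon_len >= 100 & pairs$amplicon_len <= 250))
  # mutually non-identical (left_start, right_start) tuples
  expect_equal(anyDuplicated(pairs[, c("left_start", "right_start")]), 0L)
  # every primer base within the tail window
  len <- nchar(r$search_seq)
  expect_true(all(pairs$left_start >= len - 500))
  expect_true(all(pairs$right_start + pairs$right_len <= len - 100))
  # reported sequences match the template coordinates
  for (k in 1:5) {
    expect_equal(pairs$left_seq[k],
                 substring(r$search_seq, pairs$left_start[k] + 1,
                           pairs$left_start[k] + pairs$left_len[k]))
    templ <- substring(r$search_seq, pairs$right_start[k] + 1,
                       pairs$right_start[k] + pairs$right_len[k])
    expect_equal(pairs$right_seq[k], refprimer:::.revcomp(templ))
  }
})

test_that("a homopolymer design window yields zero pairs with a reason", {
  seq <- paste0(strrep("ACGT", 375), strrep("A", 400), strrep("ACGT", 25))
  m <- structure(list(gene_id = "homo", chrom = "c", strand = "+",
                      exons = cbind(start = 0, end = nchar(seq)),
                      introns = NULL,
                      genomic_span = c(start = 0, end = nchar(seq)),
                      spliced_seq = seq, junctions = integer(0),
                      n_exons = 1L), class = "gene_model")
  r <- select_region(m)   # window [1500, 1900) sits in the homopolymer
  pairs <- design_pairs(r, builtin_engine())
  expect_equal(nrow(pairs), 0)
  expect_match(attr(pairs, "reason"), "no acceptable")
})

test_that("span-mode amplicons straddle the junction", {
  dir <- withr::local_tempdir()
  g <- simulate_genome(genome_sim_spec(
    n_genes = 6, exon_count_props = c("1" = 0, "2" = 0.5, "3" = 0.5),
    seed = 19), dir)
  models <- load_annotation(g$fasta, g$gff3)
  for (m in models) {
    r <- select_region(m)
    pairs <- design_pairs(r, builtin_engine())
    expect_gt(nrow(pairs), 0)
    expect_true(all(pairs$spans_intron))
    expect_true(all(pairs$left_start < r$junction_target))
    expect_true(all(pairs$right_start + pairs$right_len > r$junction_target))
  }
})

test_that("strand symmetry: a flipped annotation yields identical primers", {
  dir <- withr::local_tempdir()
  g <- simulate_genome(genome_sim_spec(
    n_genes = 2, exon_count_props = c("1" = 0, "2" = 1, "3" = 0),
    minus_strand_prop = 0, seed = 31), dir)
  # flip: reverse-complement the contig and mirror the annotation
  genome <- Biostrings::readDNAStringSet(g$fasta)
  L <- Biostrings::width(genome)[1]
  flipped <- Biostrings::reverseComplement(genome)
  fa2 <- file.path(dir, "flipped.fa")
  Biostrings::writeXStringSet(flipped, fa2)
  gff <- read.table(g$gff3, sep = "\t", stringsAsFactors = FALSE)
  gff2 <- gff
  gff2$V4 <- L - gff$V5 + 1
  gff2$V5 <- L - gff$V4 + 1
  gff2$V7 <- ifelse(gff$V7 == "+", "-", "+")
  gff2_path <- file.path(dir, "flipped.gff3")
  writeLines(c("##gff-version 3",
               apply(gff2, 1, paste, collapse = "\t")), gff2_path)
  cat1 <- build_catalog(g$fasta, g$gff3)
  cat2 <- build_catalog(fa2, gff2_path)
  expect_equal(cat1$pairs$left_seq, cat2$pairs$left_seq)
  expect_equal(cat1$pairs$right_seq, cat2$pairs$right_seq)
  expect_equal(cat1$pairs$pair_penalty, cat2$pairs$pair_penalty)
})

test_that("catalog bookkeeping counts failures with reasons", {
  dir <- withr::local_tempdir()
  g <- simulate_genome(genome_sim_spec(n_genes = 8, seed = 41), dir)
  # append a pathological gene: a 600 bp homopolymer mono-exonic gene
  genome <- Biostrings::readDNAStringSet(g$fasta)
  homo <- Biostrings::DNAStringSet(strrep("A", 700))
  names(homo) <- "chrHomo"
  Biostrings::writeXStringSet(c(genome, homo), file.path(dir, "g2.fa"))
  gff <- readLines(g$gff3)
  gff <- c(gff,
    "chrHomo\ttest\tgene\t1\t700\t.\t+\t.\tID=homo_gene",
    "chrHomo\ttest\tmRNA\t1\t700\t.\t+\t.\tID=homo;Parent=homo_gene",
    "chrHomo\ttest\texon\t1\t700\t.\t+\t.\tID=homo_e1;Parent=homo")
  writeLines(gff, file.path(dir, "g2.gff3"))
  cat_obj <- build_catalog(file.path(dir, "g2.fa"), file.path(dir, "g2.gff3"))
  expect_equal(cat_obj$summary$attempted, 9)
  expect_equal(cat_obj$summary$with_full, 8)
  expect_equal(cat_obj$summary$failures$gene_id, "homo")
  expect_match(cat_obj$summary$failures$reason, "no acceptable")

  # deterministic output files on re-run
  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  build_catalog(g$fasta, g$gff3, out_dir = out1)
  build_catalog(g$fasta, g$gff3, out_dir = out2)
  expect_identical(readLines(file.path(out1, "catalog.tsv")),
                   readLines(file.path(out2, "catalog.tsv")))
})
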