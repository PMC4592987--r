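test_that("expression simulation is seed-reproducible with faithful classes", {
  spec <- expression_sim_spec(n_genes = 80, seed = 5)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a$courses[[1]]$values, b$courses[[1]]$values)
  expect_identical(a$truth, b$truth)
  # class proportions respected and every gene labelled
  expect_equal(nrow(a$truth), 80)
  expect_equal(sum(a$truth$class == "cycler"), 24)

  # zero-noise flat gene is constant; zero-noise cycler traces the cosine
  spec0 <- expression_sim_spec(
    n_genes = 2, time_points = seq(0, 44, 11), replicates = 1, courses = 1,
    classes = data.frame(class = c("flat", "cycler"), prop = c(0.5, 0.5),
                         sigma = 0, amplitude = c(0, 1), period = c(NA, 22),
                         slope = 0, low = FALSE),
    seed = 8)
  sim0 <- simulate_expression(spec0)
  v <- sim0$courses[[1]]$values
  expect_equal(diff(range(v[1, ])), 0)
  tr <- sim0$truth[2, ]
  expected <- tr$base + cos(2 * pi * (seq(0, 44, 11) - tr$phase) / 22)
  expect_equal(unname(v[2, ]), expected)
})

test_that("class-wise empirical noise matches the specified sigma", {
  sim <- simulate_expression(expression_sim_spec(n_genes = 200, seed = 10))
  truth <- sim$truth
  vals <- sim$courses[[1]]$values
  time <- sim$courses[[1]]$samples$time
  # flat genes: residual SD around the gene mean estimates sigma
  flats <- truth$class == "flat"
  sds <- apply(vals[flats, ], 1, sd)
  expect_lt(abs(mean(sds) - 0.2) / 0.2, 0.2)
})

test_that("planted construction nulls the time effect exactly", {
  sim <- planted_sim(seed = 12, n_genes = 100)
  tcm <- sim$courses[[1]]
  planted <- sim$truth$class == "planted"
  for (g in which(planted)) {
    p <- anova_time(tcm$values[g, ], tcm$samples$time)
    expect_gt(p, 0.999)
  }
  # opposed gradient: planted noise magnitudes reverse between courses
  sd_course <- function(cr) apply(sim$courses[[cr]]$values[planted, ], 1, sd)
  s1 <- sd_course(1); s2 <- sd_course(2)
  expect_equal(order(s1), rev(order(s2)))
})

test_that("genome simulation validates against its own FASTA", {
  dir <- withr::local_tempdir()
  g <- simulate_genome(genome_sim_spec(n_genes = 15, seed = 44), dir)
  genome <- Biostrings::readDNAStringSet(g$fasta)
  ann <- rtracklayer::import(g$gff3)
  expect_true(all(GenomicRanges::end(ann) <= Biostrings::width(genome)))
  # both strands and all three exon classes represented
  expect_setequal(unique(g$truth$strand), c("+", "-"))
  expect_setequal(unique(g$truth$n_exons), c(1L, 2L, 3L))
  # no homopolymer beyond 6 bp inside gene sequence
  models <- load_annotation(g$fasta, g$gff3)
  runs <- vapply(models, function(m)
    max(rle(strsplit(m$spliced_seq, "")[[1]])$lengths), 0)
  expect_true(all(runs <= 6))
})

test_that("all genes of the default genome spec are designable", {
  dir <- withr::local_tempdir()
  g <- simulate_genome(genome_sim_spec(n_genes = 25, seed = 46), dir)
  cat_obj <- build_catalog(g$fasta, g$gff3)
  expect_equal(cat_obj$summary$with_full, 25)
})

test_that("Ct simulation follows the dilution relation and dropout model", {
  catalog <- data.frame(gene_id = c("gHi", "gLo"), rank = 1,
                        pair_penalty = 0)
  lv <- c(gHi = 3, gLo = 2)
  tab <- simulate_ct(catalog, lv, seed = 3, noise_sd = 0,
                     lambda_penalty = 0, lambda_ct = 0)
  # zero noise: identical replicates; 10x expression = log2(10) cycles
  expect_equal(length(unique(tab$ct[tab$gene_id == "gHi"])), 1)
  d <- unique(tab$ct[tab$gene_id == "gLo"]) - unique(tab$ct[tab$gene_id == "gHi"])
  expect_equal(d, log2(10), tolerance = 1e-12)

  # dropout increases across penalty quartiles by construction
  set.seed(60)
  big <- data.frame(gene_id = sprintf("g%03d", 1:200), rank = 1,
                    pair_penalty = seq(0, 2, length.out = 200))
  lv_big <- setNames(rep(2, 200), big$gene_id)
  tab_big <- simulate_ct(big, lv_big, seed = 61, replicates = 10)
  drop_rate <- tapply(is.na(tab_big$ct),
                      cut(big$pair_penalty[match(tab_big$gene_id, big$gene_id)],
                          4), mean)
  expect_true(all(diff(drop_rate) > 0))
})
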