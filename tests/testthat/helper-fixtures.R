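# Shared fixtures built in code: tiny time-course matrices, a toy genome,
# and the planted-reference simulation spec used by the recovery tests.

# a minimal replicated course: n_time time points, n_rep replicates
toy_tcm <- function(values, times, replicates = 1, course = "course1",
                    scale = "absolute") {
  n_samp <- length(times) * replicates
  time <- rep(times, each = replicates)
  repl <- rep(seq_len(replicates), times = length(times))
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n_samp)),
                     time = time, replicate = repl, course_id = course)
  vals <- matrix(values, ncol = n_samp, byrow = TRUE)
  rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  colnames(vals) <- meta$sample_id
  time_course_matrix(vals, meta, scale = scale)
}

# gene classes for the planted-reference recovery experiments: 10 planted
# flat genes (tiny, mean-centered, opposed-gradient noise) among ordinary
# flats, 22-h cyclers and linear trenders with sigma >= 0.2 effects
planted_classes <- function() {
  data.frame(
    class = c("planted", "flat", "cycler", "trender", "low_expressed"),
    prop = c(0.05, 0.30, 0.30, 0.20, 0.15),
    sigma = c(2e-5, 0.2, 0.2, 0.2, 0.3),
    amplitude = c(0, 0, 1, 0, 0),
    period = c(NA, NA, 22, NA, NA),
    slope = c(0, 0, 0, 0.02, 0),
    low = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    centered_noise = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    opposed_gradient = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

planted_sim <- function(seed = 1, n_genes = 200) {
  simulate_expression(expression_sim_spec(
    n_genes = n_genes, classes = planted_classes(), seed = seed))
}

# rhythm calls taken from generator truth (the precomputed-calls workflow)
truth_rhythm_calls <- function(truth) {
  data.frame(gene_id = truth$gene_id,
             p_value = NA_real_,
             q_value = ifelse(truth$class == "cycler", 0, 1),
             is_rhythmic = truth$class == "cycler",
             stringsAsFactors = FALSE)
}

# one mono-exonic gene of the given length written as FASTA + GFF3
mono_exonic_fixture <- function(dir, len = 2000, seed = 11) {
  spec <- genome_sim_spec(n_genes = 1,
                          exon_count_props = c("1" = 1, "2" = 0, "3" = 0),
                          mono_len_range = c(len, len), seed = seed)
  simulate_genome(spec, dir)
}

# brute-force Kendall S by pair enumeration (oracle)
brute_kendall_S <- function(x, ref) {
  S <- 0
  n <- length(x)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      S <- S + sign(x[j] - x[i]) * sign(ref[j] - ref[i])
  S
}
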