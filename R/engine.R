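# Nearest-neighbor duplex parameters, unified oligonucleotide set
# (Allawi & SantaLucia 1997). dH in kcal/mol, dS in cal/(mol K); a
# dinucleotide and its reverse complement share one duplex value.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex-initiation terms per terminal base
.INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_R <- 1.987  # cal/(mol K)

.check_acgt <- function(seq) {
  if (!is.character(seq) || length(seq) != 1)
    stop("`seq` must be a single character string")
  if (grepl("[^ACGT]", seq))
    stop("non-ACGT character in sequence: ", seq)
}

.revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex Tm from nearest-neighbor thermodynamics with the unified
#' oligonucleotide parameter set, entropic salt correction
#' `0.368 (N-1) ln[Na+]`, and a two-state model at primer concentration
#' `CT/4`. Self-complementary sequences get the symmetry entropy correction
#' and full-concentration kinetics.
#'
#' @param seq Primer sequence, ACGT only, length >= 2.
#' @param mono_mM Monovalent cation concentration in mM (default 50).
#' @param dnac_nM Concentration of each strand in nM (default 25, giving
#'   `CT/4 = 12.5` nM for non-self-complementary primers).
#' @return Melting temperature in degrees Celsius.
#' @export
primer_tm <- function(seq, mono_mM = 50, dnac_nM = 25) {
  .check_acgt(seq)
  n <- nchar(seq)
  if (n < 2) stop("sequence too short for a nearest-neighbor Tm")
  chars <- strsplit(seq, "")[[1]]
  dinucs <- paste0(chars[-n], chars[-1])
  dh <- sum(.NN_DH[dinucs]) + .INIT_DH[chars[1]] + .INIT_DH[chars[n]]
  ds <- sum(.NN_DS[dinucs]) + .INIT_DS[chars[1]] + .INIT_DS[chars[n]]
  sym <- identical(seq, .revcomp(seq))
  if (sym) ds <- ds - 1.4
  k <- if (sym) dnac_nM * 1e-9 else (dnac_nM / 2) * 1e-9
  ds <- ds + 0.368 * (n - 1) * log(mono_mM / 1000)
  unname(dh * 1000 / (ds + .GAS_R * log(k)) - 273.15)
}

# Region-wide self-complementarity screen: finds every pair of k-length
# segments in [rng[1], rng[2]) that are reverse complements of each other
# and rejects candidate windows containing both segments — exactly the
# windows whose .max_comp_run() reaches k. Shared across all candidates of
# a design region.
.self_comp_rejected <- function(chars, rng, starts, lens, k) {
  rejected <- rep(FALSE, length(starts))
  if (rng[2] - rng[1] < k) return(rejected)
  pos <- seq.int(rng[1], rng[2] - k)        # 0-based k-mer starts
  seqstr <- paste(chars, collapse = "")
  kmers <- substring(seqstr, pos + 1L, pos + k)
  rck <- vapply(kmers, .revcomp, character(1), USE.NAMES = FALSE)
  by_kmer <- split(pos, kmers)
  lo <- integer(0); hi <- integer(0)
  for (j in seq_along(pos)) {
    is <- by_kmer[[rck[j]]]
    if (is.null(is)) next
    lo <- c(lo, pmin(is, pos[j]))
    hi <- c(hi, pmax(is, pos[j]) + k)
  }
  if (length(lo) == 0) return(rejected)
  iv <- unique(cbind(lo, hi))
  for (p in seq_len(nrow(iv)))
    rejected <- rejected | (starts <= iv[p, 1] & starts + lens >= iv[p, 2])
  rejected
}

# longest complementarity run: longest common substring between the
# sequence and its reverse complement (self-dimer / hairpin stem proxy)
.max_comp_run <- function(seq) {
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(.revcomp(seq), "")[[1]]
  n <- length(a)
  best <- 0L
  prev <- integer(n)
  for (i in seq_len(n)) {
    cur <- integer(n)
    match_j <- which(b == a[i])
    for (j in match_j)
      cur[j] <- if (j > 1) prev[j - 1] + 1L else 1L
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

#' Built-in primer search engine
#'
#' A self-contained, deterministic primer scorer and searcher used by
#' [design_pairs()] and [build_catalog()]. Single-primer penalty is a
#' weighted deviation from the optimum:
#' `w_tm |Tm - tm_opt| + w_size |len - size_opt| + w_gc |GC - gc_opt|`;
#' a pair's penalty adds both primer penalties and `w_diff |Tm_L - Tm_R|`.
#' Candidates whose melting temperature or GC fraction falls outside the
#' acceptance window, or whose longest self-complementarity run reaches
#' `self_comp_max`, are rejected. All parameters are echoed into catalog
#' metadata.
#'
#' @param tm_opt,tm_min,tm_max Optimal and acceptable primer Tm in degrees C.
#'   The default optimum of 60 matches a standard 60-degree annealing step;
#'   the window is opt +/- 6 on this engine's Tm scale.
#' @param size_opt,size_min,size_max Primer length in nt.
#' @param gc_opt,gc_min,gc_max GC content as a fraction.
#' @param w_tm,w_size,w_gc,w_diff Penalty weights.
#' @param max_tm_diff Largest allowed |Tm_L - Tm_R| for a pair (degrees C).
#' @param self_comp_max Reject primers with a complementarity run of this
#'   many bases or more.
#' @param product_range Allowed amplicon length on the spliced transcript.
#' @param max_candidates Candidate primers retained per side (best by
#'   penalty) before the pair search; the default keeps all acceptable
#'   candidates of a typical 400-500 bp region.
#' @param mono_mM,dnac_nM Passed to [primer_tm()].
#' @return An object of class `c("builtin_engine", "primer_search_engine")`.
#' @export
builtin_engine <- function(tm_opt = 60, tm_min = 54, tm_max = 66,
                           size_opt = 20, size_min = 18, size_max = 27,
                           gc_opt = 0.5, gc_min = 0.2, gc_max = 0.8,
                           w_tm = 1, w_size = 1, w_gc = 1, w_diff = 1,
                           max_tm_diff = 3, self_comp_max = 8,
                           product_range = c(100, 250),
                           max_candidates = 3000, mono_mM = 50, dnac_nM = 25) {
  structure(list(tm_opt = tm_opt, tm_min = tm_min, tm_max = tm_max,
                 size_opt = size_opt, size_min = size_min, size_max = size_max,
                 gc_opt = gc_opt, gc_min = gc_min, gc_max = gc_max,
                 w_tm = w_tm, w_size = w_size, w_gc = w_gc, w_diff = w_diff,
                 max_tm_diff = max_tm_diff, self_comp_max = self_comp_max,
                 product_range = product_range, max_candidates = max_candidates,
                 mono_mM = mono_mM, dnac_nM = dnac_nM),
            class = c("builtin_engine", "primer_search_engine"))
}

#' @export
print.builtin_engine <- function(x, ...) {
  cat(sprintf(paste0("builtin primer engine: Tm opt %g C [%g, %g], ",
                     "size %d-%d nt (opt %d), GC [%g, %g], product %d-%d bp\n"),
              x$tm_opt, x$tm_min, x$tm_max, x$size_min, x$size_max,
              x$size_opt, x$gc_min, x$gc_max,
              x$product_range[1], x$product_range[2]))
  invisible(x)
}

#' Binding for an external Primer3 executable
#'
#' Looks up `primer3_core` on the PATH. When present, returns an engine
#' handle for [design_pairs()]; when absent, raises an error directing the
#' caller to [builtin_engine()].
#'
#' @param path Optional explicit path to `primer3_core`.
#' @return An object of class `c("primer3_engine", "primer_search_engine")`.
#' @export
primer3_engine <- function(path = Sys.which("primer3_core")) {
  if (is.na(path) || !nzchar(path) || !file.exists(path))
    stop("primer3_core not found on this system; ",
         "use builtin_engine() instead")
  structure(list(path = path), class = c("primer3_engine", "primer_search_engine"))
}

#' Score a single primer candidate
#'
#' Computes the built-in engine's melting temperature, GC fraction and
#' penalty for one primer sequence, along with whether the candidate passes
#' the engine's acceptance constraints.
#'
#' @param seq Primer sequence (ACGT).
#' @param engine A [builtin_engine()].
#' @return A list: `tm` (degrees C), `gc` (fraction), `penalty`,
#'   `comp_run` (longest self-complementarity run), `acceptable` (logical).
#' @export
primer_score <- function(seq, engine = builtin_engine()) {
  .check_acgt(seq)
  n <- nchar(seq)
  tm <- primer_tm(seq, engine$mono_mM, engine$dnac_nM)
  gc <- (nchar(gsub("[AT]", "", seq))) / n
  penalty <- engine$w_tm * abs(tm - engine$tm_opt) +
    engine$w_size * abs(n - engine$size_opt) +
    engine$w_gc * abs(gc - engine$gc_opt)
  run <- .max_comp_run(seq)
  acceptable <- n >= engine$size_min && n <= engine$size_max &&
    tm >= engine$tm_min && tm <= engine$tm_max &&
    gc >= engine$gc_min && gc <= engine$gc_max &&
    run < engine$self_comp_max
  list(tm = tm, gc = gc, penalty = penalty, comp_run = run,
       acceptable = acceptable)
}

# Vectorized window thermodynamics over one template sequence: Tm, GC and
# single-primer penalty for every window of length L at the given 0-based
# starts. Equals primer_tm()/primer_score() on the extracted subsequence
# (and on its reverse complement: the duplex is the same). `cums` holds
# per-sequence cumulative sums so repeated calls share the lookup work.
.thermo_cums <- function(chars) {
  n <- length(chars)
  dinucs <- paste0(chars[-n], chars[-1])
  list(dh = c(0, cumsum(.NN_DH[dinucs])),
       ds = c(0, cumsum(.NN_DS[dinucs])),
       gc = c(0, cumsum(chars %in% c("G", "C"))),
       init_dh = unname(.INIT_DH[chars]),
       init_ds = unname(.INIT_DS[chars]))
}

.window_scores <- function(cums, starts0, L, engine) {
  s1 <- starts0 + 1L                      # 1-based window start
  e1 <- starts0 + L                       # 1-based window end
  dh <- (cums$dh[e1] - cums$dh[s1]) + cums$init_dh[s1] + cums$init_dh[e1]
  ds <- (cums$ds[e1] - cums$ds[s1]) + cums$init_ds[s1] + cums$init_ds[e1]
  ds <- ds + 0.368 * (L - 1) * log(engine$mono_mM / 1000)
  k <- (engine$dnac_nM / 2) * 1e-9
  tm <- dh * 1000 / (ds + .GAS_R * log(k)) - 273.15
  gc <- (cums$gc[e1 + 1L] - cums$gc[s1]) / L
  penalty <- engine$w_tm * abs(tm - engine$tm_opt) +
    engine$w_size * abs(L - engine$size_opt) +
    engine$w_gc * abs(gc - engine$gc_opt)
  data.frame(start = starts0, len = L, tm = tm, gc = gc, penalty = penalty)
}
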