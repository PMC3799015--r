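#' Extract promoter windows around transcription start sites
#'
#' Cuts `-upstream..+downstream` nt windows (801 nt by default) around
#' each TSS from a genome. BED is 0-based half-open: the TSS is `start`
#' on the + strand and `end - 1` on the - strand; minus-strand windows
#' are reverse-complemented so position 0 of every returned sequence is
#' `-upstream` in promoter coordinates. Windows running off a contig
#' end are clipped and flagged.
#'
#' @param genome named character vector / `DNAStringSet` of contig
#'   sequences, or a FASTA path.
#' @param tss_bed data.frame from [read_bed_intervals()] (or a BED6
#'   path); the `name` column labels the promoters.
#' @param upstream,downstream window half-widths in nt.
#' @return A `PromoterSet` with `clipped` flags.
#' @export
extract_promoters <- function(genome, tss_bed, upstream = 400,
                              downstream = 400) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)$seqs
  } else if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (is.character(tss_bed) && length(tss_bed) == 1) {
    tss_bed <- read_bed_intervals(tss_bed)
  }
  seqs <- character(nrow(tss_bed))
  clipped <- logical(nrow(tss_bed))
  for (i in seq_len(nrow(tss_bed))) {
    chrom <- tss_bed$chrom[i]
    if (!chrom %in% names(genome)) stop_("contig not in genome: ", chrom)
    clen <- nchar(genome[[chrom]])
    tss0 <- if (tss_bed$strand[i] == "+") tss_bed$start[i] else tss_bed$end[i] - 1L
    if (tss0 < 0 || tss0 >= clen) {
      stop_("TSS of '", tss_bed$name[i], "' outside contig ", chrom)
    }
    if (tss_bed$strand[i] == "+") {
      from0 <- tss0 - upstream
      to0 <- tss0 + downstream           # inclusive, 0-based
    } else {
      from0 <- tss0 - downstream
      to0 <- tss0 + upstream
    }
    cf <- max(from0, 0L)
    ct <- min(to0, clen - 1L)
    clipped[i] <- cf != from0 || ct != to0
    s <- toupper(substr(genome[[chrom]], cf + 1L, ct + 1L))
    if (tss_bed$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    seqs[i] <- s
  }
  names(seqs) <- tss_bed$name
  promoter_set(seqs, upstream = upstream, downstream = downstream,
               clipped = clipped)
}

#' TRAP biophysical binding affinity of a sequence for a PWM
#'
#' The expected occupancy model: every length-L window `i` (on both
#' strands by default) contributes `R0 * exp(-E_i) / (1 + R0 *
#' exp(-E_i))`, where the mismatch energy is `E_i = (1/lambda) *
#' sum_pos ln(p_max,pos / p_obs,pos)` — zero for the consensus window
#' and growing with every departure from it. Defaults are the
#' published TRAP parameterisation `lambda = 0.7`, `ln R0 = 0.584 * L -
#' 5.66`. `N` bases contribute the neutral background probability
#' 0.25. Sequences shorter than the PWM have affinity 0 by convention.
#'
#' @param sequence character string over A,C,G,T,N.
#' @param pwm a `PWM`; all entries must be positive (use a pseudocount).
#' @param lambda energy scale.
#' @param r0_slope,r0_intercept parameters of `ln R0 = slope * L +
#'   intercept`.
#' @param ln_r0 override `ln R0` directly (ignores slope/intercept).
#' @param both_strands also scan the reverse complement (default).
#' @return Scalar affinity (sum of per-window occupancies).
#' @export
trap_affinity <- function(sequence, pwm, lambda = 0.7, r0_slope = 0.584,
                          r0_intercept = -5.66, ln_r0 = NULL,
                          both_strands = TRUE) {
  mat <- pwm$mat
  if (any(mat <= 0)) {
    stop_("PWM '", pwm$id, "' has non-positive entries: mismatch energy ",
          "undefined; rebuild it with a pseudocount")
  }
  L <- ncol(mat)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < L) return(0)
  ln_r0 <- ln_r0 %||% (r0_slope * L + r0_intercept)
  code <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T", "N"))
  if (any(is.na(code))) stop_("sequence contains characters outside A,C,G,T,N")
  nw <- n - L + 1L

  window_sum <- function(m) {
    pmaxc <- apply(m, 2, max)
    lr <- rbind(log(pmaxc / m["A", ]), log(pmaxc / m["C", ]),
                log(pmaxc / m["G", ]), log(pmaxc / m["T", ]),
                log(pmaxc / 0.25))
    e <- numeric(nw)
    for (j in seq_len(L)) {
      e <- e + lr[cbind(code[j:(j + nw - 1L)], j)]
    }
    # occupancy R0 e^-E / (1 + R0 e^-E) = logistic(ln R0 - E)
    sum(stats::plogis(ln_r0 - e / lambda))
  }
  aff <- window_sum(mat)
  if (both_strands) aff <- aff + window_sum(revcomp_pwm_matrix(mat))
  aff
}

#' TRAP affinities for a promoter set against a PWM collection
#'
#' @param promoters a `PromoterSet` (or named character vector).
#' @param pwms list of `PWM` objects.
#' @param ... passed to [trap_affinity()].
#' @return Numeric matrix, genes x PWMs.
#' @export
trap_affinity_table <- function(promoters, pwms, ...) {
  seqs <- if (inherits(promoters, "PromoterSet")) promoters$seqs else promoters
  out <- vapply(pwms, function(p) {
    vapply(seqs, trap_affinity, numeric(1), pwm = p, ...)
  }, numeric(length(seqs)))
  out <- matrix(out, nrow = length(seqs),
                dimnames = list(names(seqs),
                                vapply(pwms, `[[`, character(1), "id")))
  out
}

#' Rank-cutoff-maximised hypergeometric motif enrichment
#'
#' The PASTAA-style association statistic: genes are ranked by
#' affinity (ties broken by symbol), and for each cutoff `k` of a grid
#' the hypergeometric tail p of the overlap between the top-k genes
#' and the test set is computed; the best (smallest) p and its cutoff
#' are reported. Because the minimum over cutoffs is optimised, the
#' raw p is anti-conservative; a label-permutation adjustment rates it
#' against `n_perm` random test sets of equal size, and the adjusted p
#' is additionally clamped to be no smaller than the raw best p.
#'
#' @param affinities named numeric vector (one PWM) or gene x PWM
#'   matrix from [trap_affinity_table()].
#' @param test_set genes whose promoters are tested for enrichment
#'   (>= 3, a subset of the universe).
#' @param universe gene universe; defaults to the affinity names. The
#'   control set is the universe minus the test set.
#' @param cutoff_grid rank cutoffs; default
#'   `{20, 50, 100, 200, 500, |universe|}` clipped to the universe.
#' @param n_perm label permutations (>= 100).
#' @param seed integer seed.
#' @return data.frame of class `MotifEnrichment`, one row per PWM:
#'   `pwm`, `k_best`, `overlap`, `p_raw`, `p_adj`.
#' @export
pastaa_enrichment <- function(affinities, test_set, universe = NULL,
                              cutoff_grid = NULL, n_perm = 1000, seed = 1) {
  if (is.matrix(affinities)) {
    rows <- lapply(colnames(affinities), function(pw) {
      pastaa_enrichment(affinities[, pw], test_set, universe, cutoff_grid,
                        n_perm, seed)
    })
    out <- do.call(rbind, rows)
    out$pwm <- colnames(affinities)
    rownames(out) <- NULL
    class(out) <- c("MotifEnrichment", "data.frame")
    return(out[, c("pwm", "k_best", "overlap", "p_raw", "p_adj")])
  }
  if (n_perm < 100) stop_("n_perm must be >= 100")
  universe <- universe %||% names(affinities)
  if (is.null(universe)) stop_("affinities must be named by gene")
  affinities <- affinities[universe]
  if (any(is.na(affinities))) stop_("affinity missing for part of the universe")
  if (length(test_set) < 3) stop_("test set needs >= 3 genes")
  if (!all(test_set %in% universe)) {
    stop_("test set gene outside the universe: ",
          setdiff(test_set, universe)[1])
  }
  n <- length(universe)
  grid <- cutoff_grid %||% c(20, 50, 100, 200, 500, n)
  grid <- sort(unique(pmin(pmax(as.integer(grid), 1L), n)))
  if (!length(grid)) stop_("empty cutoff grid")

  ord <- order(-affinities, universe)
  is_test <- universe[ord] %in% test_set
  k_test <- length(unique(test_set))
  best_p <- function(member) {
    ct <- cumsum(member)
    p <- stats::phyper(ct[grid] - 1, k_test, n - k_test, grid,
                       lower.tail = FALSE)
    i <- which.min(p)
    c(p[i], grid[i], ct[grid[i]])
  }
  obs <- best_p(is_test)
  perm_best <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    best_p(sample(is_test))[1]
  }, numeric(1)))
  p_adj <- (sum(perm_best <= obs[1] + 1e-12) + 1) / (n_perm + 1)
  p_adj <- max(p_adj, obs[1])
  out <- data.frame(pwm = NA_character_, k_best = as.integer(obs[2]),
                    overlap = as.integer(obs[3]), p_raw = obs[1],
                    p_adj = p_adj, stringsAsFactors = FALSE)
  class(out) <- c("MotifEnrichment", "data.frame")
  out
}
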