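# Independent brute-force oracles. These deliberately re-derive each
# statistic by direct enumeration, sharing no code with the package
# implementations they check.

# step-by-step GSEA running sum over every position of the ranked list
oracle_es <- function(genes, scores, set_genes, weight_p = 1) {
  n <- length(genes)
  hit <- genes %in% set_genes
  nh <- sum(hit)
  w <- abs(scores)^weight_p
  wsum <- sum(w[hit])
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + (if (wsum > 0) w[i] / wsum else 1 / nh)
    } else {
      cur <- cur - 1 / (n - nh)
    }
    run[i] <- cur
  }
  i_max <- which.max(run)
  i_min <- which.min(run)
  if (run[i_max] >= -run[i_min]) {
    peak <- i_max
    es <- run[i_max]
    le <- genes[which(hit & seq_len(n) <= peak)]
  } else {
    # minimum of the running sum; members at or after it drive the deficit
    peak <- i_min
    es <- run[i_min]
    le <- genes[which(hit & seq_len(n) >= peak)]
  }
  list(es = es, peak = peak, leading_edge = le)
}

# O(n^3) complete-linkage agglomeration, lowest-index pair first on ties
oracle_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights[step] <- best_h
    partitions[[step]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# hand step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[o][seq(i, m)] * m / seq(i, m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# TRAP affinity by explicit loop over windows and strands
oracle_trap <- function(seq, pwm_mat, lambda = 0.7, ln_r0 = NULL) {
  L <- ncol(pwm_mat)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < L) return(0)
  if (is.null(ln_r0)) ln_r0 <- 0.584 * L - 5.66
  r0 <- exp(ln_r0)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  occupancy <- function(window, m) {
    e <- 0
    for (j in seq_len(L)) {
      pobs <- if (window[j] == "N") 0.25 else m[window[j], j]
      e <- e + log(max(m[, j]) / pobs)
    }
    e <- e / lambda
    r0 * exp(-e) / (1 + r0 * exp(-e))
  }
  total <- 0
  for (i in seq_len(n - L + 1)) {
    win <- chars[i:(i + L - 1)]
    total <- total + occupancy(win, pwm_mat)
    rc <- rev(unname(comp[win]))
    total <- total + occupancy(rc, pwm_mat)
  }
  unname(total)
}

# random PWM with strictly positive entries
random_pwm <- function(id, L, min_p = 0.02) {
  counts <- matrix(stats::runif(4 * L, 1, 20), 4, L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_from_counts(id, counts, pseudocount = 4 * L * min_p)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny valid study written by hand: 2 contrasts x 2 states x 2 replicates
tiny_study <- function(n_genes = 20, n_contrasts = 2, seed = 42,
                       species = "mouse", n_replicates = 2) {
  withr::with_seed(seed, {
    cons <- sprintf("c%02d", seq_len(n_contrasts))
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           state = c("quiescent", "activated"),
                           contrast = cons, stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_%s_%d", samples$contrast,
                                 substr(samples$state, 1, 1),
                                 samples$replicate)
    samples$subset <- "pDC"
    samples$species <- species
    x <- matrix(stats::rnorm(n_genes * nrow(samples), 7, 1),
                n_genes, nrow(samples),
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                samples$sample_id))
    expression_study(x, samples)
  })
}
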