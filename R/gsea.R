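#' Rank the genes of a contrast
#'
#' Orders genes best-to-worst for an activated-vs-quiescent contrast.
#' The default metric is the log2 fold change of replicate means — the
#' stable choice with duplicate arrays. Signal-to-noise is available
#' with a variance floor (each group sd is floored at
#' `sd_floor_frac * |mean|`, the convention of classic GSEA). Ties are
#' broken by lexicographic gene symbol so rankings are reproducible.
#'
#' @param study an `ExpressionStudy`.
#' @param contrast contrast id.
#' @param metric `"log2fc"` or `"s2n"`.
#' @param sd_floor_frac variance-floor fraction for `"s2n"`.
#' @return A data.frame of class `RankedList` with columns `gene` and
#'   `score`, sorted by non-increasing score.
#' @export
rank_genes <- function(study, contrast, metric = c("log2fc", "s2n"),
                       sd_floor_frac = 0.2) {
  metric <- match.arg(metric)
  ids_q <- contrast_samples(study, contrast, "quiescent")
  ids_a <- contrast_samples(study, contrast, "activated")
  rank_genes_groups(study, ids_a, ids_q, metric, sd_floor_frac,
                    label = contrast)
}

#' Rank genes for an arbitrary two-group comparison
#'
#' Same metrics as [rank_genes()], but over explicit sample-id groups —
#' the form needed for pairwise subset-vs-subset comparisons.
#' @param study an `ExpressionStudy`.
#' @param ids_a,ids_b sample ids of the two groups (scores favour `a`).
#' @param metric,sd_floor_frac see [rank_genes()].
#' @param label label stored on the result.
#' @export
rank_genes_groups <- function(study, ids_a, ids_b,
                              metric = c("log2fc", "s2n"),
                              sd_floor_frac = 0.2, label = NULL) {
  metric <- match.arg(metric)
  xa <- study$exprs[, ids_a, drop = FALSE]
  xb <- study$exprs[, ids_b, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  if (metric == "log2fc") {
    score <- ma - mb
  } else {
    sa <- apply(xa, 1, stats::sd)
    sb <- apply(xb, 1, stats::sd)
    if (sd_floor_frac > 0) {
      sa <- pmax(sa, sd_floor_frac * abs(ma))
      sb <- pmax(sb, sd_floor_frac * abs(mb))
    }
    pooled <- sa + sb
    if (any(pooled == 0)) {
      stop_("zero pooled sd for signal-to-noise ranking; set a variance floor")
    }
    score <- (ma - mb) / pooled
  }
  ord <- order(-score, rownames(study$exprs))
  out <- data.frame(gene = rownames(study$exprs)[ord], score = score[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "label") <- label
  class(out) <- c("RankedList", class(out))
  out
}

# Weighted running-sum ES from sorted hit positions.
# `aw` = |score|^weight_p over the whole ranked list. Hit increments are
# normalised weights, miss decrements 1/(N - n_hits); the ES is the
# signed extremum of the running sum. Extrema can only occur at a hit
# position (maximum) or just before a hit (minimum), which keeps this
# O(n_hits) per evaluation.
es_from_positions <- function(hits, aw, n) {
  m <- length(hits)
  w <- aw[hits]
  tot <- sum(w)
  w <- if (tot > 0) w / tot else rep(1 / m, m)
  ch <- cumsum(w)
  adj <- (hits - seq_len(m)) / (n - m)
  r_at <- ch - adj                      # running sum at each hit
  r_before <- c(0, ch[-m]) - adj        # running sum just before each hit
  es_pos <- max(r_at)
  es_neg <- min(r_before)
  if (es_pos >= -es_neg) {
    j <- which.max(r_at)
    list(es = es_pos, j = j, peak = hits[j], positive = TRUE)
  } else {
    j <- which.min(r_before)
    list(es = es_neg, j = j, peak = hits[j] - 1L, positive = FALSE)
  }
}

#' Weighted running-sum enrichment score with leading edge
#'
#' The GSEA statistic: walking down the ranked list, set members ("hits")
#' increment a running sum by their normalised weight
#' `|score|^weight_p / sum(|score|^weight_p over hits)` and non-members
#' decrement it by `1/(N - n_hits)`; the enrichment score (ES) is the
#' signed extremum, bounded in `[-1, 1]`. The leading edge is the set
#' members at or before the peak for positive ES, and at or after the
#' (position of the) negative peak for negative ES. An exact tie
#' between the positive and negative extremum resolves to the positive
#' one.
#'
#' @param ranked a `RankedList`.
#' @param gene_set a `GeneSet` or character vector of symbols; must
#'   intersect the ranked universe and must not cover it entirely.
#' @param weight_p weight exponent (1 = standard weighted GSEA; 0 =
#'   classic Kolmogorov-Smirnov form).
#' @return list with `es`, `peak` (index in the ranked list) and
#'   `leading_edge` (character vector of genes).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  set_genes <- if (inherits(gene_set, "GeneSet")) gene_set$genes else gene_set
  n <- length(genes)
  hits <- which(genes %in% set_genes)
  if (!length(hits)) stop_("gene set is disjoint from the ranked universe")
  if (length(hits) == n) {
    stop_("gene set covers the whole universe: miss decrement undefined")
  }
  aw <- abs(ranked$score)^weight_p
  r <- es_from_positions(hits, aw, n)
  le <- if (r$positive) genes[hits[seq_len(r$j)]] else genes[hits[r$j:length(hits)]]
  list(es = r$es, peak = r$peak, leading_edge = le)
}

#' GSEA with a gene-set permutation null
#'
#' Tests each gene set against a null of random same-size gene sets
#' drawn from the universe — the recommended null when contrasts carry
#' only duplicate samples, where phenotype permutation is impossible.
#' NES rescales the ES by the mean |null ES| of matching sign; the
#' nominal p is the same-sign permutation tail, and the FDR q follows
#' the GSEA tail-ratio procedure over the pooled normalised null.
#' Null sets are drawn from the lexicographically sorted universe so
#' results are deterministic under `seed` and invariant to the ranking
#' order of the input.
#'
#' @param ranked a `RankedList`.
#' @param gene_sets list of `GeneSet` objects (or character vectors).
#' @param n_perm number of null sets per gene set (>= 100).
#' @param seed integer seed.
#' @param weight_p weight exponent, see [enrichment_score()].
#' @return data.frame with one row per set: `set`, `direction`, `size`,
#'   `es`, `peak`, `nes`, `p`, `q`, plus a `leading_edge` list-column;
#'   `n_perm` and `seed` in attributes.
#' @export
gsea_test <- function(ranked, gene_sets, n_perm = 1000, seed = 1,
                      weight_p = 1) {
  if (n_perm < 100) stop_("n_perm must be >= 100")
  genes <- ranked$gene
  n <- length(genes)
  aw <- abs(ranked$score)^weight_p
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- vapply(gene_sets, function(s)
      if (inherits(s, "GeneSet")) s$name else stop_("unnamed gene set"),
      character(1))
  }

  obs <- lapply(gene_sets, function(s) enrichment_score(ranked, s, weight_p))
  sizes <- vapply(gene_sets, function(s) {
    g <- if (inherits(s, "GeneSet")) s$genes else s
    sum(genes %in% g)
  }, integer(1))

  # null draws keyed to the sorted universe: identical seeds give
  # identical null *gene* sets whatever the ranking order
  canon_to_rank <- order(genes)  # position in `genes` of each sorted symbol
  null_by_size <- list()
  withr::with_seed(seed, {
    for (k in sort(unique(sizes))) {
      null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
        hits <- sort(canon_to_rank[sample.int(n, k)])
        es_from_positions(hits, aw, n)$es
      }, numeric(1))
    }
  })

  nes <- p_nom <- numeric(length(gene_sets))
  null_nes_pool <- numeric(0)
  norm_null <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    nl <- null_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(nl[nl > 0])
    neg_mean <- mean(abs(nl[nl < 0]))
    if (!is.finite(pos_mean)) pos_mean <- mean(abs(nl))
    if (!is.finite(neg_mean)) neg_mean <- mean(abs(nl))
    es <- obs[[i]]$es
    nes[i] <- if (es >= 0) es / pos_mean else es / neg_mean
    same <- if (es >= 0) nl[nl >= 0] else nl[nl < 0]
    p_nom[i] <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
    nn <- ifelse(nl >= 0, nl / pos_mean, nl / neg_mean)
    norm_null[[i]] <- nn
    null_nes_pool <- c(null_nes_pool, nn)
  }

  q <- vapply(seq_along(gene_sets), function(i) {
    x <- nes[i]
    if (x >= 0) {
      num_den <- sum(null_nes_pool >= 0)
      num <- if (num_den > 0) sum(null_nes_pool >= x) / num_den else 1
      den_den <- sum(nes >= 0)
      den <- if (den_den > 0) sum(nes >= x) / den_den else 1
    } else {
      num_den <- sum(null_nes_pool < 0)
      num <- if (num_den > 0) sum(null_nes_pool <= x) / num_den else 1
      den_den <- sum(nes < 0)
      den <- if (den_den > 0) sum(nes <= x) / den_den else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  dirs <- vapply(gene_sets, function(s)
    if (inherits(s, "GeneSet")) s$direction else "unsigned", character(1))
  out <- data.frame(set = names(gene_sets), direction = dirs, size = sizes,
                    es = vapply(obs, `[[`, numeric(1), "es"),
                    peak = vapply(obs, `[[`, numeric(1), "peak"),
                    nes = nes, p = p_nom, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$leading_edge <- lapply(obs, `[[`, "leading_edge")
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "weight_p") <- weight_p
  out
}

#' GSEA across a panel of contrasts
#'
#' Runs [gsea_test()] for every activation contrast of one or more
#' studies (or for explicit sample-group pairs), producing the long
#' table behind circle-plot style summaries: one row per
#' (comparison, gene set) with NES, |NES|, FDR q and the leading edge.
#' For human-species comparisons the (mouse-symbol) gene sets are
#' translated with [map_orthologs()] first.
#'
#' @param studies an `ExpressionStudy` or list of them.
#' @param gene_sets list of `GeneSet` objects.
#' @param n_perm,seed,weight_p,metric GSEA parameters.
#' @param ortholog_table named mouse-to-human vector (optional; unmapped
#'   symbols fall back to upper-casing).
#' @param min_set_size skip (comparison, set) pairs whose intersection
#'   with the universe is smaller than this.
#' @param pairs optional list of explicit comparisons, each a list with
#'   `label`, `study` (index into `studies`), `a` and `b` (sample ids);
#'   when given, contrasts are not enumerated.
#' @return data.frame with columns `species`, `contrast`, `set`,
#'   `direction`, `size`, `es`, `nes`, `abs_nes`, `p`, `q` and a
#'   `leading_edge` list-column.
#' @export
pairwise_matrix <- function(studies, gene_sets, n_perm = 1000, seed = 1,
                            weight_p = 1, metric = "log2fc",
                            ortholog_table = NULL, min_set_size = 3,
                            pairs = NULL) {
  if (inherits(studies, "ExpressionStudy")) studies <- list(studies)
  comparisons <- list()
  if (is.null(pairs)) {
    for (si in seq_along(studies)) {
      st <- studies[[si]]
      for (cid in unique(st$samples$contrast)) {
        comparisons[[length(comparisons) + 1]] <- list(
          study = si, label = cid,
          a = contrast_samples(st, cid, "activated"),
          b = contrast_samples(st, cid, "quiescent"))
      }
    }
  } else {
    comparisons <- pairs
  }
  rows <- list()
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    st <- studies[[cmp$study %||% 1]]
    species <- unique(st$samples$species[st$samples$sample_id %in% c(cmp$a, cmp$b)])
    if (length(species) != 1) species <- unique(st$samples$species)[1]
    ranked <- rank_genes_groups(st, cmp$a, cmp$b, metric, label = cmp$label)
    sets <- gene_sets
    if (identical(species, "human")) {
      sets <- lapply(sets, function(s) {
        gene_set(s$name, map_orthologs(s$genes, ortholog_table,
                                       fallback = "uppercase"), s$direction)
      })
    }
    keep <- vapply(sets, function(s) {
      k <- sum(ranked$gene %in% s$genes)
      k >= min_set_size && k < length(ranked$gene)
    }, logical(1))
    if (!any(keep)) next
    res <- gsea_test(ranked, sets[keep], n_perm = n_perm,
                     seed = seed + ci - 1, weight_p = weight_p)
    res$species <- species
    res$contrast <- cmp$label
    rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop_("no (comparison, gene set) pair was testable")
  out <- do.call(rbind, rows)
  out$abs_nes <- abs(out$nes)
  rownames(out) <- NULL
  out[, c("species", "contrast", "set", "direction", "size", "es", "nes",
          "abs_nes", "p", "q", "peak", "leading_edge")]
}

#' Hypergeometric over-representation test
#'
#' One-sided hypergeometric tail of the overlap between a gene list and
#' each annotation set, within a stated universe; BH-adjusted across
#' sets. This is the generic annotation-enrichment companion to the
#' ranked GSEA.
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param universe character vector of all eligible genes.
#' @param annotation_sets named list of `GeneSet` objects or character
#'   vectors.
#' @return data.frame with per-set overlap counts, `p` and `q`.
#' @export
ora_test <- function(gene_list, universe, annotation_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop_("empty universe")
  if (!all(gene_list %in% universe)) {
    stop_("gene_list contains genes outside the universe: ",
          setdiff(gene_list, universe)[1])
  }
  gene_list <- unique(gene_list)
  res <- lapply(names(annotation_sets), function(nm) {
    s <- annotation_sets[[nm]]
    g <- if (inherits(s, "GeneSet")) s$genes else s
    g <- intersect(g, universe)
    x <- length(intersect(gene_list, g))
    p <- stats::phyper(x - 1, length(g), length(universe) - length(g),
                       length(gene_list), lower.tail = FALSE)
    data.frame(set = nm, overlap = x, set_size = length(g),
               list_size = length(gene_list), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
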