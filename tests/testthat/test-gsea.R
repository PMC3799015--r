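ranked_fixture <- function(n = 10, seed = 1) {
  withr::with_seed(seed, {
    score <- sort(rnorm(n), decreasing = TRUE)
    data.frame(gene = sprintf("g%03d", sample(n)), score = score,
               stringsAsFactors = FALSE)
  })
}

test_that("gene ranking orders by metric with deterministic ties", {
  x <- rbind(hi = c(6, 6, 8, 8), lo = c(8, 8, 6, 6), tie_b = c(7, 7, 7, 7),
             tie_a = c(5, 5, 5, 5))
  colnames(x) <- c("q1", "q2", "a1", "a2")
  samples <- data.frame(sample_id = colnames(x), subset = "pDC",
                        state = rep(c("quiescent", "activated"), each = 2),
                        species = "mouse", contrast = "c1",
                        replicate = c(1, 2, 1, 2))
  study <- expression_study(x, samples)
  r <- rank_genes(study, "c1")
  expect_equal(r$gene[1], "hi")
  expect_equal(r$gene[4], "lo")
  expect_equal(r$score[c(1, 4)], c(2, -2))
  expect_equal(r$gene[2:3], c("tie_a", "tie_b"))  # lexicographic tie-break

  shuffled <- expression_study(x[c(3, 1, 4, 2), ], samples)
  expect_equal(rank_genes(shuffled, "c1"), r, ignore_attr = TRUE)
})

test_that("planted core genes rank near the top", {
  gen <- generate_study(n_genes = 1000, seed = 17)
  r <- rank_genes(gen$mouse, "m01")
  pos <- match(gen$truth$core_up, r$gene)
  expect_lt(median(pos), 100)  # top decile of 1000
})

test_that("enrichment score handles the degenerate and singleton cases", {
  r <- ranked_fixture(10)
  top <- r$gene[1]
  es <- enrichment_score(r, top)
  expect_equal(es$es, 1.0)
  expect_equal(es$peak, 1)
  expect_equal(es$leading_edge, top)
  expect_error(enrichment_score(r, r$gene), "whole universe")
  expect_error(enrichment_score(r, c("absent1", "absent2")), "disjoint")
})

test_that("enrichment scores match the step-by-step oracle", {
  # fixed small case
  r <- ranked_fixture(10, seed = 3)
  set <- r$gene[c(2, 5, 9)]
  got <- enrichment_score(r, set)
  want <- oracle_es(r$gene, r$score, set)
  expect_equal(got$es, want$es, tolerance = 1e-12)
  expect_equal(got$peak, want$peak)
  expect_equal(got$leading_edge, want$leading_edge)

  withr::with_seed(11, {
    for (i in 1:30) {
      n <- sample(10:50, 1)
      r <- ranked_fixture(n, seed = 1000 + i)
      set <- sample(r$gene, sample(2:min(10, n - 1), 1))
      for (p in c(0, 1)) {
        got <- enrichment_score(r, set, weight_p = p)
        want <- oracle_es(r$gene, r$score, set, weight_p = p)
        expect_equal(got$es, want$es, tolerance = 1e-12)
        expect_equal(got$peak, want$peak)
        expect_equal(got$leading_edge, want$leading_edge)
        expect_lte(abs(got$es), 1)
      }
    }
  })
})

test_that("enrichment scores agree with an independent library implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(20:60, 1)
      r <- ranked_fixture(n, seed = 2000 + i)
      set <- sample(r$gene, sample(3:10, 1))
      got <- enrichment_score(r, set, weight_p = 1)$es
      ref <- fgsea::calcGseaStat(setNames(r$score, r$gene),
                                 selectedStats = which(r$gene %in% set),
                                 gseaParam = 1)
      expect_equal(got, ref, tolerance = 1e-9)
    }
  })
})

test_that("with weight 0 the ES is invariant under monotone score transforms", {
  r <- ranked_fixture(30, seed = 5)
  set <- r$gene[c(3, 7, 8, 20)]
  es0 <- enrichment_score(r, set, weight_p = 0)
  r2 <- r
  r2$score <- exp(r$score) + 5
  es1 <- enrichment_score(r2, set, weight_p = 0)
  expect_equal(es0$es, es1$es, tolerance = 1e-12)
  # with weight 1 the transform changes the score only through weights
  esw <- enrichment_score(r2, set, weight_p = 1)
  expect_true(is.finite(esw$es))
})

test_that("the leading edge of a positive ES never extends past the peak", {
  withr::with_seed(7, {
    for (i in 1:20) {
      r <- ranked_fixture(40, seed = 3000 + i)
      set <- sample(r$gene, 6)
      es <- enrichment_score(r, set)
      if (es$es > 0) {
        expect_true(all(match(es$leading_edge, r$gene) <= es$peak))
      } else {
        expect_true(all(match(es$leading_edge, r$gene) >= es$peak))
      }
    }
  })
})

test_that("gsea_test is deterministic, sign-consistent, and validates n_perm", {
  r <- ranked_fixture(60, seed = 9)
  sets <- list(a = gene_set("a", r$gene[c(1, 3, 5, 8)], "up"),
               b = gene_set("b", r$gene[c(50, 55, 58)], "down"),
               c = gene_set("c", sample(r$gene, 10)))
  g1 <- gsea_test(r, sets, n_perm = 200, seed = 4)
  g2 <- gsea_test(r, sets, n_perm = 200, seed = 4)
  expect_identical(g1, g2)
  expect_true(all(sign(g1$nes) == sign(g1$es)))
  expect_true(all(g1$q >= 0 & g1$q <= 1))
  expect_error(gsea_test(r, sets, n_perm = 50), "n_perm")
})

test_that("planted gene sets reach significance and random sets do not", {
  gen <- generate_study(n_genes = 1000, seed = 23)
  r <- rank_genes(gen$mouse, "m01")
  withr::with_seed(1, {
    rand <- sample(setdiff(r$gene, c(gen$truth$core_up, gen$truth$core_down)),
                   length(gen$truth$core_up))
  })
  res <- gsea_test(r, list(core = gene_set("core", gen$truth$core_up, "up"),
                           rand = gene_set("rand", rand)),
                   n_perm = 1000, seed = 2)
  expect_gt(res$nes[res$set == "core"], 0)
  expect_lte(res$q[res$set == "core"], 0.05)
  expect_gt(res$q[res$set == "rand"], 0.25)
})

test_that("hypergeometric over-representation matches exact values", {
  universe <- sprintf("u%02d", 1:10)
  lst <- universe[1:5]
  res <- ora_test(lst, universe, list(hit = lst, miss = universe[6:10]))
  expect_equal(res$p[res$set == "hit"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "miss"], 1)  # overlap 0 is the entire tail
  # doubling the universe with null genes strengthens a fixed overlap
  bigger <- c(universe, sprintf("x%02d", 1:10))
  res2 <- ora_test(lst, bigger, list(hit = lst))
  expect_lt(res2$p, res$p[res$set == "hit"])
  expect_error(ora_test(lst, character(), list(hit = lst)), "empty universe")
  expect_error(ora_test("zz", universe, list(hit = lst)), "outside")
})

test_that("pairwise matrices have one row per testable pair and are antisymmetric", {
  gen <- generate_study(n_genes = 300, seed = 29,
                        truth_params = list(n_core_up = 20, n_core_down = 15,
                                            n_fingerprint = 6,
                                            n_condition_specific = 2))
  sets <- list(cu = gene_set("cu", gen$truth$core_up, "up"),
               cd = gene_set("cd", gen$truth$core_down, "down"),
               fp = gene_set("fp", gen$truth$subset_fingerprints$pDC))
  st <- gen$mouse
  a1 <- contrast_ids <- c("m01", "m02")
  sub <- expression_study(
    st$exprs[, st$samples$contrast %in% contrast_ids],
    st$samples[st$samples$contrast %in% contrast_ids, ])
  res <- pairwise_matrix(sub, sets, n_perm = 100, seed = 3, min_set_size = 3)
  expect_equal(nrow(res), 2 * 3)

  # explicit pair (A, B) vs (B, A): NES negates exactly
  ids_a <- sub$samples$sample_id[sub$samples$contrast == "m01" &
                                   sub$samples$state == "activated"]
  ids_b <- sub$samples$sample_id[sub$samples$contrast == "m01" &
                                   sub$samples$state == "quiescent"]
  fwd <- pairwise_matrix(sub, sets, n_perm = 100, seed = 3,
                         pairs = list(list(label = "ab", a = ids_a, b = ids_b)))
  rev <- pairwise_matrix(sub, sets, n_perm = 100, seed = 3,
                         pairs = list(list(label = "ba", a = ids_b, b = ids_a)))
  expect_equal(rev$es, -fwd$es, tolerance = 1e-12)
  expect_equal(rev$p, fwd$p, tolerance = 0.03)
  # NES is antisymmetric up to the Monte-Carlo estimate of the null
  # normalisation (exact magnitude ties among null draws are assigned
  # to the positive side in both orientations)
  expect_equal(rev$nes, -fwd$nes, tolerance = 0.03)
})
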