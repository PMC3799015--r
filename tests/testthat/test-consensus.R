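# hand-built leading-edge table: helper for threshold tests
freq_fixture <- function(entries) {
  res <- do.call(rbind, lapply(entries, function(e) {
    data.frame(species = e$species, contrast = e$contrast, set = e$set,
               direction = e$direction, es = if (e$direction == "down") -1 else 1,
               stringsAsFactors = FALSE)
  }))
  res$leading_edge <- lapply(entries, `[[`, "genes")
  res
}

panel_entries <- function(gene, set, direction, mouse_k, human_k,
                          n_mouse = 12, n_human = 6) {
  c(lapply(seq_len(n_mouse), function(i) {
    list(species = "mouse", contrast = sprintf("m%02d", i), set = set,
         direction = direction,
         genes = if (i <= mouse_k) gene else "Filler1")
  }),
  lapply(seq_len(n_human), function(i) {
    list(species = "human", contrast = sprintf("h%02d", i), set = set,
         direction = direction,
         genes = if (i <= human_k) toupper(gene) else "FILLER2")
  }))
}

test_that("ortholog mapping applies table, fallback and drop semantics", {
  expect_equal(map_orthologs("Cd86", NULL, "uppercase"), "CD86",
               ignore_attr = TRUE)
  tab <- c(Ly6a = "LY6S", Il6 = "IL6")
  expect_setequal(map_orthologs(c("Ly6a", "Cd40"), tab, "uppercase"),
                  c("LY6S", "CD40"))
  dropped <- map_orthologs(c("Ly6a", "Cd40"), tab, "drop")
  expect_equal(unclass(dropped)[1], "LY6S", ignore_attr = TRUE)
  expect_equal(attr(dropped, "n_dropped"), 1L)
  expect_error(map_orthologs(c("Ly6a", "Cd40"), tab, "error"), "Cd40")
})

test_that("synthetic mouse symbols survive the ortholog round trip", {
  gen <- generate_study(n_genes = 200, seed = 31,
                        truth_params = list(n_core_up = 10, n_core_down = 10,
                                            n_fingerprint = 5,
                                            n_condition_specific = 2))
  mapped <- map_orthologs(gen$truth$core_up, NULL, "uppercase")
  expect_true(all(mapped %in% rownames(gen$human$exprs)))
})

test_that("leading-edge frequencies count contrasts per species", {
  res <- freq_fixture(panel_entries("Ccl2", "s1", "up", 3, 2,
                                    n_mouse = 3, n_human = 2))
  freq <- leading_edge_frequencies(res)
  expect_equal(freq$n_mouse, 3)
  expect_equal(freq$n_human, 2)
  row <- freq$counts[freq$counts$gene == "CCL2", ]
  expect_equal(row$mouse_k, 3)
  expect_equal(row$human_k, 2)
  # a gene never in any leading edge is absent from the table
  expect_false("ABSENT" %in% freq$counts$gene)

  bad <- res
  bad$species[1] <- "rat"
  expect_error(leading_edge_frequencies(bad), "species")
})

test_that("discordant-direction enrichments are excluded by default", {
  entries <- panel_entries("Ccl2", "s1", "up", 3, 2, n_mouse = 3, n_human = 2)
  res <- freq_fixture(entries)
  res$es[1] <- -2  # m01 run went the wrong way for an up-set
  freq <- leading_edge_frequencies(res)
  expect_equal(freq$counts$mouse_k[freq$counts$gene == "CCL2"], 2)
  freq_all <- leading_edge_frequencies(res, require_direction = FALSE)
  expect_equal(freq_all$counts$mouse_k[freq_all$counts$gene == "CCL2"], 3)
})

test_that("core membership follows the two-species frequency thresholds", {
  res <- freq_fixture(c(
    panel_entries("Ccl2", "s1", "up", 12, 6),     # 12/12, 6/6 -> in
    panel_entries("Cflar", "s1", "up", 10, 5),    # 10/12, 5/6 -> boundary in
    panel_entries("Gbp2", "s1", "up", 9, 6),      # 9/12 -> out
    panel_entries("Ifit2", "s1", "up", 12, 4),    # 4/6 -> out
    panel_entries("Cerk", "s2", "down", 11, 5)))  # down direction
  sig <- core_signature(leading_edge_frequencies(res))
  expect_setequal(sig$up, c("CCL2", "CFLAR"))
  expect_equal(sig$down, "CERK")
  row <- sig$table[sig$table$gene == "CCL2", ]
  expect_equal(row$bin, "6/6 12/12")
  expect_false("GBP2" %in% sig$up)
  expect_false("IFIT2" %in% sig$up)
})

test_that("directional conflicts error unless explicitly dropped", {
  res <- freq_fixture(c(panel_entries("Ccl2", "s1", "up", 12, 6),
                        panel_entries("Ccl2", "s2", "down", 12, 6)))
  freq <- leading_edge_frequencies(res)
  expect_error(core_signature(freq), "both directions")
  sig <- core_signature(freq, resolve = "drop")
  expect_false("CCL2" %in% c(sig$up, sig$down))
  expect_equal(sig$dropped, "CCL2")
})

test_that("raising either threshold never grows the core", {
  gen <- generate_study(n_genes = 400, seed = 37,
                        truth_params = list(n_core_up = 25, n_core_down = 20,
                                            n_fingerprint = 8,
                                            n_condition_specific = 2))
  sets <- list(cu = gene_set("cu", gen$truth$core_up, "up"),
               cd = gene_set("cd", gen$truth$core_down, "down"))
  res <- pairwise_matrix(list(gen$mouse, gen$human), sets, n_perm = 100,
                         seed = 5, min_set_size = 3)
  freq <- leading_edge_frequencies(res)
  grid <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  prev_up <- NULL
  for (f in grid) {
    sig <- core_signature(freq, mouse_min_frac = f, human_min_frac = f,
                          resolve = "drop")
    if (!is.null(prev_up)) {
      expect_true(all(sig$up %in% prev_up))
      expect_true(all(sig$down %in% prev_down))
    }
    prev_up <- sig$up
    prev_down <- sig$down
  }
  # reordering contrasts or sets does not change membership
  perm <- sample(nrow(res))
  sig_a <- core_signature(leading_edge_frequencies(res), resolve = "drop")
  sig_b <- core_signature(leading_edge_frequencies(res[perm, ]),
                          resolve = "drop")
  expect_identical(sig_a$up, sig_b$up)
  expect_identical(sig_a$down, sig_b$down)
})

test_that("a minimal threshold reduces the core to the cross-species union", {
  gen <- generate_study(n_genes = 400, seed = 41,
                        truth_params = list(n_core_up = 25, n_core_down = 20,
                                            n_fingerprint = 8,
                                            n_condition_specific = 2))
  sets <- list(cu = gene_set("cu", gen$truth$core_up, "up"),
               cd = gene_set("cd", gen$truth$core_down, "down"))
  res <- pairwise_matrix(list(gen$mouse, gen$human), sets, n_perm = 100,
                         seed = 7, min_set_size = 3)
  freq <- leading_edge_frequencies(res)
  eps <- 1 / (2 * max(freq$n_mouse, freq$n_human))
  sig <- core_signature(freq, mouse_min_frac = eps, human_min_frac = eps,
                        resolve = "drop")
  ct <- freq$counts
  for (dir in c("up", "down")) {
    want <- sort(unique(ct$gene[ct$direction == dir & ct$mouse_k >= 1 &
                                  ct$human_k >= 1]))
    want <- setdiff(want, sig$dropped)
    expect_setequal(sig[[dir]], want)
  }
})
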