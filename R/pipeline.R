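#' Default pipeline configuration
#'
#' One nested list holds every path and threshold of the synthetic
#' end-to-end run: the generator settings, the printed thresholds of
#' the analysis (expression filter level 5 / fold 2, FDR 0.05, fold
#' change 2, consensus fractions 10/12 and 5/6), and the GSEA and
#' motif-stage parameters. Override any entry by passing a partial
#' list to [run_stage()]; overrides merge recursively.
#'
#' @param out_dir artifact directory.
#' @param seed master seed; stage-specific seeds are derived from it.
#' @return Named configuration list.
#' @export
default_config <- function(out_dir = "pipeline_out", seed = 1) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    synth = list(n_genes = 2000, subsets = c("pDC", "cDC8", "cDC11b"),
                 n_mouse_contrasts = 12, n_human_contrasts = 6,
                 n_replicates = 2, truth = list()),
    thresholds = list(min_log2 = 5, min_fold = 2, fdr_max = 0.05, fc_min = 2,
                      mouse_min_frac = 10 / 12, human_min_frac = 5 / 6),
    gsea = list(n_perm = 200, weight_p = 1, metric = "log2fc",
                min_set_size = 5),
    consensus = list(resolve = "drop", require_direction = TRUE),
    motif = list(lambda = 0.7, r0_slope = 0.584, r0_intercept = -5.66,
                 cutoff_grid = NULL, n_perm = 200, n_promoters = 200,
                 n_motif_bearing = 60, n_planted_sites = 2,
                 background_gc = 0.45, promoter_length = 801)
  )
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (th$min_fold <= 1) stop_("min_fold must be > 1")
  if (th$fdr_max <= 0 || th$fdr_max > 1) stop_("fdr_max must be in (0, 1]")
  if (th$fc_min < 1) stop_("fc_min must be >= 1")
  for (f in c("mouse_min_frac", "human_min_frac")) {
    if (th[[f]] <= 0 || th[[f]] > 1) stop_(f, " must be in (0, 1]")
  }
  if (cfg$gsea$n_perm < 100 || cfg$motif$n_perm < 100) {
    stop_("permutation counts must be >= 100")
  }
  invisible(cfg)
}

pipeline_paths <- function(cfg) {
  d <- cfg$out_dir
  f <- function(x) file.path(d, x)
  list(mouse_matrix = f("mouse_matrix.tsv"), mouse_samples = f("mouse_samples.tsv"),
       human_matrix = f("human_matrix.tsv"), human_samples = f("human_samples.tsv"),
       truth_sets = f("truth_sets.gmt"), truth_yaml = f("truth.yaml"),
       orthologs = f("ortholog_table.tsv"), promoters = f("promoters.fasta"),
       promoter_truth = f("promoter_truth.yaml"), pwms = f("pwms.txt"),
       filtered = f("filtered_matrix.tsv"), newick = f("dendrogram.newick"),
       merges = f("cluster_merges.tsv"), pca_scores = f("pca_scores.tsv"),
       pca_varfrac = f("pca_varfrac.tsv"), error_model = f("error_model.tsv"),
       de_prefix = f("de_"), venn_counts = f("venn_counts.tsv"),
       venn_sets = f("venn_sets.gmt"), gsea_results = f("gsea_results.tsv"),
       core_gmt = f("core_signature.gmt"), core_tsv = f("core_signature.tsv"),
       affinities = f("affinities.tsv"), motif = f("motif_enrichment.tsv"))
}

provenance <- function(cfg) {
  c(paste0("config_hash=", rlang::hash(cfg[setdiff(names(cfg), "out_dir")])),
    paste0("seed=", cfg$seed),
    paste0("version=", as.character(utils::packageVersion("dcmature"))))
}

needs_artifacts <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_("missing artifact '", basename(missing[1]), "'; run stage '",
          stage, "' first")
  }
}

read_pipeline_study <- function(p, species) {
  read_expression_study(p[[paste0(species, "_matrix")]],
                        p[[paste0(species, "_samples")]])
}

discovery_contrasts <- function(study, n = 3) {
  unique(study$samples$contrast)[seq_len(n)]
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic studies, promoters, PWMs, truth),
#' `filter`, `cluster`, `pca`, `de` (error model + differential tests
#' on the discovery contrasts), `venn`, `gsea` (panel-wide GSEA of the
#' Venn gene sets), `consensus` (leading-edge frequencies and core
#' signature), `motif` (TRAP affinities and PASTAA-style enrichment on
#' the core-UP promoters), or `all`. Every artifact is a text file
#' under `config$out_dir` carrying a provenance header (config hash,
#' seed, package version); no stage mutates its inputs, and rerunning
#' with an identical config is byte-identical.
#'
#' @param stage stage name.
#' @param config configuration from [default_config()], or a partial
#'   override list (merged over the defaults).
#' @return Invisibly, the named artifact paths written by the stage.
#' @export
run_stage <- function(stage, config = default_config()) {
  stages <- c("simulate", "filter", "cluster", "pca", "de", "venn",
              "gsea", "consensus", "motif", "all")
  if (!is.character(stage) || length(stage) != 1 || !stage %in% stages) {
    stop_("unknown stage '", paste(stage, collapse = ","),
          "'; expected one of: ", paste(stages, collapse = ", "))
  }
  cfg <- merge_config(default_config(), config)
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_paths(cfg)
  hdr <- provenance(cfg)

  if (stage == "all") {
    for (s in setdiff(stages, "all")) run_stage(s, cfg)
    return(invisible(unlist(p)))
  }

  switch(stage,
    simulate = {
      gen <- do.call(generate_study,
                     c(cfg$synth[setdiff(names(cfg$synth), "truth")],
                       list(truth_params = cfg$synth$truth, seed = cfg$seed)))
      write_expression_study(gen$mouse, p$mouse_matrix, p$mouse_samples, hdr)
      write_expression_study(gen$human, p$human_matrix, p$human_samples, hdr)
      write_study_truth(gen$truth, p$truth_sets, p$truth_yaml)
      write_tsv_artifact(data.frame(mouse = gen$truth$universe,
                                    human = toupper(gen$truth$universe)),
                         p$orthologs, hdr)
      pwms <- demo_pwms(cfg$seed)
      write_pwm_counts(pwms, p$pwms)
      mc <- cfg$motif
      core_up_h <- toupper(gen$truth$core_up)
      others <- setdiff(toupper(gen$truth$universe),
                        toupper(c(gen$truth$core_up, gen$truth$core_down)))
      panel <- c(core_up_h,
                 utils::head(others, max(mc$n_promoters - length(core_up_h), 0)))
      prom <- generate_promoters(
        panel, motif_bearing = utils::head(core_up_h, mc$n_motif_bearing),
        length = mc$promoter_length, pwm = pwms$planted,
        n_planted_sites = mc$n_planted_sites,
        background_gc = mc$background_gc, seed = cfg$seed + 500)
      write_fasta(prom$promoters, p$promoters)
      yaml::write_yaml(list(motif_bearing = prom$truth$motif_bearing,
                            sites_per_promoter = prom$truth$sites_per_promoter,
                            background_gc = prom$truth$background_gc),
                       p$promoter_truth)
      invisible(unlist(p[1:10]))
    },
    filter = {
      needs_artifacts(c(p$mouse_matrix, p$mouse_samples), "simulate")
      study <- read_pipeline_study(p, "mouse")
      filtered <- filter_features(study, cfg$thresholds$min_log2,
                                  cfg$thresholds$min_fold)
      write_expression_study(filtered, p$filtered,
                             file.path(cfg$out_dir, "filtered_samples.tsv"), hdr)
      invisible(p$filtered)
    },
    cluster = {
      needs_artifacts(c(p$filtered, p$mouse_samples), "filter")
      study <- read_expression_study(p$filtered, p$mouse_samples)
      dend <- hierarchical_cluster(study)
      dendrogram_newick(dend, p$newick)
      write_tsv_artifact(data.frame(step = seq_along(dend$height),
                                    left = dend$merge[, 1],
                                    right = dend$merge[, 2],
                                    height = dend$height),
                         p$merges, hdr)
      invisible(c(p$newick, p$merges))
    },
    pca = {
      needs_artifacts(c(p$mouse_matrix, p$mouse_samples), "simulate")
      study <- read_pipeline_study(p, "mouse")
      fit <- pca_study(study)
      write_tsv_artifact(data.frame(sample_id = rownames(fit$scores),
                                    round(fit$scores[, seq_len(min(5, ncol(fit$scores)))], 6)),
                         p$pca_scores, hdr)
      write_tsv_artifact(data.frame(component = seq_along(fit$var_frac),
                                    var_frac = fit$var_frac),
                         p$pca_varfrac, hdr)
      invisible(c(p$pca_scores, p$pca_varfrac))
    },
    de = {
      needs_artifacts(c(p$mouse_matrix, p$mouse_samples), "simulate")
      study <- read_pipeline_study(p, "mouse")
      model <- fit_error_model(study)
      write_tsv_artifact(data.frame(sigma_add = model$sigma_add,
                                    sigma_prop = model$sigma_prop,
                                    n_genes = model$n_genes,
                                    n_groups = model$n_groups,
                                    loss = model$loss),
                         p$error_model, hdr)
      for (cid in discovery_contrasts(study)) {
        de <- differential_test(study, cid, model,
                                fdr_max = cfg$thresholds$fdr_max,
                                fc_min = cfg$thresholds$fc_min)
        write_tsv_artifact(de, paste0(p$de_prefix, cid, ".tsv"), hdr)
      }
      invisible(p$error_model)
    },
    venn = {
      needs_artifacts(c(p$mouse_samples, p$error_model), "de")
      study_samples <- read_tsv_artifact(p$mouse_samples)
      cids <- unique(study_samples$contrast)[1:3]
      de_paths <- paste0(p$de_prefix, cids, ".tsv")
      needs_artifacts(de_paths, "de")
      up <- list()
      down <- list()
      for (i in seq_along(cids)) {
        de <- read_tsv_artifact(de_paths[i])
        lab <- study_samples$subset[study_samples$contrast == cids[i]][1]
        up[[lab]] <- de$gene[de$call == "up"]
        down[[lab]] <- de$gene[de$call == "down"]
      }
      vp <- venn_partition(up, down)
      write_tsv_artifact(vp$counts, p$venn_counts, hdr)
      write_gmt(venn_gene_sets(vp), p$venn_sets)
      invisible(c(p$venn_counts, p$venn_sets))
    },
    gsea = {
      needs_artifacts(c(p$venn_sets), "venn")
      needs_artifacts(c(p$human_matrix, p$human_samples, p$orthologs),
                      "simulate")
      mouse <- read_pipeline_study(p, "mouse")
      human <- read_pipeline_study(p, "human")
      sets <- read_gmt(p$venn_sets)
      orth <- read_ortholog_table(p$orthologs)
      res <- pairwise_matrix(list(mouse, human), sets,
                             n_perm = cfg$gsea$n_perm,
                             seed = cfg$seed + 1000,
                             weight_p = cfg$gsea$weight_p,
                             metric = cfg$gsea$metric,
                             ortholog_table = orth,
                             min_set_size = cfg$gsea$min_set_size)
      flat <- res
      flat$leading_edge <- vapply(res$leading_edge, paste, character(1),
                                  collapse = ",")
      write_tsv_artifact(flat, p$gsea_results, hdr)
      invisible(p$gsea_results)
    },
    consensus = {
      needs_artifacts(p$gsea_results, "gsea")
      needs_artifacts(p$orthologs, "simulate")
      res <- read_tsv_artifact(p$gsea_results)
      res$leading_edge <- strsplit(res$leading_edge, ",", fixed = TRUE)
      orth <- read_ortholog_table(p$orthologs)
      freq <- leading_edge_frequencies(
        res, orth, require_direction = cfg$consensus$require_direction)
      sig <- core_signature(freq,
                            mouse_min_frac = cfg$thresholds$mouse_min_frac,
                            human_min_frac = cfg$thresholds$human_min_frac,
                            resolve = cfg$consensus$resolve)
      write_core_signature(sig, p$core_gmt, p$core_tsv, hdr)
      invisible(c(p$core_gmt, p$core_tsv))
    },
    motif = {
      needs_artifacts(p$core_gmt, "consensus")
      needs_artifacts(c(p$promoters, p$pwms), "simulate")
      core <- read_gmt(p$core_gmt)
      prom <- read_fasta(p$promoters)
      pwms <- read_pwm_counts(p$pwms, pseudocount = 1)
      mc <- cfg$motif
      aff <- trap_affinity_table(prom, pwms, lambda = mc$lambda,
                                 r0_slope = mc$r0_slope,
                                 r0_intercept = mc$r0_intercept)
      write_tsv_artifact(data.frame(gene = rownames(aff), aff,
                                    check.names = FALSE),
                         p$affinities, hdr)
      test_set <- intersect(core$core_up$genes, rownames(aff))
      enr <- pastaa_enrichment(aff, test_set,
                               cutoff_grid = mc$cutoff_grid,
                               n_perm = mc$n_perm, seed = cfg$seed + 2000)
      write_tsv_artifact(enr, p$motif, hdr)
      invisible(c(p$affinities, p$motif))
    })
}
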