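#' Default parameters of the planted-truth generator
#'
#' The defaults emulate the structure of the cross-condition DC
#' maturation panel the pipeline targets: 12 mouse and 6 human
#' quiescent-vs-activated contrasts profiled in duplicate, a shared
#' activation signature of 72 induced and 58 repressed genes, per-subset
#' identity fingerprints that are attenuated upon activation, and
#' per-contrast private response modules. Core genes are planted in only
#' a fraction of contrasts (11/12 mouse, 5/6 human) so the >80%
#' consensus rule is exercised non-trivially; they are always active in
#' the discovery contrasts from which the differential gene sets are
#' derived.
#'
#' @return Named list of generator parameters (see source for fields).
#' @export
default_truth_params <- function() {
  list(
    n_core_up = 72L,
    n_core_down = 58L,
    n_fingerprint = 40L,          # per subset
    n_condition_specific = 10L,   # per contrast
    effect_size_log2 = 2.0,
    fingerprint_effect = 2.0,
    fingerprint_attenuation = 0.5,
    baseline_mean = 7.0,
    baseline_sd = 1.5,
    sigma_add = 0.3,
    sigma_prop = 0.02,
    mouse_active_frac = 11 / 12,
    human_active_frac = 5 / 6,
    n_discovery = 3L              # mouse contrasts where core genes are always active
  )
}

#' Generate a synthetic two-species expression study panel
#'
#' Produces a mouse and a human `ExpressionStudy` with a shared planted
#' truth: baseline log2 expression drawn per gene, a +/- effect on the
#' planted core UP/DOWN genes in activated samples of their active
#' contrasts, subset fingerprints elevated in their own subset in both
#' states but attenuated upon activation, condition-specific genes
#' private to one contrast, and additive-plus-proportional Gaussian
#' noise (sd = sqrt(sigma_add^2 + sigma_prop^2 * true^2)). Human
#' features use the upper-case ortholog symbols of the mouse universe.
#'
#' @param n_genes size of the gene universe.
#' @param subsets mouse cell-subset labels (one contrast per subset in
#'   the discovery block).
#' @param n_mouse_contrasts,n_human_contrasts panel sizes.
#' @param n_replicates replicates per (contrast, state); must be >= 2.
#' @param truth_params named list overriding [default_truth_params()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with elements `mouse`, `human` (ExpressionStudy) and
#'   `truth` (class `StudyTruth`).
#' @export
generate_study <- function(n_genes = 2000,
                           subsets = c("pDC", "cDC8", "cDC11b"),
                           n_mouse_contrasts = 12,
                           n_human_contrasts = 6,
                           n_replicates = 2,
                           truth_params = list(),
                           seed = 1) {
  p <- merge_config(default_truth_params(), truth_params)
  if (n_replicates < 2) stop_("n_replicates must be >= 2 (duplicate design)")
  for (f in c("mouse_active_frac", "human_active_frac")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop_(f, " must be in [0, 1]")
  }
  if (p$fingerprint_attenuation < 0 || p$fingerprint_attenuation > 1) {
    stop_("fingerprint_attenuation must be in [0, 1]")
  }
  if (p$n_discovery > n_mouse_contrasts) stop_("n_discovery exceeds mouse panel")

  n_planted <- p$n_core_up + p$n_core_down +
    length(subsets) * p$n_fingerprint +
    (n_mouse_contrasts + n_human_contrasts) * p$n_condition_specific
  if (n_planted >= n_genes) {
    stop_("planted gene groups (", n_planted, ") must sum to < n_genes (",
          n_genes, ")")
  }

  genes <- sprintf("Gene%05d", seq_len(n_genes))  # mouse (title-case) symbols
  idx <- 0L
  take <- function(n) {
    out <- idx + seq_len(n)
    idx <<- idx + n
    out
  }
  core_up <- take(p$n_core_up)
  core_down <- take(p$n_core_down)
  fingerprints <- stats::setNames(
    lapply(subsets, function(s) take(p$n_fingerprint)), subsets)

  mouse_contrasts <- sprintf("m%02d", seq_len(n_mouse_contrasts))
  human_contrasts <- sprintf("h%02d", seq_len(n_human_contrasts))
  mouse_subset <- rep_len(subsets, n_mouse_contrasts)
  human_subset <- rep_len(c("pDC", "MoDC"), n_human_contrasts)
  stimuli <- rep_len(c("MCMV", "polyIC", "CpG", "LPS", "R848", "HCMV"),
                     n_mouse_contrasts + n_human_contrasts)

  cs_idx <- stats::setNames(
    lapply(seq_len(n_mouse_contrasts + n_human_contrasts),
           function(i) take(p$n_condition_specific)),
    c(mouse_contrasts, human_contrasts))

  withr::with_seed(seed, {
    baseline <- stats::rnorm(n_genes, p$baseline_mean, p$baseline_sd)

    # per-core-gene active contrasts; skips drawn outside the discovery block
    pick_active <- function(contrasts, frac, protected) {
      k <- round(frac * length(contrasts))
      k <- max(k, length(protected))
      free <- setdiff(contrasts, protected)
      lapply(seq_len(p$n_core_up + p$n_core_down), function(g) {
        extra <- if (k - length(protected) > 0) {
          sample(free, k - length(protected))
        } else character()
        sort(c(protected, extra))
      })
    }
    discovery <- mouse_contrasts[seq_len(p$n_discovery)]
    core_idx <- c(core_up, core_down)
    mouse_active <- pick_active(mouse_contrasts, p$mouse_active_frac, discovery)
    human_active <- pick_active(human_contrasts, p$human_active_frac, character())
    names(mouse_active) <- names(human_active) <- genes[core_idx]

    build_study <- function(species, contrasts, contrast_subset, stim,
                            active, symbols) {
      n_samp <- length(contrasts) * 2L * n_replicates
      samples <- data.frame(
        sample_id = character(n_samp), subset = character(n_samp),
        state = character(n_samp), species = species,
        contrast = character(n_samp), replicate = integer(n_samp),
        stimulus = character(n_samp), stringsAsFactors = FALSE)
      tru <- matrix(baseline, n_genes, n_samp)
      j <- 0L
      for (ci in seq_along(contrasts)) {
        cid <- contrasts[ci]
        # indices of core genes active in this contrast
        act <- vapply(active, function(a) cid %in% a, logical(1))
        act_up <- core_idx[act][core_idx[act] %in% core_up]
        act_down <- core_idx[act][core_idx[act] %in% core_down]
        fp <- fingerprints[[contrast_subset[ci]]]
        for (state in c("quiescent", "activated")) {
          for (r in seq_len(n_replicates)) {
            j <- j + 1L
            samples$sample_id[j] <- sprintf("%s_%s_%d", cid,
                                            substr(state, 1, 1), r)
            samples$subset[j] <- contrast_subset[ci]
            samples$state[j] <- state
            samples$contrast[j] <- cid
            samples$replicate[j] <- r
            samples$stimulus[j] <- stim[ci]
            if (!is.null(fp)) {
              fac <- if (state == "activated") p$fingerprint_attenuation else 1
              tru[fp, j] <- tru[fp, j] + p$fingerprint_effect * fac
            }
            if (state == "activated") {
              tru[act_up, j] <- tru[act_up, j] + p$effect_size_log2
              tru[act_down, j] <- tru[act_down, j] - p$effect_size_log2
              tru[cs_idx[[cid]], j] <- tru[cs_idx[[cid]], j] + p$effect_size_log2
            }
          }
        }
      }
      noise_sd <- sqrt(p$sigma_add^2 + p$sigma_prop^2 * tru^2)
      obs <- tru + stats::rnorm(length(tru)) * noise_sd
      dimnames(obs) <- list(symbols, samples$sample_id)
      expression_study(obs, samples)
    }

    mouse <- build_study("mouse", mouse_contrasts, mouse_subset,
                         stimuli[seq_len(n_mouse_contrasts)],
                         mouse_active, genes)
    human <- build_study("human", human_contrasts, human_subset,
                         stimuli[n_mouse_contrasts + seq_len(n_human_contrasts)],
                         human_active, toupper(genes))
  })

  truth <- structure(list(
    universe = genes,
    core_up = genes[core_up],
    core_down = genes[core_down],
    subset_fingerprints = lapply(fingerprints, function(i) genes[i]),
    condition_specific = lapply(cs_idx, function(i) genes[i]),
    effect_size_log2 = p$effect_size_log2,
    noise = c(sigma_add = p$sigma_add, sigma_prop = p$sigma_prop),
    mouse_active = mouse_active,
    human_active = human_active,
    discovery_contrasts = mouse_contrasts[seq_len(p$n_discovery)],
    params = p,
    seed = seed), class = "StudyTruth")

  list(mouse = mouse, human = human, truth = truth)
}

#' @export
print.StudyTruth <- function(x, ...) {
  cat("StudyTruth:", length(x$core_up), "core UP,", length(x$core_down),
      "core DOWN genes; effect", x$effect_size_log2, "log2; noise sd_add",
      x$noise[["sigma_add"]], "sd_prop", x$noise[["sigma_prop"]], "\n")
  invisible(x)
}

#' Generate synthetic promoter sequences with planted binding sites
#'
#' Backgrounds are i.i.d. nucleotides at the requested GC content;
#' motif-bearing promoters additionally receive `n_planted_sites`
#' draws from the PWM placed at uniform-random non-overlapping
#' positions on a uniform-random strand.
#'
#' @param genes promoter names.
#' @param motif_bearing subset of `genes` receiving planted sites.
#' @param length promoter length in nt (default 801, a -400..+400
#'   window around the TSS).
#' @param pwm `PWM` whose columns the planted sites are drawn from
#'   (required when `n_planted_sites > 0` and `motif_bearing` is
#'   non-empty).
#' @param n_planted_sites sites per motif-bearing promoter.
#' @param background_gc background GC fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `promoters` (a `PromoterSet`) and `truth` (class
#'   `PromoterTruth`: `motif_bearing`, `sites_per_promoter`,
#'   `background_gc`, and the planted `positions`/`strands`).
#' @export
generate_promoters <- function(genes, motif_bearing = character(),
                               length = 801, pwm = NULL,
                               n_planted_sites = 2, background_gc = 0.5,
                               seed = 1) {
  if (background_gc <= 0 || background_gc >= 1) {
    stop_("background_gc must be in (0, 1)")
  }
  if (!all(motif_bearing %in% genes)) {
    stop_("motif_bearing must be a subset of genes")
  }
  plant <- length(motif_bearing) > 0 && n_planted_sites > 0
  if (plant) {
    if (is.null(pwm)) stop_("a PWM is required to plant sites")
    L <- ncol(pwm$mat)
    if (length < L) stop_("promoter length shorter than the PWM")
    if (n_planted_sites * L > length) {
      stop_("cannot place ", n_planted_sites, " non-overlapping sites of ",
            L, " nt in ", length, " nt")
    }
  }
  probs <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
             G = background_gc / 2, T = (1 - background_gc) / 2)
  positions <- list()
  strands <- list()
  withr::with_seed(seed, {
    seqs <- vapply(genes, function(g) {
      paste(sample(names(probs), length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    if (plant) {
      for (g in motif_bearing) {
        chars <- strsplit(seqs[[g]], "")[[1]]
        starts <- NULL
        for (attempt in seq_len(200)) {
          cand <- sort(sample.int(length - L + 1L, n_planted_sites))
          if (n_planted_sites == 1L || all(diff(cand) >= L)) {
            starts <- cand
            break
          }
        }
        if (is.null(starts)) {
          stop_("could not place non-overlapping sites in promoter '", g, "'")
        }
        strand <- sample(c("+", "-"), n_planted_sites, replace = TRUE)
        for (k in seq_len(n_planted_sites)) {
          site <- vapply(seq_len(L), function(j) {
            sample(rownames(pwm$mat), 1, prob = pwm$mat[, j])
          }, character(1))
          if (strand[k] == "-") {
            site <- rev(c(A = "T", C = "G", G = "C", T = "A")[site])
          }
          chars[starts[k]:(starts[k] + L - 1L)] <- site
        }
        seqs[[g]] <- paste(chars, collapse = "")
        positions[[g]] <- starts
        strands[[g]] <- strand
      }
    }
  })
  truth <- structure(list(motif_bearing = motif_bearing,
                          sites_per_promoter = if (plant) n_planted_sites else 0L,
                          background_gc = background_gc,
                          positions = positions, strands = strands,
                          seed = seed), class = "PromoterTruth")
  list(promoters = promoter_set(seqs, upstream = (length - 1) %/% 2,
                                downstream = length %/% 2),
       truth = truth)
}

#' Built-in demonstration PWMs for the synthetic pipeline
#'
#' Returns a sharply informative NF-kB-like matrix (consensus
#' GGGACTTTCC, 85% weight on the consensus base) used to plant sites,
#' and a column-permuted decoy of identical composition used as a
#' negative control in the motif-enrichment stage.
#' @param seed seed for the decoy column permutation.
#' @return named list of two `PWM` objects (`planted`, `decoy`).
#' @export
demo_pwms <- function(seed = 1) {
  consensus <- strsplit("GGGACTTTCC", "")[[1]]
  L <- length(consensus)
  counts <- matrix(5, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) counts[consensus[j], j] <- 85
  planted <- pwm_from_counts("NFKB_SYN", counts, pseudocount = 0)
  perm <- withr::with_seed(seed, sample.int(L))
  decoy <- pwm_from_counts("DECOY_SYN", counts[, perm], pseudocount = 0)
  list(planted = planted, decoy = decoy)
}

#' Write the planted truth of a synthetic study to GMT + YAML
#'
#' @param truth a `StudyTruth`.
#' @param gmt_path GMT receiving the planted gene groups.
#' @param yaml_path YAML receiving scalar parameters and active-contrast
#'   maps.
#' @export
write_study_truth <- function(truth, gmt_path, yaml_path) {
  sets <- c(list(core_up = gene_set("core_up", truth$core_up, "up"),
                 core_down = gene_set("core_down", truth$core_down, "down")),
            stats::setNames(
              lapply(names(truth$subset_fingerprints), function(s) {
                gene_set(paste0("fingerprint_", s),
                         truth$subset_fingerprints[[s]])
              }),
              paste0("fingerprint_", names(truth$subset_fingerprints))))
  write_gmt(sets, gmt_path)
  yaml::write_yaml(list(
    effect_size_log2 = truth$effect_size_log2,
    sigma_add = unname(truth$noise[["sigma_add"]]),
    sigma_prop = unname(truth$noise[["sigma_prop"]]),
    seed = truth$seed,
    discovery_contrasts = truth$discovery_contrasts,
    mouse_active = truth$mouse_active,
    human_active = truth$human_active), yaml_path)
  invisible(c(gmt_path, yaml_path))
}
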