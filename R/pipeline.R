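#' Build and validate a pipeline configuration
#'
#' Every numeric threshold used anywhere in the pipeline lives here; stages
#' read them from the config rather than from hidden constants. The config
#' round-trips through YAML/JSON unchanged.
#'
#' @param seed Global seed; per-stage streams are derived from it.
#' @param outdir Output directory (NULL for no file output).
#' @param rg_group Genetic-correlation grouping threshold.
#' @param p_seed,p_sig,gap_kb Region-definition thresholds.
#' @param p_stop Conditional-selection stopping threshold.
#' @param p_cond,p_orig Signal-validity thresholds.
#' @param pp4_min Colocalization grouping/reporting threshold.
#' @param cfi_min,srmr_max Factor-model fit thresholds.
#' @param mr_alpha MR reporting threshold.
#' @param maf_min Munging minor-allele-frequency floor.
#' @param window_kb LD-score window half-width.
#' @param n_jackknife_blocks LD-score regression jackknife blocks.
#' @param coloc_p1,coloc_p2,coloc_p12 Colocalization priors.
#' @param prior_sd_cc,prior_sd_quant Effect-size priors for case/control and
#'   quantitative datasets.
#' @param r2_cap Conditional-analysis collinearity cap.
#' @param pad_bp Region padding for conditional analysis (bp).
#' @param freq_diff_max Summary-vs-reference frequency mismatch cap.
#' @param min_overlap Minimum shared variants for colocalization.
#' @param sim Named list of overrides passed to [simulate_study()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL,
                            rg_group = 0.4,
                            p_seed = 1e-6, p_sig = 5e-8, gap_kb = 250,
                            p_stop = 1e-4, p_cond = 1e-6, p_orig = 5e-8,
                            pp4_min = 0.9, cfi_min = 0.95, srmr_max = 0.10,
                            mr_alpha = 0.05, maf_min = 0.01,
                            window_kb = 100, n_jackknife_blocks = 200,
                            coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
                            prior_sd_cc = 0.2, prior_sd_quant = 0.15,
                            r2_cap = 0.9, pad_bp = 1e5, freq_diff_max = 0.2,
                            min_overlap = 25, sim = list()) {
  cfg <- list(
    seed = seed, outdir = outdir, rg_group = rg_group,
    p_seed = p_seed, p_sig = p_sig, gap_kb = gap_kb,
    p_stop = p_stop, p_cond = p_cond, p_orig = p_orig,
    pp4_min = pp4_min, cfi_min = cfi_min, srmr_max = srmr_max,
    mr_alpha = mr_alpha, maf_min = maf_min,
    window_kb = window_kb, n_jackknife_blocks = n_jackknife_blocks,
    coloc_p1 = coloc_p1, coloc_p2 = coloc_p2, coloc_p12 = coloc_p12,
    prior_sd_cc = prior_sd_cc, prior_sd_quant = prior_sd_quant,
    r2_cap = r2_cap, pad_bp = pad_bp, freq_diff_max = freq_diff_max,
    min_overlap = min_overlap, sim = sim
  )
  probs <- c("p_seed", "p_sig", "p_stop", "p_cond", "p_orig", "pp4_min",
             "mr_alpha", "maf_min", "coloc_p1", "coloc_p2", "coloc_p12",
             "rg_group", "srmr_max", "cfi_min", "r2_cap")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("config field `%s` must be a probability/fraction in [0, 1]", nm),
           call. = FALSE)
    }
  }
  for (nm in c("gap_kb", "window_kb", "pad_bp", "n_jackknife_blocks",
               "min_overlap")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop(sprintf("config field `%s` must be positive", nm), call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-study pipeline
#'
#' Simulate, munge, LD-score regression, factor-model fitting and selection,
#' factor GWAS with Q_SNP, region definition and merging, conditional signal
#' decomposition, cross-factor colocalization and grouping, QTL
#' colocalization, and Wald-ratio MR. Each stage's wall time is recorded in
#' the manifest; with an `outdir` the stage outputs are written as
#' tab-separated/JSON files. Rerunning with an identical config reproduces
#' identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return A list of class `pipeline_run`: study, munged, scores, est,
#'   groups, fits, selection, fit (chosen model), fgwas, regions_by_factor,
#'   regions (merged, HLA-excluded), signal_sets, coloc (pairwise results),
#'   locus_groups, qtl_results, mr_results, manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, prev) {
    now <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(now - prev, 2)
    now
  }

  tp <- t0
  study <- do.call(simulate_study, c(list(seed = config$seed), config$sim))
  tp <- tick("simulate", tp)

  munged <- purrr::map(study$sumstats, munge, reference = study$reference,
                       maf_min = config$maf_min)
  tp <- tick("munge", tp)

  scores <- compute_ld_scores(study$panel, window_kb = config$window_kb)
  est <- multivariable_ldsc(munged, scores,
                            n_blocks = config$n_jackknife_blocks)
  tp <- tick("ldsc", tp)

  groups <- propose_groups(rg_matrix(est), threshold = config$rg_group)
  specs <- purrr::imap(study$loading_patterns,
                       function(lp, nm) model_spec(lp, name = nm))
  fits <- purrr::map(specs, fit_wls, est = est)
  selection <- select_model(fits, cfi_min = config$cfi_min,
                            srmr_max = config$srmr_max)
  fit <- selection$chosen
  if (is.null(fit)) {
    stop("pipeline: no adequate factor model among the candidates",
         call. = FALSE)
  }
  tp <- tick("factor_model", tp)

  fgwas <- factor_gwas(munged, est, fit)
  tp <- tick("factor_gwas", tp)

  regions_by_factor <- purrr::imap(fgwas, function(tab, f) {
    define_regions(tab, p_seed = config$p_seed, gap_kb = config$gap_kb,
                   p_sig = config$p_sig, trait = f)
  })
  sig_regions <- purrr::map(regions_by_factor, dplyr::filter, .data$significant)
  regions <- exclude_hla(merge_regions(sig_regions))
  tp <- tick("regions", tp)

  # conditional decomposition: per merged region, per contributing factor
  signal_sets <- list()
  for (ri in seq_len(nrow(regions))) {
    region <- regions[ri, ]
    rfactors <- strsplit(region$traits, ",")[[1]]
    vs <- dplyr::filter(study$panel$variants,
                        .data$chr == region$chr,
                        .data$pos >= region$start - config$pad_bp,
                        .data$pos <= region$end + config$pad_bp)
    ld <- panel_ld_matrix(study$panel, vs$rsid)
    for (f in rfactors) {
      ss <- decompose_region(fgwas[[f]], region, ld,
                             pad_bp = config$pad_bp, p_stop = config$p_stop,
                             p_cond = config$p_cond, p_orig = config$p_orig,
                             type = "cc")
      if (length(ss$datasets) > 0) {
        signal_sets[[sprintf("region%02d_%s", ri, f)]] <-
          c(ss, list(region_id = ri, factor = f))
      }
    }
  }
  tp <- tick("conditional", tp)

  # cross-factor colocalization within each merged region
  coloc_rows <- list()
  all_nodes <- list()
  flat <- list()
  for (nm in names(signal_sets)) {
    ss <- signal_sets[[nm]]
    for (tg in names(ss$datasets)) {
      id <- sprintf("%s::%s", nm, tg)
      flat[[id]] <- ss$datasets[[tg]]
      all_nodes[[id]] <- tibble::tibble(trait = ss$factor, signal = id,
                                        region_id = ss$region_id)
    }
  }
  nodes <- dplyr::bind_rows(all_nodes)
  if (nrow(nodes) > 0) {
    for (ri in unique(nodes$region_id)) {
      rn <- nodes[nodes$region_id == ri, ]
      if (nrow(rn) < 2) next
      for (i in seq_len(nrow(rn) - 1)) {
        for (j in (i + 1):nrow(rn)) {
          if (rn$trait[i] == rn$trait[j]) next
          cc <- coloc_pair(flat[[rn$signal[i]]], flat[[rn$signal[j]]],
                           p1 = config$coloc_p1, p2 = config$coloc_p2,
                           p12 = config$coloc_p12,
                           min_overlap = config$min_overlap,
                           prior_sd_a = config$prior_sd_cc,
                           prior_sd_b = config$prior_sd_cc)
          coloc_rows[[length(coloc_rows) + 1L]] <- tibble::tibble(
            trait_a = rn$trait[i], signal_a = rn$signal[i],
            trait_b = rn$trait[j], signal_b = rn$signal[j],
            nsnps = cc$nsnps, pp3 = cc$pp3, pp4 = cc$pp4,
            testable = cc$testable
          )
        }
      }
    }
  }
  coloc_results <- dplyr::bind_rows(coloc_rows)
  locus_groups <- group_signals(
    if (nrow(coloc_results) > 0) coloc_results else
      tibble::tibble(trait_a = character(), signal_a = character(),
                     trait_b = character(), signal_b = character(),
                     pp4 = numeric()),
    pp4_min = config$pp4_min,
    nodes = if (nrow(nodes) > 0) nodes[, c("trait", "signal")] else NULL
  )
  tp <- tick("coloc", tp)

  # QTL colocalization + MR
  qtl_results <- list()
  mr_results <- list()
  for (qi in seq_len(nrow(study$qtl_meta))) {
    meta <- study$qtl_meta[qi, ]
    qtl <- study$qtls[[meta$qtl]]
    # regions of the QTL's target factor that overlap the QTL's strongest signal
    cand <- names(signal_sets)[vapply(signal_sets, function(s)
      s$factor == meta$target_factor, logical(1))]
    lead_bp <- qtl$BP[which.min(qtl$P)]
    lead_chr <- qtl$CHR[which.min(qtl$P)]
    for (nm in cand) {
      ss <- signal_sets[[nm]]
      if (ss$region$chr != lead_chr ||
          lead_bp < ss$region$start - config$pad_bp ||
          lead_bp > ss$region$end + config$pad_bp) next
      vs <- dplyr::filter(study$panel$variants,
                          .data$chr == ss$region$chr,
                          .data$pos >= ss$region$start - config$pad_bp,
                          .data$pos <= ss$region$end + config$pad_bp)
      ld <- panel_ld_matrix(study$panel, vs$rsid)
      qc <- qtl_coloc(ss, qtl, mode = meta$mode, ld = ld,
                      pp4_min = config$pp4_min,
                      p1 = config$coloc_p1, p2 = config$coloc_p2,
                      p12 = config$coloc_p12,
                      min_overlap = config$min_overlap)
      if (nrow(qc) == 0) next
      qc$qtl <- meta$qtl
      qc$gene <- meta$gene
      qc$cell_type <- meta$cell_type
      qc$factor <- ss$factor
      qc$signal_set <- nm
      qtl_results[[length(qtl_results) + 1L]] <- qc

      hits <- dplyr::filter(qc, .data$colocalized)
      if (nrow(hits) > 0) {
        qtl_slice <- dplyr::filter(
          qtl, .data$CHR == ss$region$chr,
          .data$BP >= ss$region$start - config$pad_bp,
          .data$BP <= ss$region$end + config$pad_bp,
          .data$SNP %in% rownames(ld)
        )
        qds_all <- if (meta$mode == "decomposed") {
          sel <- stepwise_select(qtl_slice, ld, p_stop = config$p_stop,
                                 r2_cap = config$r2_cap)
          if (length(sel) > 0) all_but_one(qtl_slice, ld, sel, type = "quant")
          else list()
        } else {
          ds <- qtl_slice; attr(ds, "type") <- "quant"
          list(main_effect = ds)
        }
        mr <- mr_colocalized(hits, qds_all, ss$datasets,
                             exposure_id = meta$gene,
                             outcome_id = ss$factor,
                             alpha = config$mr_alpha)
        if (nrow(mr) > 0) {
          mr$qtl <- meta$qtl
          mr$cell_type <- meta$cell_type
          mr_results[[length(mr_results) + 1L]] <- mr
        }
      }
    }
  }
  qtl_results <- dplyr::bind_rows(qtl_results)
  mr_results <- dplyr::bind_rows(mr_results)
  tp <- tick("qtl_mr", tp)

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    stage_seconds = timings,
    selected_model = fit$spec$name,
    n_regions = nrow(regions),
    n_signals = nrow(nodes),
    n_coloc_pairs = nrow(coloc_results),
    n_mr = nrow(mr_results)
  )

  run <- structure(
    list(study = study, munged = munged, scores = scores, est = est,
         groups = groups, fits = fits, selection = selection, fit = fit,
         fgwas = fgwas, regions_by_factor = regions_by_factor,
         regions = regions, signal_sets = signal_sets, nodes = nodes,
         coloc = coloc_results, locus_groups = locus_groups,
         qtl_results = qtl_results, mr_results = mr_results,
         manifest = manifest, config = config),
    class = "pipeline_run"
  )
  if (!is.null(config$outdir)) write_pipeline_outputs(run, config$outdir)
  run
}

write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genetic_covariance(run$est, file.path(outdir, "ldsc"))
  write_factor_fit(run$fit, file.path(outdir, "factor_model.json"))
  for (f in names(run$fgwas)) {
    readr::write_tsv(run$fgwas[[f]], file.path(outdir, sprintf("gwas_%s.tsv", f)))
  }
  write_regions(run$regions, file.path(outdir, "regions.tsv"))
  if (nrow(run$coloc) > 0) {
    readr::write_tsv(run$coloc, file.path(outdir, "coloc_pairs.tsv"))
  }
  readr::write_tsv(run$locus_groups, file.path(outdir, "locus_groups.tsv"))
  if (nrow(run$qtl_results) > 0) {
    readr::write_tsv(run$qtl_results, file.path(outdir, "qtl_coloc.tsv"))
  }
  if (nrow(run$mr_results) > 0) {
    readr::write_tsv(run$mr_results, file.path(outdir, "mr.tsv"))
  }
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  digests <- vapply(files, function(f) {
    as.character(sum(as.integer(charToRaw(paste(readLines(f, warn = FALSE),
                                                collapse = "\n")))))
  }, character(1))
  manifest <- run$manifest
  manifest$file_digests <- as.list(digests)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline_run> model %s | %d merged regions | %d signals | %d coloc pairs | %d MR results\n",
    x$manifest$selected_model, x$manifest$n_regions, x$manifest$n_signals,
    x$manifest$n_coloc_pairs, x$manifest$n_mr))
  invisible(x)
}

#' Score a pipeline run against the study's planted truth
#'
#' Checks, for every planted locus, whether the pipeline recovered it and
#' classified it correctly: factor loci must yield a significant region for
#' their factor and end up in a factor-specific locus group; cross-factor
#' loci must end in a shared locus group; trait-specific loci must be
#' Q_SNP-significant at `qsnp_p_max`; QTL partners must colocalize (or not)
#' as planted, and colocalizing MR results must have the planted direction.
#'
#' @param run A `pipeline_run`.
#' @param qsnp_p_max Q_SNP detection threshold (default 5e-8).
#' @return List with `checks` (tibble: check, expected, observed, correct)
#'   and `accuracy` (fraction correct).
#' @export
evaluate_pipeline <- function(run, qsnp_p_max = 5e-8) {
  study <- run$study
  checks <- list()
  add <- function(check, expected, observed) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, expected = as.character(expected),
      observed = as.character(observed),
      correct = identical(as.character(expected), as.character(observed))
    )
  }

  region_of <- function(rsid) {
    pos <- study$panel$variants$pos[match(rsid, study$panel$variants$rsid)]
    chr <- study$panel$variants$chr[match(rsid, study$panel$variants$rsid)]
    hit <- which(run$regions$chr == chr & run$regions$start - 1e5 <= pos &
                   run$regions$end + 1e5 >= pos)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  group_label_of_region <- function(ri, factor) {
    sigs <- run$nodes$signal[run$nodes$region_id == ri &
                               run$nodes$trait %in% factor]
    if (length(sigs) == 0) return(NA_character_)
    labs <- run$locus_groups$label[run$locus_groups$signal %in% sigs]
    if (any(labs == "shared")) "shared" else "specific"
  }

  pl <- study$planted
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    if (p$type == "factor") {
      ri <- region_of(p$rsid)
      detected <- !is.na(ri) && grepl(p$factor, run$regions$traits[ri])
      add(sprintf("factor locus %s detected in %s", p$rsid, p$factor),
          TRUE, detected)
      if (detected) {
        add(sprintf("factor locus %s classified", p$rsid), "specific",
            group_label_of_region(ri, p$factor))
      }
    } else if (p$type == "cross-factor") {
      ri <- region_of(p$rsid)
      detected <- !is.na(ri)
      add(sprintf("cross-factor locus %s detected", p$rsid), TRUE, detected)
      if (detected) {
        add(sprintf("cross-factor locus %s classified", p$rsid), "shared",
            group_label_of_region(ri, c("F1", "F2")))
      }
    } else if (p$type == "trait-specific") {
      qp <- run$fgwas[[1]]$QSNP_P[match(p$rsid, run$fgwas[[1]]$SNP)]
      add(sprintf("trait-specific locus %s Q_SNP significant", p$rsid),
          TRUE, isTRUE(qp < qsnp_p_max))
    }
  }

  for (qi in seq_len(nrow(study$qtl_meta))) {
    meta <- study$qtl_meta[qi, ]
    qres <- run$qtl_results
    hit <- nrow(qres) > 0 &&
      any(qres$qtl == meta$qtl & qres$colocalized, na.rm = TRUE)
    add(sprintf("QTL %s colocalization", meta$qtl), meta$shares_causal, hit)
    if (meta$shares_causal && hit) {
      mrr <- run$mr_results
      dir_ok <- nrow(mrr) > 0 && any(mrr$qtl == meta$qtl &
                                       mrr$direction == meta$true_direction)
      add(sprintf("QTL %s MR direction", meta$qtl), TRUE, dir_ok)
    }
  }

  checks <- dplyr::bind_rows(checks)
  list(checks = checks, accuracy = mean(checks$correct))
}
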