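# End-to-end synthetic analysis pipeline: simulate -> peaks -> consistency ->
# motif -> eqtl -> personal -> report. Deterministic given (config, seed);
# every stage writes TSV tables into the output directory.

#' Default pipeline configuration
#'
#' Desk-scale defaults: 4,096 bp windows with 32 x 128 bp bins (TSS at the
#' central bin junction), a 2,048 bp receptive field, M = 5 replicates and
#' perturbation scale sigma = 0.25. All sizes are configurable.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L, M = 5L, sigma = 0.25,
    window_length = 4096L, bin_width = 128L,
    receptive_field = 2048L, decay_scale = 384,
    n_tracks = 4L, baseline_rate = 0.5, model_seed = 42L,
    n_windows = 50L, gc = 0.41, motif_density = 0.5,
    downsample_stride = 10L, fdr = 0.01,
    offsets = c(10L, 100L, 1000L), n_backgrounds = 10L,
    motif_mode = "sample",
    eqtl_n_pos = 60L, eqtl_n_neg = 60L,
    personal_n_genes = 8L, personal_n_individuals = 80L,
    personal_n_variants = 15L, personal_h2 = 0.3,
    allele_freq_min = 0.05, allele_freq_max = 0.5,
    driver_delta = 0.05, driver_max = 6L,
    saliency_n_windows = 2L,
    stages = c("simulate", "peaks", "consistency", "motif", "eqtl",
               "personal", "report")
  )
}

.load_config <- function(config, ...) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.list(config)) cfg[names(config)] <- config
  dots <- list(...)
  if (base::length(dots)) cfg[names(dots)] <- dots
  cfg
}

# Gene-level binarization for background selection: a gene (window) counts as
# a peak on a track when either of its two TSS-flanking bins is called.
.gene_track_categories <- function(exp_calls, pred_calls, window_ids,
                                   nb_per_win, track_ids) {
  n_windows <- base::length(window_ids)
  tssA <- (seq_len(n_windows) - 1L) * nb_per_win + nb_per_win %/% 2L
  tssB <- tssA + 1L
  out <- list()
  for (t in seq_along(track_ids)) {
    truth <- as.integer(exp_calls[[t]]$is_peak[tssA] |
                          exp_calls[[t]]$is_peak[tssB])
    labels <- sapply(pred_calls[[t]], function(p)
      as.integer(p$is_peak[tssA] | p$is_peak[tssB]))
    labels <- matrix(labels, nrow = n_windows)
    rec <- classify_consistency_matrix(labels, truth, unit_ids = window_ids)
    out[[t]] <- data.frame(gene_id = rec$unit_id, track_id = track_ids[t],
                           category = rec$category, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full synthetic consistency pipeline
#'
#' @param config a configuration list, a path to a YAML config file, or NULL
#'   for the defaults; see [default_config()].
#' @param outdir output directory for result tables and the run log.
#' @param ... configuration overrides (e.g. `sigma = 0`, `seed = 7`).
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("enseq_run"), ...) {
  cfg <- .load_config(config, ...)
  if (cfg$M < 2L) stop("consistency analysis requires M >= 2", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("enseq %s | R %s", as.character(utils::packageVersion("enseq")),
          paste(R.version$major, R.version$minor, sep = "."))
  logline("seed=%d M=%d sigma=%g n_windows=%d window=%d bin=%d",
          cfg$seed, cfg$M, cfg$sigma, cfg$n_windows, cfg$window_length,
          cfg$bin_width)

  model <- default_ground_truth(
    n_tracks = cfg$n_tracks, seed = cfg$model_seed,
    baseline_rate = cfg$baseline_rate, decay_scale = cfg$decay_scale,
    receptive_field = cfg$receptive_field,
    window_length = cfg$window_length, bin_width = cfg$bin_width)
  ensemble <- make_replicate_ensemble(
    model, M = cfg$M, sigma = cfg$sigma,
    seeds = vapply(seq_len(cfg$M), function(i) derive_seed(cfg$seed, 100L + i),
                   integer(1)))
  res <- list(config = cfg, model = model, ensemble = ensemble)
  need <- function(what, from) {
    if (is.null(res[[what]])) {
      stop(sprintf("stage input '%s' missing: run stage '%s' first", what, from),
           call. = FALSE)
    }
  }
  nb <- cfg$window_length %/% cfg$bin_width

  for (stage in cfg$stages) {
    logline("stage %s", stage)
    if (stage == "simulate") {
      sim <- simulate_regulatory_genome(model, cfg$n_windows,
                                        gc = cfg$gc,
                                        motif_density = cfg$motif_density,
                                        seed = derive_seed(cfg$seed, 1L))
      exp_rates <- lapply(sim$windows, function(w) predict_tracks(model, w))
      counts <- lapply(seq_along(sim$windows), function(i)
        simulate_track_counts(exp_rates[[i]], seed = derive_seed(cfg$seed,
                                                                 1000L + i)))
      res$simulate <- list(windows = sim$windows, sites = sim$sites,
                           exp_rates = exp_rates, counts = counts)
      write_fasta(sim$windows, file.path(outdir, "windows.fa"))
      write_tsv(sim$sites, file.path(outdir, "planted_sites.tsv"))
      tss <- data.frame(
        chrom = vapply(sim$windows, function(w) w$chrom, character(1)),
        start = vapply(sim$windows, function(w) w$start + w$anchor, integer(1)),
        end = vapply(sim$windows, function(w) w$start + w$anchor + 1L,
                     integer(1)),
        name = vapply(sim$windows, function(w) w$id, character(1)))
      write_bed(tss, file.path(outdir, "tss.bed"))
      counts_long <- do.call(rbind, lapply(seq_along(counts), function(i) {
        data.frame(window_id = sim$windows[[i]]$id,
                   bin = seq_len(nrow(counts[[i]])),
                   counts[[i]], check.names = FALSE)
      }))
      names(counts_long)[-(1:2)] <- model$track_ids
      write_tsv(counts_long, file.path(outdir, "experimental_counts.tsv"))
    } else if (stage == "peaks") {
      need("simulate", "simulate")
      keep_ids <- vapply(downsample_windows(res$simulate$windows,
                                            cfg$downsample_stride),
                         function(w) w$id, character(1))
      idx <- which(vapply(res$simulate$windows, function(w)
        w$id %in% keep_ids, logical(1)))
      pred <- lapply(idx, function(i)
        robust_predict(ensemble, res$simulate$windows[[i]]))
      n_aw <- base::length(idx)
      exp_mat <- do.call(rbind, res$simulate$counts[idx])
      exp_calls <- lapply(seq_len(cfg$n_tracks), function(t)
        call_peaks(exp_mat[, t], fdr = cfg$fdr))
      pred_calls <- lapply(seq_len(cfg$n_tracks), function(t)
        lapply(seq_len(cfg$M), function(m)
          call_peaks(do.call(c, lapply(pred, function(p) p[, t, m])),
                     fdr = cfg$fdr)))
      tss_bins <- as.vector(vapply(seq_len(n_aw), function(i)
        (i - 1L) * nb + c(nb %/% 2L, nb %/% 2L + 1L), integer(2)))
      breakdown <- do.call(rbind, lapply(seq_len(cfg$n_tracks), function(t) {
        bd <- bin_consistency_breakdown(exp_calls[[t]], pred_calls[[t]],
                                        tss_bins)
        cbind(track_id = model$track_ids[t], bd$proportions)
      }))
      gene_cats <- .gene_track_categories(exp_calls, pred_calls, keep_ids, nb,
                                          model$track_ids)
      res$peaks <- list(analysis_ids = keep_ids, predictions = pred,
                        exp_calls = exp_calls, pred_calls = pred_calls,
                        breakdown = breakdown, gene_categories = gene_cats)
      write_tsv(breakdown, file.path(outdir, "peak_consistency.tsv"))
      write_tsv(gene_cats, file.path(outdir, "gene_track_categories.tsv"))
    } else if (stage == "consistency") {
      need("peaks", "peaks")
      pred <- res$peaks$predictions
      cors <- do.call(rbind, lapply(seq_len(cfg$n_tracks), function(t) {
        mat <- do.call(rbind, lapply(pred, function(p) p[, t, ]))
        cbind(track_id = model$track_ids[t],
              pairwise_correlation(mat, method = "pearson"))
      }))
      nw <- min(cfg$saliency_n_windows, base::length(res$peaks$analysis_ids))
      sal_cors <- NULL
      if (nw > 0L && cfg$M >= 2L) {
        wid <- res$peaks$analysis_ids[seq_len(nw)]
        widx <- which(vapply(res$simulate$windows, function(w)
          w$id %in% wid, logical(1)))
        sal <- lapply(widx, function(i) {
          at <- ism_attributions(ensemble, res$simulate$windows[[i]], track = 1L)
          apply(at, 2L, saliency_window_scores, window = cfg$bin_width)
        })
        sal_mat <- do.call(rbind, sal)
        sal_cors <- pairwise_correlation(sal_mat, method = "pearson")
      }
      res$consistency <- list(prediction_correlations = cors,
                              saliency_correlations = sal_cors)
      write_tsv(cors, file.path(outdir, "replicate_prediction_correlations.tsv"))
      if (!is.null(sal_cors)) {
        write_tsv(sal_cors, file.path(outdir, "saliency_correlations.tsv"))
      }
    } else if (stage == "motif") {
      need("peaks", "peaks")
      bg_ids <- select_backgrounds(res$peaks$gene_categories,
                                   n = min(cfg$n_backgrounds,
                                           base::length(res$peaks$analysis_ids)))
      bgs <- res$simulate$windows[vapply(res$simulate$windows, function(w)
        w$id %in% bg_ids, logical(1))]
      ma <- motif_activity_analysis(ensemble, bgs, model$motifs,
                                    offsets = cfg$offsets,
                                    mode = cfg$motif_mode,
                                    seed = derive_seed(cfg$seed, 3L))
      frac <- list()
      for (t in seq_len(cfg$n_tracks)) {
        for (off in cfg$offsets) {
          sel <- which(ma$combos$offset == off)
          for (kind in c("CANONICAL", "MUTATION")) {
            sc <- t(vapply(sel, function(i) ma$scores[[i]][[kind]]$scores[, t],
                           numeric(cfg$M)))
            frac[[base::length(frac) + 1L]] <- data.frame(
              track_id = model$track_ids[t], offset = off, kind = kind,
              inconsistency = inconsistency_fraction(sc),
              stringsAsFactors = FALSE)
          }
        }
      }
      frac <- do.call(rbind, frac)
      # mutation vs canonical inconsistency across tracks, per offset, BH over
      # the offset family
      pairs <- lapply(cfg$offsets, function(off) {
        list(a = frac$inconsistency[frac$offset == off & frac$kind == "MUTATION"],
             b = frac$inconsistency[frac$offset == off & frac$kind == "CANONICAL"],
             name = sprintf("offset_%d", off))
      })
      tests <- group_compare_family(pairs, alternative = "greater")
      res$motif <- list(analysis = ma, inconsistency = frac, tests = tests,
                        backgrounds = bg_ids)
      write_tsv(ma$long, file.path(outdir, "motif_activity_scores.tsv"))
      write_tsv(frac, file.path(outdir, "motif_inconsistency.tsv"))
      write_tsv(tests, file.path(outdir, "motif_mutation_tests.tsv"))
    } else if (stage == "eqtl") {
      need("simulate", "simulate")
      variants <- simulate_eqtls(model, res$simulate$windows,
                                 res$simulate$sites,
                                 n_pos = cfg$eqtl_n_pos,
                                 n_neg = cfg$eqtl_n_neg,
                                 seed = derive_seed(cfg$seed, 4L))
      vg <- data.frame(variant_id = variants$variant_id,
                       gene_id = variants$gene_id,
                       tss_distance = variants$tss_distance,
                       sign = variants$true_sign, stringsAsFactors = FALSE)
      kept <- filter_variants(vg, cfg$receptive_field)
      variants <- variants[variants$variant_id %in% kept$variant_id, ,
                           drop = FALSE]
      eff <- variant_effect_table(ensemble, res$simulate$windows, variants,
                                  track = 1L)
      pos <- !is.na(variants$true_sign)
      cons <- eqtl_consistency_table(eff$sad[pos, , drop = FALSE],
                                     variants$true_sign[pos],
                                     variants$variant_id[pos])
      acc <- ensemble_vs_single_accuracy(eff$sad[pos, , drop = FALSE],
                                         variants$true_sign[pos])
      strata <- effect_size_strata(eff$table$mean_abs_sad[pos])
      by_size <- stratify_consistency(cons$records, strata)
      res$eqtl <- list(variants = variants, effects = eff,
                       consistency = cons, accuracy = acc,
                       by_effect_size = by_size)
      write_phased_vcf(data.frame(chrom = variants$chrom, pos = variants$pos,
                                  id = variants$variant_id,
                                  ref = variants$ref, alt = variants$alt),
                       path = file.path(outdir, "eqtl_variants.vcf"))
      write_tsv(eff$table, file.path(outdir, "eqtl_effects.tsv"))
      write_tsv(data.frame(category = names(cons$proportions),
                           proportion = as.numeric(cons$proportions)),
                file.path(outdir, "eqtl_consistency.tsv"))
      write_tsv(by_size, file.path(outdir, "eqtl_by_effect_size.tsv"))
    } else if (stage == "personal") {
      need("simulate", "simulate")
      ng <- min(cfg$personal_n_genes, base::length(res$simulate$windows))
      genes <- res$simulate$windows[seq_len(ng)]
      rho <- matrix(NA_real_, ng, cfg$M)
      rho_ens <- numeric(ng)
      drivers <- list()
      sad_signs <- list()
      gene_ids <- vapply(genes, function(w) w$id, character(1))
      pops <- vector("list", ng)
      for (g in seq_len(ng)) {
        w <- genes[[g]]
        pseed <- derive_seed(cfg$seed, 5000L + g)
        n_planted <- with_seed(derive_seed(cfg$seed, 5500L + g),
                               sample(0:3, 1L))
        panel <- draw_variant_panel(w, res$simulate$sites,
                                    n_variants = cfg$personal_n_variants,
                                    n_planted = n_planted, seed = pseed,
                                    freq_range = c(cfg$allele_freq_min,
                                                   cfg$allele_freq_max))
        pop <- simulate_population(model, w, panel,
                                   n_individuals = cfg$personal_n_individuals,
                                   allele_freq = panel$freq,
                                   h2 = cfg$personal_h2,
                                   seed = derive_seed(cfg$seed, 6000L + g))
        preds <- predict_population(ensemble, w, panel, pop$haplotypes)
        for (m in seq_len(cfg$M)) {
          rho[g, m] <- suppressWarnings(
            cross_individual_correlation(preds[, m], pop$measured))
        }
        rho_ens[g] <- suppressWarnings(
          cross_individual_correlation(ensemble_mean_rank(preds), pop$measured))
        for (m in seq_len(cfg$M)) {
          dr <- identify_drivers(preds[, m], pop$dosage,
                                 variant_ids = panel$variant_id,
                                 delta = cfg$driver_delta,
                                 max_drivers = cfg$driver_max)
          if (nrow(dr)) {
            drivers[[base::length(drivers) + 1L]] <-
              cbind(gene_id = w$id, replicate = m, dr)
          }
        }
        veff <- variant_effect_table(ensemble, list(w),
                                     cbind(panel, gene_id = w$id), track = 1L)
        sad_signs[[g]] <- data.frame(
          gene_id = w$id,
          variant_id = rep(panel$variant_id, cfg$M),
          replicate = rep(seq_len(cfg$M), each = nrow(panel)),
          sign = as.vector(sign(veff$sad)), stringsAsFactors = FALSE)
        pops[[g]] <- pop
      }
      gu <- gene_uncertainty_table(rho, gene_ids)
      ext <- select_uncertainty_extremes(gu, n = max(1L, ng %/% 4L))
      drivers_df <- if (base::length(drivers)) do.call(rbind, drivers) else
        data.frame(gene_id = character(0), replicate = integer(0),
                   variant_id = character(0))
      conc <- driver_concordance(drivers_df, do.call(rbind, sad_signs),
                                 ext$table, M = cfg$M)
      res$personal <- list(rho = rho, rho_ensemble = rho_ens,
                           uncertainty = ext$table, drivers = drivers_df,
                           concordance = conc, gene_ids = gene_ids)
      write_tsv(ext$table, file.path(outdir, "gene_uncertainty.tsv"))
      if (nrow(drivers_df)) {
        write_tsv(drivers_df, file.path(outdir, "drivers.tsv"))
      }
      write_tsv(conc$reproducibility,
                file.path(outdir, "driver_reproducibility.tsv"))
      write_tsv(data.frame(gene_id = gene_ids, rho_rep1 = rho[, 1L],
                           rho_rep2 = rho[, 2L], rho_ensemble = rho_ens),
                file.path(outdir, "cross_individual_scatter.tsv"))
    } else if (stage == "report") {
      lines <- list()
      add <- function(metric, value) {
        lines[[base::length(lines) + 1L]] <<-
          data.frame(metric = metric, value = value, stringsAsFactors = FALSE)
      }
      if (!is.null(res$consistency)) {
        add("median_replicate_pearson",
            stats::median(res$consistency$prediction_correlations$correlation,
                          na.rm = TRUE))
      }
      if (!is.null(res$peaks)) {
        bd <- res$peaks$breakdown
        for (s in unique(bd$stratum)) {
          add(sprintf("peak_inconsistent_%s", s),
              mean(bd$INCONSISTENT[bd$stratum == s], na.rm = TRUE))
        }
      }
      if (!is.null(res$motif)) {
        fr <- res$motif$inconsistency
        for (kind in c("CANONICAL", "MUTATION")) {
          add(sprintf("motif_inconsistency_%s", tolower(kind)),
              mean(fr$inconsistency[fr$kind == kind]))
        }
      }
      if (!is.null(res$eqtl)) {
        pr <- res$eqtl$consistency$proportions
        for (nm in names(pr)) add(sprintf("eqtl_%s", tolower(nm)), pr[[nm]])
        add("eqtl_accuracy_single", res$eqtl$accuracy$accuracy_single)
        add("eqtl_accuracy_majority", res$eqtl$accuracy$accuracy_majority)
      }
      if (!is.null(res$personal)) {
        gu <- res$personal$uncertainty
        disag <- mean(gu$n_positive > 0 & gu$n_positive < cfg$M)
        add("personal_sign_disagreement_fraction", disag)
      }
      summary <- do.call(rbind, lines)
      res$report <- summary
      write_tsv(summary, file.path(outdir, "summary.tsv"))
    } else {
      stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
    }
  }
  logline("done")
  invisible(res)
}
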