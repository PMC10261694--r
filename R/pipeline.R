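#' Experiment configuration
#'
#' Bundles everything needed to run the full denoising experiment: phantom
#' geometry, train/test phantom counts, denoiser architecture, the two
#' comparison filters, and explicit seeds for every source of randomness.
#'
#' The defaults are a deliberately scaled-down study that runs on one CPU in
#' minutes: 64 x 64 in-plane slices, 40 slices per phantom, 8 training and
#' 4 test phantoms, and a 5-layer network with 7 x 7 kernels, 16 filters and
#' 15 epochs. Full-scale values (236 x 132 slices, 15 x 15 kernels,
#' 128 filters, 100 epochs) can be restored through [phantom_spec()] and
#' [denoiser_config()].
#'
#' @param phantom a [phantom_spec()]; `NULL` for the scaled-down default.
#' @param n_train_phantoms,n_test_phantoms phantom counts for training and
#'   held-out evaluation.
#' @param denoiser a [denoiser_config()]; `NULL` for the scaled-down default.
#' @param gaussian a [gaussian_params()]; applied both to LC (comparator) and
#'   FC (reference), with the same FWHM.
#' @param nlm an [nlm_params()]; when its `h` is `NULL`, the filtering
#'   strength is estimated per test phantom as the pooled background SD of
#'   the LC image.
#' @param seeds named list with integer entries `simulate`, `split`, `train`,
#'   `rois`.
#' @param n_bg_rois,n_edge_rois ROIs per phantom (default 5 each).
#' @param output_dir optional directory; when set, volumes (NIfTI), tables
#'   (CSV) and MIP renderings (PNG) are persisted there.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = NULL,
                              n_train_phantoms = 8, n_test_phantoms = 4,
                              denoiser = NULL,
                              gaussian = gaussian_params(1.17),
                              nlm = nlm_params(),
                              seeds = list(simulate = 101, split = 102,
                                           train = 103, rois = 104),
                              n_bg_rois = 5, n_edge_rois = 5,
                              output_dir = NULL) {
  if (is.null(phantom))
    phantom <- phantom_spec(n_slices = 40, slice_shape = c(64, 64),
                            gland_texture_sigma = 6)
  if (is.null(denoiser))
    denoiser <- denoiser_config(n_conv_layers = 5, kernel = 7,
                                n_filters = 16,
                                input_shape = phantom$slice_shape,
                                epochs = 15, seed = seeds$train)
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(denoiser, "denoiser_config"),
            inherits(gaussian, "gaussian_params"),
            inherits(nlm, "nlm_params"))
  for (nm in c("simulate", "split", "train", "rois"))
    if (is.null(seeds[[nm]]))
      stop(sprintf("seeds$%s must be set explicitly", nm), call. = FALSE)
  structure(list(phantom = phantom,
                 n_train_phantoms = as.integer(n_train_phantoms),
                 n_test_phantoms = as.integer(n_test_phantoms),
                 denoiser = denoiser, gaussian = gaussian, nlm = nlm,
                 seeds = seeds, n_bg_rois = n_bg_rois,
                 n_edge_rois = n_edge_rois, output_dir = output_dir),
            class = "experiment_config")
}

target_sets <- c("LC", "LC+Gaussian", "LC+NLM", "LC+DL")
all_sets <- c(target_sets, "FC+Gaussian")

#' Run the full denoising experiment
#'
#' Simulates paired LC/FC phantom datasets (train/test separation at phantom
#' level), trains the residual network on the training slices, produces the
#' five image sets for each held-out phantom — LC, LC+Gaussian, LC+NLM,
#' LC+DL and the FC+Gaussian reference — and evaluates them: background and
#' FOV-edge ROI statistics, lesion SUVmax/SUVpeak, relative differences and
#' Bland-Altman agreement against the reference, relative SUVmax differences
#' against the noise-free truth, and Bonferroni-corrected paired comparisons.
#'
#' @param config an [experiment_config()].
#' @return An object of class `experiment_report`: a list of data frames
#'   (`background`, `edge`, `lesions`, `d_values`, `bland_altman`,
#'   `truth_bias`, `comparisons`), the training `history`, the fitted
#'   `model` and the `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  spec <- config$phantom
  sim_seeds <- derive_seeds(config$seeds$simulate, 2)
  train_data <- make_paired_dataset(spec, config$n_train_phantoms,
                                    sim_seeds[1])
  test_data <- make_paired_dataset(spec, config$n_test_phantoms,
                                   sim_seeds[2])

  pairs <- unlist(lapply(train_data, function(ph) {
    lapply(seq_len(dim(ph$lc$values)[3]), function(z)
      list(lc = ph$lc$values[, , z], fc = ph$fc$values[, , z]))
  }), recursive = FALSE)
  sp <- split_train_val(pairs, config$denoiser$val_fraction,
                        config$seeds$split)

  model <- build_denoiser(config$denoiser)
  if (config$denoiser$epochs > 0L)
    model <- train_denoiser(model, sp$train, val_pairs = sp$val)

  roi_seeds <- matrix(derive_seeds(config$seeds$rois,
                                   2L * config$n_test_phantoms), nrow = 2L)
  bg_rows <- list(); edge_rows <- list(); lesion_rows <- list()
  volumes <- list()

  for (i in seq_along(test_data)) {
    ph <- test_data[[i]]
    masks <- ph$activity$masks
    sets <- list()
    sets[["LC"]] <- ph$lc
    sets[["LC+Gaussian"]] <- gaussian_post_filter(ph$lc, config$gaussian)
    bg_rois <- place_background_rois(ph$lc, masks$gland, n = config$n_bg_rois,
                                     seed = roi_seeds[1L, i],
                                     lesion_mask = masks$lesion)
    nlm_p <- config$nlm
    if (is.null(nlm_p$h))
      nlm_p$h <- estimate_background_sigma(ph$lc, bg_rois)
    sets[["LC+NLM"]] <- nlm_filter(ph$lc, nlm_p)
    sets[["LC+DL"]] <- denoise_volume(model, ph$lc)
    ref <- gaussian_post_filter(ph$fc, config$gaussian)
    ref$meta <- "FC+Gaussian"
    sets[["FC+Gaussian"]] <- ref
    edge_rois <- place_edge_rois(ph$lc, masks$breast,
                                 n = config$n_edge_rois,
                                 seed = roi_seeds[2L, i])

    for (set in all_sets) {
      vol <- sets[[set]]
      for (j in seq_along(bg_rois)) {
        st <- roi_stats(vol, bg_rois[[j]])
        bg_rows[[length(bg_rows) + 1L]] <- data.frame(
          phantom = i, roi = j, set = set, suv_mean = st$suv_mean,
          sd = st$sd, cv = st$cv)
      }
      for (j in seq_along(edge_rois)) {
        st <- roi_stats(vol, edge_rois[[j]])
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          phantom = i, roi = j, set = set, cv = st$cv)
      }
      for (j in seq_along(ph$lesions)) {
        les <- ph$lesions[[j]]
        off <- sphere_offsets(les$diameter_mm / 2, spec$voxel_mm)
        voi <- sweep(off, 2L, les$center, `+`)
        lm <- measure_lesion(vol, voi)
        lesion_rows[[length(lesion_rows) + 1L]] <- data.frame(
          phantom = i, lesion = j, kind = les$kind,
          diameter_mm = les$diameter_mm, true_suv = les$suv, set = set,
          suv_max = lm$suv_max, suv_peak = lm$suv_peak)
      }
    }
    volumes[[i]] <- sets
  }

  background <- do.call(rbind, bg_rows)
  edge <- do.call(rbind, edge_rows)
  lesions <- if (length(lesion_rows)) do.call(rbind, lesion_rows) else NULL

  # relative differences and Bland-Altman agreement vs the reference set
  d_values <- NULL
  ba_rows <- list()
  truth_rows <- list()
  if (!is.null(lesions)) {
    ref_tab <- lesions[lesions$set == "FC+Gaussian", ]
    key <- function(df) paste(df$phantom, df$lesion)
    d_list <- list()
    for (set in target_sets) {
      tgt <- lesions[lesions$set == set, ]
      tgt <- tgt[match(key(ref_tab), key(tgt)), ]
      d_list[[set]] <- data.frame(
        phantom = ref_tab$phantom, lesion = ref_tab$lesion, set = set,
        d_suv_max = relative_difference(tgt$suv_max, ref_tab$suv_max),
        d_suv_peak = relative_difference(tgt$suv_peak, ref_tab$suv_peak))
      for (metric in c("d_suv_max", "d_suv_peak")) {
        ds <- d_list[[set]][[metric]]
        if (length(ds) >= 2L) {
          ba <- bland_altman(ds)
          ba_rows[[length(ba_rows) + 1L]] <- data.frame(
            set = set, metric = sub("^d_", "", metric),
            bias = ba$bias, limits = ba$limits, n = length(ds))
        }
      }
    }
    d_values <- do.call(rbind, d_list)
    for (set in all_sets) {
      tab <- lesions[lesions$set == set, ]
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        set = set,
        mean_d_suv_max = mean(relative_difference(tab$suv_max,
                                                  tab$true_suv)),
        n = nrow(tab))
    }
  }

  comparisons <- compare_sets(background, edge, lesions)

  report <- structure(
    list(background = background, edge = edge, lesions = lesions,
         d_values = d_values,
         bland_altman = if (length(ba_rows)) do.call(rbind, ba_rows) else NULL,
         truth_bias = if (length(truth_rows)) do.call(rbind, truth_rows)
         else NULL,
         comparisons = comparisons, history = model$history,
         model = model, config = config),
    class = "experiment_report")
  if (!is.null(config$output_dir))
    write_report(report, volumes, config$output_dir)
  report
}

# Bonferroni-corrected paired comparisons of each target set against the
# reference: t-tests on background CV (paired over ROIs), Wilcoxon
# signed-rank on lesion SUVmax/SUVpeak (paired over lesions).
compare_sets <- function(background, edge, lesions) {
  rows <- list()
  n_cmp <- length(target_sets)
  ref_cv <- background$cv[background$set == "FC+Gaussian"]
  for (set in target_sets) {
    cv <- background$cv[background$set == set]
    pc <- paired_compare(cv, ref_cv, test = "t", n_comparisons = n_cmp)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = "background_cv", set = set, test = pc$test,
      p_raw = pc$p_raw, p_adj = pc$p_adj, significant = pc$significant,
      degenerate = pc$degenerate)
  }
  if (!is.null(lesions) &&
      sum(lesions$set == "FC+Gaussian") >= 2L) {
    for (metric in c("suv_max", "suv_peak")) {
      ref <- lesions[lesions$set == "FC+Gaussian", metric]
      for (set in target_sets) {
        tgt <- lesions[lesions$set == set, metric]
        pc <- paired_compare(tgt, ref, test = "wilcoxon",
                             n_comparisons = n_cmp)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = metric, set = set, test = pc$test, p_raw = pc$p_raw,
          p_adj = pc$p_adj, significant = pc$significant,
          degenerate = pc$degenerate)
      }
    }
  }
  do.call(rbind, rows)
}

write_report <- function(report, volumes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("background", "edge", "lesions", "d_values", "bland_altman",
               "truth_bias", "comparisons", "history")) {
    tab <- report[[nm]]
    if (!is.null(tab))
      write.csv(tab, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  for (i in seq_along(volumes)) {
    for (set in names(volumes[[i]])) {
      base <- file.path(dir, sprintf("phantom%02d_%s", i,
                                     gsub("[^A-Za-z0-9]", "_", set)))
      write_volume(volumes[[i]][[set]], paste0(base, ".nii.gz"))
      if (requireNamespace("png", quietly = TRUE)) {
        img <- render_mip(mip(volumes[[i]][[set]], "craniocaudal"))
        png::writePNG(img, paste0(base, "_mip_cc.png"))
      }
    }
  }
  invisible(dir)
}

#' @export
summary.experiment_report <- function(object, ...) {
  bg <- stats::aggregate(cv ~ set, data = object$background, FUN = mean)
  bg$sd_cv <- stats::aggregate(cv ~ set, data = object$background,
                               FUN = sd)$cv
  bg$mean_suv <- stats::aggregate(suv_mean ~ set, data = object$background,
                                  FUN = mean)$suv_mean
  eg <- stats::aggregate(cv ~ set, data = object$edge, FUN = mean)
  names(eg)[2] <- "edge_cv"
  out <- merge(bg, eg, by = "set", sort = FALSE)
  out <- out[order(match(out$set, all_sets)), ]
  structure(list(sets = out, bland_altman = object$bland_altman,
                 truth_bias = object$truth_bias,
                 comparisons = object$comparisons),
            class = "summary.experiment_report")
}

#' @export
print.summary.experiment_report <- function(x, ...) {
  cat("Image-set noise summary (background fibroglandular ROIs):\n")
  tab <- x$sets
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s SUVmean %.3f   CV %5.2f +/- %4.2f %%   edge CV %5.2f %%\n",
                tab$set[i], tab$mean_suv[i], tab$cv[i], tab$sd_cv[i],
                tab$edge_cv[i]))
  ranked <- tab$set[order(tab$cv)]
  cat("  CV ranking (lowest first):", paste(ranked, collapse = " < "), "\n")
  if (!is.null(x$bland_altman)) {
    cat("Bland-Altman agreement vs FC+Gaussian reference:\n")
    ba <- x$bland_altman
    for (i in seq_len(nrow(ba)))
      cat(sprintf("  %-12s %-8s bias %+6.2f %%   limits %.2f %%\n",
                  ba$set[i], ba$metric[i], ba$bias[i], ba$limits[i]))
  }
  if (!is.null(x$truth_bias)) {
    cat("Mean relative SUVmax difference vs noise-free truth:\n")
    tb <- x$truth_bias
    for (i in seq_len(nrow(tb)))
      cat(sprintf("  %-12s %+6.2f %% (n = %d)\n", tb$set[i],
                  tb$mean_d_suv_max[i], tb$n[i]))
  }
  invisible(x)
}

#' @export
print.experiment_report <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
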