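#' Pipeline run configuration
#'
#' Bundles the protocol constants (360 resampled points, 95% harmonic
#' power, balancing to 30 per class, 1000 benchmark and 100 assignment
#' permutations) with paths and the mandatory RNG seed. All stochastic
#' stages derive named sub-seeds from `rng_seed`, so a config fully
#' determines every output.
#'
#' @param out_dir output directory for all artifacts.
#' @param rng_seed master RNG seed (mandatory; no silent nondeterminism).
#' @param simulate if `TRUE` (default) generate the synthetic study
#'   design; otherwise read `masks_dir`, `landmarks_file`,
#'   `records_file`.
#' @param k_points outline resampling count (default 360).
#' @param harmonic_threshold power fraction for harmonic retention
#'   (default 0.95).
#' @param max_harmonics harmonics computed before retention (default 8).
#' @param n_per_class balanced class size (default 30).
#' @param n_perm_benchmark benchmark permutations (default 1000).
#' @param n_perm_assign assignment permutations (default 100).
#' @param separation shape separation of the rounded triple (default 1).
#' @param px_per_mm rendering resolution (default 100).
#' @param render rasterize seeds to masks and re-extract (default
#'   `TRUE`); `FALSE` keeps the acquisition outlines in memory.
#' @param feature_sets subset of `c("cells", "size", "shape", "all")`.
#' @param acquisition_noise,me_position_noise,me_cleaning_noise,me_landmark_noise
#'   noise levels (sd) for the main acquisition and the three
#'   reproducibility tests; see [noise_spec()] for units.
#' @param masks_dir,landmarks_file,records_file inputs when
#'   `simulate = FALSE`.
#' @param n_unknowns number of archaeological-like unknowns (default 33,
#'   drawn half and half from the setigerum and somniferum models).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, rng_seed,
                       simulate = TRUE,
                       k_points = 360, harmonic_threshold = 0.95,
                       max_harmonics = 8,
                       n_per_class = 30, n_perm_benchmark = 1000,
                       n_perm_assign = 100,
                       separation = 1, px_per_mm = 100, render = TRUE,
                       feature_sets = c("cells", "size", "shape", "all"),
                       acquisition_noise = c(rotation = 0.08, outline = 0.004,
                                             landmark = 0.008),
                       me_position_noise = c(rotation = 0.35, outline = 0.001,
                                             landmark = 0.004),
                       me_cleaning_noise = c(rotation = 0, outline = 0.008,
                                             landmark = 0),
                       me_landmark_noise = c(rotation = 0, outline = 0,
                                             landmark = 0.015),
                       masks_dir = NULL, landmarks_file = NULL,
                       records_file = NULL, n_unknowns = 33) {
  if (missing(rng_seed)) stop2("run_config requires rng_seed")
  counts <- c(k_points = k_points, max_harmonics = max_harmonics,
              n_per_class = n_per_class, n_perm_benchmark = n_perm_benchmark,
              n_perm_assign = n_perm_assign, px_per_mm = px_per_mm,
              n_unknowns = n_unknowns)
  if (any(counts <= 0)) stop2("all counts must be positive")
  if (harmonic_threshold <= 0 || harmonic_threshold > 1)
    stop2("harmonic_threshold must be in (0, 1]")
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  if (!simulate && (is.null(masks_dir) || is.null(landmarks_file) ||
                    is.null(records_file)))
    stop2("simulate = FALSE needs masks_dir, landmarks_file and records_file")
  structure(list(out_dir = out_dir, rng_seed = as.integer(rng_seed),
                 simulate = simulate, k_points = k_points,
                 harmonic_threshold = harmonic_threshold,
                 max_harmonics = max_harmonics, n_per_class = n_per_class,
                 n_perm_benchmark = n_perm_benchmark,
                 n_perm_assign = n_perm_assign, separation = separation,
                 px_per_mm = px_per_mm, render = render,
                 feature_sets = feature_sets,
                 acquisition_noise = acquisition_noise,
                 me_position_noise = me_position_noise,
                 me_cleaning_noise = me_cleaning_noise,
                 me_landmark_noise = me_landmark_noise,
                 masks_dir = masks_dir, landmarks_file = landmarks_file,
                 records_file = records_file, n_unknowns = n_unknowns),
            class = "run_config")
}

noise_from <- function(v, seed) {
  noise_spec(rotation_sd = v[["rotation"]], outline_jitter_sd = v[["outline"]],
             landmark_jitter_sd = v[["landmark"]], seed = seed)
}

run_stage <- function(name, expr) {
  message("[seedmorph] stage: ", name)
  tryCatch(expr, error = function(e)
    stop2("stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> extract -> align -> transform -> statistics
#' -> classify -> assign and writes every stage's table under
#' `config$out_dir`, plus a machine-readable `summary.json`. Rerunning
#' with the same config reproduces every output.
#'
#' @param config a [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_of <- function(stage) stage_seed(config$rng_seed, stage)
  scale <- 1 / config$px_per_mm

  # -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    if (config$simulate) {
      models <- default_taxon_models(config$separation)
      modern_models <- c(models,
                         list(setigerum_b = accession_variant(models$setigerum),
                              somniferum_b = accession_variant(models$somniferum)))
      acq <- function(seed) noise_from(config$acquisition_noise, seed)
      modern <- simulate_population(modern_models, acq(seed_of("simulate_modern")),
                                    px_per_mm = config$px_per_mm,
                                    render = config$render)
      n_set <- ceiling(config$n_unknowns / 2)
      unk_models <- list(u1 = models$setigerum, u2 = models$somniferum)
      unk_models$u1$n_seeds <- n_set
      unk_models$u2$n_seeds <- config$n_unknowns - n_set
      unk_models$u1$accession <- unk_models$u2$accession <- "arch"
      unknown <- simulate_population(unk_models, acq(seed_of("simulate_unknown")),
                                     px_per_mm = config$px_per_mm,
                                     render = config$render,
                                     taxon_label = "unknown")
      me_base <- simulate_population(lapply(models[c("setigerum", "somniferum", "nigrum")],
                                            function(m) { m$n_seeds <- 5L; m }),
                                     acq(seed_of("simulate_me_base")),
                                     px_per_mm = config$px_per_mm,
                                     render = config$render)
      me_sets <- list(
        position = simulate_repeats(me_base, 5,
          noise_from(config$me_position_noise, seed_of("me_position")),
          render = config$render),
        cleaning = simulate_repeats(me_base, 3,
          noise_from(config$me_cleaning_noise, seed_of("me_cleaning")),
          render = config$render),
        landmark = simulate_repeats(me_base, 3,
          noise_from(config$me_landmark_noise, seed_of("me_landmark")),
          render = config$render))
      list(modern = modern, unknown = unknown, me_sets = me_sets)
    } else {
      mask_files <- list.files(config$masks_dir, pattern = "\\.(png|tif|tiff)$",
                               full.names = TRUE)
      ids <- tools::file_path_sans_ext(basename(mask_files))
      lmks <- read_landmarks(config$landmarks_file)
      recs <- read_descriptors(config$records_file)
      masks <- lapply(mask_files, read_mask)
      names(masks) <- ids
      pop <- structure(list(records = recs, truth = NULL, outlines = NULL,
                            landmarks = lmks[ids], masks = masks,
                            px_per_mm = config$px_per_mm),
                       class = "seed_population")
      list(modern = pop, unknown = NULL, me_sets = NULL)
    }
  })

  # -- extract + efa on the combined modern + unknown material -------------
  combined <- run_stage("extract", {
    pops <- Filter(Negate(is.null), list(sim$modern, sim$unknown))
    records <- do.call(rbind, lapply(pops, `[[`, "records"))
    outs <- list(); lmks <- list()
    for (pop in pops) {
      for (id in pop$records$id) {
        if (!is.null(pop$masks)) {
          o <- extract_outline(pop$masks[[id]], scale = scale)
        } else {
          o <- pop$outlines[[id]]
        }
        outs[[id]] <- o
        lmks[[id]] <- pop$landmarks[[id]]
      }
    }
    sizes <- t(vapply(outs, bounding_box_size, numeric(2)))
    records$length <- sizes[records$id, 1]
    records$width <- sizes[records$id, 2]
    records$log_length <- log(records$length)
    records$log_width <- log(records$width)
    list(records = records, outlines = outs, landmarks = lmks)
  })

  efa <- run_stage("efa", {
    res <- mapply(function(o, l) resample_outline(o, config$k_points,
                                                  start = unclass(l)[2, ],
                                                  check = FALSE),
                  combined$outlines, combined$landmarks, SIMPLIFY = FALSE)
    ali <- gpa_align(res, combined$landmarks)
    coeff_all <- lapply(ali$outlines, efourier, H = config$max_harmonics)
    hsel <- choose_harmonics(coeff_all, config$harmonic_threshold)
    mat <- coeff_matrix(coeff_all, H = hsel$H_star)
    write_coefficients(mat, file.path(config$out_dir, "coefficients.csv"))
    list(alignment = ali, coeffs = mat, H_star = hsel$H_star,
         mean_cumulative = hsel$mean_cumulative)
  })

  records <- combined$records
  modern_idx <- records$taxon != "unknown"
  shape_cols <- colnames(efa$coeffs)
  features <- data.frame(records[c("id", "taxon", "accession", "cells",
                                   "log_length", "log_width")],
                         efa$coeffs[records$id, , drop = FALSE],
                         check.names = FALSE)
  rownames(features) <- records$id

  # -- measurement error ----------------------------------------------------
  me_tab <- if (is.null(sim$me_sets)) NULL else run_stage("measurement_error", {
    rows <- list()
    for (test in names(sim$me_sets)) {
      rep_pop <- sim$me_sets[[test]]
      res <- lapply(rep_pop$records$id, function(id) {
        if (!is.null(rep_pop$masks)) extract_outline(rep_pop$masks[[id]], scale = scale)
        else rep_pop$outlines[[id]]
      })
      names(res) <- rep_pop$records$id
      res <- mapply(function(o, l) resample_outline(o, config$k_points,
                                                    start = unclass(l)[2, ],
                                                    check = FALSE),
                    res, rep_pop$landmarks[rep_pop$records$id], SIMPLIFY = FALSE)
      ali <- gpa_align(res, rep_pop$landmarks[rep_pop$records$id])
      cf <- coeff_matrix(lapply(ali$outlines, efourier, H = config$max_harmonics),
                         H = efa$H_star)
      for (tx in unique(rep_pop$records$taxon)) {
        sel <- rep_pop$records$taxon == tx
        me <- measurement_error_shape(cf[sel, , drop = FALSE],
                                      rep_pop$records$individual[sel])
        rows[[paste(test, tx)]] <- data.frame(test = test, taxon = tx,
                                              F = me$pooled$F, p = me$pooled$p,
                                              pct_me = me$pooled$pct_me)
      }
    }
    tab <- do.call(rbind, c(rows, make.row.names = FALSE))
    utils::write.csv(tab, file.path(config$out_dir, "measurement_error.csv"),
                     row.names = FALSE)
    tab
  })

  # -- descriptive statistics ----------------------------------------------
  stats_res <- run_stage("stats", {
    mod <- features[modern_idx, ]
    grp <- interaction(mod$taxon, mod$accession, drop = TRUE)
    uni <- lapply(c(log_length = "log_length", log_width = "log_width",
                    cells = "cells"),
                  function(v) kruskal_wallis(mod[[v]], grp))
    wil <- lapply(c(log_length = "log_length", log_width = "log_width",
                    cells = "cells"),
                  function(v) pairwise_wilcoxon(mod[[v]], grp))
    pca <- pca_fit(efa$coeffs[records$id[modern_idx], , drop = FALSE])
    supp <- if (any(!modern_idx)) {
      pca_project(pca, efa$coeffs[records$id[!modern_idx], , drop = FALSE])
    } else NULL
    scores <- rbind(
      data.frame(id = records$id[modern_idx], taxon = records$taxon[modern_idx],
                 is_supplementary = FALSE, pca$scores[, 1:2, drop = FALSE]),
      if (!is.null(supp))
        data.frame(id = records$id[!modern_idx], taxon = "unknown",
                   is_supplementary = TRUE, supp[, 1:2, drop = FALSE]))
    utils::write.csv(scores, file.path(config$out_dir, "pca_scores.csv"),
                     row.names = FALSE)
    manova <- permutational_manova(efa$coeffs[records$id[modern_idx], , drop = FALSE],
                                   mod$taxon, n_perm = 999,
                                   seed = seed_of("permanova"))
    ms <- mean_shapes(efa$coeffs[records$id[modern_idx], , drop = FALSE], mod$taxon)
    tree <- upgma_tree(ms$coeffs, newick_file = file.path(config$out_dir, "upgma.nwk"))
    tests <- do.call(rbind, lapply(names(uni), function(v)
      data.frame(test = "kruskal_wallis", variable = v,
                 statistic = uni[[v]]$chi2, df = uni[[v]]$df, p = uni[[v]]$p)))
    utils::write.csv(tests, file.path(config$out_dir, "tests.csv"), row.names = FALSE)
    list(kruskal = uni, wilcoxon = wil, pca = pca, permanova = manova,
         mean_shapes = ms, tree = tree)
  })

  # -- classification benchmark --------------------------------------------
  fsets <- list(cells = "cells", size = c("log_length", "log_width"),
                shape = shape_cols,
                all = c("cells", "log_length", "log_width", shape_cols))
  fsets <- fsets[config$feature_sets]
  bench <- run_stage("classify", {
    mod <- features[modern_idx, ]
    b <- balanced_benchmark(mod, mod$taxon, fsets,
                            n_per_class = config$n_per_class,
                            n_perm = config$n_perm_benchmark,
                            seed = seed_of("benchmark"))
    utils::write.csv(b$accuracy, file.path(config$out_dir, "benchmark.csv"),
                     row.names = FALSE)
    base_fs <- fsets[[length(fsets)]]
    base <- shuffled_label_baseline(mod, mod$taxon, base_fs,
                                    n_per_class = config$n_per_class,
                                    n_perm = min(config$n_perm_benchmark, 100),
                                    seed = seed_of("baseline"))
    list(benchmark = b, baseline = base)
  })

  # -- archaeological-style assignment -------------------------------------
  assign_res <- if (all(modern_idx)) NULL else run_stage("assign", {
    mod <- features[modern_idx, ]
    unk <- features[!modern_idx, ]
    res <- lapply(names(fsets), function(fs)
      assign_unknowns(mod, mod$taxon, unk, fsets[[fs]],
                      n_per_class = config$n_per_class,
                      n_perm = config$n_perm_assign,
                      seed = seed_of(paste0("assign_", fs))))
    names(res) <- names(fsets)
    out <- do.call(rbind, lapply(names(res), function(fs)
      data.frame(feature_set = fs, res[[fs]]$assignments)))
    utils::write.csv(out, file.path(config$out_dir, "assignments.csv"),
                     row.names = FALSE)
    res
  })

  summary <- list(
    params = config[c("rng_seed", "k_points", "harmonic_threshold",
                      "max_harmonics", "n_per_class", "n_perm_benchmark",
                      "n_perm_assign", "separation", "px_per_mm")],
    n_specimens = nrow(records),
    n_modern = sum(modern_idx),
    n_unknown = sum(!modern_idx),
    h_star = efa$H_star,
    mean_cumulative_power = efa$mean_cumulative,
    gpa_converged = efa$alignment$converged,
    kruskal = lapply(stats_res$kruskal, function(k)
      list(chi2 = k$chi2, df = k$df, p = k$p)),
    permanova = unclass(stats_res$permanova)[c("F", "r2", "adj_r2", "p",
                                               "df_between", "n_perm")],
    pca_explained = stats_res$pca$explained[1:2],
    measurement_error = me_tab,
    benchmark = bench$benchmark$summary,
    baseline_max_accuracy = bench$baseline$overall_max,
    assignment_composition = if (!is.null(assign_res))
      lapply(assign_res, function(a) as.list(a$composition))
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
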