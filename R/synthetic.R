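#' Taxon models for synthetic seed populations
#'
#' A taxon model holds the generative parameters for one seed population:
#' mean elliptic Fourier coefficients (the ground-truth shape), a
#' coefficient covariance (scalar / vector = diagonal, or full matrix),
#' log-normal length and width distributions (mm), and a
#' negative-binomial surface cell count.
#'
#' @param name taxon label.
#' @param mean_coeffs numeric vector in [coeff_matrix()] layout (4 x H).
#' @param coeff_sd scalar or per-coefficient standard deviation, or a
#'   full covariance matrix (must be positive semi-definite).
#' @param length_logmean,length_logsd natural-log parameters of seed
#'   length (mm).
#' @param width_logmean,width_logsd same for seed width.
#' @param cell_mean expected cell count (> 0).
#' @param cell_dispersion negative-binomial size parameter; `Inf` gives
#'   the Poisson limit.
#' @param n_seeds seeds to draw for this taxon (>= 1).
#' @param accession accession label (the study design includes two taxa
#'   sampled from two collections each).
#' @return An object of class `taxon_model`.
#' @export
taxon_model <- function(name, mean_coeffs, coeff_sd = 0,
                        length_logmean, length_logsd,
                        width_logmean, width_logsd,
                        cell_mean, cell_dispersion = Inf,
                        n_seeds = 30, accession = "a") {
  if (length(mean_coeffs) %% 4 != 0) stop2("mean_coeffs length must be 4*H")
  if (is.matrix(coeff_sd)) {
    ev <- eigen(coeff_sd, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop2("coeff covariance must be positive semi-definite")
  } else if (any(coeff_sd < 0)) stop2("coeff_sd must be >= 0")
  if (length_logsd < 0 || width_logsd < 0) stop2("log-sd parameters must be >= 0")
  if (cell_mean <= 0) stop2("cell_mean must be > 0")
  if (cell_dispersion <= 0) stop2("cell_dispersion must be > 0")
  if (n_seeds < 1) stop2("n_seeds must be >= 1")
  structure(list(name = name, mean_coeffs = as.numeric(mean_coeffs),
                 coeff_sd = coeff_sd,
                 length_logmean = length_logmean, length_logsd = length_logsd,
                 width_logmean = width_logmean, width_logsd = width_logsd,
                 cell_mean = cell_mean, cell_dispersion = cell_dispersion,
                 n_seeds = as.integer(n_seeds), accession = accession),
            class = "taxon_model")
}

#' Acquisition noise specification
#'
#' Controls the three reproducibility perturbations emulated by the
#' generator: seed re-positioning (random rotation before the photo),
#' outline digitising/cleaning noise (per-point radial jitter), and
#' landmark placement noise. An identical `seed` yields bit-identical
#' output.
#'
#' @param rotation_sd radians of random in-plane rotation.
#' @param outline_jitter_sd per-point radial jitter, as a fraction of
#'   centroid size.
#' @param landmark_jitter_sd landmark placement noise, same units.
#' @param seed RNG seed (mandatory).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(rotation_sd = 0, outline_jitter_sd = 0,
                       landmark_jitter_sd = 0, seed) {
  if (missing(seed)) stop2("noise_spec requires an explicit RNG seed")
  if (rotation_sd < 0 || outline_jitter_sd < 0 || landmark_jitter_sd < 0)
    stop2("noise standard deviations must be >= 0")
  structure(list(rotation_sd = rotation_sd, outline_jitter_sd = outline_jitter_sd,
                 landmark_jitter_sd = landmark_jitter_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

# ---------------------------------------------------------------------------
# Default study design: seven Papaver-like taxa.
#
# Shape templates are written directly in coefficient space (H = 5, unit
# nominal length, length axis = y, counterclockwise). Aspect (width as a
# fraction of length) lives in a1 vs d1; egg/kidney components in
# harmonics 2-3; fine texture in 4-5. The three rounded taxa share a base
# template plus taxon-specific offsets scaled by `separation`, so their
# pairwise mean distances are exactly linear in it.
# ---------------------------------------------------------------------------

template_row <- function(aspect, extra = list()) {
  H <- 5
  row <- numeric(4 * H)
  names(row) <- c(paste0("a", 1:H), paste0("b", 1:H), paste0("c", 1:H), paste0("d", 1:H))
  row["a1"] <- aspect / 2
  row["d1"] <- 0.5
  for (nm in names(extra)) row[nm] <- row[nm] + extra[[nm]]
  row
}

#' The seven-taxon synthetic reference design
#'
#' Returns the seven taxon models emulated throughout: two elongated taxa
#' (argemone, hybridum), two reniform taxa (rhoeas, dubium) and three
#' rounded, strongly overlapping taxa (setigerum, somniferum, nigrum --
#' the somniferum-group analogue). Cell counts are ordered with setigerum
#' lowest and argemone highest; the two domesticated analogues
#' (somniferum, nigrum) are the largest-seeded.
#'
#' @param separation non-negative scale factor on the mean-shape offsets
#'   within the rounded triple; 0 makes their mean shapes identical, and
#'   pairwise mean-coefficient distances scale exactly linearly.
#' @param n_seeds seeds per taxon (the reference design uses 30).
#' @return Named list of 7 [taxon_model()] objects.
#' @export
default_taxon_models <- function(separation = 1, n_seeds = 30) {
  if (separation < 0) stop2("separation must be >= 0")
  sd5 <- rep(c(0.012, 0.008, 0.006, 0.004, 0.003), 4)  # per-harmonic sd, a..d blocks
  round_base <- template_row(0.82, list(a2 = -0.160, c2 = 0.200, b2 = 0.075,
                                        d2 = 0.065, b3 = 0.065, d3 = -0.056,
                                        a4 = 0.025, c5 = 0.015))
  # offsets defining the rounded triple (norms comparable, directions distinct)
  off_set <- c(a1 = -0.0375, c2 = -0.0275, d2 = 0.012)
  off_som <- c(a1 = 0.0375, d1 = 0.0225, b3 = 0.0125)
  off_nig <- c(a1 = 0.015, c2 = -0.020, b3 = -0.018, d3 = 0.016)
  apply_off <- function(base, off) { base[names(off)] <- base[names(off)] + separation * off; base }

  models <- list(
    setigerum = taxon_model("setigerum", apply_off(round_base, off_set), sd5,
                            length_logmean = log(0.95), length_logsd = 0.075,
                            width_logmean = log(0.74), width_logsd = 0.075,
                            cell_mean = 28, cell_dispersion = 50, n_seeds = n_seeds),
    somniferum = taxon_model("somniferum", apply_off(round_base, off_som), sd5,
                             length_logmean = log(1.25), length_logsd = 0.08,
                             width_logmean = log(1.05), width_logsd = 0.08,
                             cell_mean = 36, cell_dispersion = 50, n_seeds = n_seeds),
    nigrum = taxon_model("nigrum", apply_off(round_base, off_nig), sd5,
                         length_logmean = log(1.18), length_logsd = 0.07,
                         width_logmean = log(0.97), width_logsd = 0.07,
                         cell_mean = 44, cell_dispersion = 50, n_seeds = n_seeds),
    rhoeas = taxon_model("rhoeas",
                         template_row(0.80, list(a2 = -0.220, c2 = 0.125, b2 = 0.0625,
                                                 d2 = 0.050, a3 = 0.075, d4 = 0.025)),
                         sd5,
                         length_logmean = log(0.72), length_logsd = 0.07,
                         width_logmean = log(0.55), width_logsd = 0.07,
                         cell_mean = 52, cell_dispersion = 50, n_seeds = n_seeds),
    dubium = taxon_model("dubium",
                         template_row(0.78, list(a2 = -0.200, c2 = 0.150, b2 = -0.050,
                                                 d2 = -0.045, c3 = 0.0625, a4 = -0.025)),
                         sd5,
                         length_logmean = log(0.76), length_logsd = 0.07,
                         width_logmean = log(0.57), width_logsd = 0.07,
                         cell_mean = 58, cell_dispersion = 50, n_seeds = n_seeds),
    hybridum = taxon_model("hybridum",
                           template_row(0.70, list(c2 = 0.175, a2 = -0.080, d2 = 0.050,
                                                   b3 = -0.040, d5 = 0.018)),
                           sd5,
                           length_logmean = log(0.66), length_logsd = 0.065,
                           width_logmean = log(0.47), width_logsd = 0.065,
                           cell_mean = 66, cell_dispersion = 50, n_seeds = n_seeds),
    argemone = taxon_model("argemone",
                           template_row(0.66, list(c2 = 0.210, a2 = -0.0625, b2 = 0.055,
                                                   a3 = 0.056, c4 = 0.025)),
                           sd5,
                           length_logmean = log(0.62), length_logsd = 0.065,
                           width_logmean = log(0.43), width_logsd = 0.065,
                           cell_mean = 82, cell_dispersion = 50, n_seeds = n_seeds)
  )
  models
}

#' Second-collection variant of a taxon model
#'
#' Emulates an additional accession of the same taxon from another seed
#' collection: a small shift in log-size and a slight shape offset, with
#' the same taxon label.
#'
#' @param model a [taxon_model()].
#' @param size_shift additive shift on both log-means.
#' @param shape_shift additive shift applied to coefficient a1.
#' @export
accession_variant <- function(model, size_shift = 0.04, shape_shift = 0.006) {
  m <- model
  m$length_logmean <- m$length_logmean + size_shift
  m$width_logmean <- m$width_logmean + size_shift
  m$mean_coeffs[1] <- m$mean_coeffs[1] + shape_shift
  m$accession <- "b"
  m
}

# Draw one coefficient row from a taxon model.
draw_coeffs <- function(model) {
  mu <- model$mean_coeffs
  if (is.matrix(model$coeff_sd)) {
    ev <- eigen(model$coeff_sd, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(mu))
    as.numeric(mu + L %*% stats::rnorm(length(mu)))
  } else {
    mu + stats::rnorm(length(mu), 0, model$coeff_sd)
  }
}

draw_cells <- function(model) {
  if (is.finite(model$cell_dispersion)) {
    stats::rnbinom(1, mu = model$cell_mean, size = model$cell_dispersion)
  } else {
    stats::rpois(1, model$cell_mean)
  }
}

# Circular moving average with a boxcar kernel of half-width `width`.
smooth_circular <- function(v, width) {
  n <- length(v)
  k <- 2L * as.integer(width) + 1L
  idx <- outer(seq_len(n), -width:width, function(i, o) ((i + o - 1L) %% n) + 1L)
  rowMeans(matrix(v[idx], n, k))
}

# Auto-place the five landmarks on an acquired outline (mm frame):
# 4 = top extreme, 5 = bottom extreme, 1-3 at fixed fractions (0.45,
# 0.50, 0.55) of the perimeter from the top point, counterclockwise.
auto_landmarks <- function(out, jitter_sd = 0, image_id = NA_character_) {
  p <- unclass(out)
  i_top <- which.max(p[, 2]); i_bot <- which.min(p[, 2])
  ap <- arc_positions(p)
  s_top <- ap$at[i_top]
  fr <- c(0.45, 0.50, 0.55)
  targ <- (s_top + fr * ap$total) %% ap$total
  xs <- c(p[, 1], p[1, 1]); ys <- c(p[, 2], p[1, 2]); at <- c(ap$at, ap$total)
  arc_pts <- cbind(stats::approx(at, xs, xout = targ, ties = "ordered")$y,
                   stats::approx(at, ys, xout = targ, ties = "ordered")$y)
  coords <- rbind(arc_pts, p[i_top, ], p[i_bot, ])
  if (jitter_sd > 0) {
    ctr <- colMeans(p)
    r_rms <- sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
    coords <- coords + matrix(stats::rnorm(10, 0, jitter_sd * r_rms), 5, 2)
  }
  landmark_set(coords, image_id = image_id)
}

# Rasterize a closed outline (pixel coordinates, y-up, 0-based pixel
# centers) into a logical mask of dimension nr x nc via even-odd scanline
# fill.
rasterize_outline <- function(p, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  for (row in seq_len(nr)) {
    yc <- nr - row  # y-up coordinate of this pixel row's centers
    crosses <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(crosses)) next
    t <- (yc - y1[crosses]) / (y2[crosses] - y1[crosses])
    xc <- sort(x1[crosses] + t * (x2[crosses] - x1[crosses]))
    for (s in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[s]); hi <- floor(xc[s + 1])
      if (hi >= lo) mask[row, (max(lo, 0):min(hi, nc - 1)) + 1L] <- TRUE
    }
  }
  mask
}

# One acquisition of a seed with known true shape/size: rotate, jitter,
# place landmarks, optionally render to a mask. Returns the acquired
# outline (mm), landmarks, and the rendered mask (pixel frame shared with
# the landmarks).
acquire_seed <- function(truth_row, length_mm, width_mm, noise, px_per_mm,
                         k_gen = 720, render = TRUE, id = NA_character_) {
  shp <- inverse_efourier(row_to_eft(truth_row), k = k_gen)
  p <- unclass(shp)
  p <- sweep(p, 2, colMeans(p))
  theta <- if (noise$rotation_sd > 0) stats::rnorm(1, 0, noise$rotation_sd) else 0
  if (theta != 0) p <- p %*% t(rot_mat(theta))
  if (noise$outline_jitter_sd > 0) {
    r <- sqrt(rowSums(p^2)); r[r == 0] <- 1
    # spatially correlated radial noise (digitising error is smooth along
    # the boundary); scale: RMS centroid radius, so the sd is
    # point-count free
    eps <- smooth_circular(stats::rnorm(nrow(p)), width = max(3, nrow(p) %/% 72))
    eps <- eps / stats::sd(eps) * noise$outline_jitter_sd * sqrt(mean(r^2))
    p <- p * (1 + eps / r)
  }
  out <- outline(p)
  lmk <- auto_landmarks(out, noise$landmark_jitter_sd, image_id = id)
  mask <- NULL
  if (render) {
    mm_per_px <- 1 / px_per_mm
    xr <- range(p[, 1]); yr <- range(p[, 2])
    if (diff(xr) * px_per_mm < 10 || diff(yr) * px_per_mm < 10)
      stop2("rendering resolution too small: seed spans fewer than 10 px; ",
            "increase px_per_mm")
    margin <- 0.15 * max(diff(xr), diff(yr))
    x0 <- xr[1] - margin; y0 <- yr[1] - margin
    nc <- ceiling((diff(xr) + 2 * margin) * px_per_mm) + 1L
    nr <- ceiling((diff(yr) + 2 * margin) * px_per_mm) + 1L
    ppx <- cbind((p[, 1] - x0) * px_per_mm, (p[, 2] - y0) * px_per_mm)
    mask <- rasterize_outline(ppx, nr, nc)
    lpx <- cbind((unclass(lmk)[, 1] - x0) * px_per_mm,
                 (unclass(lmk)[, 2] - y0) * px_per_mm)
    lmk <- landmark_set(lpx, image_id = id)
  }
  list(outline = out, landmarks = lmk, mask = mask, theta = theta)
}

#' Simulate a seed population
#'
#' Draws one seed record per seed of every taxon model: shape
#' coefficients from the taxon distribution, length and width log-normal,
#' cell counts negative-binomial. Each seed's outline is reconstructed
#' from its coefficients, scaled anisotropically to the drawn length and
#' width (an exact operation on the coefficients, so ground truth is
#' preserved), perturbed per the [noise_spec()], rendered to a binary
#' mask, and landmarked automatically. Output is fully reproducible from
#' `noise$seed`.
#'
#' @param models list of [taxon_model()] objects.
#' @param noise a [noise_spec()].
#' @param px_per_mm rendering resolution (default 100, so a 1 mm seed
#'   spans about 100 px).
#' @param render if `FALSE`, skip rasterization (fast in-memory path; the
#'   acquired outlines are still produced).
#' @param out_dir if non-`NULL`, write masks as PNG under
#'   `out_dir/masks/`, landmarks as `landmarks.csv`, records as
#'   `records.csv`.
#' @param taxon_label optional label overriding every record's taxon
#'   (used to mark unknowns).
#' @return Object of class `seed_population`: list with `records` (data
#'   frame: id, taxon, accession, length, width, cells), `truth` (matrix
#'   of true coefficient rows, post size-scaling), `outlines` (acquired
#'   outlines, mm), `landmarks`, `masks`, `px_per_mm`.
#' @export
simulate_population <- function(models, noise, px_per_mm = 100, render = TRUE,
                                out_dir = NULL, taxon_label = NULL) {
  if (inherits(models, "taxon_model")) models <- list(models)
  with_seed(noise$seed, {
    recs <- list(); truths <- list(); outs <- list(); lmks <- list(); masks <- list()
    for (m in models) {
      for (s in seq_len(m$n_seeds)) {
        id <- sprintf("%s_%s_%03d", m$name, m$accession, s)
        row <- draw_coeffs(m)
        L <- stats::rlnorm(1, m$length_logmean, m$length_logsd)
        W <- stats::rlnorm(1, m$width_logmean, m$width_logsd)
        row <- scale_row_to_size(row, L, W)
        acq <- acquire_seed(row, L, W, noise, px_per_mm, render = render, id = id)
        recs[[id]] <- data.frame(id = id,
                                 taxon = taxon_label %||% m$name,
                                 accession = m$accession,
                                 length = L, width = W,
                                 cells = draw_cells(m),
                                 true_taxon = m$name)
        truths[[id]] <- row
        outs[[id]] <- acq$outline
        lmks[[id]] <- acq$landmarks
        masks[[id]] <- acq$mask
      }
    }
    pop <- structure(list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
                          truth = do.call(rbind, truths),
                          outlines = outs, landmarks = lmks,
                          masks = if (render) masks else NULL,
                          px_per_mm = px_per_mm),
                     class = "seed_population")
    if (!is.null(out_dir)) write_population(pop, out_dir)
    pop
  })
}

# Anisotropic scaling in coefficient space: x-coefficients (a, b) scale
# with width, y-coefficients (c, d) with length.
scale_row_to_size <- function(row, length_mm, width_mm) {
  H <- length(row) / 4
  shp <- inverse_efourier(row_to_eft(row), k = 360)
  ext <- bounding_box_size(shp)
  sx <- width_mm / ext["width_mm"]; sy <- length_mm / ext["length_mm"]
  row[1:(2 * H)] <- row[1:(2 * H)] * sx
  row[(2 * H + 1):(4 * H)] <- row[(2 * H + 1):(4 * H)] * sy
  row
}

#' @export
print.seed_population <- function(x, ...) {
  cat(sprintf("<seed_population> %d seeds, %d taxa%s\n",
              nrow(x$records), length(unique(x$records$taxon)),
              if (is.null(x$masks)) " (not rendered)" else ""))
  invisible(x)
}

#' Write a population to disk
#'
#' Masks as `masks/<id>.png` (foreground > 0), landmarks as
#' `landmarks.csv` (`image,ldk,x,y`, pixel y-up frame), records as
#' `records.csv` (`id,taxon,length,width,cells`, plus accession and
#' true_taxon provenance columns).
#' @param pop a `seed_population`.
#' @param out_dir output directory (created).
#' @export
write_population <- function(pop, out_dir) {
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (is.null(pop$masks)) stop2("population was simulated with render = FALSE")
  for (id in names(pop$masks)) {
    write_mask(pop$masks[[id]], file.path(out_dir, "masks", paste0(id, ".png")))
  }
  write_landmarks(pop$landmarks, file.path(out_dir, "landmarks.csv"))
  write_descriptors(pop$records, file.path(out_dir, "records.csv"))
  invisible(out_dir)
}

#' Repeated acquisitions of the same seeds
#'
#' Re-acquires each selected individual `n_repeats` times under the given
#' noise: the true outline is re-rotated and re-jittered, re-rendered and
#' re-landmarked, preserving the individual id. This emulates the
#' position / cleaning / landmarking reproducibility designs (which of
#' the three is emulated depends on which noise sd is non-zero).
#'
#' @param pop a `seed_population` (source of ground truth).
#' @param n_repeats acquisitions per individual (>= 2).
#' @param noise a [noise_spec()] for the repeat acquisitions.
#' @param ids individuals to re-acquire (default: all).
#' @param render rasterize each repeat (default `TRUE`).
#' @return A `seed_population` whose records carry an `individual`
#'   column; ids are `<individual>_r<j>`.
#' @export
simulate_repeats <- function(pop, n_repeats, noise, ids = NULL, render = TRUE) {
  if (n_repeats < 2) stop2("n_repeats must be >= 2")
  ids <- ids %||% pop$records$id
  with_seed(noise$seed, {
    recs <- list(); truths <- list(); outs <- list(); lmks <- list(); masks <- list()
    for (ind in ids) {
      rec <- pop$records[pop$records$id == ind, ]
      if (!nrow(rec)) stop2("unknown individual id: ", ind)
      row <- pop$truth[ind, ]
      for (j in seq_len(n_repeats)) {
        rid <- sprintf("%s_r%d", ind, j)
        acq <- acquire_seed(row, rec$length, rec$width, noise, pop$px_per_mm,
                            render = render, id = rid)
        recs[[rid]] <- data.frame(id = rid, individual = ind,
                                  taxon = rec$taxon, accession = rec$accession,
                                  length = rec$length, width = rec$width,
                                  cells = rec$cells, true_taxon = rec$true_taxon)
        truths[[rid]] <- row
        outs[[rid]] <- acq$outline
        lmks[[rid]] <- acq$landmarks
        masks[[rid]] <- acq$mask
      }
    }
    structure(list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
                   truth = do.call(rbind, truths),
                   outlines = outs, landmarks = lmks,
                   masks = if (render) masks else NULL,
                   px_per_mm = pop$px_per_mm),
              class = "seed_population")
  })
}
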