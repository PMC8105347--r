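# Shared fixture builders (all generated in code; no stored data).

circle_outline <- function(r = 1, k = 360, center = c(0, 0)) {
  th <- 2 * pi * (0:(k - 1)) / k
  outline(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# A well-behaved 5-harmonic coefficient row (near-circular, all entries
# bounded away from zero so relative comparisons are meaningful).
smooth_row5 <- function() {
  c(a = c(0.45, -0.030, 0.016, -0.012, 0.008),
    b = c(0.020, 0.024, -0.014, 0.010, -0.006),
    c = c(-0.015, 0.035, 0.018, -0.010, 0.007),
    d = c(0.50, 0.022, -0.016, 0.009, -0.005))
}

# Random simple closed shape with its 5 landmarks, for GPA tests.
random_shape_with_landmarks <- function(k = 180) {
  row <- c(0.4 + runif(1, -0.05, 0.05), runif(4, -0.02, 0.02),
           runif(5, -0.02, 0.02),
           runif(5, -0.02, 0.02),
           0.5 + runif(1, -0.05, 0.05), runif(4, -0.02, 0.02))
  out <- inverse_efourier(row_to_eft(row), k = k)
  lmk <- seedmorph:::auto_landmarks(out)
  list(outline = out, landmarks = lmk)
}

apply_pose <- function(out, lmk, translate, scale, theta) {
  R <- seedmorph:::rot_mat(theta)
  o2 <- seedmorph:::transform_outline(out, translate, scale, R)
  l2 <- landmark_set(sweep(unclass(lmk) %*% t(R) * scale, 2, -translate),
                     image_id = attr(lmk, "image_id"))
  list(outline = o2, landmarks = l2)
}

# One-taxon model with controllable variation, for generator tests.
fixed_taxon <- function(name = "t1", n_seeds = 5, coeff_sd = 0,
                        length_logsd = 0, width_logsd = 0,
                        cell_dispersion = Inf) {
  taxon_model(name, smooth_row5(), coeff_sd = coeff_sd,
              length_logmean = log(1), length_logsd = length_logsd,
              width_logmean = log(0.8), width_logsd = width_logsd,
              cell_mean = 40, cell_dispersion = cell_dispersion,
              n_seeds = n_seeds)
}

resample_from_ldk2 <- function(pop, k = 360) {
  mapply(function(o, l) resample_outline(o, k, start = unclass(l)[2, ],
                                         check = FALSE),
         pop$outlines, pop$landmarks[names(pop$outlines)], SIMPLIFY = FALSE)
}
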