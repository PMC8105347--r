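#' Elliptic Fourier transform of a closed outline
#'
#' Decomposes the outline coordinates x(t), y(t) into `H` harmonics, each
#' carrying a coefficient quadruple (a_n, b_n, c_n, d_n), plus the center
#' terms (a0, c0). The integrals use the piecewise-linear (chain-sum)
#' formulation with the curve parameter taken as vertex index scaled to
#' the measured perimeter; on input that is equally spaced along the
#' curvilinear abscissa -- which [resample_outline()] guarantees and the
#' protocol always applies first -- this is the classical curvilinear
#' parameterization, and reconstructions from known coefficients
#' round-trip to the generating values. Grossly unequal spacing on an
#' outline that has not been through [resample_outline()] triggers a
#' warning.
#'
#' @param x an [outline()], counterclockwise (enforced).
#' @param H number of harmonics; must satisfy `H <= nrow(x) / 2`.
#' @return Object of class `eft`: list with vectors `a`, `b`, `c`, `d`
#'   (length `H`), scalars `a0`, `c0`, `H`, and `perimeter`.
#' @export
efourier <- function(x, H) {
  x <- ensure_ccw(x)
  p <- unclass(x)
  k <- nrow(p)
  if (H < 1) stop2("H must be >= 1")
  if (H > k / 2) stop2("H = ", H, " exceeds points/2 = ", k / 2)
  ap <- arc_positions(p)
  rng <- range(ap$chords)
  if (rng[1] <= 0) stop2("outline has zero-length chords")
  if (!isTRUE(attr(x, "equal_arc")) && rng[2] / rng[1] > 2)
    warning("outline points look unequally spaced along the curve; ",
            "apply resample_outline() first for curvilinear-abscissa ",
            "coefficients", call. = FALSE)
  T <- ap$total
  nxt <- c(2:k, 1)
  Dx <- p[nxt, 1] - p[, 1]
  Dy <- p[nxt, 2] - p[, 2]
  j <- seq_len(k)
  a <- b <- cc <- d <- numeric(H)
  for (n in seq_len(H)) {
    co <- cos(2 * pi * n * j / k) - cos(2 * pi * n * (j - 1) / k)
    si <- sin(2 * pi * n * j / k) - sin(2 * pi * n * (j - 1) / k)
    f <- k / (2 * pi^2 * n^2)
    a[n] <- f * sum(Dx * co)
    b[n] <- f * sum(Dx * si)
    cc[n] <- f * sum(Dy * co)
    d[n] <- f * sum(Dy * si)
  }
  structure(list(a = a, b = b, c = cc, d = d,
                 a0 = mean(p[, 1]), c0 = mean(p[, 2]),
                 H = H, perimeter = T),
            class = "eft")
}

#' @export
print.eft <- function(x, ...) {
  cat(sprintf("<eft> %d harmonics, center (%.3g, %.3g), perimeter %.4g\n",
              x$H, x$a0, x$c0, x$perimeter))
  invisible(x)
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `k` equally spaced parameter
#' values; the first point corresponds to parameter 0 (the outline start).
#'
#' @param coeffs an `eft` object (or list with a, b, c, d, a0, c0).
#' @param k number of points to generate.
#' @param H_use harmonics to use (default all; must be `<= coeffs$H`).
#' @return An [outline()].
#' @export
inverse_efourier <- function(coeffs, k = 360, H_use = coeffs$H) {
  if (H_use > length(coeffs$a)) stop2("H_use exceeds the number of stored harmonics")
  t <- 2 * pi * (0:(k - 1)) / k
  xs <- rep((coeffs$a0 %||% 0), k)
  ys <- rep((coeffs$c0 %||% 0), k)
  for (n in seq_len(H_use)) {
    xs <- xs + coeffs$a[n] * cos(n * t) + coeffs$b[n] * sin(n * t)
    ys <- ys + coeffs$c[n] * cos(n * t) + coeffs$d[n] * sin(n * t)
  }
  outline(cbind(xs, ys))
}

#' Harmonic power and the retention rule
#'
#' The power of harmonic n is (a_n^2 + b_n^2 + c_n^2 + d_n^2)/2.
#' Cumulative fractions include every computed harmonic (harmonic 1 is in
#' the denominator). `choose_harmonics` applies the retention rule on a
#' population: the retained count H* is the smallest H whose mean
#' cumulative power fraction reaches `threshold`.
#'
#' @param coeffs an `eft` object.
#' @return `harmonic_power`: data frame with `harmonic`, `power`,
#'   `cumulative` (fraction of total).
#' @export
harmonic_power <- function(coeffs) {
  pw <- (coeffs$a^2 + coeffs$b^2 + coeffs$c^2 + coeffs$d^2) / 2
  tot <- sum(pw)
  if (tot <= 0) stop2("all coefficients are zero; harmonic power undefined")
  data.frame(harmonic = seq_along(pw), power = pw, cumulative = cumsum(pw) / tot)
}

#' @rdname harmonic_power
#' @param coeff_list list of `eft` objects (the population).
#' @param threshold power fraction in (0, 1]; the protocol value is 0.95.
#' @return `choose_harmonics`: list with `H_star` and the matrix of mean
#'   cumulative fractions.
#' @export
choose_harmonics <- function(coeff_list, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop2("threshold must be in (0, 1]")
  cums <- vapply(coeff_list, function(cf) harmonic_power(cf)$cumulative,
                 numeric(coeff_list[[1]]$H))
  mean_cum <- if (is.matrix(cums)) rowMeans(cums) else mean(cums)
  H_star <- which(mean_cum >= threshold - 1e-12)[1]
  if (is.na(H_star)) H_star <- length(mean_cum)
  list(H_star = as.integer(H_star), mean_cumulative = mean_cum)
}

#' Coefficient table layout
#'
#' Flattens a list of `eft` objects into the analysis matrix with columns
#' `a1..aH, b1..bH, c1..cH, d1..dH` (column-major by letter), and back.
#'
#' @param coeff_list named list of `eft` objects.
#' @param H harmonics to keep (truncation allowed).
#' @return `coeff_matrix`: numeric matrix, one row per specimen.
#' @export
coeff_matrix <- function(coeff_list, H = coeff_list[[1]]$H) {
  rows <- t(vapply(coeff_list, function(cf) {
    if (H > cf$H) stop2("requested H exceeds stored harmonics")
    c(cf$a[1:H], cf$b[1:H], cf$c[1:H], cf$d[1:H])
  }, numeric(4 * H)))
  colnames(rows) <- c(paste0("a", 1:H), paste0("b", 1:H),
                      paste0("c", 1:H), paste0("d", 1:H))
  rows
}

#' @rdname coeff_matrix
#' @param row numeric vector in the `coeff_matrix` column layout.
#' @return `row_to_eft`: an `eft` object (center terms zero).
#' @export
row_to_eft <- function(row) {
  H <- length(row) / 4
  if (H != floor(H)) stop2("coefficient row length must be a multiple of 4")
  structure(list(a = unname(row[1:H]), b = unname(row[H + 1:H]),
                 c = unname(row[2 * H + 1:H]), d = unname(row[3 * H + 1:H]),
                 a0 = 0, c0 = 0, H = as.integer(H), perimeter = NA_real_),
            class = "eft")
}

#' Write coefficients as CSV (`id, a1..aH, ..., d1..dH`)
#' @param mat matrix from [coeff_matrix()] with specimen rownames.
#' @param path output CSV.
#' @export
write_coefficients <- function(mat, path) {
  utils::write.csv(data.frame(id = rownames(mat), mat, check.names = FALSE),
                   path, row.names = FALSE)
}
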