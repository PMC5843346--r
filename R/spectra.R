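# FTIR amide-I analysis: spectrum I/O, linear baseline + unit-area
# normalization over 1600-1700 cm^-1, Fourier self-deconvolution,
# Savitzky-Golay second derivative, band picking, constrained Gaussian band
# fitting and secondary-structure class totals.

GAUSS_AREA_FACTOR <- sqrt(pi / (4 * log(2)))  # area = amp * fwhm * this

new_spectrum <- function(wavenumber, absorbance, metadata = list()) {
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 metadata = metadata),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("ir_spectrum: %d points, %.1f..%.1f cm^-1, step %.4g cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              spectrum_step(x)))
  invisible(x)
}

spectrum_step <- function(spectrum) {
  d <- diff(spectrum$wavenumber)
  mean(d)
}

check_amide_resolution <- function(spectrum) {
  n_amide <- sum(spectrum$wavenumber >= 1600 & spectrum$wavenumber <= 1700)
  if (n_amide < 64)
    stop("insufficient resolution: ", n_amide,
         " points across 1600-1700 cm^-1 (need >= 64)")
  invisible(TRUE)
}

#' Read a two-column wavenumber/absorbance spectrum
#'
#' Comma-, tab- or whitespace-delimited ASCII; '#' lines are skipped. The
#' grid is returned ascending in wavenumber; non-uniform grids are resampled
#' to a uniform grid by linear interpolation with a warning. At least 64
#' points must span 1600-1700 cm^-1.
#'
#' @param path file path.
#' @param label sample label stored in the metadata.
#' @return object of class `ir_spectrum`.
#' @export
read_spectrum <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\t ]+")
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad) > 0) stop("cannot parse spectrum line ", bad[1])
  nu <- as.numeric(vapply(parts, `[`, character(1), 1))
  ab <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (any(is.na(nu)) || any(is.na(ab))) stop("non-numeric spectrum values")
  o <- order(nu)
  nu <- nu[o]; ab <- ab[o]
  d <- diff(nu)
  if (any(d <= 0)) stop("wavenumber grid not strictly monotone")
  if (diff(range(d)) > 1e-6) {
    warning("non-uniform wavenumber grid; resampling by linear interpolation")
    grid <- seq(min(nu), max(nu), length.out = length(nu))
    ab <- stats::approx(nu, ab, xout = grid)$y
    nu <- grid
  }
  sp <- new_spectrum(nu, ab, metadata = list(label = label))
  check_amide_resolution(sp)
  sp
}

#' Linear baseline subtraction and unit-area normalization
#'
#' Subtracts the straight line anchored at `(lo, A(lo))` and `(hi, A(hi))`
#' from the whole grid and scales the trapezoidal area over `[lo, hi]` to
#' exactly 1; the amide-I pre-processing convention. The grid is kept
#' uncropped so that later Fourier steps see naturally decaying band tails
#' rather than cut edges.
#'
#' @param spectrum an `ir_spectrum`.
#' @param lo,hi baseline anchors and normalization window, cm^-1.
#' @return normalized `ir_spectrum`.
#' @export
baseline_normalize <- function(spectrum, lo = 1600, hi = 1700) {
  nu <- spectrum$wavenumber
  if (lo < min(nu) || hi > max(nu)) stop("window outside the spectral grid")
  a_lo <- stats::approx(nu, spectrum$absorbance, xout = lo)$y
  a_hi <- stats::approx(nu, spectrum$absorbance, xout = hi)$y
  base <- a_lo + (nu - lo) * (a_hi - a_lo) / (hi - lo)
  ab <- spectrum$absorbance - base
  win <- nu >= lo & nu <= hi
  nw <- nu[win]; aw <- ab[win]
  area <- sum(diff(nw) * (aw[-1] + aw[-length(aw)]) / 2)
  if (area <= 1e-12)
    stop("degenerate spectrum: non-positive area after baseline subtraction")
  new_spectrum(nu, ab / area,
               metadata = c(spectrum$metadata, list(normalized = TRUE)))
}

#' Fourier self-deconvolution parameters
#'
#' @param bandwidth assumed Lorentzian full width, cm^-1.
#' @param k resolution-enhancement (narrowing) factor, >= 1.
#' @param apodization apodization window; only the Bessel-type
#'   `(1-(x/X)^2)^2` window is implemented.
#' @return list of class `fsd_params`.
#' @export
fsd_params <- function(bandwidth = 18, k = 2, apodization = "bessel") {
  apodization <- match.arg(apodization, "bessel")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (k < 1) stop("k must be >= 1")
  structure(list(bandwidth = bandwidth, k = k, apodization = apodization),
            class = "fsd_params")
}

# FWHM (in its conjugate variable) of the Fourier transform of the
# unit-support Bessel window (1 - u^2)^2: the instrument line shape that an
# apodized, fully deconvolved band collapses to. Computed numerically once.
bessel_ils_fwhm <- local({
  val <- NULL
  function() {
    if (!is.null(val)) return(val)
    u <- seq(-1, 1, length.out = 4001)
    B <- function(nu) sum((1 - u^2)^2 * cos(2 * pi * nu * u)) * (u[2] - u[1])
    b0 <- B(0)
    f <- function(nu) B(nu) - b0 / 2
    lo <- 0; hi <- 1
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    val <<- 2 * (lo + hi) / 2
    val
  }
})

#' Fourier self-deconvolution of an amide-I spectrum
#'
#' Kauppinen self-deconvolution on a uniform grid: the Fourier transform of
#' the spectrum is multiplied by the inverse of the assumed Lorentzian
#' interferogram decay, `exp(+pi * bandwidth * |x|)`, and by a Bessel-type
#' apodization window `(1-(x/X)^2)^2` whose cutoff `X` is set so that a
#' Lorentzian of FWHM `bandwidth` collapses to the window's line shape with
#' FWHM `bandwidth / k`. The zero-frequency component is untouched, so the
#' integrated area is conserved. `k = 1` requests no enhancement and
#' returns the input unchanged.
#'
#' @param spectrum an `ir_spectrum` (uniform grid).
#' @param params an `fsd_params`.
#' @return deconvolved `ir_spectrum`.
#' @export
fsd <- function(spectrum, params = fsd_params()) {
  check_amide_resolution(spectrum)
  nu <- spectrum$wavenumber
  d <- diff(nu)
  if (diff(range(d)) > 1e-6) stop("FSD requires a uniform grid")
  if (params$k == 1) return(spectrum)
  dnu <- mean(d)
  A <- spectrum$absorbance
  N <- length(A)
  j <- seq_len(N) - 1
  x <- pmin(j, N - j) / (N * dnu)  # interferogram-domain coordinate, cm
  X <- bessel_ils_fwhm() * params$k / params$bandwidth  # window cutoff, cm
  if (X > 1 / (2 * dnu))
    stop("over-deconvolution: k = ", params$k,
         " puts the apodization cutoff beyond the Nyquist point of the grid")
  filt <- exp(pi * params$bandwidth * x)
  filt <- filt * ifelse(x <= X, (1 - (x / X)^2)^2, 0)
  out <- Re(stats::fft(stats::fft(A) * filt, inverse = TRUE)) / N
  new_spectrum(nu, out, metadata = c(spectrum$metadata,
                                     list(fsd = unclass(params))))
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Polynomial order 3; band centers appear as minima of the derivative.
#'
#' @param spectrum an `ir_spectrum` (uniform grid).
#' @param window_points odd filter length >= 5.
#' @return `ir_spectrum` holding the second derivative.
#' @export
second_derivative <- function(spectrum, window_points = 7) {
  if (window_points %% 2 != 1 || window_points < 5)
    stop("window_points must be odd and >= 5")
  if (window_points > length(spectrum$absorbance))
    stop("window exceeds the series length")
  d2 <- signal::sgolayfilt(spectrum$absorbance, p = 3, n = window_points,
                           m = 2, ts = spectrum_step(spectrum))
  new_spectrum(spectrum$wavenumber, d2,
               metadata = c(spectrum$metadata, list(derivative = 2)))
}

local_minima <- function(y) {
  n <- length(y)
  which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1
}

#' Identify candidate amide-I component bands
#'
#' Candidate centers are second-derivative minima of the (normalized)
#' spectrum that coincide (within `match_tol` cm^-1) with a peak registered
#' by the self-deconvolved trace, within 1600-1700 cm^-1. Peaks of the FSD
#' trace are detected through its own second derivative, which registers
#' shoulders of closely spaced components as well as outright maxima while
#' rejecting deconvolution ringing (ringing sidelobes appear in only one of
#' the two traces). Minima shallower than `min_prominence` times the
#' deepest minimum are discarded.
#'
#' @param fsd_spectrum deconvolved `ir_spectrum`.
#' @param deriv_spectrum second-derivative `ir_spectrum` (same grid),
#'   normally of the normalized undeconvolved spectrum.
#' @param min_prominence relative depth threshold in (0, 1].
#' @param match_tol coincidence tolerance, cm^-1.
#' @param init_fwhm initial width given to each candidate, cm^-1.
#' @param deriv_window Savitzky-Golay window used on the FSD trace.
#' @param amp_floor candidates must carry at least this fraction of the
#'   window's peak absorbance in the undeconvolved spectrum — a component
#'   band absorbs, derivative noise and ringing sidelobes do not.
#' @param spectrum the normalized undeconvolved spectrum used for the
#'   amplitude floor; when NULL the floor is applied on the magnitude of
#'   the FSD trace instead.
#' @return data.frame of class `band_set`: `center`, `fwhm`, `area_frac`
#'   (equal initial split, percent).
#' @export
pick_bands <- function(fsd_spectrum, deriv_spectrum, min_prominence = 0.05,
                       match_tol = 2, init_fwhm = 14, deriv_window = 5,
                       amp_floor = 0.05, spectrum = NULL) {
  if (!isTRUE(all.equal(fsd_spectrum$wavenumber, deriv_spectrum$wavenumber)))
    stop("spectra are not on the same grid")
  nu <- deriv_spectrum$wavenumber
  d2 <- deriv_spectrum$absorbance
  in_amide <- nu >= 1600 & nu <= 1700
  prominent_minima <- function(y) {
    m <- local_minima(y)
    m <- m[in_amide[m] & y[m] < 0]
    if (length(m) > 0) m <- m[-y[m] >= min_prominence * max(-y[m])]
    m
  }
  cand1 <- prominent_minima(d2)
  d2f <- second_derivative(fsd_spectrum, deriv_window)$absorbance
  # FSD-trace curvature registers shoulders; the measured spectrum must be
  # concave there (vetoes ringing sidelobes, which live only in one trace)
  cand2 <- prominent_minima(d2f)
  cand2 <- cand2[d2[cand2] < 0]
  cand <- union(cand1, cand2)
  # a real component carries absorbance at its center
  amp <- if (is.null(spectrum)) abs(fsd_spectrum$absorbance) else
    abs(spectrum$absorbance)
  cand <- cand[amp[cand] >= amp_floor * max(amp[in_amide])]
  centers <- sort(nu[cand])
  if (length(centers) == 0)
    stop("no bands: no derivative minima confirmed across the two traces")
  # merge candidates closer than the coincidence tolerance
  cl <- cumsum(c(TRUE, diff(centers) > match_tol))
  centers <- as.numeric(tapply(centers, cl, mean))
  out <- data.frame(center = centers, fwhm = init_fwhm,
                    area_frac = 100 / length(centers))
  class(out) <- c("band_set", "data.frame")
  out
}

gaussian_sum <- function(nu, center, fwhm, amp) {
  y <- numeric(length(nu))
  for (i in seq_along(center))
    y <- y + amp[i] * exp(-4 * log(2) * ((nu - center[i]) / fwhm[i])^2)
  y
}

#' Constrained Gaussian band fitting of an amide-I spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt) of a sum of Gaussian
#' components over the fit window. Centers are confined to the initial
#' positions plus/minus `position_window`, widths to `[6, 40]` cm^-1 and
#' amplitudes to be non-negative. Component areas are reported as percent of
#' the total fitted area.
#'
#' @param spectrum baseline-normalized `ir_spectrum`.
#' @param bands initial `band_set` (from [pick_bands()] or a preset).
#' @param position_window center constraint half-width, cm^-1.
#' @param window fit window, cm^-1.
#' @return object of class `band_model`: data.frame `center`, `fwhm`,
#'   `amplitude`, `area`, `area_frac`, `class`; attributes `rms`, `window`.
#' @export
fit_bands <- function(spectrum, bands, position_window = 2,
                      window = c(1600, 1700)) {
  if (nrow(bands) < 1) stop("need at least one initial band")
  keep <- spectrum$wavenumber >= window[1] & spectrum$wavenumber <= window[2]
  nu <- spectrum$wavenumber[keep]
  y <- spectrum$absorbance[keep]
  nb <- nrow(bands)
  lower <- c(bands$center - position_window, rep(6, nb), rep(0, nb))
  upper <- c(bands$center + position_window, rep(40, nb), rep(Inf, nb))
  resid_fn <- function(p) {
    gaussian_sum(nu, p[1:nb], p[(nb + 1):(2 * nb)], p[(2 * nb + 1):(3 * nb)]) - y
  }
  # amplitudes initialised by a non-negative linear solve at fixed
  # centers/widths; several width starts guard against local optima of the
  # strongly overlapped component problem
  lin_amp <- function(fw) {
    G <- vapply(seq_len(nb), function(i)
      exp(-4 * log(2) * ((nu - bands$center[i]) / fw[i])^2), numeric(length(nu)))
    a <- tryCatch(stats::coef(stats::lm.fit(G, y)), error = function(e) NULL)
    if (is.null(a)) a <- rep(max(y) / nb, nb)
    a[!is.finite(a)] <- 1e-8
    pmax(a, 1e-8)
  }
  width_starts <- unique(pmin(pmax(c(bands$fwhm[1], 8, 11), 6), 40))
  fit <- NULL
  for (w0 in width_starts) {
    fw <- rep(w0, nb)
    cand <- minpack.lm::nls.lm(c(bands$center, fw, lin_amp(fw)),
                               lower = lower, upper = upper, fn = resid_fn,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, maxfev = 20000))
    if (is.null(fit) || mean(cand$fvec^2) < mean(fit$fvec^2)) fit <- cand
  }
  if (fit$info == 0 || fit$info == 9)
    stop("fit failure: no convergence (residual RMS ",
         signif(sqrt(mean(fit$fvec^2)), 4), ")")
  p <- fit$par
  center <- p[1:nb]; fwhm <- p[(nb + 1):(2 * nb)]; amp <- p[(2 * nb + 1):(3 * nb)]
  area <- amp * fwhm * GAUSS_AREA_FACTOR
  o <- order(center)
  out <- data.frame(center = center[o], fwhm = fwhm[o], amplitude = amp[o],
                    area = area[o], area_frac = 100 * area[o] / sum(area),
                    class = classify_band(center[o]),
                    stringsAsFactors = FALSE)
  attr(out, "rms") <- sqrt(mean(fit$fvec^2))
  attr(out, "window") <- window
  attr(out, "nu") <- nu
  attr(out, "fitted") <- gaussian_sum(nu, center, fwhm, amp)
  class(out) <- c("band_model", "data.frame")
  out
}

#' Secondary-structure class of an amide-I band center
#'
#' beta-structure for 1620-1642 and 1668-1678 cm^-1; unordered for
#' 1642-1648; alpha-helix for 1648-1658; turns for 1658-1668 and 1678-1690.
#'
#' @param center wavenumber(s), cm^-1.
#' @return character vector among `"beta"`, `"unordered"`, `"alpha"`,
#'   `"turns"`, `"unassigned"`.
#' @export
classify_band <- function(center) {
  vapply(center, function(cc) {
    if ((cc >= 1620 && cc <= 1642) || (cc >= 1668 && cc <= 1678)) "beta"
    else if (cc > 1642 && cc < 1648) "unordered"
    else if (cc >= 1648 && cc <= 1658) "alpha"
    else if ((cc > 1658 && cc < 1668) || (cc > 1678 && cc <= 1690)) "turns"
    else "unassigned"
  }, character(1))
}

#' Secondary-structure percentages of a fitted band model
#'
#' Sums the component area fractions per structure class.
#'
#' @param model a `band_model`.
#' @return named numeric vector (percent) over beta, unordered, alpha,
#'   turns; any unassigned total is reported separately with a warning.
#' @export
assign_secondary_structure <- function(model) {
  cls <- model$class
  if (any(cls == "unassigned"))
    warning("band(s) outside all class ranges at ",
            paste(round(model$center[cls == "unassigned"], 1), collapse = ", "),
            " cm^-1")
  out <- c(beta = 0, unordered = 0, alpha = 0, turns = 0)
  for (k in names(out)) out[k] <- sum(model$area_frac[cls == k])
  if (any(cls == "unassigned"))
    out <- c(out, unassigned = sum(model$area_frac[cls == "unassigned"]))
  out
}

#' Full amide-I decomposition pipeline
#'
#' baseline/normalize -> FSD -> second derivative -> band picking ->
#' constrained fit -> class totals, with the standard parameters
#' (FSD bandwidth 18 cm^-1, k = 2).
#'
#' @param spectrum raw `ir_spectrum`.
#' @param params `fsd_params`.
#' @param deriv_window Savitzky-Golay window (points; the default suits the
#'   2 cm^-1-resolution grids of the measured spectra).
#' @param min_prominence band-picking threshold.
#' @return list with `model` (a `band_model`), `classes` (percent totals),
#'   `normalized`, `fsd` spectra.
#' @export
amide_decompose <- function(spectrum, params = fsd_params(18, 2),
                            deriv_window = 5, min_prominence = 0.05) {
  norm <- baseline_normalize(spectrum)
  dec <- fsd(norm, params)
  der <- second_derivative(norm, deriv_window)
  bands <- pick_bands(dec, der, min_prominence = min_prominence,
                      spectrum = norm)
  model <- fit_bands(norm, bands)
  list(model = model, classes = assign_secondary_structure(model),
       normalized = norm, fsd = dec)
}

#' Amide-I component presets of the studied FABP spectra
#'
#' Band centers (cm^-1) and percent areas of ReP1-NCXSQ in solution and
#' bound to DMPG, DMTAP and EDMPC membranes, as determined by band fitting
#' of the measured amide-I spectra.
#'
#' @param name one of `"solution"`, `"dmpg"`, `"dmtap"`, `"edmpc"`.
#' @return data.frame: `center`, `area_frac` (percent).
#' @export
amideI_preset <- function(name = c("solution", "dmpg", "dmtap", "edmpc")) {
  name <- match.arg(name)
  presets <- list(
    solution = data.frame(center = c(1626, 1638, 1652, 1662, 1671, 1684),
                          area_frac = c(34, 26, 19, 8, 8, 5)),
    dmpg = data.frame(center = c(1624, 1635, 1645, 1654, 1667, 1680),
                      area_frac = c(19, 27, 16, 23, 13, 2)),
    dmtap = data.frame(center = c(1625, 1639, 1653, 1666, 1680),
                       area_frac = c(21, 27, 25, 15, 11)),
    edmpc = data.frame(center = c(1625, 1637, 1651, 1666, 1671, 1680),
                       area_frac = c(17, 34, 24, 14, 5, 6)))
  presets[[name]]
}
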