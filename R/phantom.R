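# Synthetic 2D FLAIR-like brain phantoms: concentric smoothed-ellipse anatomy
# (background / CSF rim + ventricles / gray-matter ribbon / white-matter core)
# with focal hyperintense white-matter lesions, plus smooth complex coil
# sensitivity maps. These stand in for a patient cohort: the evaluation needs
# contrast classes and focal lesions, not anatomical realism.

LABEL_BACKGROUND <- 0L
LABEL_CSF <- 1L
LABEL_GM <- 2L
LABEL_WM <- 3L
LABEL_LESION <- 4L

# FLAIR-like tissue signal levels (arbitrary units): CSF suppressed, gray
# matter brighter than white matter, lesions hyperintense relative to WM.
TISSUE_SIGNAL <- c(background = 0, csf = 0.15, gm = 0.75, wm = 0.55)

#' Generate a FLAIR-like brain phantom with white-matter lesions
#'
#' Builds a smoothed-ellipse brain (CSF rim and ventricles, gray-matter
#' ribbon, white-matter core) on a regular grid and rasterizes `n_lesions`
#' non-overlapping hyperintense discs into the white matter. Tissue
#' boundaries get a mild per-case angular deformation so cases differ.
#'
#' @param shape integer pair, grid rows x columns (>= 32 each).
#' @param fov_mm physical field of view in mm (scalar or pair).
#' @param n_lesions number of lesions to place (>= 0).
#' @param diameter_range_mm lesion diameter interval in mm.
#' @param lesion_contrast multiplicative intensity factor relative to white
#'   matter at the lesion core.
#' @param seed integer seed; the phantom is a pure function of the arguments.
#' @return object of class `phantom_case`: `image` (non-negative matrix),
#'   `labels` (integer matrix: 0 background, 1 CSF, 2 GM, 3 WM, 4 lesion),
#'   `lesions` (data.frame: id, row, col, diameter_mm, contrast), `fov_mm`,
#'   `pixel_mm`, `seed`.
#' @export
generate_phantom <- function(shape = c(120L, 120L), fov_mm = c(240, 240),
                             n_lesions = 4L, diameter_range_mm = c(3, 10),
                             lesion_contrast = 1.4, seed = 1L) {
  shape <- as.integer(rep(shape, length.out = 2L))
  fov_mm <- rep(as.numeric(fov_mm), length.out = 2L)
  if (any(shape < 32L)) stop("invalid configuration: grid must be at least 32x32")
  if (any(fov_mm <= 0)) stop("invalid configuration: non-positive field of view")
  if (n_lesions < 0) stop("invalid configuration: negative lesion count")
  if (diameter_range_mm[1] <= 0 || diameter_range_mm[2] > min(fov_mm) / 4 ||
      diameter_range_mm[1] > diameter_range_mm[2])
    stop("invalid configuration: diameter range must lie within (0, min(fov)/4]")

  pixel_mm <- fov_mm / shape
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    # physical coordinates, centered
    y <- (seq_len(nr) - (nr + 1) / 2) * pixel_mm[1]
    x <- (seq_len(nc) - (nc + 1) / 2) * pixel_mm[2]
    Y <- matrix(y, nr, nc)
    X <- matrix(x, nr, nc, byrow = TRUE)

    # smooth per-case angular deformation of the tissue boundaries
    amp <- stats::runif(4, -0.025, 0.025)
    phs <- stats::runif(4, 0, 2 * pi)
    theta <- atan2(Y, X)
    rho <- 1 + amp[1] * cos(2 * theta + phs[1]) + amp[2] * cos(3 * theta + phs[2]) +
      amp[3] * cos(4 * theta + phs[3]) + amp[4] * cos(5 * theta + phs[4])

    ax <- 0.42 * fov_mm[2]; ay <- 0.45 * fov_mm[1]
    f <- sqrt((X / ax)^2 + (Y / ay)^2) / rho

    labels <- matrix(LABEL_BACKGROUND, nr, nc)
    labels[f <= 1] <- LABEL_CSF                 # outer CSF rim (sulcal fluid)
    labels[f <= 0.93] <- LABEL_GM               # cortical ribbon
    labels[f <= 0.76] <- LABEL_WM               # white-matter core

    # lateral ventricles: two small ellipses near center, CSF
    for (sgn in c(-1, 1)) {
      vx <- sgn * 0.055 * fov_mm[2]
      vy <- -0.02 * fov_mm[1]
      fv <- sqrt(((X - vx) / (0.052 * fov_mm[2]))^2 + ((Y - vy) / (0.14 * fov_mm[1]))^2)
      labels[fv <= 1 & labels == LABEL_WM] <- LABEL_CSF
    }

    # per-case intensity jitter, small enough to keep tissue ordering
    jit <- 1 + stats::rnorm(3, 0, 0.02)
    sig <- TISSUE_SIGNAL
    sig["csf"] <- sig["csf"] * jit[1]
    sig["gm"] <- sig["gm"] * jit[2]
    sig["wm"] <- sig["wm"] * jit[3]

    image <- matrix(sig["background"], nr, nc)
    image[labels == LABEL_CSF] <- sig["csf"]
    image[labels == LABEL_GM] <- sig["gm"]
    image[labels == LABEL_WM] <- sig["wm"]

    # lesion placement: rasterized discs with a 1-pixel smoothed edge,
    # footprint restricted to white matter, non-overlapping
    lesions <- data.frame(id = integer(), row = integer(), col = integer(),
                          diameter_mm = numeric(), contrast = numeric())
    if (n_lesions > 0) {
      wm_idx <- which(labels == LABEL_WM)
      px <- mean(pixel_mm)
      placed <- 0L
      tries <- 0L
      max_tries <- 400L * n_lesions
      centers <- matrix(0, 0, 2)
      radii_px <- numeric()
      while (placed < n_lesions) {
        tries <- tries + 1L
        if (tries > max_tries) stop("phantom overcrowded: lesion placement failed")
        d_mm <- stats::runif(1, diameter_range_mm[1], diameter_range_mm[2])
        r_px <- d_mm / 2 / px
        pick <- wm_idx[sample.int(length(wm_idx), 1L)]
        cr <- (pick - 1L) %% nr + 1L
        cc <- (pick - 1L) %/% nr + 1L
        # footprint must be fully WM
        rr <- max(1L, floor(cr - r_px - 1)):min(nr, ceiling(cr + r_px + 1))
        cc2 <- max(1L, floor(cc - r_px - 1)):min(nc, ceiling(cc + r_px + 1))
        dist <- outer(rr - cr, cc2 - cc, function(a, b) sqrt(a^2 + b^2))
        foot <- dist <= r_px
        if (!all(labels[rr, cc2][foot] == LABEL_WM)) next
        # no overlap with already placed lesions (1 px margin)
        if (placed > 0L) {
          sep <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
          if (any(sep < radii_px + r_px + 1)) next
        }
        # paint: full contrast inside, 1-pixel linear ramp at the edge
        w <- pmin(1, pmax(0, r_px + 0.5 - dist))
        sub <- image[rr, cc2]
        sub <- sub * (1 + (lesion_contrast - 1) * w)
        image[rr, cc2] <- sub
        lab <- labels[rr, cc2]
        lab[foot] <- LABEL_LESION
        labels[rr, cc2] <- lab
        placed <- placed + 1L
        centers <- rbind(centers, c(cr, cc))
        radii_px <- c(radii_px, r_px)
        lesions <- rbind(lesions, data.frame(id = placed, row = cr, col = cc,
                                             diameter_mm = d_mm,
                                             contrast = lesion_contrast))
      }
    }

    # mild partial-volume smoothing of the signal (labels stay crisp)
    image <- sep_conv2_reflect(image, gaussian_kernel1d(0.5))
    image[image < 0] <- 0

    structure(list(image = image, labels = labels, lesions = lesions,
                   fov_mm = fov_mm, pixel_mm = pixel_mm, shape = shape,
                   seed = as.integer(seed)),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %dx%d grid, FOV %g x %g mm, %d lesion(s), seed %d\n",
              x$shape[1], x$shape[2], x$fov_mm[1], x$fov_mm[2],
              nrow(x$lesions), x$seed))
  invisible(x)
}

#' Generate smooth complex coil sensitivity maps
#'
#' Channels are broad Gaussian magnitude lobes centered on points spaced
#' around the object, with slowly varying linear phase; maps are normalized so
#' the sum of squared magnitudes is 1 at every pixel (band-limited and
#' strictly positive by construction).
#'
#' @param shape grid rows x columns.
#' @param n_channels number of receive channels (>= 1).
#' @param lobe_width Gaussian lobe width of each channel's magnitude profile,
#'   as a fraction of the grid extent. Wider lobes overlap more, which raises
#'   the g-factor (noise amplification) of parallel-imaging reconstruction.
#' @param phase_range maximum linear phase gradient per channel (cycles
#'   across the field of view). Smaller values make channel sensitivities
#'   more nearly parallel, further raising the g-factor.
#' @param seed integer seed.
#' @return object of class `coil_sensitivities`: `maps` (complex array
#'   rows x cols x channels), `n_channels`, `shape`.
#' @export
generate_coil_sensitivities <- function(shape = c(120L, 120L), n_channels = 8L,
                                        lobe_width = 0.7, phase_range = 0.3,
                                        seed = 1L) {
  shape <- as.integer(rep(shape, length.out = 2L))
  if (n_channels < 1L) stop("invalid configuration: n_channels must be >= 1")
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    yv <- (seq_len(nr) - (nr + 1) / 2) / nr
    xv <- (seq_len(nc) - (nc + 1) / 2) / nc
    Y <- matrix(yv, nr, nc)
    X <- matrix(xv, nr, nc, byrow = TRUE)
    maps <- array(0 + 0i, dim = c(nr, nc, n_channels))
    width <- lobe_width
    for (ch in seq_len(n_channels)) {
      if (n_channels == 1L) {
        cx <- 0; cy <- 0
      } else {
        ang <- 2 * pi * (ch - 1) / n_channels + stats::runif(1, -0.1, 0.1)
        cx <- 0.5 * cos(ang)
        cy <- 0.5 * sin(ang)
      }
      mag <- 0.05 + exp(-((X - cx)^2 + (Y - cy)^2) / (2 * width^2))
      a <- stats::runif(1, -phase_range, phase_range)
      b <- stats::runif(1, -phase_range, phase_range)
      ph <- 2 * pi * (a * X + b * Y) + stats::runif(1, 0, 2 * pi)
      maps[, , ch] <- mag * exp(1i * ph)
    }
    sos <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
    for (ch in seq_len(n_channels)) maps[, , ch] <- maps[, , ch] / sos
    structure(list(maps = maps, n_channels = as.integer(n_channels),
                   shape = shape, seed = as.integer(seed)),
              class = "coil_sensitivities")
  })
}

#' Sum of squared sensitivity magnitudes
#' @param coils a `coil_sensitivities` object.
#' @return non-negative matrix.
#' @export
coil_sos <- function(coils) apply(abs(coils$maps)^2, c(1, 2), sum)

#' Generate a cohort of phantom cases
#'
#' Per-case seeds are derived reproducibly from `master_seed`, so cases
#' differ in lesion placement and anatomy jitter while the whole cohort is a
#' pure function of the configuration.
#'
#' @param n_cases number of cases (>= 1).
#' @param shape,fov_mm,n_lesions,diameter_range_mm,lesion_contrast passed to
#'   [generate_phantom()].
#' @param master_seed integer master seed.
#' @return list of `phantom_case` objects.
#' @export
generate_cohort <- function(n_cases, shape = c(120L, 120L), fov_mm = c(240, 240),
                            n_lesions = 4L, diameter_range_mm = c(3, 10),
                            lesion_contrast = 1.4, master_seed = 42L) {
  if (n_cases < 1L) stop("invalid configuration: n_cases must be >= 1")
  seeds <- derive_seeds(master_seed, n_cases, "phantom")
  lapply(seq_len(n_cases), function(i)
    generate_phantom(shape = shape, fov_mm = fov_mm, n_lesions = n_lesions,
                     diameter_range_mm = diameter_range_mm,
                     lesion_contrast = lesion_contrast, seed = seeds[i]))
}
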