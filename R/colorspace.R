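# Color representations and the CIEDE2000 difference metric.
#
# All conversion functions are vectorised over rows: a color argument is a
# numeric matrix (or data.frame) with one row per color, or a length-3 vector
# for a single color. Channel conventions:
#   RGB : integer-valued sRGB channels in 0..255 (as delivered by a picker)
#   HSL : hue in degrees [0, 360) (NA when undefined), saturation and
#         lightness in [0, 1]
#   Lab : CIE L*a*b*, D65 white, L in [0, 100]

.as_color_matrix <- function(x, what = "color") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a single ", what, " must have 3 components")
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L) stop(what, " input must have 3 columns")
  storage.mode(x) <- "double"
  unname(x)
}

.check_rgb <- function(rgb) {
  if (anyNA(rgb) || any(rgb < 0 | rgb > 255))
    stop("RGB channels must lie in [0, 255]")
  rgb
}

#' Convert sRGB picker colors to HSL
#'
#' Standard RGB to hue/saturation/lightness mapping. Achromatic colors
#' (saturation 0) have no defined hue; their hue is returned as `NA` rather
#' than coerced to 0 degrees, so the circular variable never enters a
#' correlation silently.
#'
#' @param rgb matrix (rows = colors) or length-3 vector of sRGB channels in
#'   0..255.
#' @return matrix with columns `h` (degrees in \[0, 360) or NA), `s`, `l`
#'   (both in \[0, 1\]).
#' @seealso [hsl_to_rgb()] for the inverse mapping.
#' @export
#' @examples
#' rgb_to_hsl(c(255, 0, 0))     # pure red: h = 0, s = 1, l = 0.5
#' rgb_to_hsl(c(128, 128, 128)) # achromatic: hue undefined (NA)
rgb_to_hsl <- function(rgb) {
  rgb <- .check_rgb(.as_color_matrix(rgb, "RGB"))
  v <- rgb / 255
  mx <- pmax(v[, 1], v[, 2], v[, 3])
  mn <- pmin(v[, 1], v[, 2], v[, 3])
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- rep(NA_real_, nrow(v))
  idx <- which(d > 0)
  for (i in idx) {
    r <- v[i, 1]; g <- v[i, 2]; b <- v[i, 3]
    h[i] <- if (mx[i] == r) {
      ((g - b) / d[i]) %% 6
    } else if (mx[i] == g) {
      (b - r) / d[i] + 2
    } else {
      (r - g) / d[i] + 4
    }
  }
  h <- (h * 60) %% 360
  cbind(h = h, s = pmin(pmax(s, 0), 1), l = pmin(pmax(l, 0), 1))
}

#' Convert HSL colors back to sRGB
#'
#' Inverse of [rgb_to_hsl()]; round-trips within 1/255 per channel. An `NA`
#' hue (undefined, achromatic) is treated as hue 0, which is exact when
#' saturation is 0.
#'
#' @param hsl matrix with columns h (degrees), s, l, or a length-3 vector.
#' @return matrix of sRGB channels in 0..255 (rounded to integers).
#' @export
hsl_to_rgb <- function(hsl) {
  hsl <- .as_color_matrix(hsl, "HSL")
  h <- ifelse(is.na(hsl[, 1]), 0, hsl[, 1] %% 360)
  s <- pmin(pmax(hsl[, 2], 0), 1)
  l <- pmin(pmax(hsl[, 3], 0), 1)
  c_ <- (1 - abs(2 * l - 1)) * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c_ / 2
  hp <- floor(h / 60) %% 6
  r <- g <- b <- numeric(length(h))
  for (i in seq_along(h)) {
    rgb1 <- switch(as.character(hp[i]),
      "0" = c(c_[i], x[i], 0),
      "1" = c(x[i], c_[i], 0),
      "2" = c(0, c_[i], x[i]),
      "3" = c(0, x[i], c_[i]),
      "4" = c(x[i], 0, c_[i]),
      "5" = c(c_[i], 0, x[i]))
    r[i] <- rgb1[1]; g[i] <- rgb1[2]; b[i] <- rgb1[3]
  }
  out <- cbind(r = r + m, g = g + m, b = b + m) * 255
  round(pmin(pmax(out, 0), 255))
}

# sRGB linearisation per IEC 61966-2-1 and the D65 sRGB->XYZ matrix.
.srgb_to_xyz_matrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.d65_white <- c(0.95047, 1.00000, 1.08883)

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert sRGB colors to CIELAB
#'
#' Decodes the sRGB transfer function (IEC 61966-2-1), converts through CIE
#' XYZ with the D65 white point, and applies the CIELAB transform. This is
#' the input space of the CIEDE2000 metric.
#'
#' @param rgb matrix (rows = colors) or length-3 vector of sRGB channels in
#'   0..255.
#' @return matrix with columns `L` (0..100), `a`, `b`.
#' @export
#' @examples
#' srgb_to_lab(c(255, 255, 255)) # reference white: L = 100, a = b = 0
srgb_to_lab <- function(rgb) {
  rgb <- .check_rgb(.as_color_matrix(rgb, "RGB"))
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz_matrix)
  f <- .lab_f(sweep(xyz, 2, .d65_white, "/"))
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' Convert CIELAB colors to sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut results are clamped to the sRGB
#' cube; the fraction of clamped colors is available via
#' `attr(result, "clamped")` (a logical vector, one flag per row).
#'
#' @param lab matrix with columns L, a, b, or a length-3 vector.
#' @return matrix of sRGB channels in 0..255 (rounded), with attribute
#'   `clamped`.
#' @export
lab_to_srgb <- function(lab) {
  lab <- .as_color_matrix(lab, "Lab")
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(.lab_f_inv(fx), .lab_f_inv(fy), .lab_f_inv(fz))
  xyz <- sweep(xyz, 2, .d65_white, "*")
  lin <- xyz %*% t(solve(.srgb_to_xyz_matrix))
  clamped <- apply(lin < -1e-9 | lin > 1 + 1e-9, 1, any)
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- round(pmin(pmax(v * 255, 0), 255))
  colnames(out) <- c("r", "g", "b")
  attr(out, "clamped") <- as.logical(clamped)
  out
}

#' CIEDE2000 color difference
#'
#' The full CIEDE2000 formula, including the lightness/chroma/hue weighting
#' functions and the blue-region rotation term, with unit parametric factors
#' (kL = kC = kH = 1). Symmetric in its arguments, zero exactly on identical
#' inputs. A just-noticeable difference is about 1 on this scale; the
#' consistency scoring in [score_subjects()] treats 16 and above as
#' "different colors".
#'
#' @param lab1,lab2 CIELAB colors, matrices (rows = colors, recycled to a
#'   common number of rows) or length-3 vectors.
#' @return numeric vector of nonnegative color differences.
#' @references Sharma, G., Wu, W., Dalal, E. N. (2005). The CIEDE2000
#'   color-difference formula: implementation notes, supplementary test data,
#'   and mathematical observations. Color Research & Application 30(1).
#' @export
#' @examples
#' delta_e_ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485)) # 2.0425
delta_e_ciede2000 <- function(lab1, lab2) {
  lab1 <- .as_color_matrix(lab1, "Lab")
  lab2 <- .as_color_matrix(lab2, "Lab")
  n <- max(nrow(lab1), nrow(lab2))
  if (nrow(lab1) == 1L) lab1 <- lab1[rep(1L, n), , drop = FALSE]
  if (nrow(lab2) == 1L) lab2 <- lab2[rep(1L, n), , drop = FALSE]
  if (nrow(lab1) != nrow(lab2))
    stop("lab1 and lab2 must have the same number of rows")

  deg2rad <- pi / 180
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hp_of <- function(b, ap) {
    h <- atan2(b, ap) / deg2rad
    h <- ifelse(h < 0, h + 360, h)
    ifelse(b == 0 & ap == 0, 0, h)
  }
  h1p <- hp_of(b1, a1p)
  h2p <- hp_of(b2, a2p)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(dh) <= 180, dh,
         ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * deg2rad)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  T_ <- 1 - 0.17 * cos((hbp - 30) * deg2rad) +
            0.24 * cos(2 * hbp * deg2rad) +
            0.32 * cos((3 * hbp + 6) * deg2rad) -
            0.20 * cos((4 * hbp - 63) * deg2rad)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T_
  RT <- -sin(2 * dtheta * deg2rad) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
       RT * (dCp / SC) * (dHp / SH))
}

#' @rdname delta_e_ciede2000
#' @export
delta_e <- delta_e_ciede2000

#' Hex notation helpers
#'
#' Colors are serialised in CSV both as `#RRGGBB` hex and as `h,s,l`
#' columns; readers accept either form and reconstruct the other.
#'
#' @param rgb sRGB channel matrix or length-3 vector (0..255).
#' @param hex character vector of `#RRGGBB` strings.
#' @return `rgb_to_hex`: character vector; `hex_to_rgb`: matrix of channels.
#' @export
rgb_to_hex <- function(rgb) {
  rgb <- .check_rgb(.as_color_matrix(rgb, "RGB"))
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' @rdname rgb_to_hex
#' @export
hex_to_rgb <- function(hex) {
  out <- t(grDevices::col2rgb(hex))
  colnames(out) <- c("r", "g", "b")
  out
}
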