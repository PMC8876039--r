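#' @include AllClasses.R
NULL

.check_pixels <- function(pixels) {
  need <- c("x", "y", "mz", "intensity")
  if (!is.data.frame(pixels) || !all(need %in% colnames(pixels)))
    stop("pixel table must have columns x, y, mz, intensity")
  if (!nrow(pixels)) stop("empty pixel spectra")
  if (any(pixels$mz <= 0)) stop("m/z values must be positive")
  if (any(pixels$intensity < 0)) stop("intensities must be non-negative")
  pixels
}

#' Read pixel-indexed centroided spectra from long TSV
#'
#' Expects columns \code{x}, \code{y} (raster indices), \code{mz} (Da) and
#' \code{intensity}.
#'
#' @param path TSV file path
#' @export
readPixels <- function(path) {
  .check_pixels(utils::read.delim(path, check.names = FALSE))
}

#' Extract an ion image at a target m/z
#'
#' For each raster pixel, sums the intensities of all centroided peaks
#' whose m/z lies within the closed mass window
#' \eqn{|m/z - target| \le tol} (the boundary is included: a peak exactly
#' \code{tol} away counts). Pixels without matching peaks are filled with
#' zero; the grid spans the full x/y index range of the acquisition.
#'
#' @param pixels long data.frame with columns x, y, mz, intensity
#' @param target_mz target m/z in Da
#' @param tol mass tolerance half-width in Da (default 0.01)
#' @param pixel_size raster pitch in micrometres (default 100)
#' @return an \linkS4class{IonImage} with scale bounds set to its own
#'   min/max
#' @export
extractIonImage <- function(pixels, target_mz, tol = 0.01, pixel_size = 100) {
  pixels <- .check_pixels(pixels)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  xr <- range(pixels$x); yr <- range(pixels$y)
  nx <- xr[2] - xr[1] + 1L; ny <- yr[2] - yr[1] + 1L
  grid <- matrix(0, nx, ny,
                 dimnames = list(seq(xr[1], xr[2]), seq(yr[1], yr[2])))
  hit <- abs(pixels$mz - target_mz) <= tol
  if (any(hit)) {
    sub <- pixels[hit, ]
    ij <- cbind(sub$x - xr[1] + 1L, sub$y - yr[1] + 1L)
    for (k in seq_len(nrow(sub)))
      grid[ij[k, 1], ij[k, 2]] <- grid[ij[k, 1], ij[k, 2]] + sub$intensity[k]
  }
  new("IonImage", grid = grid, target_mz = target_mz, tolerance = tol,
      scale_min = min(grid), scale_max = max(grid), pixel_size = pixel_size)
}

#' Put ion images of one metabolite on a common display scale
#'
#' Sets every image's \code{scale_min}/\code{scale_max} to the global
#' minimum and maximum over the whole set, so images of the same
#' metabolite in different samples are directly comparable. Grids are
#' untouched. Idempotent.
#'
#' @param images list of \linkS4class{IonImage} objects sharing one
#'   \code{target_mz}
#' @return list of rescaled \linkS4class{IonImage} objects
#' @export
commonScale <- function(images) {
  if (!length(images)) stop("need at least one image")
  mz <- vapply(images, function(im) im@target_mz, 0)
  if (length(unique(mz)) != 1L)
    stop("images have mixed target m/z; scale each metabolite separately")
  lo <- min(vapply(images, function(im) min(im@grid), 0))
  hi <- max(vapply(images, function(im) max(im@grid), 0))
  lapply(images, function(im) {
    im@scale_min <- lo; im@scale_max <- hi
    im
  })
}

#' Tissue mask from total ion current
#'
#' Flags pixels whose summed intensity over all peaks exceeds the given
#' quantile of per-pixel totals.
#'
#' @param pixels long pixel data.frame
#' @param probs quantile of per-pixel total ion current (default 0.1)
#' @return logical matrix matching \code{\link{extractIonImage}} grids
#' @export
tissueMask <- function(pixels, probs = 0.1) {
  pixels <- .check_pixels(pixels)
  tic <- extractIonImage(pixels, target_mz = mean(range(pixels$mz)),
                         tol = diff(range(pixels$mz)) / 2 + 1)
  thr <- stats::quantile(tic@grid, probs, names = FALSE)
  tic@grid > thr
}

#' Spatial uniformity statistics for an ion image
#'
#' Quantifies how uniformly a lipid is distributed over the tissue:
#' the quartile coefficient of dispersion
#' \eqn{(Q_3 - Q_1)/(Q_3 + Q_1)} of masked intensities, and Moran's I
#' spatial autocorrelation under rook (4-neighbour) adjacency among masked
#' pixels. Low dispersion together with near-zero Moran's I indicates a
#' uniform distribution; a smooth gradient yields strongly positive I and
#' a checkerboard strongly negative I.
#'
#' @param img an \linkS4class{IonImage}
#' @param mask logical matrix of tissue pixels matching \code{img}'s grid
#'   (default: all pixels)
#' @return list with \code{qcd}, \code{morans_i} and \code{degenerate}
#'   (TRUE when all masked intensities are equal, in which case Moran's I
#'   is reported as 0)
#' @export
uniformityStat <- function(img, mask = NULL) {
  g <- img@grid
  if (is.null(mask)) mask <- matrix(TRUE, nrow(g), ncol(g))
  stopifnot(identical(dim(mask), dim(g)))
  if (!any(mask)) stop("empty tissue mask")
  v <- g[mask]
  qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  qcd <- if (qs[1] + qs[2] == 0) 0 else (qs[2] - qs[1]) / (qs[2] + qs[1])
  if (length(unique(v)) == 1L)
    return(list(qcd = 0, morans_i = 0, degenerate = TRUE))
  idx <- which(mask, arr.ind = TRUE)
  key <- function(i, j) paste(i, j)
  pos <- stats::setNames(seq_len(nrow(idx)), key(idx[, 1], idx[, 2]))
  z <- g[mask] - mean(g[mask])
  num <- 0; W <- 0
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pos[key(idx[, 1] + d[1], idx[, 2] + d[2])]
    ok <- !is.na(nb)
    num <- num + sum(z[ok] * z[nb[ok]])
    W <- W + sum(ok)
  }
  I <- (nrow(idx) / W) * num / sum(z^2)
  list(qcd = qcd, morans_i = I, degenerate = FALSE)
}

#' Write an ion image grid as TSV
#'
#' Long format with columns \code{x}, \code{y}, \code{intensity} plus a
#' header comment carrying the mass window and scale bounds.
#'
#' @param img an \linkS4class{IonImage}
#' @param path output file path
#' @export
writeIonImage <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# target_mz=%g tol=%g pixel_size=%g scale_min=%g scale_max=%g",
                     img@target_mz, img@tolerance, img@pixel_size,
                     img@scale_min, img@scale_max), con)
  df <- data.frame(x = as.integer(rownames(img@grid)[row(img@grid)]),
                   y = as.integer(colnames(img@grid)[col(img@grid)]),
                   intensity = as.vector(img@grid))
  utils::write.table(df[order(df$x, df$y), ], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
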