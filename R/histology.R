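# Standard published stain vectors (optical density per RGB channel),
# hematoxylin / DAB, residual completed by the normalized cross product.
stain_matrix_hdab <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- cbind(h / sqrt(sum(h^2)), d / sqrt(sum(d^2)), r / sqrt(sum(r^2)))
  colnames(m) <- c("hematoxylin", "dab", "residual")
  m
}

#' Extract the DAB stain from an RGB section image
#'
#' Converts the 8-bit RGB image to optical density (`OD = -log10(I / 255)`,
#' intensities clipped at 1 to keep OD finite) and unmixes it with a fixed
#' hematoxylin / DAB / residual stain matrix (standard published vectors;
#' configurable). Returns the DAB concentration map clipped at zero.
#'
#' @param rgb 8-bit RGB array `[rows, cols, 3]` (values 0-255, or 0-1 as
#'   read by [png::readPNG()] / [tiff::readTIFF()]).
#' @param stains 3x3 stain matrix, columns = unit OD stain vectors.
#' @return Non-negative DAB OD matrix.
#' @export
extract_dab <- function(rgb, stains = stain_matrix_hdab()) {
  stop_if(!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] < 3,
          "input must be an RGB raster")
  rgb <- rgb[, , 1:3, drop = FALSE]
  if (max(rgb) <= 1) rgb <- rgb * 255
  d <- dim(rgb)
  od <- -log10(pmax(rgb, 1) / 255)
  odm <- matrix(od, ncol = 3)            # pixels x channels
  conc <- t(solve(stains, t(odm)))       # pixels x stains
  dab <- matrix(pmax(conc[, 2], 0), d[1], d[2])
  dab
}

#' Pixel-based immunohistochemistry H-score
#'
#' Bins DAB optical density into intensity classes 0 / 1+ / 2+ / 3+ by three
#' increasing thresholds and computes
#' `H = 100 * (1 * p1 + 2 * p2 + 3 * p3)` from the bin fractions, bounded
#' to `[0, 300]`. Pixel-based binning stands in for pathologist per-cell
#' scoring, which would require nuclear segmentation.
#'
#' @param dab non-negative DAB OD matrix from [extract_dab()].
#' @param mask logical matrix of evaluated pixels (default: all).
#' @param thresholds three strictly increasing OD cut points
#'   (default `c(0.2, 0.4, 0.6)`).
#' @return Object of class `h_score`: list `h_score`, `fractions`
#'   (named 0/1+/2+/3+, summing to 1), `thresholds`.
#' @export
compute_h_score <- function(dab, mask = NULL,
                            thresholds = c(0.2, 0.4, 0.6)) {
  stop_if(length(thresholds) != 3 || any(diff(thresholds) <= 0),
          "`thresholds` must be three increasing values")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dab), ncol(dab))
  vals <- dab[mask]
  stop_if(length(vals) == 0, "mask selects no pixels")
  bin <- findInterval(vals, thresholds)   # 0..3
  p <- tabulate(bin + 1L, nbins = 4L) / length(vals)
  names(p) <- c("0", "1+", "2+", "3+")
  structure(list(h_score = unname(100 * (p[2] + 2 * p[3] + 3 * p[4])),
                 fractions = p, thresholds = thresholds),
            class = "h_score")
}

#' @export
print.h_score <- function(x, ...) {
  cat(sprintf("H-score %.1f (0/1+/2+/3+ = %s)\n", x$h_score,
              paste(sprintf("%.2f", x$fractions), collapse = "/")))
  invisible(x)
}

#' Synthesize a DAB-stained section image with known ground truth
#'
#' Renders Gaussian DAB deposits over a uniform hematoxylin background with
#' an optional staining gradient that darkens away from the "membrane" (top)
#' edge, emulating the mottled, depth-graded hypoxia staining of tumor
#' sections. The forward model is the exact inverse of [extract_dab()]'s
#' mixing matrix, so round-trip tests can compare recovered bin fractions
#' against the exported ground truth.
#'
#' @param n_rows,n_cols raster size.
#' @param n_blobs number of DAB deposits (0 = unstained).
#' @param blob_od peak DAB OD of a deposit.
#' @param blob_sigma_px deposit Gaussian radius, pixels.
#' @param hematoxylin_od background hematoxylin OD.
#' @param depth_gradient multiplicative DAB gain from top row (1) to bottom
#'   row (`1 + depth_gradient`).
#' @param thresholds bin thresholds used for the exported ground truth.
#' @param seed RNG seed.
#' @return list `rgb` (8-bit array), `dab_truth` (OD matrix),
#'   `fractions_truth`, `h_score_truth`.
#' @export
synthesize_stained_section <- function(n_rows = 128, n_cols = 128,
                                       n_blobs = 30, blob_od = 0.8,
                                       blob_sigma_px = 6,
                                       hematoxylin_od = 0.35,
                                       depth_gradient = 0,
                                       thresholds = c(0.2, 0.4, 0.6),
                                       seed = 1L) {
  with_seed(seed, function() {
    dab <- matrix(0, n_rows, n_cols)
    if (n_blobs > 0) {
      cz <- stats::runif(n_blobs, 1, n_rows)
      cx <- stats::runif(n_blobs, 1, n_cols)
      amp <- blob_od * stats::runif(n_blobs, 0.4, 1)
      zg <- seq_len(n_rows); xg <- seq_len(n_cols)
      for (b in seq_len(n_blobs)) {
        dab <- dab + amp[b] * outer(
          exp(-(zg - cz[b])^2 / (2 * blob_sigma_px^2)),
          exp(-(xg - cx[b])^2 / (2 * blob_sigma_px^2)))
      }
    }
    if (depth_gradient != 0) {
      dab <- dab * (1 + depth_gradient * (seq_len(n_rows) - 1) / (n_rows - 1))
    }
    m <- stain_matrix_hdab()
    odm <- cbind(hematoxylin_od, as.vector(dab), 0) %*% t(m)  # pixels x rgb
    rgb_arr <- array(255 * 10^(-odm), dim = c(n_rows, n_cols, 3))
    rgb_arr <- round(pmin(pmax(rgb_arr, 0), 255))
    hs <- compute_h_score(dab, thresholds = thresholds)
    list(rgb = rgb_arr, dab_truth = dab,
         fractions_truth = hs$fractions, h_score_truth = hs$h_score)
  })
}
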