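# Stain vectors for hematoxylin + DAB color deconvolution (unit-normalized
# optical-density directions; third channel = normalized cross product).
g7_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  x <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = x / sqrt(sum(x^2)))
  m
}

#' Separate the DAB channel of an RGB immunohistochemistry image
#'
#' Color deconvolution of a hematoxylin + DAB stained image. Each 8-bit RGB
#' pixel is converted to optical density `OD = -log10((value + 1) / 256)` and
#' projected onto the stain basis (hematoxylin, DAB, and their cross-product
#' residual, each unit-normalized). The DAB coordinate is returned, clipped
#' below at 0: high values mean strong brown (galectin-7) staining.
#'
#' @param image Numeric array `height x width x 3` with 8-bit values in
#'   `[0, 255]`, e.g. from [read_ihc_image()].
#' @return Numeric `height x width` matrix of DAB optical density.
#' @export
separate_dab <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3 || !prod(dim(image)))
    stop("image must be a nonempty height x width x 3 RGB array", call. = FALSE)
  od <- -log10((image + 1) / 256)
  dm <- dim(od)
  od <- matrix(od, ncol = 3)
  conc <- od %*% solve(g7_stain_matrix())
  dab <- matrix(pmax(conc[, 2], 0), dm[1], dm[2])
  dab
}

# Otsu threshold over arbitrary-range values (EBImage's otsu works on a
# fixed data range; map onto it).
otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) <= 0) return(rng[1])
  EBImage::otsu(matrix(values, nrow = 1), range = rng, levels = 256)
}

#' Galectin-7 stained-area fraction (G7S) of a tissue section
#'
#' The fraction of tissue pixels whose DAB optical density exceeds a
#' threshold (Otsu over the tissue pixels by default, or a fixed override).
#' An intensity-weighted variant (total supra-threshold DAB OD over total
#' tissue DAB OD) is available behind `weighted = TRUE`.
#'
#' @param dab DAB optical-density matrix from [separate_dab()].
#' @param tissue_mask Logical matrix of the same dimensions; `TRUE` marks
#'   tissue pixels.
#' @param threshold Fixed DAB OD threshold; `NULL` (default) computes Otsu's
#'   threshold over the tissue pixels.
#' @param weighted If `TRUE`, weight pixels by their DAB OD instead of
#'   counting them.
#' @return List with `g7s_fraction`, `dab_threshold`, `stained_pixels`,
#'   `tissue_pixels`.
#' @export
compute_g7s <- function(dab, tissue_mask, threshold = NULL, weighted = FALSE) {
  if (!identical(dim(dab), dim(tissue_mask)))
    stop("dab and tissue_mask dimensions differ", call. = FALSE)
  if (!any(tissue_mask)) stop("tissue mask is empty", call. = FALSE)
  vals <- dab[tissue_mask]
  if (is.null(threshold)) threshold <- otsu_threshold(vals)
  stained <- dab > threshold & tissue_mask
  frac <- if (weighted) {
    tot <- sum(dab[tissue_mask])
    if (tot > 0) sum(dab[stained]) / tot else 0
  } else sum(stained) / sum(tissue_mask)
  list(g7s_fraction = frac, dab_threshold = threshold,
       stained_pixels = sum(stained), tissue_pixels = sum(tissue_mask))
}

#' Nuclear fraction of galectin-7 staining (G7N)
#'
#' The fraction of DAB-stained tissue pixels that fall inside nuclei:
#' `stained & nuclei / stained & tissue`, 0 when no pixel is stained. Uses
#' the same threshold as the G7S measurement of the same image.
#'
#' @param dab DAB optical-density matrix.
#' @param tissue_mask,nuclei_mask Logical matrices; nuclei must lie within
#'   tissue.
#' @param threshold DAB OD threshold, typically `$dab_threshold` from
#'   [compute_g7s()] on the same image.
#' @return List with `g7n_fraction`, `stained_nuclear_pixels`,
#'   `stained_pixels`.
#' @export
compute_g7n <- function(dab, tissue_mask, nuclei_mask, threshold) {
  if (!identical(dim(dab), dim(tissue_mask)) ||
      !identical(dim(dab), dim(nuclei_mask)))
    stop("mask dimensions differ from the DAB image", call. = FALSE)
  if (any(nuclei_mask & !tissue_mask))
    stop("nuclei_mask must be contained in tissue_mask", call. = FALSE)
  stained <- dab > threshold & tissue_mask
  ns <- sum(stained)
  nn <- sum(stained & nuclei_mask)
  list(g7n_fraction = if (ns > 0) nn / ns else 0,
       stained_nuclear_pixels = nn, stained_pixels = ns)
}

#' Ordinal nuclear-staining grade (G7NL)
#'
#' Grades the nuclear fraction G7N as weak (0, G7N < 0.15), positive
#' (1, 0.15 <= G7N <= 0.40) or strongly positive (2, G7N > 0.40). The
#' boundaries themselves grade 1.
#'
#' @param g7n_fraction Numeric vector in `[0, 1]`.
#' @return Integer vector of grades in `{0, 1, 2}`.
#' @examples
#' grade_g7nl(c(0.042, 0.168, 0.549))
#' @export
grade_g7nl <- function(g7n_fraction) {
  if (any(is.na(g7n_fraction)) || any(g7n_fraction < 0 | g7n_fraction > 1))
    stop("g7n_fraction must lie in [0, 1]", call. = FALSE)
  ifelse(g7n_fraction < 0.15, 0L, ifelse(g7n_fraction <= 0.40, 1L, 2L))
}

#' Measure one stained tissue image end to end
#'
#' Convenience wrapper: DAB separation, G7S, G7N and the G7NL grade for one
#' RGB image with its masks, returned as a one-row `data.frame` suitable for
#' appending to a per-image measurement CSV.
#'
#' @param image RGB array (`[0, 255]`).
#' @param tissue_mask,nuclei_mask Logical matrices.
#' @param image_id Identifier recorded in the output row.
#' @param threshold Optional fixed DAB threshold (default Otsu).
#' @return One-row `data.frame`: `image_id`, `g7s_fraction`, `g7n_fraction`,
#'   `g7nl_grade`, `dab_threshold`, `stained_pixels`, `tissue_pixels`,
#'   `stained_nuclear_pixels`.
#' @export
measure_ihc <- function(image, tissue_mask, nuclei_mask, image_id = "image",
                        threshold = NULL) {
  dab <- separate_dab(image)
  s <- compute_g7s(dab, tissue_mask, threshold = threshold)
  n <- compute_g7n(dab, tissue_mask, nuclei_mask, s$dab_threshold)
  data.frame(image_id = image_id,
             g7s_fraction = s$g7s_fraction,
             g7n_fraction = n$g7n_fraction,
             g7nl_grade = grade_g7nl(n$g7n_fraction),
             dab_threshold = s$dab_threshold,
             stained_pixels = s$stained_pixels,
             tissue_pixels = s$tissue_pixels,
             stained_nuclear_pixels = n$stained_nuclear_pixels)
}

#' Read / write 8-bit RGB images and binary masks as PNG
#'
#' Thin wrappers over the png package keeping the package's in-memory
#' conventions: RGB arrays carry values in `[0, 255]`, masks are logical
#' matrices stored as single-channel 0/255 PNGs.
#'
#' @param path PNG file path.
#' @return `read_ihc_image`: RGB array in `[0, 255]`; `read_mask`: logical
#'   matrix.
#' @export
read_ihc_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 3) stop("not an RGB PNG: ", path, call. = FALSE)
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname read_ihc_image
#' @param image RGB array in `[0, 255]` (written) .
#' @export
write_ihc_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname read_ihc_image
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

#' @rdname read_ihc_image
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
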