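#' Labeled two-phase volume
#'
#' A 3D array of binary phase labels with per-axis voxel sizes, the substrate
#' of all microstructure morphometrics. Phase 1 is the foreground
#' (gelatin-rich) phase, phase 0 the background (gelatin-poor) phase.
#'
#' @param labels 3D integer or logical array of 0/1 phase codes.
#' @param voxel_size micrometres per voxel along each array dimension
#'   (scalar or length 3).
#' @return An object of class `"labeled_volume"`: list with `labels` and
#'   `voxel_size`.
#' @export
labeled_volume <- function(labels, voxel_size = c(1, 1, 1)) {
  if (is.logical(labels)) labels <- array(as.integer(labels), dim = dim(labels))
  if (length(dim(labels)) != 3) stop("labels must be a 3D array")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive spacings (micrometres)")
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels (%g x %g x %g um), phase-1 fraction %.3f\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], mean(x$labels)))
  invisible(x)
}

#' Per-phase volume fractions
#'
#' Voxel volume of each phase divided by the total volume of the region of
#' interest. The two fractions sum to one.
#'
#' @param vol a [labeled_volume()].
#' @return named numeric vector `c(phase0 = ..., phase1 = ...)`.
#' @export
volume_fractions <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  f1 <- mean(vol$labels)
  c(phase0 = 1 - f1, phase1 = f1)
}

#' Connectivity of one phase
#'
#' Percent of a phase's volume contained in its single largest connected
#' component ("flood-fill" connectivity). 100% means the phase forms one
#' continuous domain; both phases above ~90% is the operational signature of
#' a bicontinuous microstructure.
#'
#' @param vol a [labeled_volume()].
#' @param phase 0 or 1.
#' @param connectivity 6 (face) or 26 (face+edge+corner, default, matching
#'   common 3D object-counter defaults). Both phases are measured with the
#'   same neighbourhood even though the two are not topologically dual.
#' @return connectivity percentage in \[0, 100\].
#' @export
phase_connectivity <- function(vol, phase = 1, connectivity = 26) {
  comp <- phase_components(vol, phase, connectivity)
  if (comp$n == 0)
    stop(sprintf("phase %d is absent: connectivity undefined", phase))
  100 * max(comp$sizes) / sum(comp$sizes)
}

#' Number of discrete objects of one phase
#'
#' Connected-component count; 0 when the phase is absent.
#'
#' @inheritParams phase_connectivity
#' @return integer component count.
#' @export
object_count <- function(vol, phase = 1, connectivity = 26) {
  phase_components(vol, phase, connectivity)$n
}

phase_components <- function(vol, phase, connectivity) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!phase %in% c(0, 1)) stop("phase must be 0 or 1")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  mask <- as.integer(vol$labels == phase)
  lab <- cc_label_3d(mask, dim(vol$labels), as.integer(connectivity))
  n <- max(lab)
  sizes <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer()
  list(labels = array(lab, dim = dim(vol$labels)), n = n, sizes = sizes)
}

#' Interfacial surface area per volume
#'
#' Counts internal voxel faces whose two adjacent voxels belong to different
#' phases, each weighted by its anisotropy-aware face area, and divides the
#' total by the region-of-interest volume. Faces on the array boundary are
#' excluded (only internal interface is measured). Exact for the voxel
#' representation and symmetric under phase swap.
#'
#' @param vol a [labeled_volume()].
#' @return interfacial surface area per volume, 1/micrometres.
#' @export
interfacial_area <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  L <- vol$labels
  d <- dim(L)
  vs <- vol$voxel_size
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  sa <- 0
  if (d[1] > 1)
    sa <- sa + face_area[1] *
      sum(L[-d[1], , , drop = FALSE] != L[-1, , , drop = FALSE])
  if (d[2] > 1)
    sa <- sa + face_area[2] *
      sum(L[, -d[2], , drop = FALSE] != L[, -1, , drop = FALSE])
  if (d[3] > 1)
    sa <- sa + face_area[3] *
      sum(L[, , -d[3], drop = FALSE] != L[, , -1, drop = FALSE])
  sa / (prod(d) * prod(vs))
}

#' All structure metrics of a labeled volume
#'
#' Convenience wrapper collecting volume fractions, per-phase connectivity
#' and object counts, and interfacial surface area per volume.
#'
#' @param vol a [labeled_volume()].
#' @param connectivity neighbourhood for the component analysis (6 or 26).
#' @return An object of class `"structure_metrics"`: list with
#'   `volume_fraction` (per phase), `connectivity_pct` (per phase, `NA` for
#'   an absent phase), `object_count` (per phase) and
#'   `interfacial_sa_per_volume` (1/micrometres).
#' @export
structure_metrics <- function(vol, connectivity = 26) {
  vf <- volume_fractions(vol)
  conn <- sapply(c(0, 1), function(ph)
    if (vf[[ph + 1]] > 0) phase_connectivity(vol, ph, connectivity) else NA_real_)
  cnt <- sapply(c(0, 1), function(ph) object_count(vol, ph, connectivity))
  structure(list(volume_fraction = vf,
                 connectivity_pct = stats::setNames(conn, c("phase0", "phase1")),
                 object_count = stats::setNames(as.integer(cnt),
                                                c("phase0", "phase1")),
                 interfacial_sa_per_volume = interfacial_area(vol),
                 connectivity = connectivity),
            class = "structure_metrics")
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf("<structure_metrics> (%d-connectivity)\n", x$connectivity))
  cat(sprintf("  volume fraction:   phase0 %.3f  phase1 %.3f\n",
              x$volume_fraction[1], x$volume_fraction[2]))
  cat(sprintf("  connectivity (%%):  phase0 %.1f  phase1 %.1f\n",
              x$connectivity_pct[1], x$connectivity_pct[2]))
  cat(sprintf("  objects:           phase0 %d  phase1 %d\n",
              x$object_count[1], x$object_count[2]))
  cat(sprintf("  interfacial SA/V:  %.4g 1/um\n", x$interfacial_sa_per_volume))
  invisible(x)
}

#' Coefficient of variation of image intensities
#'
#' Population standard deviation divided by the mean of the intensities in a
#' region of interest, the heterogeneity measure used to compare uniform and
#' phase-separated structures. The population (1/n) standard deviation is
#' used so that, e.g., an image of half 1s and half 3s has CoV exactly 1/2.
#'
#' @param image 2D or 3D numeric array.
#' @param roi optional list of index ranges (one integer vector per
#'   dimension) selecting a box; default is the whole image.
#' @return dimensionless CoV.
#' @export
intensity_cov <- function(image, roi = NULL) {
  if (!is.null(roi)) {
    stopifnot(length(roi) == length(dim(image)))
    image <- do.call(`[`, c(list(image), roi, list(drop = FALSE)))
  }
  v <- as.numeric(image)
  m <- mean(v)
  if (m <= 0) stop("ROI mean must be > 0 for a coefficient of variation")
  sqrt(mean((v - m)^2)) / m
}

#' Otsu threshold of an intensity array
#'
#' Maximises between-class variance over a 256-bin histogram; the standard
#' automatic foreground/background split for fluorescence images.
#'
#' @param image numeric array.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale; values strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(v, breaks = edges, plot = FALSE)$counts
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(n_bins))
  total <- w[n_bins]; mu_t <- mu[n_bins]
  w1 <- w[-n_bins]; mu1 <- mu[-n_bins]
  w2 <- total - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mu_t * w1[valid] - total * mu1[valid])^2 /
    (w1[valid] * w2[valid])
  k <- which.max(bcv)
  edges[k + 1]
}

#' Threshold a fluorescence stack into a labeled volume
#'
#' Converts an intensity stack into phase labels: voxels above the threshold
#' become the foreground phase. With `invert = TRUE` the labels are flipped,
#' mirroring the convention that the gelatin-poor phase is the inverse of
#' the gelatin-rich fluorescence.
#'
#' @param image 3D numeric array of intensities.
#' @param voxel_size micrometres per voxel per dimension.
#' @param threshold numeric threshold, or `"otsu"` (default).
#' @param invert flip foreground/background after thresholding.
#' @return a [labeled_volume()].
#' @export
threshold_volume <- function(image, voxel_size = c(1, 1, 1),
                             threshold = "otsu", invert = FALSE) {
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(image)
  lab <- image > threshold
  if (invert) lab <- !lab
  labeled_volume(array(as.integer(lab), dim = dim(image)), voxel_size)
}

#' Write a labeled volume as plain text
#'
#' Plain-text serialisation: a header line `nx ny nz dx dy dz` followed by
#' the label values in column-major order, 0/1, whitespace-separated. The
#' counterpart of [read_labeled_volume()].
#'
#' @param vol a [labeled_volume()].
#' @param path output file.
#' @export
write_labeled_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(dim(vol$labels), vol$voxel_size), collapse = " "), con)
  writeLines(paste(as.integer(vol$labels), collapse = " "), con)
  invisible(path)
}

#' Read a labeled volume written by [write_labeled_volume()]
#'
#' @param path file to read.
#' @return a [labeled_volume()].
#' @export
read_labeled_volume <- function(path) {
  hdr <- scan(path, nlines = 1, quiet = TRUE)
  if (length(hdr) != 6) stop("volume file format error: bad header")
  d <- as.integer(hdr[1:3])
  vals <- scan(path, skip = 1, quiet = TRUE)
  if (length(vals) != prod(d))
    stop("volume file format error: value count does not match dimensions")
  labeled_volume(array(as.integer(vals), dim = d), voxel_size = hdr[4:6])
}
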