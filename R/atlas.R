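#' Names of the atlas regions
#'
#' Nine early-visual sub-regions (areas V1, V2, V3 crossed with eccentricity
#' bands fovea, periphery, far periphery) plus auditory cortex (AC) and motor
#' cortex (MC).
#' @export
atlas_region_names <- function() {
  c(paste(rep(c("V1", "V2", "V3"), each = 3),
          rep(c("fovea", "periphery", "far_periphery"), 3), sep = "_"),
    "AC", "MC")
}

#' Default atlas geometry for a voxel grid
#'
#' Early visual cortex is modelled as three adjacent "area" slabs (V1, V2, V3)
#' along the second (posterior-anterior) axis, each containing three
#' concentric eccentricity rings (fovea innermost) in the orthogonal plane.
#' Auditory and motor cortex are cubic blocks placed anteriorly, away from the
#' visual slabs. All extents scale with the grid so a small grid yields a
#' compact atlas.
#'
#' @param grid_shape Integer vector of length 3.
#' @return A list describing slab positions, ring radii and control boxes.
#' @export
atlas_geometry <- function(grid_shape) {
  g <- as.integer(grid_shape)
  stopifnot(length(g) == 3, all(g >= 10))
  thick <- max(2L, round(g[2] / 8))
  slab_start <- 2L
  slabs <- lapply(0:2, function(i) {
    y0 <- slab_start + i * thick
    c(y0, y0 + thick - 1L)
  })
  names(slabs) <- c("V1", "V2", "V3")
  radii <- g[1] * c(0.09, 0.17, 0.25)
  box <- max(3L, round(min(g) / 6))
  y_box <- c(g[2] - box - 1L, g[2] - 2L)
  geom <- list(grid_shape = g,
               slabs = slabs,
               ring_center = c((g[1] + 1) / 2, (g[3] + 1) / 2),
               radii = radii,
               ac_box = list(x = c(2L, 1L + box), y = y_box, z = c(2L, 1L + box)),
               mc_box = list(x = c(g[1] - box - 1L, g[1] - 2L), y = y_box,
                             z = c(g[3] - box - 1L, g[3] - 2L)))
  last_slab <- slabs[["V3"]][2]
  if (y_box[1] <= last_slab)
    stop("grid too small: control boxes would overlap the visual slabs")
  geom
}

#' Construct a synthetic ROI atlas
#'
#' A stand-in for probabilistically mapped retinotopic ROIs: an integer label
#' volume with a lookup table and an eccentricity-band map. Region labels are
#' pairwise disjoint by construction; the early-visual-cortex (EVC) mask is
#' always derived as the union of the nine V1/V2/V3 sub-regions.
#'
#' @param grid_shape Integer vector of length 3 (default 24^3).
#' @param geometry Geometry list from [atlas_geometry()]; defaults to the
#'   geometry derived from `grid_shape`.
#' @return A list of class `roi_atlas` with elements `labels` (3-D integer
#'   array; 0 = background), `lut` (named integer vector, name = region),
#'   `bands` (named character vector region -> eccentricity band),
#'   `grid_shape`.
#' @export
#' @examples
#' atl <- make_roi_atlas(c(24, 24, 24))
#' sum(roi_mask(atl, "EVC"))
make_roi_atlas <- function(grid_shape = c(24L, 24L, 24L),
                           geometry = atlas_geometry(grid_shape)) {
  g <- as.integer(grid_shape)
  labels <- array(0L, dim = g)
  regions <- atlas_region_names()
  lut <- stats::setNames(seq_along(regions), regions)

  cx <- geometry$ring_center[1]; cz <- geometry$ring_center[2]
  r <- geometry$radii
  bands <- c("fovea", "periphery", "far_periphery")
  dist_xz <- sqrt(outer((seq_len(g[1]) - cx)^2, (seq_len(g[3]) - cz)^2, "+"))
  for (area in names(geometry$slabs)) {
    yr <- geometry$slabs[[area]]
    for (bi in 1:3) {
      lo <- if (bi == 1) -Inf else r[bi - 1]
      sel <- dist_xz > lo & dist_xz <= r[bi]   # x-z plane mask
      lab <- lut[[paste(area, bands[bi], sep = "_")]]
      for (y in yr[1]:yr[2]) {
        plane <- labels[, y, ]
        if (any(plane[sel] != 0)) stop("overlapping region request: ", area)
        plane[sel] <- lab
        labels[, y, ] <- plane
      }
    }
  }
  fill_box <- function(labels, box, lab) {
    sub <- labels[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]]
    if (any(sub != 0)) stop("overlapping region request: control box")
    labels[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]] <- lab
    labels
  }
  labels <- fill_box(labels, geometry$ac_box, lut[["AC"]])
  labels <- fill_box(labels, geometry$mc_box, lut[["MC"]])

  band_map <- stats::setNames(rep("none", length(regions)), regions)
  for (area in c("V1", "V2", "V3")) for (b in bands)
    band_map[paste(area, b, sep = "_")] <- b

  atl <- structure(list(labels = labels, lut = lut, bands = band_map,
                        grid_shape = g),
                   class = "roi_atlas")
  counts <- vapply(regions, function(rg) sum(labels == lut[[rg]]), integer(1))
  if (any(counts == 0))
    stop("empty region(s): ", paste(regions[counts == 0], collapse = ", "))
  atl
}

#' Logical mask for a named region
#'
#' Accepts the 11 atomic region names plus the derived unions `EVC`
#' (all nine V1/V2/V3 sub-regions), `V1`, `V2`, `V3` (the three eccentricity
#' bands of one area) and `fovea`, `periphery`, `far_periphery` (one band
#' across areas).
#'
#' @param atlas A `roi_atlas`.
#' @param roi Region name.
#' @return Logical 3-D array.
#' @export
roi_mask <- function(atlas, roi) {
  stopifnot(inherits(atlas, "roi_atlas"))
  atomic <- names(atlas$lut)
  members <- if (roi %in% atomic) {
    roi
  } else if (roi == "EVC") {
    grep("^V[123]_", atomic, value = TRUE)
  } else if (roi %in% c("V1", "V2", "V3")) {
    grep(paste0("^", roi, "_"), atomic, value = TRUE)
  } else if (roi %in% c("fovea", "periphery", "far_periphery")) {
    grep(paste0("^V[123]_", roi, "$"), atomic, value = TRUE)
  } else {
    stop("unknown ROI '", roi, "'; available: ",
         paste(c(atomic, "EVC", "V1", "V2", "V3"), collapse = ", "))
  }
  array(atlas$labels %in% atlas$lut[members], dim = atlas$grid_shape)
}

#' Default ROI list reported by the decoding stage
#' @export
default_roi_list <- function() {
  c("EVC", "V1", "V2", "V3", atlas_region_names()[1:9], "AC", "MC")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("roi_atlas: %s grid, %d regions, %d labelled voxels\n",
              paste(x$grid_shape, collapse = "x"), length(x$lut),
              sum(x$labels != 0)))
  invisible(x)
}
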