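#' Reference-region statistics and segmentation threshold
#'
#' Internal constructor; use [liver_reference()] or [aorta_reference()].
#'
#' @keywords internal
reference_stats <- function(region_kind, mean_suv, sd_suv, threshold_suv,
                            geometry) {
  structure(list(region_kind = region_kind, mean_suv = mean_suv,
                 sd_suv = sd_suv, threshold_suv = threshold_suv,
                 geometry = geometry),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat("<reference_stats> ", x$region_kind, "\n", sep = "")
  cat(sprintf("  mean SUV %.4g, SD %.4g -> threshold %.4g\n",
              x$mean_suv, x$sd_suv, x$threshold_suv))
  invisible(x)
}

ref_region_stats <- function(vol, mask, min_voxels = 10L) {
  n <- sum(mask)
  if (n < min_voxels)
    stop("reference region contains only ", n, " voxels (need >= ",
         min_voxels, ")")
  v <- vol$data[mask]
  list(mean = mean(v), sd = if (n > 1) stats::sd(v) else 0)
}

#' Liver reference region and threshold
#'
#' Places a 3 cm spherical ROI (diameter 3 cm, the PERCIST-style liver
#' reference) at the supplied centre, computes mean and SD of the SUV over
#' the voxels whose centres fall inside the sphere, and derives the lesion
#' segmentation threshold as `1.5 * mean + 2 * SD`.
#'
#' @param vol an [suv_volume].
#' @param center_mm sphere centre in mm.
#' @param diameter_mm ROI diameter, default 30 mm.
#' @return A `reference_stats` object.
#' @export
liver_reference <- function(vol, center_mm, diameter_mm = 30) {
  stopifnot(inherits(vol, "suv_volume"))
  r <- diameter_mm / 2
  ext <- volume_extent_mm(vol)
  if (any(center_mm - r < 0) || any(center_mm + r > ext))
    stop("liver reference sphere extends outside the volume")
  mask <- shape_mask(dim(vol$data), vol$voxel_size_mm, center_mm,
                     "sphere", rep(r, 3))
  s <- ref_region_stats(vol, mask)
  reference_stats("liver_sphere", s$mean, s$sd,
                  1.5 * s$mean + 2 * s$sd,
                  list(center_mm = center_mm, diameter_mm = diameter_mm))
}

#' Aortic blood-pool reference region and threshold
#'
#' For patients with liver metastases the liver is unusable as a reference;
#' a cylindrical ROI (1 cm diameter, 2 cm z-extent) in the descending
#' thoracic aorta is used instead, with threshold `2 * mean + 2 * SD`.
#' The cylinder axis runs along z.
#'
#' @param vol an [suv_volume].
#' @param center_mm cylinder centre in mm.
#' @param diameter_mm cylinder diameter, default 10 mm.
#' @param z_extent_mm cylinder length along z, default 20 mm.
#' @return A `reference_stats` object.
#' @export
aorta_reference <- function(vol, center_mm, diameter_mm = 10,
                            z_extent_mm = 20) {
  stopifnot(inherits(vol, "suv_volume"))
  r <- diameter_mm / 2
  hz <- z_extent_mm / 2
  ext <- volume_extent_mm(vol)
  lo <- center_mm - c(r, r, hz); hi <- center_mm + c(r, r, hz)
  if (any(lo < 0) || any(hi > ext))
    stop("aortic reference cylinder extends outside the volume")
  d <- dim(vol$data)
  cx <- voxel_centres(d[1], vol$voxel_size_mm[1]) - center_mm[1]
  cy <- voxel_centres(d[2], vol$voxel_size_mm[2]) - center_mm[2]
  cz <- voxel_centres(d[3], vol$voxel_size_mm[3]) - center_mm[3]
  inxy <- outer(cx^2, cy^2, "+") <= r^2
  mask <- outer(inxy, abs(cz) <= hz, "&")
  s <- ref_region_stats(vol, mask)
  reference_stats("aorta_cylinder", s$mean, s$sd,
                  2 * s$mean + 2 * s$sd,
                  list(center_mm = center_mm, diameter_mm = diameter_mm,
                       z_extent_mm = z_extent_mm))
}

# 26-connected component labelling of a 3D logical mask.
# Supra-threshold voxels become vertices of a graph with edges between
# 26-neighbours; components come from igraph. Returns an integer array,
# 0 = background.
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  pos <- which(mask)
  if (length(pos) == 0L) return(lab)
  idx_map <- array(0L, dim = d)
  idx_map[pos] <- seq_along(pos)
  co <- arrayInd(pos, d)
  # 13 lexicographically-positive offsets cover all 26 neighbours once
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] +
      nb[ok, 1]
    j <- idx_map[nb_lin]
    hit <- j > 0L
    if (any(hit))
      edges[[k]] <- rbind(which(ok)[hit], j[hit])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(pos), directed = FALSE)
  if (!is.null(em))
    g <- igraph::add_edges(g, as.vector(em))
  memb <- igraph::components(g)$membership
  lab[pos] <- as.integer(memb)
  lab
}

#' Segment PSMA-positive lesions by isocontour thresholding
#'
#' Voxels with `SUV >= threshold_suv` (inclusive) and not excluded form the
#' lesion mask; its 26-connected components are the lesions. Components
#' smaller than `min_voxels` are dropped. Lesions are ordered by descending
#' SUVmax, ties broken by ascending centroid (x, then y, then z), and
#' numbered 1..n in that order, so output is deterministic.
#'
#' @param vol an [suv_volume].
#' @param threshold_suv positive segmentation threshold, typically from
#'   [liver_reference()] or [aorta_reference()].
#' @param exclude optional logical array congruent with the volume marking
#'   physiological-uptake structures (salivary glands, coeliac ganglia, ...)
#'   to ignore.
#' @param min_voxels minimum component size kept, default 1.
#' @return Data frame with one row per lesion: `lesion_id`, `voxel_count`,
#'   `volume_cm3`, `suv_mean`, `suv_max`, `centroid_x_mm`, `centroid_y_mm`,
#'   `centroid_z_mm`. Zero rows when nothing exceeds the threshold.
#' @export
segment_lesions <- function(vol, threshold_suv, exclude = NULL,
                            min_voxels = 1L) {
  stopifnot(inherits(vol, "suv_volume"))
  if (threshold_suv <= 0) stop("`threshold_suv` must be positive")
  mask <- vol$data >= threshold_suv
  if (!is.null(exclude)) {
    if (!identical(dim(exclude), dim(vol$data)))
      stop("exclusion mask shape does not match the volume")
    mask <- mask & !exclude
  }
  lab <- label_components_26(mask)
  empty <- data.frame(lesion_id = integer(0), voxel_count = integer(0),
                      volume_cm3 = numeric(0), suv_mean = numeric(0),
                      suv_max = numeric(0), centroid_x_mm = numeric(0),
                      centroid_y_mm = numeric(0), centroid_z_mm = numeric(0))
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  pos <- which(lab > 0L)
  lb <- lab[pos]
  v <- vol$data[pos]
  co <- arrayInd(pos, dim(vol$data))
  cnt <- tabulate(lb, nbins = nlab)
  suv_sum <- as.vector(rowsum(v, lb))
  suv_max <- vapply(split(v, lb), max, numeric(1))
  cen <- rowsum(sweep(co - 0.5, 2, vol$voxel_size_mm, "*"), lb) / cnt
  keep <- cnt >= min_voxels
  if (!any(keep)) return(empty)
  out <- data.frame(voxel_count = cnt[keep],
                    volume_cm3 = cnt[keep] * voxel_volume_cm3(vol),
                    suv_mean = (suv_sum / cnt)[keep],
                    suv_max = suv_max[keep],
                    centroid_x_mm = cen[keep, 1],
                    centroid_y_mm = cen[keep, 2],
                    centroid_z_mm = cen[keep, 3])
  ord <- order(-out$suv_max, out$centroid_x_mm, out$centroid_y_mm,
               out$centroid_z_mm)
  out <- out[ord, , drop = FALSE]
  out <- cbind(lesion_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Hottest lesion of a study
#'
#' Returns the lesion with the highest SUVmax (ties: lowest `lesion_id`),
#' the anchor of PERCIST-style response assessment.
#'
#' @param lesions data frame from [segment_lesions()].
#' @return One-row data frame.
#' @export
hottest_lesion <- function(lesions) {
  if (nrow(lesions) == 0L)
    stop("no measurable lesion")
  i <- which(lesions$suv_max == max(lesions$suv_max))
  i <- i[which.min(lesions$lesion_id[i])]
  lesions[i, , drop = FALSE]
}
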