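#' Classical (Torgerson) multidimensional scaling into two axes
#'
#' Double-centers the element-wise squared distance matrix,
#' B = -1/2 J D2 J, and embeds the samples on the eigenvectors of B
#' scaled by the square roots of the two largest positive eigenvalues
#' ("2DS"). If fewer than two eigenvalues are positive the missing
#' axis is filled with zeros. Negative eigenvalues (phi distances are
#' not guaranteed Euclidean) are dropped and reflected in the goodness
#' statistic: the share of the retained positive eigenvalue mass over
#' all positive eigenvalues. A deterministic sign convention is
#' applied: each axis's largest-magnitude coordinate is positive.
#'
#' @param d labelled symmetric distance matrix, n >= 3.
#' @return object of class `"ordination_result"`: list with `labels`,
#'   `coords` (n x 2, rownames = labels), `eigenvalues` (all n,
#'   descending), `goodness` in \[0, 1\].
#' @export
classical_mds_2d <- function(d) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need >= 3 samples for 2D scaling", call. = FALSE)
  d2 <- d^2
  rm_ <- rowMeans(d2)
  b <- -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(d2))
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- 1e-12 * max(1, abs(vals[1]))
  pos <- which(vals > tol)
  coords <- matrix(0, n, 2, dimnames = list(rownames(d), c("axis1", "axis2")))
  take <- utils::head(pos, 2L)
  for (j in seq_along(take)) {
    coords[, j] <- e$vectors[, take[j]] * sqrt(vals[take[j]])
  }
  for (j in 1:2) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  pos_mass <- sum(vals[pos])
  goodness <- if (pos_mass > 0) sum(vals[take]) / pos_mass else 0
  structure(list(labels = rownames(d), coords = coords,
                 eigenvalues = vals, goodness = goodness),
            class = "ordination_result")
}

#' Convex-hull polygon area of a 2D point set
#'
#' Area enclosed by the convex hull of the points (monotone hull via
#' [grDevices::chull()], area via the shoelace formula as implemented
#' in [pracma::polyarea()]). Fewer than three distinct non-collinear
#' points give area 0. Duplicated points are allowed.
#'
#' @param points two-column matrix or data.frame of coordinates.
#' @return non-negative area.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop("points must have two columns", call. = FALSE)
  if (nrow(p) == 0L) return(0)
  if (any(!is.finite(p))) {
    stop("points contain non-finite coordinates", call. = FALSE)
  }
  p <- unique(p)
  if (nrow(p) < 3L) return(0)
  hull <- grDevices::chull(p[, 1], p[, 2])
  if (length(hull) < 3L) return(0)
  abs(pracma::polyarea(p[hull, 1], p[hull, 2]))
}

#' Per-time-point polygon areas of one family's ordination
#'
#' For a per-family ordination, computes the convex-hull area covered
#' by the family's samples at each time point — the dispersion measure
#' whose shrinkage from T0 to T60 quantifies microbiota convergence.
#' Time points with fewer than three non-collinear distinct points get
#' area 0 (noted via a message).
#'
#' @param ord an `"ordination_result"` for the samples of one family.
#' @param samples sample metadata covering the ordination's labels.
#' @return data.frame with columns `family_id`, `time_point`,
#'   `n_points`, `area`.
#' @export
group_areas <- function(ord, samples) {
  stopifnot(inherits(ord, "ordination_result"))
  validate_sample_meta(samples)
  meta <- samples[match(ord$labels, samples$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("metadata missing for ordination label(s): ",
         paste(ord$labels[is.na(meta$sample_id)], collapse = ", "),
         call. = FALSE)
  }
  fam <- unique(meta$family_id)
  if (length(fam) != 1L) {
    stop("ordination must cover a single family (found: ",
         paste(fam, collapse = ", "), ")", call. = FALSE)
  }
  tps <- intersect(tp_levels(), unique(meta$time_point))
  rows <- lapply(tps, function(tp) {
    pts <- ord$coords[meta$time_point == tp, , drop = FALSE]
    area <- polygon_area(pts)
    if (nrow(pts) < 3L || area == 0) {
      message("family ", fam, " ", tp, ": degenerate polygon (",
              nrow(pts), " point(s)), area 0")
    }
    data.frame(family_id = fam, time_point = tp,
               n_points = nrow(pts), area = area,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
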