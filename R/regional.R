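# Standardized septal coordinates and regional labels.
#
# rho: apicobasal coordinate, 0 at the apex and 1 at the annulus plane
# (normalized projection on the apex -> annulus-centre axis).  phi:
# circumferential coordinate, 0 on the anterior RV-attachment line and 1 on
# the posterior/inferior attachment line (normalized signed angle about the
# long axis).  Both are invariant under rigid transforms applied to the
# anatomy and its landmarks together.

# map arbitrary 3D points to (rho, phi) given landmarks
points_to_septal_coords <- function(pts, landmarks) {
  pts <- matrix(pts, ncol = 3)
  a <- as.numeric(landmarks$apex)
  cc <- as.numeric(landmarks$tv_centre)
  A <- as.numeric(landmarks$attach_anterior)
  P <- as.numeric(landmarks$attach_posterior)
  axis <- cc - a
  L <- sqrt(sum(axis^2))
  if (L < 1e-9) stop("coincident apex and annulus-centre landmarks")
  ez <- axis / L
  rel <- sweep(pts, 2, a)
  rho <- pmin(pmax(as.numeric(rel %*% ez) / L, 0), 1)
  perp <- function(v) v - sum(v * ez) * ez
  wA <- perp(A - a)
  wP <- perp(P - a)
  if (sqrt(sum(wA^2)) < 1e-9 || sqrt(sum(wP^2)) < 1e-9) {
    stop("attachment landmarks coincide with the long axis")
  }
  # signed angle of each node direction relative to the anterior line
  wrel <- rel - outer(as.numeric(rel %*% ez), ez)
  cross_w <- cbind(wA[2] * wrel[, 3] - wA[3] * wrel[, 2],
                   wA[3] * wrel[, 1] - wA[1] * wrel[, 3],
                   wA[1] * wrel[, 2] - wA[2] * wrel[, 1])
  theta <- atan2(as.numeric(cross_w %*% ez), as.numeric(wrel %*% wA))
  cross_P <- cross3(wA, wP)
  theta_P <- atan2(sum(cross_P * ez), sum(wP * wA))
  if (abs(theta_P) < 1e-9) stop("attachment landmarks are angularly coincident")
  phi <- pmin(pmax(theta / theta_P, 0), 1)
  data.frame(rho = rho, phi = phi)
}

#' Septal coordinates for every septal node
#'
#' @param anatomy a `patient_anatomy` (end-diastolic geometry is used)
#' @return data.frame `node`, `rho`, `phi`
#' @export
compute_coordinates <- function(anatomy) {
  sep <- anatomy$sequence$frames[[1]]$structures$SEPTUM
  co <- points_to_septal_coords(sep$vertices, anatomy$landmarks)
  data.frame(node = seq_len(nrow(sep$vertices)), co)
}

#' AHA segment labels on the septum
#'
#' Septal subset of the 17-segment model: basal anteroseptal (2), basal
#' inferoseptal (3), mid anteroseptal (8), mid inferoseptal (9), apical
#' septum (14).  Basal third `rho >= 2/3`, mid third `rho in [1/3, 2/3)`,
#' apical `rho < 1/3`; the anterior/inferior split is `phi = 0.5`.
#'
#' @param coords data.frame with `rho`, `phi`
#' @return integer vector of AHA labels
#' @export
assign_aha <- function(coords) {
  rho <- coords$rho; phi <- coords$phi
  out <- integer(length(rho))
  basal <- rho >= 2 / 3
  mid <- rho >= 1 / 3 & rho < 2 / 3
  out[basal & phi < 0.5] <- 2L
  out[basal & phi >= 0.5] <- 3L
  out[mid & phi < 0.5] <- 8L
  out[mid & phi >= 0.5] <- 9L
  out[rho < 1 / 3] <- 14L
  out
}

#' TV-band membership: septal nodes within 20 mm of the annulus plane
#'
#' Distance is the end-diastolic Euclidean distance from the node to the
#' tricuspid annulus plane (the underside of the 2-mm slab), measured along
#' the long axis.
#'
#' @param anatomy a `patient_anatomy`
#' @param threshold band width (mm), default 20
#' @return logical vector per septal node
#' @export
tv_band <- function(anatomy, threshold = 20) {
  sep <- anatomy$sequence$frames[[1]]$structures$SEPTUM
  lm <- anatomy$landmarks
  axis <- as.numeric(lm$tv_centre) - as.numeric(lm$apex)
  ez <- axis / sqrt(sum(axis^2))
  rel <- matrix(as.numeric(lm$tv_centre), nrow(sep$vertices), 3, byrow = TRUE) -
    sep$vertices
  d <- as.numeric(rel %*% ez)
  pmax(d, 0) < threshold
}

#' LBBAP region labels
#'
#' Each conduction branch (LBB, LAF, LPF, LSF) spans the convex region of
#' its seed-path coordinates in the flattened `(rho, phi)` chart, dilated by
#' a metric margin; nodes falling in several regions take the branch with
#' the nearest path centroid.  A degenerate (collinear) path falls back to a
#' buffered polyline corridor, which the margin test covers naturally.
#'
#' @param anatomy a `patient_anatomy` with `conduction_paths`
#' @param coords output of [compute_coordinates()]
#' @param margin dilation margin (mm equivalent), default 5
#' @return character vector per node: `"LBB"`, `"LAF"`, `"LPF"`, `"LSF"` or
#'   `"none"`
#' @export
lbbap_regions <- function(anatomy, coords, margin = 5) {
  lm <- anatomy$landmarks
  L <- sqrt(sum((as.numeric(lm$tv_centre) - as.numeric(lm$apex))^2))
  W <- sqrt(sum((as.numeric(lm$attach_anterior) -
                   as.numeric(lm$attach_posterior))^2))
  # chart metric: rho spans L mm, phi spans ~W mm
  sc <- function(df) cbind(df$rho * L, df$phi * W)
  nodes <- sc(coords)
  out <- rep("none", nrow(nodes))
  best_d <- rep(Inf, nrow(nodes))
  for (nm in names(anatomy$conduction_paths)) {
    path <- anatomy$conduction_paths[[nm]]
    pc <- points_to_septal_coords(path, lm)
    pxy <- sc(pc)
    member <- hull_membership(nodes, pxy, margin)
    centroid <- colMeans(pxy)
    d <- sqrt((nodes[, 1] - centroid[1])^2 + (nodes[, 2] - centroid[2])^2)
    take <- member & d < best_d
    out[take] <- nm
    best_d[take] <- d[take]
  }
  out
}

# inside the convex hull of pts, or within margin of its boundary; degenerate
# hulls reduce to the buffered polyline corridor
hull_membership <- function(nodes, pts, margin) {
  u <- unique(round(pts, 9))
  if (nrow(u) >= 3) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    poly <- pts[h, , drop = FALSE]
    inside <- point_in_polygon(nodes, poly)
    near <- dist_to_polyline(nodes, rbind(poly, poly[1, , drop = FALSE])) <= margin
    inside | near
  } else {
    dist_to_polyline(nodes, pts) <= margin
  }
}

# even-odd rule point-in-polygon, vectorized over query points
point_in_polygon <- function(q, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(q))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > q[, 2]) != (yj > q[, 2])) &
      (q[, 1] < (xj - xi) * (q[, 2] - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

dist_to_polyline <- function(q, pts) {
  d <- rep(Inf, nrow(q))
  if (nrow(pts) == 1) {
    return(sqrt((q[, 1] - pts[1, 1])^2 + (q[, 2] - pts[1, 2])^2))
  }
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 < 1e-30) rep(0, nrow(q)) else
      pmin(pmax(((q[, 1] - a[1]) * ab[1] + (q[, 2] - a[2]) * ab[2]) / len2, 0), 1)
    dx <- q[, 1] - (a[1] + t * ab[1])
    dy <- q[, 2] - (a[2] + t * ab[2])
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

#' All septal labels in one table
#'
#' @param anatomy a `patient_anatomy`
#' @param margin LBBAP dilation margin (mm)
#' @return data.frame `node`, `rho`, `phi`, `aha`, `lbbap`, `tv_band`
#' @export
septal_labels <- function(anatomy, margin = 5) {
  co <- compute_coordinates(anatomy)
  co$aha <- assign_aha(co)
  co$lbbap <- lbbap_regions(anatomy, co, margin)
  co$tv_band <- tv_band(anatomy)
  co
}

#' Resample per-node values onto a standardized (rho, phi) grid
#'
#' Nearest-node binning: each node falls in one cell; the cell value is the
#' mean of its nodes' values, `NA` where no node falls (flagged missing).
#'
#' @param coords data.frame with `rho`, `phi`
#' @param values numeric/logical per-node vector
#' @param resolution cells per axis (default 50, minimum 2)
#' @return list with `grid` (resolution x resolution matrix, rho in rows)
#'   and `counts` (nodes per cell)
#' @export
grid_resample <- function(coords, values, resolution = 50) {
  if (resolution < 2) stop("resolution must be >= 2")
  i <- pmin(floor(coords$rho * resolution) + 1L, resolution)
  j <- pmin(floor(coords$phi * resolution) + 1L, resolution)
  grid <- matrix(NA_real_, resolution, resolution)
  counts <- matrix(0L, resolution, resolution)
  cell <- (j - 1L) * resolution + i
  sums <- rowsum(as.numeric(values), cell)
  ns <- rowsum(rep(1L, length(cell)), cell)
  idx <- as.integer(rownames(sums))
  grid[idx] <- sums / ns
  counts[idx] <- ns
  list(grid = grid, counts = counts)
}
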