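#' Sensor layouts and spatial adjacency
#'
#' A `sensor_layout` holds scalp electrode names, their 3D positions (metres,
#' head frame), a 2D azimuthal-equidistant projection used for topographies
#' and neighbourhood construction, and (optionally) a symmetric adjacency
#' relation over channels that the cluster-based permutation test consumes.
#'
#' @name sensor_layout
NULL

#' Load the shipped 64-channel 10-10 montage
#'
#' Reads the standard 10-10 electrode coordinates bundled with the package
#' (64 scalp channels, FCz recording reference not included as a data
#' channel) and computes the 2D projection.
#'
#' @param path optional path to a TSV with columns `channel`, `x`, `y`, `z`.
#' @return a `sensor_layout` (without adjacency; see [build_adjacency()]).
#' @export
load_montage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montage_1010_64.tsv", package = "vection")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "x", "y", "z") %in% names(tab)))
  if (anyDuplicated(tab$channel)) {
    stop_vection("duplicate channel labels in montage", "vection_validation_error")
  }
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  rownames(xyz) <- tab$channel
  new_sensor_layout(tab$channel, xyz)
}

#' Construct a sensor layout from 3D positions
#'
#' @param channels character vector of unique channel names.
#' @param xyz numeric matrix, one row per channel, columns x/y/z. Positions
#'   are re-centred on a least-squares sphere fit (the head centre) before
#'   projecting.
#' @return `sensor_layout` list with `channels`, `pos3d`, `pos2d`.
#' @export
new_sensor_layout <- function(channels, xyz) {
  stopifnot(length(channels) == nrow(xyz), !anyDuplicated(channels))
  xyz <- sweep(xyz, 2, fit_sphere_centre(xyz))
  pos2d <- project_azimuthal(xyz)
  rownames(xyz) <- rownames(pos2d) <- channels
  structure(list(channels = channels, pos3d = xyz, pos2d = pos2d,
                 adjacency = NULL, adjacency_method = NULL),
            class = "sensor_layout")
}

# Least-squares sphere fit: |x - c|^2 = r^2 is linear in (c, r^2 - |c|^2).
# Degenerate (planar/collinear) point sets fall back to the centroid.
fit_sphere_centre <- function(xyz) {
  if (nrow(xyz) < 4) return(c(0, 0, 0))  # assume head-frame coordinates
  A <- cbind(2 * xyz, 1)
  b <- rowSums(xyz^2)
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit)) return(colMeans(xyz))
  fit[1:3]
}

# Azimuthal equidistant projection about the vertex (+z axis): planar radius
# proportional to the polar angle from the vertex, azimuth preserved.
project_azimuthal <- function(xyz) {
  r <- sqrt(rowSums(xyz^2))
  r[r == 0] <- 1
  polar <- acos(pmin(1, pmax(-1, xyz[, 3] / r)))
  az <- atan2(xyz[, 2], xyz[, 1])
  cbind(x = polar * cos(az), y = polar * sin(az))
}

#' Build a spatial adjacency relation over electrodes
#'
#' Default method: Delaunay triangulation of the 2D-projected positions with
#' edges longer than `prune_factor` times the median edge length removed
#' (long boundary edges connect electrodes across the cap rim and are not
#' physiological neighbours). Alternative: fixed-radius neighbourhoods.
#' Degenerate layouts (fewer than 3 electrodes, or collinear positions) fall
#' back to the radius method with a warning.
#'
#' The returned relation is symmetric and irreflexive.
#'
#' @param layout a `sensor_layout`.
#' @param method `"delaunay"` (default) or `"radius"`.
#' @param prune_factor edges longer than this multiple of the median Delaunay
#'   edge length are dropped (default 1.5).
#' @param radius neighbourhood radius, in units of the 2D projection
#'   (radians of polar angle); used by the radius method. Default 0.4.
#' @return the layout with `adjacency` set to a logical channel-by-channel
#'   matrix and `adjacency_method` recording the method and parameters.
#' @export
build_adjacency <- function(layout, method = c("delaunay", "radius"),
                            prune_factor = 1.5, radius = 0.4) {
  method <- match.arg(method)
  p <- layout$pos2d
  n <- nrow(p)
  degenerate <- n < 3 || is_collinear(p)
  if (method == "delaunay" && degenerate) {
    warning("layout degenerate for triangulation; falling back to radius method")
    method <- "radius"
  }
  if (method == "delaunay") {
    edges <- delaunay_edges(p)
    len <- sqrt(rowSums((p[edges[, 1], , drop = FALSE] -
                           p[edges[, 2], , drop = FALSE])^2))
    keep <- len <= prune_factor * median(len)
    edges <- edges[keep, , drop = FALSE]
    params <- list(method = "delaunay", prune_factor = prune_factor)
  } else {
    d <- as.matrix(dist(p))
    idx <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
    edges <- idx
    params <- list(method = "radius", radius = radius)
  }
  adj <- matrix(FALSE, n, n, dimnames = list(layout$channels, layout$channels))
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  diag(adj) <- FALSE
  layout$adjacency <- adj
  layout$adjacency_method <- params
  layout
}

is_collinear <- function(p) {
  if (nrow(p) < 3) return(TRUE)
  p0 <- sweep(p, 2, p[1, ])
  qr(p0)$rank < 2
}

# Brute-force Delaunay triangulation in 2D: a triangle (i, j, k) belongs to
# the triangulation iff no other point lies strictly inside its circumcircle.
# O(n^4) worst case but fully vectorised per triangle; fine for <= a few
# hundred electrodes.
delaunay_edges <- function(p) {
  n <- nrow(p)
  tri <- t(combn(n, 3))
  keep <- logical(nrow(tri))
  for (t_i in seq_len(nrow(tri))) {
    a <- p[tri[t_i, 1], ]; b <- p[tri[t_i, 2], ]; cc <- p[tri[t_i, 3], ]
    cen <- circumcentre(a, b, cc)
    if (any(!is.finite(cen))) next  # collinear triple: no circumcircle
    r2 <- sum((a - cen)^2)
    d2 <- (p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2
    d2[tri[t_i, ]] <- Inf
    keep[t_i] <- all(d2 >= r2 * (1 - 1e-9))
  }
  tri <- tri[keep, , drop = FALSE]
  edges <- rbind(tri[, c(1, 2), drop = FALSE],
                 tri[, c(1, 3), drop = FALSE],
                 tri[, c(2, 3), drop = FALSE])
  edges <- t(apply(edges, 1, sort))
  unique(edges)
}

circumcentre <- function(a, b, cc) {
  d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) + cc[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(c(NA_real_, NA_real_))
  ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
           sum(cc^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
           sum(cc^2) * (b[1] - a[1])) / d
  c(ux, uy)
}

#' Neighbour counts of an adjacency relation
#' @param layout a `sensor_layout` with adjacency built.
#' @return named integer vector of per-channel neighbour counts.
#' @export
neighbour_counts <- function(layout) {
  stopifnot(!is.null(layout$adjacency))
  rowSums(layout$adjacency)
}

#' Is the adjacency graph connected?
#' @param layout a `sensor_layout` with adjacency built.
#' @return logical scalar.
#' @export
adjacency_connected <- function(layout) {
  adj <- layout$adjacency
  n <- nrow(adj)
  seen <- logical(n)
  stack <- 1L
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ] & !seen))
  }
  all(seen)
}
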