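#' Kernel density surface of a location set
#'
#' Gaussian product-kernel density estimated on a regular metric grid.
#' Locations are projected to a local azimuthal-equidistant plane centred
#' on the cloud; the grid covers the points plus a three-bandwidth margin
#' and the returned cell masses sum to the total kernel mass captured by
#' the grid (1 within ~1% at adequate resolution).
#'
#' @param lon,lat Locations in decimal degrees (>= 3 distinct points).
#' @param bandwidth_m Kernel SD in metres, or `"silverman"` for
#'   Silverman's rule per axis (the default).
#' @param cell_m Grid cell size in metres; defaults to a quarter of the
#'   bandwidth, the resolution at which isopleth areas are reliable.
#' @return A list: `x`, `y` (cell-centre coordinates, metres), `density`
#'   (matrix, x by y, per m^2), `cell_m`, `bandwidth_m`, `center`
#'   (lon/lat of the projection centre).
#' @export
kde_surface <- function(lon, lat, bandwidth_m = "silverman", cell_m = NULL) {
  ok <- is.finite(lon) & is.finite(lat)
  lon <- lon[ok]; lat <- lat[ok]
  if (nrow(unique(cbind(lon, lat))) < 3)
    stop("kde_surface needs at least 3 distinct points; ",
         "jitter coincident locations if necessary")
  pr <- project_aeqd(lon, lat)
  x <- pr$x; y <- pr$y
  n <- length(x)
  if (identical(bandwidth_m, "silverman")) {
    # Silverman's rule per axis for a bivariate Gaussian kernel
    hx <- 1.06 * stats::sd(x) * n^(-1 / 5)
    hy <- 1.06 * stats::sd(y) * n^(-1 / 5)
    h <- max(mean(c(hx, hy)), 1)
  } else {
    h <- as.numeric(bandwidth_m)
    if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
  }
  if (is.null(cell_m)) cell_m <- h / 4
  gx <- seq(min(x) - 3 * h, max(x) + 3 * h, by = cell_m)
  gy <- seq(min(y) - 3 * h, max(y) + 3 * h, by = cell_m)
  # separable kernel: density(j,k) = sum_i Kx[j,i] * Ky[k,i] / n
  Kx <- outer(gx, x, function(g, p) stats::dnorm(g, p, h))
  Ky <- outer(gy, y, function(g, p) stats::dnorm(g, p, h))
  dens <- (Kx %*% t(Ky)) / n
  list(x = gx, y = gy, density = dens, cell_m = cell_m, bandwidth_m = h,
       center = pr$center)
}

#' Isopleth (probability contour) of a density grid
#'
#' The smallest set of highest-density cells whose cumulative mass reaches
#' `p` — the p-level utilization region. Area is cell count times cell
#' area. Masses are renormalized to the grid's own total so the isopleth
#' is exact with respect to the discretized surface.
#'
#' @param grid Output of [kde_surface()].
#' @param p Probability level in (0, 1); 0.95 for the home range, 0.50 for
#'   the core area.
#' @return List with `area_km2` and `mask` (logical matrix of included
#'   cells).
#' @export
isopleth <- function(grid, p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("p must be a single probability in (0, 1)")
  cell_area <- grid$cell_m^2
  mass <- grid$density * cell_area
  mass <- mass / sum(mass)
  o <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[o])
  k <- which(cum >= p)[1]
  mask <- matrix(FALSE, nrow(grid$density), ncol(grid$density))
  mask[o[seq_len(k)]] <- TRUE
  list(area_km2 = k * cell_area / 1e6, mask = mask)
}

#' Per-individual home range and core area
#'
#' 95% and 50% kernel-density isopleths of an individual's pre-migration
#' locations, with the core-area (50%) centroid used downstream as the
#' individual's spatial anchor.
#'
#' @param fixes Accuracy-filtered fixes for one individual.
#' @param bandwidth_m Passed to [kde_surface()].
#' @return List: `kde95_area_km2`, `kde50_area_km2`, `kde50_centroid`
#'   (lon/lat), `bandwidth_m`.
#' @export
home_range <- function(fixes, bandwidth_m = "silverman") {
  fx <- fixes[is.finite(fixes$longitude) & is.finite(fixes$latitude), ]
  g <- kde_surface(fx$longitude, fx$latitude, bandwidth_m)
  i95 <- isopleth(g, 0.95)
  i50 <- isopleth(g, 0.50)
  # mass-weighted centroid of the 50% region, back-projected
  w <- g$density * i50$mask
  w <- w / sum(w)
  cx <- sum(outer(g$x, rep(1, length(g$y))) * w)
  cy <- sum(outer(rep(1, length(g$x)), g$y) * w)
  cen_lat <- g$center[2] + cy / 111320
  cen_lon <- g$center[1] + cx / (111320 * cos(g$center[2] * pi / 180))
  list(kde95_area_km2 = i95$area_km2, kde50_area_km2 = i50$area_km2,
       kde50_centroid = c(lon = cen_lon, lat = cen_lat),
       bandwidth_m = g$bandwidth_m)
}

#' Pairwise great-circle distances between individuals' median locations
#'
#' @param fixes Accuracy-filtered fixes for the cohort (pre-migration).
#' @return A symmetric distance matrix in kilometres (zero diagonal) with
#'   individual ids as dimnames; individuals without positions are dropped
#'   with a warning.
#' @export
individual_distance_matrix <- function(fixes) {
  med <- fixes[is.finite(fixes$longitude) & is.finite(fixes$latitude), ] |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(lon = stats::median(longitude),
                     lat = stats::median(latitude), .groups = "drop")
  dropped <- setdiff(unique(fixes$individual_id), med$individual_id)
  if (length(dropped))
    warning("no located fixes for: ", paste(dropped, collapse = ", "))
  n <- nrow(med)
  D <- matrix(0, n, n, dimnames = list(med$individual_id,
                                       med$individual_id))
  for (i in seq_len(n)) {
    D[i, ] <- gc_distance_m(med$lon[i], med$lat[i], med$lon, med$lat) / 1000
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Agglomerative clustering of individuals by site use
#'
#' Complete-linkage (by default) hierarchical clustering of the
#' inter-individual distance matrix, cut at `k` groups; `k` defaults to
#' the silhouette-best cut between 2 and `max_k`.
#'
#' @param D Distance matrix from [individual_distance_matrix()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param k Number of clusters, or `NULL` to choose by mean silhouette.
#' @param max_k Largest cut examined when choosing `k`.
#' @return List: `labels` (named cluster ids), `order` (dendrogram order),
#'   `hclust`, `k`.
#' @export
hierarchical_clusters <- function(D, linkage = "complete", k = NULL,
                                  max_k = 8) {
  n <- nrow(D)
  if (!is.null(k) && k > n) stop("k exceeds the number of individuals")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  if (is.null(k)) {
    ks <- 2:min(max_k, n - 1)
    sil <- vapply(ks, function(kk) {
      mean_silhouette(D, stats::cutree(hc, kk))
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  labels <- stats::cutree(hc, k)
  list(labels = labels, order = hc$order, hclust = hc, k = k)
}

# mean silhouette width from a distance matrix and hard labels
mean_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }   # singleton convention
    a <- mean(D[i, own & seq_len(n) != i])
    bs <- vapply(setdiff(unique(labels), labels[i]),
                 function(g) mean(D[i, labels == g]), numeric(1))
    if (!length(bs)) return(0)
    b <- min(bs)
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Inverse-distance spatial weights
#'
#' Weight matrix w_ij = 1/d_ij between spatial anchors (zero diagonal),
#' optionally row-standardized. Coincident anchors get the weight of the
#' smallest positive distance (capped rather than infinite).
#'
#' @param D Distance matrix (km).
#' @param row_standardize Scale each row to sum to 1 (default TRUE).
#' @return List: `W` (matrix), `scheme`, `row_standardized`.
#' @export
inverse_distance_weights <- function(D, row_standardize = TRUE) {
  W <- 1 / D
  diag(W) <- 0
  pos <- D[D > 0]
  if (length(pos)) W[!is.finite(W)] <- 1 / min(pos)
  diag(W) <- 0
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  list(W = W, scheme = "inverse_distance", row_standardized = row_standardize)
}

#' Global Moran's I
#'
#' I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' with expectation -1/(n-1) under no spatial autocorrelation. The p-value
#' is reported both from the normal approximation under the randomization
#' assumption and from a permutation null (>= 999 shuffles of the values
#' over the locations), two-sided.
#'
#' @param values Numeric attribute per spatial unit (e.g. survival days).
#' @param weights List from [inverse_distance_weights()] (or any list with
#'   a `W` matrix).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation draw.
#' @return List: `I`, `expected_I`, `sd_I`, `p_normal`, `p_perm`,
#'   `n`, `scheme`.
#' @export
morans_i <- function(values, weights, n_perm = 999, seed = NULL) {
  W <- weights$W
  n <- length(values)
  if (n < 4) stop("Moran's I needs n >= 4")
  if (stats::sd(values) == 0) stop("Moran's I undefined for constant values")
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  I_of <- function(x) {
    z <- x - mean(x)
    (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  }
  I <- I_of(values)
  EI <- -1 / (n - 1)
  # randomization variance (weights need not be symmetric)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  z <- values - mean(values)
  b2 <- n * sum(z^4) / (sum(z^2))^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(varI)
  p_normal <- 2 * stats::pnorm(-abs(zscore))
  Iperm <- vapply(seq_len(n_perm), function(b) I_of(sample(values)),
                  numeric(1))
  p_perm <- (1 + sum(abs(Iperm - EI) >= abs(I - EI))) / (n_perm + 1)
  list(I = I, expected_I = EI, sd_I = sqrt(varI), p_normal = p_normal,
       p_perm = p_perm, n = n,
       scheme = if (!is.null(weights$scheme)) weights$scheme else "custom")
}
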