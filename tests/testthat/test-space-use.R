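lonlat_cloud <- function(n, sigma_m, lon0 = 116.2, lat0 = 29.0) {
  x <- rnorm(n, 0, sigma_m); y <- rnorm(n, 0, sigma_m)
  list(lon = lon0 + x / (111320 * cos(lat0 * pi / 180)),
       lat = lat0 + y / 111320)
}

test_that("kernel density surface normalizes and respects symmetry", {
  set.seed(1)
  pts <- lonlat_cloud(1000, 2000)
  g <- kde_surface(pts$lon, pts$lat, bandwidth_m = 300)
  expect_lt(abs(sum(g$density) * g$cell_m^2 - 1), 0.01)
  # an input symmetric about its centre spreads its mass symmetrically
  lon_sym <- c(pts$lon, 2 * mean(pts$lon) - pts$lon)
  lat_sym <- c(pts$lat, pts$lat)
  gs <- kde_surface(lon_sym, lat_sym, bandwidth_m = 300)
  mass <- gs$density * gs$cell_m^2
  mid <- mean(range(gs$x))
  left <- sum(mass[gs$x < mid, ]); right <- sum(mass[gs$x > mid, ])
  expect_lt(abs(left - right), 0.01)
  expect_error(kde_surface(rep(116, 5), rep(29, 5)), "distinct")
})

test_that("isopleth areas match the bivariate-normal closed form", {
  set.seed(11)
  sigma <- 2000
  pts <- lonlat_cloud(5000, sigma)
  g <- kde_surface(pts$lon, pts$lat, bandwidth_m = sigma / 8)
  for (p in c(0.50, 0.95)) {
    area <- isopleth(g, p)$area_km2
    closed <- pi * sigma^2 * qchisq(p, 2) / 1e6
    expect_lt(abs(area / closed - 1), 0.05)
  }
  a50 <- isopleth(g, 0.50)$area_km2
  a95 <- isopleth(g, 0.95)$area_km2
  expect_lt(a50, a95)
  expect_error(isopleth(g, 1.2), "probability")
})

test_that("the density surface matches an independent grid KDE", {
  skip_if_not_installed("MASS")
  set.seed(21)
  pts <- lonlat_cloud(300, 1000)
  g <- kde_surface(pts$lon, pts$lat, bandwidth_m = 400)
  pr <- project_aeqd(pts$lon, pts$lat)
  # MASS::kde2d's kernel SD is h/4, so h = 4 * bandwidth on the same grid
  ref <- MASS::kde2d(pr$x, pr$y, h = 4 * 400,
                     n = c(length(g$x), length(g$y)),
                     lims = c(range(g$x), range(g$y)))
  expect_lt(max(abs(g$density - ref$z)), 1e-12 * max(ref$z) + 1e-15)
})

test_that("the 95% isopleth area grows with the bandwidth", {
  set.seed(3)
  pts <- lonlat_cloud(400, 1500)
  areas <- vapply(c(200, 800, 3200), function(h)
    isopleth(kde_surface(pts$lon, pts$lat, bandwidth_m = h), 0.95)$area_km2,
    numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("a uniform surface gives proportional isopleth area", {
  g <- list(x = seq_len(40), y = seq_len(50),
            density = matrix(1, 40, 50), cell_m = 100)
  a <- isopleth(g, 0.95)
  expect_equal(sum(a$mask) / (40 * 50), 0.95, tolerance = 1e-3)
})

test_that("inter-individual distances are great-circle between medians", {
  fx1 <- make_fixes(id = "A", n_h = 10, lon = 116, lat = 29)
  fx2 <- make_fixes(id = "B", n_h = 10, lon = 116, lat = 30)
  fx3 <- make_fixes(id = "C", n_h = 10, lon = 116, lat = 29)
  D <- individual_distance_matrix(rbind(fx1, fx2, fx3))
  expect_equal(D["A", "C"], 0)
  expect_equal(D["A", "B"], 111.2, tolerance = 0.01)   # 1 deg latitude
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  fx4 <- make_fixes(id = "D", n_h = 3)
  fx4$longitude <- NA_real_
  expect_warning(individual_distance_matrix(rbind(fx1, fx2, fx4)), "D")
})

test_that("hierarchical clustering separates distinct site clouds", {
  set.seed(9)
  mk <- function(id, lat0) {
    f <- make_fixes(id = id, n_h = 20, lat = lat0)
    f$latitude <- f$latitude + rnorm(20, 0, 0.01)
    f$longitude <- f$longitude + rnorm(20, 0, 0.01)
    f
  }
  fx <- dplyr::bind_rows(lapply(1:6, function(i)
    mk(paste0("I", i), if (i <= 3) 29 else 31)))
  D <- individual_distance_matrix(fx)
  cl <- hierarchical_clusters(D, k = 2)
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:6])), 1)
  expect_false(cl$labels[1] == cl$labels[4])
  # silhouette-chosen k finds the same split
  cl_auto <- hierarchical_clusters(D)
  expect_equal(cl_auto$k, 2)
  # k = n gives singletons; merge heights are monotone (complete linkage)
  cl_n <- hierarchical_clusters(D, k = 6)
  expect_equal(length(unique(cl_n$labels)), 6)
  expect_true(all(diff(cl_n$hclust$height) >= 0))
  expect_error(hierarchical_clusters(D, k = 7), "exceeds")
})

test_that("Moran's I equals the double-loop definition exactly", {
  set.seed(14)
  for (n in c(10, 37, 50)) {
    xy <- matrix(runif(2 * n, 0, 10), ncol = 2)
    vals <- rnorm(n)
    D <- as.matrix(dist(xy))
    wgt <- inverse_distance_weights(D)
    m <- morans_i(vals, wgt, n_perm = 99, seed = 1)
    expect_equal(m$I, brute_morans_i(vals, wgt$W), tolerance = 1e-12)
    expect_equal(m$expected_I, -1 / (n - 1))
  }
})

test_that("Moran's I has the right sign on structured lattices", {
  # 4x4 rook lattice
  n <- 16
  coord <- expand.grid(x = 1:4, y = 1:4)
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    W[i, j] <- as.integer(abs(coord$x[i] - coord$x[j]) +
                            abs(coord$y[i] - coord$y[j]) == 1)
  wgt <- list(W = W, scheme = "rook")
  checker <- (-1)^(coord$x + coord$y)
  m_neg <- morans_i(checker, wgt, n_perm = 99, seed = 2)
  expect_lt(m_neg$I, m_neg$expected_I)
  grad <- coord$x + coord$y
  m_pos <- morans_i(grad, wgt, n_perm = 99, seed = 2)
  expect_gt(m_pos$I, 0)
  expect_error(morans_i(rep(1, n), wgt), "constant")
})

test_that("Moran's I matches an independent reference implementation", {
  skip_if_not_installed("ape")
  set.seed(4)
  n <- 30
  xy <- matrix(runif(2 * n), ncol = 2)
  vals <- rnorm(n) + xy[, 1]
  W <- 1 / as.matrix(dist(xy)); diag(W) <- 0
  W <- W / rowSums(W)
  ours <- morans_i(vals, list(W = W), n_perm = 99, seed = 3)
  ref <- ape::Moran.I(vals, W)
  expect_equal(ours$I, ref$observed, tolerance = 1e-12)
  expect_equal(ours$expected_I, ref$expected, tolerance = 1e-12)
  expect_equal(ours$sd_I, ref$sd, tolerance = 1e-10)
  expect_equal(ours$p_normal, ref$p.value, tolerance = 1e-10)
})

test_that("permutation p-values are uniform under exchangeable labels", {
  set.seed(101)
  n <- 16
  xy <- matrix(runif(2 * n, 0, 10), ncol = 2)
  wgt <- inverse_distance_weights(as.matrix(dist(xy)))
  ps <- vapply(1:200, function(b)
    morans_i(rnorm(n), wgt, n_perm = 199, seed = b)$p_perm, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
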