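# Alignment, cone-scan extraction, null model, substituent test.

test_that("cone_geometry validates its parameters", {
  g <- cone_geometry()
  expect_equal(g$half_angle, 55)
  expect_equal(g$probe_radius, 1.22)
  expect_error(cone_geometry(half_angle = 95), "half_angle")
  expect_error(cone_geometry(angular_step = 7), "divide")
  expect_error(cone_geometry(radial_increment = 0), "radial_increment")
})

test_that("alignment onto the reference recovers identity, translation, rotation", {
  site <- fixture_site("a")
  tr <- align_to_reference(site, "C2")
  expect_lt(tr$rmsd, 1e-9)
  expect_equal(tr$R, diag(3), tolerance = 1e-9)
  expect_equal(unname(tr$t), c(0, 0, 0), tolerance = 1e-9)

  shifted <- site
  shifted$atoms <- sweep(site$atoms, 2, c(1, 2, 3), "+")  # moved by (1,2,3)
  shifted$mg <- shifted$atoms["MG", ]
  tr2 <- align_to_reference(shifted, "C2")
  expect_equal(unname(tr2$t), c(-1, -2, -3), tolerance = 1e-9)  # the inverse
  expect_lt(tr2$rmsd, 1e-9)

  R30 <- chlfscan:::rotation_about_axis(c(0, 0, 1), 30)
  rot <- site
  rot$atoms <- site$atoms %*% t(R30)
  rownames(rot$atoms) <- rownames(site$atoms)
  rot$mg <- rot$atoms["MG", ]
  tr3 <- align_to_reference(rot, "C2")
  # recovered transform composed with the applied rotation is the identity
  expect_equal(tr3$R %*% R30, diag(3), tolerance = 1e-6)
  expect_lt(tr3$rmsd, 1e-6)

  noC1 <- site
  noC1$atoms <- site$atoms[rownames(site$atoms) != "C1", ]
  expect_error(align_to_reference(noC1, "C2"), "missing alignment atom")
})

test_that("a map that is zero around the site yields an all-zero scan", {
  site <- fixture_site("a")
  m <- zero_region_map()
  s <- scan_cone(m, site, "C2", radial = FALSE)
  expect_equal(s$values, rep(0, 72))
})

test_that("a lone Gaussian at the formyl O position peaks at the O azimuth", {
  ff <- make_chl_fixture("f")
  o_pos <- unlist(ff$atoms[ff$atoms$name == "O21", c("x", "y", "z")])
  lone_o <- structure_model(ff$atoms[ff$atoms$name == "O21", ])
  box <- list(origin = c(-16, -16, -16), dim = c(81, 81, 81))
  sim <- simulate_esp_map(lone_o, resolution = 2.0, voxel_size = 0.4,
                          box = box)
  site <- fixture_site("f")
  sc <- scan_cone(sim$map, site, "C2", radial = FALSE)
  # oracle: azimuth of the O atom in the cone frame, computed independently
  ref <- reference_chl()
  apex <- ref["C21", ]
  axis <- (ref["C21", ] - ref["C2", ]); axis <- axis / sqrt(sum(axis^2))
  fl <- ref["C1", ] - ref["C2", ]
  u <- fl - sum(fl * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2], axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  d <- o_pos - apex
  az <- atan2(sum(d * v), sum(d * u)) * 180 / pi
  az <- (az + 360) %% 360
  peak <- sc$angles[which.max(sc$values)]
  diff <- min(abs(peak - az), 360 - abs(peak - az))
  expect_lte(diff, 5)
})

test_that("scan values are equivariant under a rigid rotation of model and map", {
  fx <- make_chl_fixture("f")
  n <- 33; vox <- 0.8
  box <- list(origin = rep(-(n - 1) / 2 * vox, 3), dim = rep(n, 3))
  sim <- simulate_esp_map(fx, resolution = 2.5, voxel_size = vox, box = box)
  site <- fixture_site("f")
  sc1 <- scan_cone(sim$map, site, "C2", radial = FALSE)

  # rotate model and map together by 90 degrees about z through the box
  # center: an exact grid permutation, so no resampling error enters
  R90 <- chlfscan:::rotation_about_axis(c(0, 0, 1), 90)
  fx2 <- fx
  xyz <- as.matrix(fx$atoms[, c("x", "y", "z")]) %*% t(R90)
  fx2$atoms[, c("x", "y", "z")] <- xyz
  site2 <- local({
    tb <- data.frame(chain = "X", resnum = 1, site_name = "S1")
    extract_chl_sites(fx2, tb)[[1]]
  })
  g1 <- sim$map$grid
  g2 <- array(NA_real_, dim(g1))
  for (i in seq_len(n)) g2[i, , ] <- g1[, n + 1 - i, ]
  map2 <- esp_map(g2, vox, box$origin, rescaled = TRUE)
  sc2 <- scan_cone(map2, site2, "C2", radial = FALSE)
  expect_equal(sc2$values, sc1$values, tolerance = 1e-3)
  expect_lt(max(abs(sc2$values - sc1$values)), 1e-6)
})

test_that("radial profiles span apex to probe radius at the stated increment", {
  site <- fixture_site("a")
  sim <- simulate_esp_map(make_chl_fixture("a"), resolution = 2.0,
                          voxel_size = 0.8)
  sc <- scan_cone(sim$map, site, "C7", radial = TRUE)
  expect_equal(dim(sc$radial_profiles), c(72, 123))  # 0..1.22 A by 0.01
  expect_true(all(is.finite(sc$radial_profiles)))
  # profile end point equals the azimuthal scan value
  expect_equal(unname(sc$radial_profiles[, 123]), sc$values, tolerance = 1e-9)
})

test_that("resolution binning splits at the cutoff, inclusive on the low side", {
  mk <- function(res) {
    s <- fixture_site("a")
    s$local_resolution <- res
    sc <- structure(list(site_name = "s", substituent = "C7",
                         angles = seq(0, 355, 5), values = rep(0, 72),
                         radial_profiles = NULL, mg_local_resolution = res,
                         bin_id = NA_character_, fit_rmsd = 0),
                    class = "cone_scan")
    sc
  }
  out <- assign_bins(list(mk(2.8), mk(3.0)))
  expect_equal(vapply(out, function(s) s$bin_id, ""), c("low", "high"))
  out2 <- assign_bins(list(mk(2.91)))
  expect_equal(out2[[1]]$bin_id, "low")        # boundary is inclusive
  out3 <- assign_bins(list(mk(NA_real_), mk(NA_real_)))
  expect_equal(vapply(out3, function(s) s$bin_id, ""), c("all", "all"))
  expect_error(assign_bins(list(mk(2.8), mk(NA_real_))), "mixed")
})

make_scan <- function(values, substituent = "C7", bin = "all", name = "s") {
  structure(list(site_name = name, substituent = substituent,
                 angles = seq(0, 355, 5), values = values,
                 radial_profiles = NULL, mg_local_resolution = NA_real_,
                 bin_id = bin, fit_rmsd = 0), class = "cone_scan")
}

test_that("null model arithmetic: mean, unbiased sd, mu + 3 sd threshold", {
  s1 <- make_scan(rep(0, 72)); s2 <- make_scan(rep(2, 72))
  null <- build_null(list(s1, s2))
  b <- null$bins$all
  expect_equal(unname(b$mu), rep(1, 72))
  expect_equal(unname(b$sd), rep(sqrt(2), 72))   # unbiased (n-1) estimator
  expect_equal(unname(b$threshold), rep(1 + 3 * sqrt(2), 72))
  expect_equal(b$threshold[1], 5.243, tolerance = 1e-3)

  same <- build_null(list(make_scan(rep(0.5, 72)), make_scan(rep(0.5, 72))))
  expect_equal(unname(same$bins$all$sd), rep(0, 72))
  expect_equal(same$bins$all$threshold, same$bins$all$mu)

  expect_error(build_null(list(s1)), "fewer than 2")
  expect_error(build_null(list(make_scan(rep(0, 72), substituent = "C2"), s1)),
               "C7")
})

test_that("null estimates converge on 10,000 standard-normal pseudo-scans", {
  set.seed(202)
  scans <- lapply(seq_len(10000), function(i) make_scan(rnorm(72)))
  null <- build_null(scans)
  expect_lt(max(abs(null$bins$all$mu)), 0.05)
  expect_lt(max(abs(null$bins$all$sd - 1)), 0.05)
  # threshold dominance: threshold >= mu at every angle
  expect_true(all(null$bins$all$threshold >= null$bins$all$mu))
})

test_that("substituent test uses strict exceedance and wrap-aware runs", {
  null <- build_null(list(make_scan(rep(0, 72)), make_scan(rep(2, 72))))
  thr <- null$bins$all$threshold[1]
  # exactly at threshold everywhere: fail (strict inequality)
  at <- make_scan(rep(thr, 72), substituent = "C2")
  expect_equal(test_substituent(at, null)$decision, "fail-to-reject")
  # one angle above, min_run 1: reject
  v <- rep(0, 72); v[10] <- thr + 0.1
  one <- make_scan(v, substituent = "C2")
  t1 <- test_substituent(one, null)
  expect_equal(t1$decision, "reject")
  expect_equal(t1$exceed_angles, 45)
  # wrap-around run: angles 355 and 0 count as a run of 2
  v2 <- rep(0, 72); v2[c(1, 72)] <- thr + 0.1
  t2 <- test_substituent(make_scan(v2, substituent = "C2"), null, min_run = 2)
  expect_equal(t2$decision, "reject")
  expect_equal(test_substituent(one, null, min_run = 2)$decision,
               "fail-to-reject")
  # bin mismatch
  mis <- make_scan(v, substituent = "C2", bin = "low")
  expect_error(test_substituent(mis, null), "bin")
})

test_that("simulated formyl rejects and methyl does not at 2 A / noise 0.1", {
  # small randomized battery: the null must see the same orientation/grid
  # phase variability as the tested scans
  st <- simulate_study(16, 0.25, resolutions = 2.0, noise_sigma = 0.1,
                       seed = 5)
  sites <- extract_chl_sites(st$model, st$sites)
  map <- st$maps[[1]]
  c7 <- assign_bins(lapply(sites, function(s)
    scan_cone(map, s, "C7", radial = FALSE)))
  c2 <- assign_bins(lapply(sites, function(s)
    scan_cone(map, s, "C2", radial = FALSE)))
  null <- build_null(c7)
  dec <- vapply(c2, function(s)
    test_substituent(s, null, min_run = 3)$decision, "")
  truth <- st$truth$substituent[vapply(sites, function(s) s$site_name, "")]
  expect_true(all(dec[truth == "formyl"] == "reject"))
  expect_true(all(dec[truth == "methyl"] == "fail-to-reject"))
})
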