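# Synthetic ESP maps and model fixtures with known ground truth.
#
# The simulator emulates what the analysis needs from a cryo-EM ESP map:
# atoms rendered as element-weighted Gaussians whose width combines a
# resolution term with the atomic B-factor, per-component occupancy scaling,
# attenuation of the formyl O amplitude (the partial negative charge of a
# formyl oxygen reduces its ESP visibility), and additive Gaussian noise.
# It does not emulate CTF effects, reconstruction artifacts, or solvent.

# element weights: atomic number as a proxy for ESP scattering amplitude
.element_weight <- c(H = 1, C = 6, N = 7, O = 8, MG = 12, P = 15, S = 16, FE = 26)

#' Idealized chlorophyll fixture
#'
#' Builds a planar, idealized chlorophyll-like molecule: central Mg, four
#' pyrrole N, twenty macrocycle carbons on a ring (IUPAC-style numbering
#' C1..C20), substituent anchor atoms C21 and C71 bonded to C2 and C7 at
#' 1.50 A, and distal substituent atoms: three H proxies (methyl) at both
#' positions for Chl a, or a single formyl O (1.22 A, 120 degrees to the
#' C21-C2 bond, in plane) at C2 for Chl f. The C2 and C7 neighbourhoods are
#' congruent by construction, which is what makes C7 methyl scans a valid
#' null for C2.
#'
#' @param chl_type "a" (methyl at C2) or "f" (formyl at C2).
#' @param chain_id,residue_number Identity given to the residue.
#' @param b_factor Uniform atomic B-factor (A^2).
#' @return A `structure_model` with one CLA or F6C residue.
#' @export
make_chl_fixture <- function(chl_type = c("a", "f"), chain_id = "X",
                             residue_number = 1L, b_factor = 20) {
  chl_type <- match.arg(chl_type)
  deg <- pi / 180
  pos <- list(); elem <- character(); nm <- character()
  add <- function(name, element, p) {
    pos[[length(pos) + 1L]] <<- p
    nm[length(nm) + 1L] <<- name
    elem[length(elem) + 1L] <<- element
  }
  add("MG", "MG", c(0, 0, 0))
  for (i in 0:3)
    add(c("NA", "NB", "NC", "ND")[i + 1], "N",
        2.05 * c(cos((36 + 90 * i) * deg), sin((36 + 90 * i) * deg), 0))
  for (k in 1:20)
    add(paste0("C", k), "C",
        4.2 * c(cos(18 * k * deg), sin(18 * k * deg), 0))
  # substituent anchors: radially outward from C2 and C7
  p_c2 <- 4.2 * c(cos(36 * deg), sin(36 * deg), 0)
  p_c7 <- 4.2 * c(cos(126 * deg), sin(126 * deg), 0)
  a2 <- unit3(p_c2); a7 <- unit3(p_c7)   # outward bond axes (in plane)
  p_c21 <- p_c2 + 1.50 * a2
  p_c71 <- p_c7 + 1.50 * a7
  add("C21", "C", p_c21)
  add("C71", "C", p_c71)
  # local frames congruent at C2 and C7: u = in-plane, v = plane normal
  frame <- function(axis) {
    u <- c(-axis[2], axis[1], 0)         # in-plane perpendicular
    list(u = u, v = c(0, 0, 1))
  }
  methyl_h <- function(anchor, axis, fr, tag) {
    # tetrahedral H: 109.5 deg to the anchor->ring bond = 70.5 deg off axis
    th <- 70.5 * deg
    for (j in 0:2) {
      phi <- j * 120 * deg
      d <- cos(th) * axis + sin(th) * (cos(phi) * fr$u + sin(phi) * fr$v)
      add(sprintf("H%s%d", tag, j + 1), "H", anchor + 1.09 * d)
    }
  }
  f2 <- frame(a2); f7 <- frame(a7)
  if (chl_type == "a") {
    methyl_h(p_c21, a2, f2, "21")
  } else {
    # formyl O: 120 deg to the C21->C2 bond, i.e. 60 deg off the outward axis
    th <- 60 * deg
    add("O21", "O", p_c21 + 1.22 * (cos(th) * a2 + sin(th) * f2$u))
  }
  methyl_h(p_c71, a7, f7, "71")
  n <- length(nm)
  structure_model(data.frame(
    element = elem, name = nm,
    residue_name = if (chl_type == "a") "CLA" else "F6C",
    chain_id = chain_id, residue_number = as.integer(residue_number),
    x = vapply(pos, `[`, 0, 1), y = vapply(pos, `[`, 0, 2),
    z = vapply(pos, `[`, 0, 3),
    b_factor = rep(b_factor, n), occupancy = rep(1, n),
    stringsAsFactors = FALSE),
    source_id = paste0("synthetic-chl-", chl_type))
}

#' Idealized alpha-helix fixture
#'
#' Poly-alanine backbone (N, CA, C, O) on standard helix parameters
#' (rise 1.5 A, 100 degrees per residue, CA radius 2.3 A); used as a
#' protein-like component in occupancy simulations.
#'
#' @param n_res Number of residues.
#' @param chain_id Chain identifier.
#' @param b_factor Uniform B-factor (A^2).
#' @return A `structure_model`.
#' @export
make_helix_fixture <- function(n_res = 12L, chain_id = "H", b_factor = 30) {
  deg <- pi / 180
  rows <- list()
  for (i in seq_len(n_res)) {
    phi <- (i - 1) * 100 * deg
    z <- (i - 1) * 1.5
    ca <- c(2.3 * cos(phi), 2.3 * sin(phi), z)
    nn <- c(1.6 * cos(phi - 28 * deg), 1.6 * sin(phi - 28 * deg), z - 0.9)
    cc <- c(1.7 * cos(phi + 26 * deg), 1.7 * sin(phi + 26 * deg), z + 0.5)
    oo <- cc + c(1.05 * cos(phi + 26 * deg), 1.05 * sin(phi + 26 * deg), 0.4)
    rows[[i]] <- data.frame(
      element = c("N", "C", "C", "O"), name = c("N", "CA", "C", "O"),
      residue_name = "ALA", chain_id = chain_id, residue_number = i,
      x = c(nn[1], ca[1], cc[1], oo[1]), y = c(nn[2], ca[2], cc[2], oo[2]),
      z = c(nn[3], ca[3], cc[3], oo[3]),
      b_factor = b_factor, occupancy = 1, stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), source_id = "synthetic-helix")
}

#' Simulate an ESP map from an atomic model
#'
#' Renders each atom as a 3-D Gaussian of weight
#' `Z * occupancy * component_scale` (Z = atomic number) and width
#' `sigma^2 = (resolution / (pi * sqrt(2)))^2 + B / (8 pi^2)` (resolution
#' low-pass proxy added in quadrature with the B-factor spread), attenuates
#' the formyl O amplitude, adds i.i.d. Gaussian noise, and rescales the
#' result to map-sigma units.
#'
#' @param model A `structure_model`.
#' @param resolution Nominal resolution in Angstrom; must exceed
#'   `2 * voxel_size`.
#' @param voxel_size Voxel edge (A).
#' @param padding Box padding beyond the model extent (A).
#' @param occupancy_scale Optional named numeric vector of per-component
#'   occupancy multipliers keyed `"chain:resnum"`; atoms also carry their own
#'   occupancy column.
#' @param noise_sigma Noise level in map-sigma units: the noise sd is
#'   `noise_sigma * sd(noiseless map)` (absolute when the noiseless map is
#'   empty, giving pure-noise calibration maps).
#' @param formyl_o_attenuation Multiplier in `[0,1]` applied to the formyl O
#'   amplitude of Chl f residues (default 0.7).
#' @param seed Integer RNG seed; mandatory when `noise_sigma > 0`.
#' @param box Optional list(origin, dim) fixing the grid; atoms falling
#'   outside it are an error.
#' @param rescale If `TRUE` (default) return the map in map-sigma units;
#'   `FALSE` returns raw simulated amplitudes (useful for amplitude and
#'   mass-conservation checks).
#' @return list with `map` (rescaled `esp_map`) and `truth` (`sim_truth`:
#'   per-chlorophyll substituent labels, per-component occupancy, seed).
#' @export
simulate_esp_map <- function(model, resolution = 2.0, voxel_size = 0.8,
                             padding = 5, occupancy_scale = NULL,
                             noise_sigma = 0, formyl_o_attenuation = 0.7,
                             seed = NULL, box = NULL, rescale = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  if (resolution <= 2 * max(voxel_size))
    stop("resolution must exceed 2 * voxel_size (Nyquist)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (noise_sigma > 0 && is.null(seed))
    stop("seed is mandatory when noise_sigma > 0")
  if (formyl_o_attenuation < 0 || formyl_o_attenuation > 1)
    stop("formyl_o_attenuation must be in [0, 1]")
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (is.null(box)) {
    origin <- apply(xyz, 2, min) - padding
    upper <- apply(xyz, 2, max) + padding
    dims <- pmax(ceiling((upper - origin) / voxel_size) + 1L, 2L)
  } else {
    origin <- box$origin; dims <- box$dim
    upper <- origin + (dims - 1) * voxel_size
    out <- xyz[, 1] < origin[1] | xyz[, 1] > upper[1] |
           xyz[, 2] < origin[2] | xyz[, 2] > upper[2] |
           xyz[, 3] < origin[3] | xyz[, 3] > upper[3]
    if (any(out)) stop(sum(out), " atom(s) outside the requested box")
  }
  grid <- array(0, dim = dims)
  comp_key <- paste(a$chain_id, a$residue_number, sep = ":")
  occ <- a$occupancy
  if (!is.null(occupancy_scale)) {
    m <- match(comp_key, names(occupancy_scale))
    occ <- occ * ifelse(is.na(m), 1, occupancy_scale[m])
  }
  w <- .element_weight[toupper(a$element)]
  w[is.na(w)] <- 6  # unlisted elements rendered carbon-like
  is_formyl_o <- a$residue_name == "F6C" & a$name == "O21"
  w <- w * occ * ifelse(is_formyl_o, formyl_o_attenuation, 1)
  sig_res <- resolution / (pi * sqrt(2))
  sig <- sqrt(sig_res^2 + a$b_factor / (8 * pi^2))
  amp <- w / ((2 * pi)^1.5 * sig^3)
  ax_coord <- function(k, n) origin[k] + (seq_len(n) - 1) * voxel_size
  gx_all <- ax_coord(1, dims[1]); gy_all <- ax_coord(2, dims[2])
  gz_all <- ax_coord(3, dims[3])
  for (i in seq_len(nrow(a))) {
    if (w[i] <= 0) next
    cut <- 4 * sig[i]
    rng <- function(ax, c0) which(ax >= c0 - cut & ax <= c0 + cut)
    ix <- rng(gx_all, xyz[i, 1]); iy <- rng(gy_all, xyz[i, 2])
    iz <- rng(gz_all, xyz[i, 3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    g1 <- function(ax, c0) exp(-(ax - c0)^2 / (2 * sig[i]^2))
    gx <- g1(gx_all[ix], xyz[i, 1]); gy <- g1(gy_all[iy], xyz[i, 2])
    gz <- g1(gz_all[iz], xyz[i, 3])
    grid[ix, iy, iz] <- grid[ix, iy, iz] + amp[i] * (gx %o% gy %o% gz)
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    s0 <- sqrt(mean((grid - mean(grid))^2))
    noise_sd <- if (s0 > 0) noise_sigma * s0 else noise_sigma
    grid <- grid + stats::rnorm(length(grid), sd = noise_sd)
  }
  raw <- esp_map(grid, voxel_size, origin)
  truth <- sim_truth(model, occ, seed)
  list(map = if (rescale) rescale_map(raw) else raw, truth = truth)
}

# ground-truth record for a simulated model
sim_truth <- function(model, occ = model$atoms$occupancy, seed = NULL) {
  a <- model$atoms
  key <- paste(a$chain_id, a$residue_number, sep = ":")
  chl <- a$residue_name %in% c("CLA", "F6C")
  labels <- vapply(unique(key[chl]), function(k) {
    if (a$residue_name[key == k][1] == "F6C") "formyl" else "methyl"
  }, character(1))
  occ_by_comp <- vapply(unique(key), function(k) occ[key == k][1], numeric(1))
  structure(list(substituent = labels, occupancy = occ_by_comp, seed = seed),
            class = "sim_truth")
}

#' Simulate a study battery of chlorophylls with known substituents
#'
#' Places `n_chl` randomly oriented chlorophyll fixtures at random,
#' non-clashing positions in a box, draws `round(f_fraction * n_chl)` of
#' them as Chl f (formyl) and the rest as Chl a (methyl), and renders one
#' noisy ESP map per requested resolution over the identical model so
#' resolution series are directly comparable. Fully reproducible from
#' `seed`.
#'
#' @param n_chl Number of chlorophylls (>= 4).
#' @param f_fraction Fraction labelled formyl, in `[0,1]`.
#' @param resolutions Numeric vector of map resolutions (A).
#' @param noise_sigma Noise level in map-sigma units.
#' @param seed Integer seed.
#' @param voxel_size Voxel edge (A).
#' @param min_separation Minimum Mg-Mg distance between placements (A).
#' @param occupancy Uniform chlorophyll occupancy in `[0,1]`.
#' @param max_tries Placement rejection-sampling cap per chlorophyll.
#' @return list with `maps` (named by resolution), `model`, `truth`
#'   (`sim_truth`), `sites` (site table data.frame naming each chlorophyll
#'   S1..Sn).
#' @export
simulate_study <- function(n_chl, f_fraction, resolutions = 2.0,
                           noise_sigma = 0.1, seed = 1L, voxel_size = 0.8,
                           min_separation = 13, occupancy = 1,
                           max_tries = 200L) {
  if (n_chl < 4) stop("n_chl must be >= 4")
  if (f_fraction < 0 || f_fraction > 1) stop("f_fraction must be in [0, 1]")
  set.seed(seed)
  side <- ceiling(n_chl^(1 / 3)) * min_separation + min_separation
  centers <- matrix(NA_real_, n_chl, 3)
  for (i in seq_len(n_chl)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3, 0, side)
      if (i == 1 ||
          min(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                 2, p)^2))) >= min_separation) {
        centers[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place chlorophyll ", i,
                      " without clashes after ", max_tries, " tries")
  }
  n_f <- round(f_fraction * n_chl)
  formyl_idx <- sample(n_chl, n_f)
  parts <- vector("list", n_chl)
  for (i in seq_len(n_chl)) {
    type <- if (i %in% formyl_idx) "f" else "a"
    fx <- make_chl_fixture(type, chain_id = "X", residue_number = i)
    # random proper rotation via QR of a Gaussian matrix
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    xyz <- as.matrix(fx$atoms[, c("x", "y", "z")]) %*% t(R)
    fx$atoms[, c("x", "y", "z")] <-
      sweep(xyz, 2, centers[i, ], "+")
    fx$atoms$occupancy <- occupancy
    parts[[i]] <- fx$atoms
  }
  model <- structure_model(do.call(rbind, parts), source_id = "synthetic-study")
  maps <- list()
  for (j in seq_along(resolutions)) {
    sub_seed <- (seed * 1000L + j) %% .Machine$integer.max
    sim <- simulate_esp_map(model, resolution = resolutions[j],
                            voxel_size = voxel_size, padding = 5,
                            noise_sigma = noise_sigma, seed = sub_seed)
    maps[[as.character(resolutions[j])]] <- sim$map
  }
  a <- model$atoms
  chl_rows <- !duplicated(paste(a$chain_id, a$residue_number)) &
              a$residue_name %in% c("CLA", "F6C")
  sites <- data.frame(chain = a$chain_id[chl_rows],
                      resnum = a$residue_number[chl_rows],
                      site_name = paste0("S", a$residue_number[chl_rows]),
                      stringsAsFactors = FALSE)
  truth <- sim_truth(model, seed = seed)
  names(truth$substituent) <- paste0("S", seq_len(n_chl))
  list(maps = maps, model = model, truth = truth, sites = sites)
}
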