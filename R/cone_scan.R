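# Cone-scan discrimination of formyl vs methyl substituents.
#
# Each chlorophyll is least-squares aligned onto an ideal reference via the
# first substituent atom plus its three coplanar ring neighbours; rescaled
# ESP is then sampled on a cone of candidate distal-atom positions around
# the extended ring-carbon -> substituent-carbon axis, every `angular_step`
# degrees at the expected bond length. C7 methyl scans supply a per-angle
# normal null; a C2 scan exceeding mu + k*sd (k = 3, one-sided significance
# about 0.002) rejects "methyl" in favour of "formyl-consistent".

#' Cone-scan geometry parameters
#'
#' @param half_angle Cone half-angle in degrees measured from the extended
#'   ring-carbon -> substituent-carbon axis (default 55: close to the
#'   expected off-axis angle of a formyl oxygen or methyl hydrogen).
#' @param probe_radius Probe distance from the first substituent atom in
#'   Angstrom (default 1.22, the carbonyl C=O bond length).
#' @param angular_step Azimuthal step in degrees; must divide 360.
#' @param radial_increment Step of the per-angle radial profile (A).
#' @return A `cone_geometry` list.
#' @export
cone_geometry <- function(half_angle = 55, probe_radius = 1.22,
                          angular_step = 5, radial_increment = 0.01) {
  if (half_angle <= 0 || half_angle >= 90) stop("half_angle must be in (0, 90)")
  if (angular_step <= 0 || 360 %% angular_step != 0)
    stop("angular_step must divide 360")
  if (radial_increment <= 0) stop("radial_increment must be > 0")
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  structure(list(half_angle = half_angle, probe_radius = probe_radius,
                 angular_step = angular_step,
                 radial_increment = radial_increment),
            class = "cone_geometry")
}

# alignment quartets: first substituent atom, its ring carbon, two flanking
# ring atoms (the unique chemically coplanar set)
.align_atoms <- list(C2 = c("C21", "C2", "C1", "C3"),
                     C7 = c("C71", "C7", "C6", "C8"))

# ideal reference chlorophyll coordinates (named matrix), computed once
.reference_chl_atoms <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) {
      m <- make_chl_fixture("a")
      xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
      rownames(xyz) <- m$atoms$name
      ref <<- xyz
    }
    ref
  }
})

#' The ideal reference chlorophyll
#'
#' @return Named coordinate matrix of the idealized chlorophyll onto which
#'   sites are aligned for cone scanning.
#' @export
reference_chl <- function() .reference_chl_atoms()

#' Align a chlorophyll site onto the ideal reference
#'
#' Least-squares rigid fit of the four alignment atoms (for C2: C21, C2,
#' C1, C3; for C7: C71, C7, C6, C8) onto the reference.
#'
#' @param site A `chl_site`.
#' @param substituent "C2" or "C7".
#' @return `rigid_transform` mapping site coordinates into the reference
#'   frame; `$rmsd` is the fit RMSD (A).
#' @export
align_to_reference <- function(site, substituent = c("C2", "C7")) {
  substituent <- match.arg(substituent)
  quartet <- .align_atoms[[substituent]]
  miss <- setdiff(quartet, rownames(site$atoms))
  if (length(miss))
    stop("site ", site$site_name, ": missing alignment atom(s) ",
         paste(miss, collapse = ", "))
  ref <- reference_chl()
  kabsch(site$atoms[quartet, , drop = FALSE], ref[quartet, , drop = FALSE])
}

# probe directions in the reference frame for one substituent
.cone_frame <- function(substituent) {
  ref <- reference_chl()
  q <- .align_atoms[[substituent]]
  apex <- ref[q[1], ]                       # first substituent atom
  axis <- unit3(ref[q[1], ] - ref[q[2], ])  # ring carbon -> substituent, extended
  flank <- ref[q[3], ] - ref[q[2], ]        # azimuth zero from the first flank atom
  u <- unit3(flank - sum(flank * axis) * axis)
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(apex = apex, axis = axis, u = u, v = v)
}

#' Extract an azimuthal cone-scan profile
#'
#' Samples the rescaled ESP map on the probe cone of a substituent: apex at
#' the first substituent atom, axis along the extended ring-carbon ->
#' substituent bond, one sample per azimuth at `probe_radius`, plus
#' (optionally) the full radial profile from the apex outward.
#'
#' @param map A rescaled `esp_map`.
#' @param site A `chl_site`.
#' @param substituent "C2" or "C7".
#' @param geometry A `cone_geometry`.
#' @param radial If `TRUE`, also record per-angle radial profiles at
#'   `radial_increment` spacing from the apex to the probe radius.
#' @return A `cone_scan`: `site_name`, `substituent`, `angles` (degrees),
#'   `values` (map-sigma units), `radial_profiles` (angle x radius matrix or
#'   `NULL`), `mg_local_resolution`, `bin_id` (`NA` until [assign_bins()]),
#'   `fit_rmsd` (alignment RMSD, A).
#' @export
scan_cone <- function(map, site, substituent = c("C2", "C7"),
                      geometry = cone_geometry(), radial = TRUE) {
  substituent <- match.arg(substituent)
  stopifnot(inherits(map, "esp_map"), inherits(site, "chl_site"))
  if (!map$rescaled) stop("scan_cone requires a rescaled map")
  tr <- align_to_reference(site, substituent)
  back <- invert_transform(tr)              # reference frame -> map frame
  fr <- .cone_frame(substituent)
  g <- geometry
  angles <- seq(0, 360 - g$angular_step, by = g$angular_step)
  phi <- angles * pi / 180
  alpha <- g$half_angle * pi / 180
  dirs <- outer(cos(phi), fr$u) + outer(sin(phi), fr$v)
  dirs <- cos(alpha) * matrix(fr$axis, length(phi), 3, byrow = TRUE) +
          sin(alpha) * dirs
  pts_ref <- matrix(fr$apex, length(phi), 3, byrow = TRUE) +
             g$probe_radius * dirs
  values <- tryCatch(
    sample_map(map, apply_transform(back, pts_ref)),
    error = function(e) stop("site ", site$site_name, " (", substituent,
                             "): ", conditionMessage(e)))
  profiles <- NULL
  if (radial) {
    radii <- seq(0, g$probe_radius, by = g$radial_increment)
    n_r <- length(radii)
    big <- matrix(fr$apex, length(phi) * n_r, 3, byrow = TRUE) +
           dirs[rep(seq_along(phi), each = n_r), ] * rep(radii, length(phi))
    vals <- tryCatch(
      sample_map(map, apply_transform(back, big)),
      error = function(e) stop("site ", site$site_name, " (", substituent,
                               "): ", conditionMessage(e)))
    profiles <- matrix(vals, nrow = length(phi), byrow = TRUE,
                       dimnames = list(angles, format(radii)))
  }
  structure(list(site_name = site$site_name, substituent = substituent,
                 angles = angles, values = values,
                 radial_profiles = profiles,
                 mg_local_resolution = site$local_resolution,
                 bin_id = NA_character_, fit_rmsd = tr$rmsd),
            class = "cone_scan")
}

#' @export
print.cone_scan <- function(x, ...) {
  cat(sprintf("cone_scan %s %s: %d angles, max %.2f sigma at %d deg (bin %s)\n",
              x$site_name, x$substituent, length(x$angles),
              max(x$values), x$angles[which.max(x$values)], x$bin_id))
  invisible(x)
}

#' Bin scans by local resolution of the central Mg
#'
#' Two bins split at the cutoff (inclusive on the low side: a scan exactly
#' at the cutoff goes to the "low" bin); if no scan carries a local
#' resolution, all go to a single bin `"all"`. Mixed presence/absence is an
#' error.
#'
#' @param scans List of `cone_scan` objects.
#' @param resolution_cutoff Cutoff in Angstrom (default 2.91, a typical
#'   global map resolution).
#' @return The scans with `bin_id` set ("low", "high" or "all").
#' @export
assign_bins <- function(scans, resolution_cutoff = 2.91) {
  has <- vapply(scans, function(s) !is.na(s$mg_local_resolution), logical(1))
  if (any(has) && !all(has))
    stop("mixed presence/absence of local resolution across scans")
  lapply(scans, function(s) {
    s$bin_id <- if (!any(has)) "all"
                else if (s$mg_local_resolution <= resolution_cutoff) "low"
                else "high"
    s
  })
}

#' Build the methyl null model from C7 scans
#'
#' Per resolution bin and per azimuth, the mean and unbiased standard
#' deviation of the C7 methyl scan values across chlorophylls; the
#' rejection threshold is `mu + k * sd` (k = 3 corresponds to a one-sided
#' nominal significance of about 0.002 under normality).
#'
#' @param scans List of binned C7 `cone_scan` objects (>= 2 per bin).
#' @param k Threshold multiplier (default 3).
#' @param significance Nominal per-angle one-sided level recorded alongside
#'   (default 0.002).
#' @return A `null_model`: per-bin matrices of `mu`, `sd`, `threshold` by
#'   angle, with `n_scans`, `k`, `significance`.
#' @export
build_null <- function(scans, k = 3, significance = 0.002) {
  if (!length(scans)) stop("no scans supplied")
  if (any(vapply(scans, function(s) s$substituent, "") != "C7"))
    stop("the null model is built from C7 (methyl) scans only")
  bins <- vapply(scans, function(s) s$bin_id, "")
  if (anyNA(bins)) stop("scans must be binned first (assign_bins)")
  angles <- scans[[1]]$angles
  if (!all(vapply(scans, function(s) identical(s$angles, angles), TRUE)))
    stop("scans have inconsistent angle grids")
  out <- list()
  for (b in unique(bins)) {
    vals <- do.call(rbind, lapply(scans[bins == b], function(s) s$values))
    if (nrow(vals) < 2) stop("bin '", b, "' has fewer than 2 C7 scans")
    mu <- colMeans(vals)
    sd <- apply(vals, 2, stats::sd)   # unbiased (n-1)
    out[[b]] <- list(mu = mu, sd = sd, threshold = mu + k * sd,
                     n_scans = nrow(vals))
  }
  structure(list(bins = out, angles = angles, k = k,
                 significance = significance),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("null_model (mu + ", x$k, "*sd, nominal one-sided p < ",
      x$significance, "):\n", sep = "")
  for (b in names(x$bins))
    cat(sprintf("  bin %-5s n = %d, mean threshold %.3f sigma\n", b,
                x$bins[[b]]$n_scans, mean(x$bins[[b]]$threshold)))
  invisible(x)
}

# longest circular run of TRUE in a logical vector
.max_circular_run <- function(e) {
  n <- length(e)
  if (!any(e)) return(0L)
  if (all(e)) return(n)
  d <- rle(c(e, e))
  max(d$lengths[d$values])
}

#' Test a C2 substituent against the methyl null
#'
#' Rejects "methyl" (calls the scan formyl-consistent) when the C2 profile
#' strictly exceeds the per-angle threshold in a wrap-around-aware run of at
#' least `min_run` consecutive azimuths.
#'
#' @param scan A binned C2 `cone_scan`.
#' @param null A `null_model` containing the scan's bin.
#' @param min_run Required consecutive-angle run length (default 1).
#' @return A `substituent_test`: `site_name`, `decision` ("reject" =
#'   formyl-consistent, or "fail-to-reject"), `exceed_angles`, `min_run`.
#' @export
test_substituent <- function(scan, null, min_run = 1L) {
  stopifnot(inherits(scan, "cone_scan"), inherits(null, "null_model"))
  if (is.na(scan$bin_id) || !scan$bin_id %in% names(null$bins))
    stop("scan bin '", scan$bin_id, "' not present in the null model")
  if (!identical(scan$angles, null$angles))
    stop("scan and null model use different angle grids")
  thr <- null$bins[[scan$bin_id]]$threshold
  exceed <- scan$values > thr            # strict inequality
  run <- .max_circular_run(exceed)
  structure(list(site_name = scan$site_name,
                 decision = if (run >= min_run) "reject" else "fail-to-reject",
                 exceed_angles = scan$angles[exceed],
                 min_run = as.integer(min_run)),
            class = "substituent_test")
}

#' @export
print.substituent_test <- function(x, ...) {
  cat(sprintf("substituent_test %s: %s (%d exceeding angle(s), min_run %d)\n",
              x$site_name,
              if (x$decision == "reject") "reject null (formyl-consistent)"
              else "fail to reject (methyl-consistent)",
              length(x$exceed_angles), x$min_run))
  invisible(x)
}

#' Write cone scans as TSV
#'
#' One row per site x angle with the scan value and bin.
#' @param scans List of `cone_scan` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scans, path) {
  rows <- do.call(rbind, lapply(scans, function(s)
    data.frame(site_name = s$site_name, substituent = s$substituent,
               angle = s$angles, value = s$values, bin_id = s$bin_id,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a null model as JSON
#' @param null A `null_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_null_model <- function(null, path) {
  obj <- list(k = null$k, significance = null$significance,
              angles = null$angles,
              bins = lapply(null$bins, function(b)
                list(n_scans = b$n_scans, mu = unname(b$mu),
                     sd = unname(b$sd), threshold = unname(b$threshold))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
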