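# Chemical environment of chlorophyll sites: axial ligation of the central
# Mg, hydrogen-bond donors to the (actual or hypothetical) C2 formyl oxygen,
# and the combined site-specificity call.
#
# Chl a strongly favours His axial ligation (about 70% of sites) while
# Chl f disfavours it, and Chl f sites typically place an H-bond donor
# near the C2 formyl oxygen; both regularities feed the classification.

# residue codes treated as lipid/cofactor neighbourhood
.lipid_cofactor_codes <- c("LHG", "LMG", "LMT", "BCR", "PQN", "SQD", "DGD",
                           "MGD", "SF4", "FES", "CLA", "F6C", "BDM")
# protein O atoms that cannot donate (carbonyl / carboxylate)
.acceptor_only_o <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2")

#' Find the axial ligand of a chlorophyll Mg
#'
#' Nearest N or O atom to the central Mg within the cutoff, excluding the
#' chlorophyll's own atoms, classified by chemical identity.
#'
#' @param model A `structure_model`.
#' @param site A `chl_site`.
#' @param cutoff Mg-ligand distance cutoff in Angstrom (default 3.0, the
#'   standard upper bound for Mg coordination).
#' @return An `axial_ligand`: `site_name`, `ligand_atom` (one-row data.frame
#'   or `NULL`), `distance` (A, `NA` if none), `ligand_class` in
#'   His-sidechain / backbone-carbonyl / water / other-sidechain /
#'   lipid-or-cofactor / none-found.
#' @export
find_axial_ligand <- function(model, site, cutoff = 3.0) {
  stopifnot(inherits(model, "structure_model"), inherits(site, "chl_site"))
  a <- model$atoms
  cand <- a$element %in% c("N", "O") &
          !(a$chain_id == site$chain_id &
            a$residue_number == site$residue_number)
  if (!any(cand))
    return(.axial_none(site$site_name))
  d <- sqrt(rowSums(sweep(as.matrix(a[cand, c("x", "y", "z")]), 2, site$mg)^2))
  ok <- d <= cutoff
  if (!any(ok)) return(.axial_none(site$site_name))
  idx <- which(cand)[ok][which.min(d[ok])]
  atom <- a[idx, ]
  cls <- .classify_ligand(atom)
  structure(list(site_name = site$site_name, ligand_atom = atom,
                 distance = min(d[ok]), ligand_class = cls),
            class = "axial_ligand")
}

.axial_none <- function(site_name)
  structure(list(site_name = site_name, ligand_atom = NULL,
                 distance = NA_real_, ligand_class = "none-found"),
            class = "axial_ligand")

.classify_ligand <- function(atom) {
  res <- atom$residue_name; nm <- atom$name
  if (res == "HIS" && nm %in% c("NE2", "ND1")) return("His-sidechain")
  if (res %in% c("HOH", "WAT")) return("water")
  if (res %in% .lipid_cofactor_codes || grepl("^PG", res))
    return("lipid-or-cofactor")
  if (nm %in% c("O", "OXT")) return("backbone-carbonyl")
  "other-sidechain"
}

#' @export
print.axial_ligand <- function(x, ...) {
  if (x$ligand_class == "none-found")
    cat(sprintf("axial_ligand %s: none found\n", x$site_name))
  else
    cat(sprintf("axial_ligand %s: %s (%s %s:%d %s) at %.2f A\n", x$site_name,
                x$ligand_class, x$ligand_atom$residue_name,
                x$ligand_atom$chain_id, x$ligand_atom$residue_number,
                x$ligand_atom$name, x$distance))
  invisible(x)
}

#' Hypothetical formyl-O rotamer positions at C2
#'
#' For a site without a modeled formyl oxygen, constructs the two in-plane
#' formyl rotamer oxygen positions: 1.22 A from C21 at 120 degrees to the
#' C21-C2 bond, projected into the macrocycle least-squares plane.
#'
#' @param site A `chl_site` with C2 and C21 atoms.
#' @return 2 x 3 matrix of candidate O positions.
#' @export
formyl_rotamer_positions <- function(site) {
  need <- c("C2", "C21")
  miss <- setdiff(need, rownames(site$atoms))
  if (length(miss))
    stop("site ", site$site_name, ": missing atom(s) ",
         paste(miss, collapse = ", "))
  ring <- intersect(c(paste0("C", 1:20), "NA", "NB", "NC", "ND"),
                    rownames(site$atoms))
  plane <- fit_plane(site$atoms[ring, , drop = FALSE])
  b <- unit3(site$atoms["C21", ] - site$atoms["C2", ])   # bond, outward
  b <- unit3(b - sum(b * plane$normal) * plane$normal)   # in-plane component
  w <- c(plane$normal[2] * b[3] - plane$normal[3] * b[2],
         plane$normal[3] * b[1] - plane$normal[1] * b[3],
         plane$normal[1] * b[2] - plane$normal[2] * b[1])
  th <- 60 * pi / 180   # 120 deg to C21->C2 = 60 deg to the outward axis
  d1 <- cos(th) * b + sin(th) * w
  d2 <- cos(th) * b - sin(th) * w
  rbind(site$atoms["C21", ] + 1.22 * d1,
        site$atoms["C21", ] + 1.22 * d2)
}

#' Search for H-bond donors to the C2 formyl oxygen
#'
#' Acceptor positions are the modeled formyl O when the site is Chl f and
#' the atom is present, otherwise the two hypothetical in-plane rotamer
#' positions from [formyl_rotamer_positions()]. Donors are N/O atoms with a
#' donatable proton (backbone amide N, sidechain N, hydroxyl O, water O,
#' lipid O; carbonyl and carboxylate O excluded) whose heavy-atom distance
#' to any acceptor lies in the window. Hydrogens are not required: at
#' typical cryo-EM resolutions they are unresolved, so the test is
#' heavy-atom distance only.
#'
#' @param model A `structure_model`.
#' @param site A `chl_site`.
#' @param window Length-2 numeric: allowed donor-acceptor distance (A),
#'   default `c(2.4, 3.5)`.
#' @return List of `hbond_donor_hit`: `donor_atom` (one-row data.frame),
#'   `acceptor_position`, `distance` (A), `donor_kind` (sidechain /
#'   backbone-amide / water).
#' @export
find_c2_hbond_donors <- function(model, site, window = c(2.4, 3.5)) {
  stopifnot(inherits(model, "structure_model"), inherits(site, "chl_site"))
  if (!"C21" %in% rownames(site$atoms))
    stop("site ", site$site_name, ": missing C21 atom")
  acc <- if (site$chl_type == "f" && "O21" %in% rownames(site$atoms))
    rbind(site$atoms["O21", ]) else formyl_rotamer_positions(site)
  a <- model$atoms
  own <- a$chain_id == site$chain_id & a$residue_number == site$residue_number
  can_donate <- (a$element == "N" |
                 (a$element == "O" & !(a$name %in% .acceptor_only_o))) & !own
  idx <- which(can_donate)
  if (!length(idx)) return(list())
  pts <- as.matrix(a[idx, c("x", "y", "z")])
  hits <- list()
  for (j in seq_len(nrow(acc))) {
    d <- sqrt(rowSums(sweep(pts, 2, acc[j, ])^2))
    sel <- d >= window[1] & d <= window[2]
    for (i in which(sel)) {
      atom <- a[idx[i], ]
      kind <- if (atom$residue_name %in% c("HOH", "WAT")) "water"
              else if (atom$name == "N") "backbone-amide"
              else "sidechain"
      hits[[length(hits) + 1L]] <- structure(
        list(donor_atom = atom, acceptor_position = acc[j, ],
             distance = unname(d[i]), donor_kind = kind),
        class = "hbond_donor_hit")
    }
  }
  # deduplicate donors hitting both rotamers: keep the closer approach
  if (length(hits) > 1) {
    key <- vapply(hits, function(h)
      paste(h$donor_atom$chain_id, h$donor_atom$residue_number,
            h$donor_atom$name), "")
    keep <- vapply(split(seq_along(hits), key), function(ii)
      ii[which.min(vapply(hits[ii], function(h) h$distance, 0))], 0L)
    hits <- hits[sort(keep)]
  }
  hits
}

#' @export
print.hbond_donor_hit <- function(x, ...) {
  cat(sprintf("hbond_donor %s %s:%d %s (%s) at %.2f A\n",
              x$donor_atom$residue_name, x$donor_atom$chain_id,
              x$donor_atom$residue_number, x$donor_atom$name,
              x$donor_kind, x$distance))
  invisible(x)
}

#' Combine evidence into a site-specificity call
#'
#' Rule table:
#' * high-specificity-f: non-His axial ligand AND (cone-scan rejection with
#'   an H-bond donor found, OR homology support, i.e. the donor/site
#'   environment is conserved with a confirmed Chl f site in a related
#'   structure).
#' * low-specificity-f-candidate: no cone rejection, non-His ligand, no
#'   donor, sterically clash-free C2 neighbourhood, and located in an
#'   FRL-variable sequence region.
#' * a: otherwise.
#'
#' @param test A `substituent_test`.
#' @param ligand An `axial_ligand`.
#' @param donors List of `hbond_donor_hit`.
#' @param region_flags Named logical vector/list with
#'   `frl_variable_region`, `steric_clash_free` and optionally
#'   `homology_support` (default `FALSE`).
#' @return A `site_call`: `site_name`, `call`, `evidence` (named logicals).
#' @export
classify_site <- function(test, ligand, donors, region_flags) {
  if (is.null(test)) stop("missing substituent test evidence")
  if (is.null(ligand)) stop("missing axial ligand evidence")
  if (is.null(donors)) stop("missing donor evidence")
  rf <- as.list(region_flags)
  for (nm in c("frl_variable_region", "steric_clash_free"))
    if (is.null(rf[[nm]])) stop("missing region flag: ", nm)
  homology <- isTRUE(rf$homology_support)
  evidence <- c(
    cone_reject = test$decision == "reject",
    non_his_ligand = ligand$ligand_class != "His-sidechain",
    donor_found = length(donors) > 0,
    frl_variable_region = isTRUE(rf$frl_variable_region),
    steric_clash_free = isTRUE(rf$steric_clash_free),
    homology_support = homology)
  call <- if (evidence[["non_his_ligand"]] &&
              ((evidence[["cone_reject"]] && evidence[["donor_found"]]) ||
               homology)) {
    "high-specificity-f"
  } else if (!evidence[["cone_reject"]] && evidence[["non_his_ligand"]] &&
             !evidence[["donor_found"]] && evidence[["steric_clash_free"]] &&
             evidence[["frl_variable_region"]]) {
    "low-specificity-f-candidate"
  } else "a"
  structure(list(site_name = ligand$site_name, call = call,
                 evidence = evidence),
            class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf("site_call %s: %s [%s]\n", x$site_name, x$call,
              paste(names(x$evidence)[x$evidence], collapse = ", ")))
  invisible(x)
}
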