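# Atomic model container and model IO.
#
# A structure_model is a thin, ordered table of atoms (one row per atom)
# plus chain bookkeeping; all geometric operations in the package work on
# this table. Hetero components (chlorophylls CLA/F6C, Fe-S clusters SF4/FES,
# lipids, carotenoids) are first-class atoms, never dropped.

#' Construct a structure model
#'
#' @param atoms data.frame with columns `element`, `name`, `residue_name`,
#'   `chain_id`, `residue_number`, `x`, `y`, `z`, `b_factor`, `occupancy`.
#' @param source_id Free-text provenance label (e.g. an accession or
#'   "synthetic").
#' @return A `structure_model`: list with `atoms` (order preserved),
#'   `chains`, `source_id`.
#' @export
structure_model <- function(atoms, source_id = "") {
  req <- c("element", "name", "residue_name", "chain_id", "residue_number",
           "x", "y", "z", "b_factor", "occupancy")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms missing column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 chains = unique(as.character(atoms$chain_id)),
                 source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d chain(s) [%s]\n",
              x$source_id, nrow(x$atoms), length(x$chains),
              paste(x$chains, collapse = ",")))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param model A `structure_model`.
#' @param sel Optional row index/logical selection.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(model, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Read an atomic model (PDB or mmCIF)
#'
#' Parses with bio3d; all ATOM and HETATM records are retained (chlorophylls,
#' Fe-S clusters, lipids, carotenoids included).
#'
#' @param path File path.
#' @param format "auto" (by extension), "pdb" or "mmcif".
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no atoms parsed from ", path)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- gsub("[^A-Za-z].*", "", a$elety)  # fall back to first letters of name
  elem <- ifelse(is.na(elem) | elem == "",
                 substr(gsub("[0-9']", "", a$elety), 1, 1), elem)
  occ <- a$o; occ[is.na(occ)] <- 1
  b <- a$b; b[is.na(b)] <- 0
  structure_model(data.frame(
    element = toupper(trimws(elem)),
    name = trimws(a$elety),
    residue_name = trimws(a$resid),
    chain_id = as.character(a$chain),
    residue_number = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    b_factor = b,
    occupancy = pmin(pmax(occ, 0), 1),
    stringsAsFactors = FALSE), source_id = basename(path))
}

#' Write a model as PDB
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  het <- !(a$residue_name %in% bio3d::aa.table$aa3)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$residue_number, resid = a$residue_name,
                   chain = a$chain_id, elety = a$name,
                   o = a$occupancy, b = a$b_factor,
                   elesy = a$element)
  invisible(path)
}

# component codes recognised as chlorophyll; overridable in extract_chl_sites
.chl_codes <- c(a = "CLA", f = "F6C")

# atom-name synonyms: IUPAC ring numbering as used throughout this package
# (C1, C2, C3, C6, C7, C8, C21, C71) vs the PDB chemical-component dictionary
# naming for CLA/F6C (CHA..., C1A, C2A, CMA...). Each entry: ours -> candidates.
.chl_atom_synonyms <- list(
  MG  = c("MG"),
  NA_ = c("NA", "N A", "N21"),
  NB  = c("NB", "N B", "N22"),
  NC  = c("NC", "N C", "N23"),
  ND  = c("ND", "N D", "N24"),
  C1  = c("C1", "C1A"),
  C2  = c("C2", "C2A"),
  C3  = c("C3", "C3A"),
  C6  = c("C6", "C1B"),
  C7  = c("C7", "C2B"),
  C8  = c("C8", "C3B"),
  C21 = c("C21", "CMA", "C2M"),
  C71 = c("C71", "CMB", "C7M"),
  O21 = c("O21", "OMA", "O2A")   # formyl O on the C2 substituent (Chl f)
)

.match_chl_atom <- function(res_atoms, key) {
  cands <- .chl_atom_synonyms[[key]]
  hit <- which(res_atoms$name %in% cands)
  if (length(hit)) hit[1] else NA_integer_
}

#' Enumerate chlorophyll sites in a model
#'
#' Finds chlorophyll residues (component codes CLA for Chl a, F6C for Chl f
#' by default), resolves the macrocycle atoms needed downstream, and attaches
#' site names from a site table keyed on (chain, residue number) in the
#' standard PSI site nomenclature (A21, B7, ...). Chlorophylls absent from
#' the table get site name `"unassigned:<chain>:<num>"`; residues missing
#' the Mg or C2 atom are excluded with a warning.
#'
#' @param model A `structure_model`.
#' @param site_table data.frame with columns `chain`, `resnum`, `site_name`
#'   (or `NULL` for none); see [read_site_table()].
#' @param chl_codes Named character vector mapping chl type -> component code.
#' @param local_resolution Optional data.frame (`chain`, `resnum`,
#'   `resolution`) of per-chlorophyll local resolutions (Angstrom) at the
#'   central Mg.
#' @return List of `chl_site` objects: each has `site_name`, `chain_id`,
#'   `residue_number`, `chl_type` ("a", "f" or "unknown"), `mg` (Mg position),
#'   `atoms` (named coordinate matrix: ring atoms, substituent anchors, and
#'   the formyl O when modeled), `local_resolution` (NA if not supplied).
#' @export
extract_chl_sites <- function(model, site_table = NULL,
                              chl_codes = .chl_codes,
                              local_resolution = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  is_chl <- a$residue_name %in% chl_codes
  if (!any(is_chl)) return(list())
  key <- paste(a$chain_id, a$residue_number, sep = ":")
  sites <- list()
  for (k in unique(key[is_chl])) {
    res <- a[key == k & is_chl, , drop = FALSE]
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    chain <- parts[1]; resno <- as.integer(parts[2])
    need <- c("MG", "C2")
    idx <- vapply(c("MG", "NA_", "NB", "NC", "ND", "C1", "C2", "C3",
                    "C6", "C7", "C8", "C21", "C71", "O21"),
                  function(nm) .match_chl_atom(res, nm), integer(1))
    names(idx) <- c("MG", "NA", "NB", "NC", "ND", "C1", "C2", "C3",
                    "C6", "C7", "C8", "C21", "C71", "O21")
    if (is.na(idx["MG"]) || is.na(idx["C2"])) {
      warning(sprintf("chlorophyll %s %s:%d missing Mg or C2 atom; excluded",
                      res$residue_name[1], chain, resno))
      next
    }
    have <- !is.na(idx)
    pos <- as.matrix(res[idx[have], c("x", "y", "z")])
    rownames(pos) <- names(idx)[have]
    type <- names(chl_codes)[match(res$residue_name[1], chl_codes)]
    if (is.na(type)) type <- "unknown"
    sname <- NULL
    if (!is.null(site_table)) {
      m <- which(as.character(site_table$chain) == chain &
                 site_table$resnum == resno)
      if (length(m)) sname <- as.character(site_table$site_name[m[1]])
    }
    if (is.null(sname)) sname <- sprintf("unassigned:%s:%d", chain, resno)
    lres <- NA_real_
    if (!is.null(local_resolution)) {
      m <- which(as.character(local_resolution$chain) == chain &
                 local_resolution$resnum == resno)
      if (length(m)) lres <- as.numeric(local_resolution$resolution[m[1]])
    }
    site <- structure(list(site_name = sname, chain_id = chain,
                           residue_number = resno, chl_type = type,
                           mg = pos["MG", ], atoms = pos,
                           local_resolution = lres),
                      class = "chl_site")
    validate_chl_site(site)
    sites[[length(sites) + 1L]] <- site
  }
  sites
}

# geometric sanity: Mg near pyrrole-N centroid, substituent bonds plausible
validate_chl_site <- function(site) {
  pn <- intersect(c("NA", "NB", "NC", "ND"), rownames(site$atoms))
  if (length(pn) == 4L) {
    ctr <- colMeans(site$atoms[pn, , drop = FALSE])
    if (sqrt(sum((site$mg - ctr)^2)) > 3.0)
      warning("site ", site$site_name, ": Mg > 3 A from pyrrole-N centroid")
  }
  for (pair in list(c("C2", "C21"), c("C7", "C71"))) {
    if (all(pair %in% rownames(site$atoms))) {
      d <- sqrt(sum((site$atoms[pair[1], ] - site$atoms[pair[2], ])^2))
      if (d < 1.3 || d > 1.7)
        warning(sprintf("site %s: %s-%s bond %.2f A outside [1.3, 1.7]",
                        site$site_name, pair[1], pair[2], d))
    }
  }
  invisible(site)
}

#' @export
print.chl_site <- function(x, ...) {
  cat(sprintf("chl_site %s (%s:%d) type Chl %s, %d atoms resolved%s\n",
              x$site_name, x$chain_id, x$residue_number, x$chl_type,
              nrow(x$atoms),
              if (is.na(x$local_resolution)) ""
              else sprintf(", local res %.2f A", x$local_resolution)))
  invisible(x)
}

#' Read a site-name table
#'
#' Tab-separated file with columns `chain`, `resnum`, `site_name` mapping
#' chlorophyll residues to PSI site nomenclature.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_site_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain", "resnum", "site_name")
  if (!all(need %in% names(tb)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  tb
}
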