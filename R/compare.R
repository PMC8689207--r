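# Sequence and structure comparison: pairwise global alignment identity,
# Calpha superposition RMSD, conservation profiles, Fe-S cluster distance
# geometry, and the VEGP / Glu-Gly motif scan.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch global alignment through Biostrings with BLOSUM62
#' scoring; identity is matches over aligned columns (gap columns count in
#' the denominator, not the numerator), which makes it symmetric in its
#' arguments.
#'
#' @param seq_a,seq_b Amino-acid strings (standard 20 letters plus X).
#' @param substitution_matrix Matrix name or matrix (default "BLOSUM62").
#' @param gap_open,gap_extend Gap penalties (defaults 10 and 0.5).
#' @param start_a,start_b Residue number of the first position of each
#'   sequence (for `matched_positions`).
#' @return A `pairwise_alignment`: `aligned_a`, `aligned_b` (gapped
#'   strings), `score`, `identity_percent`, `matched_positions`
#'   (data.frame `resno_a`, `resno_b` of aligned non-gap column pairs).
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5,
                         start_a = 1L, start_b = 1L) {
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("empty sequence")
    bad <- setdiff(strsplit(toupper(s), "")[[1]], .aa_alphabet)
    if (length(bad))
      stop("non-amino-acid character(s): ", paste(unique(bad), collapse = ""))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq_a)), Biostrings::AAString(toupper(seq_b)),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  pa <- as.character(Biostrings::alignedPattern(al))
  ps <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(pa, "")[[1]]; cb <- strsplit(ps, "")[[1]]
  ncol_al <- length(ca)
  matches <- sum(ca == cb & ca != "-")
  # column-wise residue numbering
  ra <- cumsum(ca != "-") + start_a - 1L
  rb <- cumsum(cb != "-") + start_b - 1L
  both <- ca != "-" & cb != "-"
  structure(list(aligned_a = pa, aligned_b = ps,
                 score = Biostrings::score(al),
                 identity_percent = 100 * matches / ncol_al,
                 matched_positions = data.frame(resno_a = ra[both],
                                                resno_b = rb[both])),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %d columns, %.1f%% identity, score %.1f\n",
              nchar(x$aligned_a), x$identity_percent, x$score))
  invisible(x)
}

# Calpha coordinates by residue number for one chain
.ca_by_resno <- function(model, chain) {
  a <- model$atoms
  sel <- a$chain_id == chain & a$name == "CA"
  ca <- a[sel, ]
  ca <- ca[!duplicated(ca$residue_number), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$residue_number
  m
}

#' Calpha superposition of two chains
#'
#' Least-squares rigid superposition over all alignment-matched Calpha
#' pairs, with no outlier rejection; reports the post-fit RMSD.
#'
#' @param model_a,model_b `structure_model`s.
#' @param chain_a,chain_b Chain ids.
#' @param alignment A `pairwise_alignment` of the two chain sequences
#'   (residue numbering must match the models), or `NULL` to pair residues
#'   by identical residue number.
#' @return A `subunit_superposition`: `chain_a`, `chain_b`, `n_matched`,
#'   `rmsd` (A), `transform` (`rigid_transform` mapping A onto B).
#' @export
superpose <- function(model_a, chain_a, model_b, chain_b, alignment = NULL) {
  ca_a <- .ca_by_resno(model_a, chain_a)
  ca_b <- .ca_by_resno(model_b, chain_b)
  if (is.null(alignment)) {
    common <- intersect(rownames(ca_a), rownames(ca_b))
    pairs <- data.frame(resno_a = as.integer(common),
                        resno_b = as.integer(common))
  } else pairs <- alignment$matched_positions
  keep <- as.character(pairs$resno_a) %in% rownames(ca_a) &
          as.character(pairs$resno_b) %in% rownames(ca_b)
  pairs <- pairs[keep, ]
  if (nrow(pairs) < 3) stop("fewer than 3 matched Calpha pairs")
  A <- ca_a[as.character(pairs$resno_a), , drop = FALSE]
  B <- ca_b[as.character(pairs$resno_b), , drop = FALSE]
  tr <- kabsch(A, B)
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 n_matched = nrow(pairs), rmsd = tr$rmsd, transform = tr),
            class = "subunit_superposition")
}

#' @export
print.subunit_superposition <- function(x, ...) {
  cat(sprintf("superposition %s vs %s: %d Calpha pairs, rmsd %.3f A\n",
              x$chain_a, x$chain_b, x$n_matched, x$rmsd))
  invisible(x)
}

#' Per-column conservation of a multiple alignment
#'
#' Score per column = frequency of the most common non-gap residue divided
#' by the number of sequences (identical columns score 1); columns that are
#' majority gap score 0. A simple, monotone surrogate for conservation,
#' suitable for mapping onto a structure.
#'
#' @param msa Character vector of equal-length gapped sequences (gap "-"),
#'   or a character matrix (sequences x columns).
#' @param reference Index of the sequence whose residue numbering the
#'   mapping uses (default 1).
#' @param start_ref Residue number of the reference's first residue.
#' @return A `conservation_profile`: `scores` (per column, in `[0,1]`),
#'   `mapping` (data.frame `column`, `resno` for non-gap reference columns).
#' @export
conservation_profile <- function(msa, reference = 1L, start_ref = 1L) {
  if (is.character(msa)) {
    if (length(unique(nchar(msa))) != 1)
      stop("ragged alignment: sequences differ in aligned length")
    if (length(msa) < 2) stop("need >= 2 aligned sequences")
    msa <- do.call(rbind, strsplit(toupper(msa), ""))
  }
  n <- nrow(msa)
  scores <- apply(msa, 2, function(col) {
    gaps <- sum(col == "-" | col == ".")
    if (gaps > n / 2) return(0)
    resid <- col[col != "-" & col != "."]
    max(table(resid)) / n
  })
  ref <- msa[reference, ]
  nong <- which(ref != "-" & ref != ".")
  structure(list(scores = as.numeric(scores),
                 mapping = data.frame(column = nong,
                                      resno = seq_along(nong) + start_ref - 1L)),
            class = "conservation_profile")
}

#' Write a conservation profile as a structure-viewer attribute file
#'
#' Plain-text residue id -> score listing (majority-residue-frequency
#' scheme), one line per mapped reference residue.
#'
#' @param profile A `conservation_profile`.
#' @param chain Chain id written in the attribute lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_attributes <- function(profile, chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# per-residue conservation (majority non-gap residue frequency)",
               "attribute: conservation"), con)
  writeLines(sprintf("\t/%s:%d\t%.4f", chain, profile$mapping$resno,
                     profile$scores[profile$mapping$column]), con)
  invisible(path)
}

#' Fe-S cluster distance geometry
#'
#' For each requested pair of cluster selections reports the
#' center-to-center distance (centroid over the clusters' Fe and S atoms)
#' and the edge-to-edge distance (minimum pairwise atom distance; include
#' coordinating Cys S atoms in the selections to reproduce the standard
#' edge-to-edge convention).
#'
#' @param model A `structure_model`.
#' @param selections Named list of integer/logical selections into
#'   `model$atoms`, one per cluster.
#' @param pairs Optional 2-column character matrix / data.frame of cluster
#'   name pairs; default all unordered pairs.
#' @return data.frame: `cluster_a`, `cluster_b`, `center_to_center`,
#'   `edge_to_edge` (A).
#' @export
fes_distances <- function(model, selections, pairs = NULL) {
  stopifnot(inherits(model, "structure_model"))
  pts <- lapply(selections, function(sel) {
    m <- coords(model, sel)
    if (nrow(m) == 0) stop("empty cluster selection")
    m
  })
  nm <- names(pts)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nm, 2))
  } else pairs <- as.matrix(pairs)
  cen <- lapply(pts, colMeans)
  out <- data.frame(cluster_a = character(), cluster_b = character(),
                    center_to_center = numeric(), edge_to_edge = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    cc <- sqrt(sum((cen[[a]] - cen[[b]])^2))
    pa <- pts[[a]]; pb <- pts[[b]]
    dd <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    ee <- sqrt(max(min(dd), 0))
    out[nrow(out) + 1L, ] <- list(a, b, cc, ee)
  }
  out
}

#' Select the Fe and S atoms of a cluster residue
#'
#' Convenience selector for [fes_distances()]: atoms of the named residue
#' (e.g. SF4/FES) with element Fe or S, optionally together with SG atoms
#' of Cys residues whose SG lies within `cys_r` of any cluster atom.
#'
#' @param model A `structure_model`.
#' @param chain,resnum Residue identity of the cluster.
#' @param include_cys_sg Include coordinating Cys SG atoms.
#' @param cys_r Coordination search radius (A).
#' @return Integer atom selection.
#' @export
select_cluster <- function(model, chain, resnum, include_cys_sg = TRUE,
                           cys_r = 2.6) {
  a <- model$atoms
  core <- which(a$chain_id == chain & a$residue_number == resnum &
                a$element %in% c("FE", "S"))
  if (!length(core)) stop("no Fe/S atoms in ", chain, ":", resnum)
  sel <- core
  if (include_cys_sg) {
    sg <- which(a$residue_name == "CYS" & a$name == "SG")
    if (length(sg)) {
      cp <- coords(model, core)
      keep <- vapply(sg, function(i) {
        d <- sqrt(rowSums(sweep(cp, 2, unlist(a[i, c("x", "y", "z")]))^2))
        any(d <= cys_r)
      }, logical(1))
      sel <- c(sel, sg[keep])
    }
  }
  sort(sel)
}

#' Scan sequences for the VEGP / Glu-Gly motif
#'
#' Matches a 4-residue motif allowing variable first and last positions
#' while holding the middle residues strict (default "VEGP" with strict E
#' and G): the conserved Glu-Gly core co-occurs with PsaX across PsaB
#' sequences even where Val/Pro vary.
#'
#' @param sequences Named character vector of amino-acid sequences (gaps
#'   tolerated and ignored).
#' @param motif Motif string (default "VEGP").
#' @param strict_positions Integer positions within the motif that must
#'   match exactly (default `c(2, 3)`).
#' @return data.frame: `sequence`, `exact_match` (full motif present),
#'   `core_match` (strict positions present with free flanks),
#'   `position` (1-based position of the first core match, NA if none).
#' @export
motif_scan <- function(sequences, motif = "VEGP", strict_positions = c(2, 3)) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  core_pat <- vapply(seq_len(nchar(motif)), function(i)
    if (i %in% strict_positions) substr(motif, i, i) else "[A-Z]", "")
  core_pat <- paste(core_pat, collapse = "")
  out <- lapply(names(sequences), function(nm) {
    s <- toupper(gsub("[-.]", "", sequences[[nm]]))
    pos <- regexpr(core_pat, s)[1]
    data.frame(sequence = nm,
               exact_match = grepl(motif, s, fixed = TRUE),
               core_match = pos > 0,
               position = if (pos > 0) pos else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise identity and RMSD matrices
#'
#' @param models Named list of `structure_model`s.
#' @param sequences Named list (same names) of named chain sequence vectors,
#'   or `NULL` to derive sequences from model CA records.
#' @param chains Character vector of chain ids shared across models.
#' @return list with `identity` and `rmsd`: one matrix per chain
#'   (models x models).
#' @keywords internal
.compare_matrices <- function(models, chains, sequences = NULL) {
  nm <- names(models)
  res <- list(identity = list(), rmsd = list())
  for (ch in chains) {
    idm <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    rmm <- idm
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i == j) { idm[i, j] <- 100; rmm[i, j] <- 0; next }
      if (i > j) next
      sa <- .chain_seq(models[[i]], ch, sequences[[nm[i]]])
      sb <- .chain_seq(models[[j]], ch, sequences[[nm[j]]])
      al <- global_align(sa$seq, sb$seq, start_a = sa$start, start_b = sb$start)
      sp <- superpose(models[[i]], ch, models[[j]], ch, al)
      idm[i, j] <- idm[j, i] <- al$identity_percent
      rmm[i, j] <- rmm[j, i] <- sp$rmsd
    }
    res$identity[[ch]] <- idm
    res$rmsd[[ch]] <- rmm
  }
  res
}

# one-letter sequence of a chain from its CA records (or supplied)
.chain_seq <- function(model, chain, provided = NULL) {
  if (!is.null(provided) && chain %in% names(provided))
    return(list(seq = provided[[chain]], start = 1L))
  a <- model$atoms
  sel <- a$chain_id == chain & a$name == "CA"
  if (!any(sel)) stop("chain ", chain, " has no CA atoms in ", model$source_id)
  ca <- a[sel, ]
  ca <- ca[!duplicated(ca$residue_number), ]
  aa1 <- bio3d::aa321(ca$residue_name)
  aa1[is.na(aa1) | aa1 == ""] <- "X"
  list(seq = paste(aa1, collapse = ""), start = min(ca$residue_number))
}
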