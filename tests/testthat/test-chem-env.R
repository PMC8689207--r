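# Axial ligation, H-bond donor search, site-specificity calls.

test_that("axial ligand classification by identity and distance", {
  site <- fixture_site("a")
  fx <- make_chl_fixture("a")
  mg <- site$mg

  his <- atom_row("N", "NE2", "HIS", "P", 10,
                  mg[1], mg[2], mg[3] + 2.2)
  m1 <- model_with(fx, his)
  a1 <- find_axial_ligand(m1, site)
  expect_equal(a1$ligand_class, "His-sidechain")
  expect_equal(a1$distance, 2.2, tolerance = 1e-9)

  # water at 2.4 wins over a His outside the 3.0 cutoff
  wat <- atom_row("O", "O", "HOH", "W", 501, mg[1], mg[2], mg[3] + 2.4)
  his_far <- atom_row("N", "NE2", "HIS", "P", 10, mg[1], mg[2], mg[3] + 3.5)
  a2 <- find_axial_ligand(model_with(fx, rbind(wat, his_far)), site)
  expect_equal(a2$ligand_class, "water")
  expect_equal(a2$distance, 2.4, tolerance = 1e-9)

  # nothing within cutoff
  a3 <- find_axial_ligand(fx |> model_with(
    atom_row("N", "NE2", "HIS", "P", 10, mg[1], mg[2], mg[3] + 3.2)), site)
  expect_equal(a3$ligand_class, "none-found")
  expect_true(is.na(a3$distance))

  # backbone carbonyl and lipid classes
  bb <- atom_row("O", "O", "ILE", "P", 318, mg[1], mg[2], mg[3] + 2.3)
  expect_equal(find_axial_ligand(model_with(fx, bb), site)$ligand_class,
               "backbone-carbonyl")
  pg <- atom_row("O", "O1P", "LHG", "L", 3, mg[1], mg[2], mg[3] + 2.3)
  expect_equal(find_axial_ligand(model_with(fx, pg), site)$ligand_class,
               "lipid-or-cofactor")
})

test_that("axial ligand assignment is independent of atom input order", {
  site <- fixture_site("a")
  fx <- make_chl_fixture("a")
  mg <- site$mg
  extra <- rbind(
    atom_row("N", "NE2", "HIS", "P", 10, mg[1], mg[2], mg[3] + 2.2),
    atom_row("O", "O", "HOH", "W", 1, mg[1], mg[2], mg[3] - 2.6),
    atom_row("O", "OG", "SER", "P", 22, mg[1] + 2.5, mg[2], mg[3]))
  m_fwd <- model_with(fx, extra)
  m_rev <- structure_model(m_fwd$atoms[rev(seq_len(nrow(m_fwd$atoms))), ])
  a_fwd <- find_axial_ligand(m_fwd, site)
  a_rev <- find_axial_ligand(m_rev, site)
  expect_equal(a_fwd$ligand_class, a_rev$ligand_class)
  expect_equal(a_fwd$distance, a_rev$distance)
})

test_that("hypothetical formyl rotamers lie in the macrocycle plane", {
  site <- fixture_site("a")
  rot <- formyl_rotamer_positions(site)
  expect_equal(dim(rot), c(2, 3))
  ring <- site$atoms[intersect(c(paste0("C", 1:20), "NA", "NB", "NC", "ND"),
                               rownames(site$atoms)), ]
  pl <- chlfscan:::fit_plane(ring)
  offplane <- abs((sweep(rot, 2, pl$center)) %*% pl$normal)
  expect_lt(max(offplane), 0.2)
  # both at 1.22 A from C21 and 120 degrees to the C21-C2 bond
  for (k in 1:2) {
    d <- sqrt(sum((rot[k, ] - site$atoms["C21", ])^2))
    expect_equal(d, 1.22, tolerance = 1e-6)
    v1 <- (site$atoms["C2", ] - site$atoms["C21", ])
    v2 <- rot[k, ] - site$atoms["C21", ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(ang, 120, tolerance = 0.5)
  }
})

test_that("H-bond donors are found within the heavy-atom window", {
  # modeled formyl O on a Chl f site
  site_f <- fixture_site("f")
  fx_f <- make_chl_fixture("f")
  o_pos <- site_f$atoms["O21", ]
  don <- atom_row("N", "N", "GLY", "P", 5, o_pos[1], o_pos[2], o_pos[3] + 2.9)
  hits <- find_c2_hbond_donors(model_with(fx_f, don), site_f)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$donor_kind, "backbone-amide")
  expect_equal(hits[[1]]$distance, 2.9, tolerance = 1e-9)

  # donor beyond the window: no hit
  far <- atom_row("N", "N", "GLY", "P", 5, o_pos[1], o_pos[2], o_pos[3] + 3.6)
  expect_length(find_c2_hbond_donors(model_with(fx_f, far), site_f), 0)
  # too close is also excluded
  near <- atom_row("N", "N", "GLY", "P", 5, o_pos[1], o_pos[2], o_pos[3] + 2.3)
  expect_length(find_c2_hbond_donors(model_with(fx_f, near), site_f), 0)

  # carbonyl O cannot donate
  carb <- atom_row("O", "O", "GLY", "P", 5, o_pos[1], o_pos[2], o_pos[3] + 2.9)
  expect_length(find_c2_hbond_donors(model_with(fx_f, carb), site_f), 0)

  # Chl a site: hypothetical rotamer acceptors are searched instead
  site_a <- fixture_site("a")
  fx_a <- make_chl_fixture("a")
  rot <- formyl_rotamer_positions(site_a)
  tyr <- atom_row("O", "OH", "TYR", "J", 8,
                  rot[2, 1], rot[2, 2], rot[2, 3] + 2.8)
  hits_a <- find_c2_hbond_donors(model_with(fx_a, tyr), site_a)
  expect_length(hits_a, 1)
  expect_equal(hits_a[[1]]$donor_kind, "sidechain")
})

test_that("a donor near both rotamers is reported once, at closest approach", {
  site <- fixture_site("a")
  fx <- make_chl_fixture("a")
  c21 <- site$atoms["C21", ]
  # place a water equidistant-ish from both rotamer positions
  wat <- atom_row("O", "O", "HOH", "W", 9, c21[1] + 3.0, c21[2], c21[3] + 1.0)
  hits <- find_c2_hbond_donors(model_with(fx, wat), site)
  expect_lte(length(hits), 1)
})

evidence_call <- function(reject, his, donor, frl = FALSE, clash_free = TRUE,
                          homology = FALSE) {
  test <- structure(list(site_name = "s",
                         decision = if (reject) "reject" else "fail-to-reject",
                         exceed_angles = integer(), min_run = 1L),
                    class = "substituent_test")
  lig <- structure(list(site_name = "s", ligand_atom = NULL, distance = 2.2,
                        ligand_class = if (his) "His-sidechain"
                                       else "other-sidechain"),
                   class = "axial_ligand")
  donors <- if (donor) list(structure(list(donor_kind = "sidechain"),
                                      class = "hbond_donor_hit")) else list()
  classify_site(test, lig, donors,
                list(frl_variable_region = frl, steric_clash_free = clash_free,
                     homology_support = homology))$call
}

test_that("site-specificity rule table", {
  # cone rejection + non-His + donor: confirmed Chl f
  expect_equal(evidence_call(TRUE, FALSE, TRUE), "high-specificity-f")
  # nothing fires: Chl a
  expect_equal(evidence_call(FALSE, TRUE, FALSE), "a")
  # promiscuous-site pattern: non-His, no donor, clash-free, FRL-variable
  expect_equal(evidence_call(FALSE, FALSE, FALSE, frl = TRUE),
               "low-specificity-f-candidate")
  # homology support promotes a quiet site with a conserved donor environment
  expect_equal(evidence_call(FALSE, FALSE, TRUE, homology = TRUE),
               "high-specificity-f")
  # His ligation blocks the high-specificity call
  expect_equal(evidence_call(TRUE, TRUE, TRUE), "a")
  # missing evidence errors
  expect_error(classify_site(NULL, NULL, list(), list()), "missing")
})

test_that("the six known Chl f sites are recovered from their evidence", {
  # evidence flags as established for the Synechococcus 7335 FRL-PSI sites:
  # A21/B7/B37 reject the cone-scan null with donors; B19 and B30 have
  # donors plus homology support (peripheral B19 does not reject; B30's
  # donor is conserved); B38 pairs with B37 (homology support, no donor)
  ev <- list(
    A21 = list(TRUE,  FALSE, TRUE,  FALSE),
    B7  = list(TRUE,  FALSE, TRUE,  FALSE),
    B37 = list(TRUE,  FALSE, TRUE,  FALSE),
    B19 = list(FALSE, FALSE, TRUE,  TRUE),
    B30 = list(FALSE, FALSE, TRUE,  TRUE),
    B38 = list(FALSE, FALSE, FALSE, TRUE),
    # promiscuous candidates: A6, A7, B40
    A6  = list(FALSE, FALSE, FALSE, FALSE),
    A7  = list(FALSE, FALSE, FALSE, FALSE),
    B40 = list(FALSE, FALSE, FALSE, FALSE))
  calls <- vapply(names(ev), function(nm) {
    e <- ev[[nm]]
    evidence_call(e[[1]], e[[2]], e[[3]], homology = e[[4]],
                  frl = nm %in% c("A6", "A7", "B40"))
  }, "")
  high <- c("A21", "B7", "B37", "B19", "B30", "B38")
  expect_true(all(calls[high] == "high-specificity-f"))
  expect_true(all(calls[c("A6", "A7", "B40")] == "low-specificity-f-candidate"))
})
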