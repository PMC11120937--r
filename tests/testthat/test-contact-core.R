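test_that("pair area and volume match the closed-form oracles", {
  a <- atom_sphere(c(0, 0, 0), 3.1)
  b <- atom_sphere(c(4, 0, 0), 3.1)
  S_ref <- cap_area_oracle(3.1, 3.1, 4.0)     # equal radii: both sides equal
  expect_equal(contact_area(a, b), S_ref, tolerance = 0.03)
  V_ref <- lens_volume_oracle(3.1, 3.1, 4.0)
  expect_equal(contact_volume(a, b), V_ref, tolerance = 0.03)
})

test_that("disjoint spheres give exactly zero contact", {
  a <- atom_sphere(c(0, 0, 0), 1.5)
  b <- atom_sphere(c(4, 0, 0), 1.5)
  expect_identical(contact_area(a, b), 0)
  expect_identical(contact_volume(a, b), 0)
  expect_identical(aowv(a, b), 0)
})

test_that("occupancy sharing halves the area when a third atom covers the cap", {
  a <- atom_sphere(c(0, 0, 0), 3.1)
  b <- atom_sphere(c(4, 0, 0), 3.1)
  cover <- atom_sphere(c(4, 0, 0), 3.2)  # contains every point inside b
  s1 <- contact_area(a, b, sides = "a")
  s2 <- contact_area(a, b, context = list(cover), sides = "a")
  expect_equal(s2, s1 / 2, tolerance = 1e-12)
})

test_that("volume and AOWV are symmetric bit-exactly", {
  a <- atom_sphere(c(0.3, -1, 2), 2.4)
  b <- atom_sphere(c(2.5, 0, 1.2), 1.9)
  expect_identical(contact_volume(a, b), contact_volume(b, a))
  expect_identical(aowv(a, b), aowv(b, a))
  expect_identical(contact_area(a, b), contact_area(b, a))
})

test_that("AOWV equals twice the volume on an isolated pair, more with crowding", {
  a <- atom_sphere(c(0, 0, 0), 2.0)
  b <- atom_sphere(c(2.5, 0, 0), 2.0)
  expect_equal(aowv(a, b), 2 * contact_volume(a, b), tolerance = 1e-12)
  # a third sphere swallowing the lens: every point has ci = 2,
  # so V halves (shares 1/2) and V0 jumps to 3*delta_v per point: ratio 6
  big <- atom_sphere(c(1.25, 0, 0), 5)
  V <- contact_volume(a, b, context = list(big))
  V0 <- aowv(a, b, context = list(big))
  expect_equal(V0 / V, 6, tolerance = 1e-12)
})

test_that("nested small sphere recovers its full volume", {
  a <- atom_sphere(c(0, 0, 0), 3.0)
  b <- atom_sphere(c(1.0, 0, 0), 1.0)
  expect_equal(contact_volume(a, b), 4 / 3 * pi, tolerance = 0.02)
})

test_that("SASA: isolated sphere, buried sphere, and exact surface partition", {
  sp <- grid_spec()
  iso <- atom_sphere(c(0, 0, 0), 3.1)   # carbon 1.7 + probe 1.4
  expect_equal(sasa(iso), 4 * pi * 3.1^2, tolerance = 1e-9)
  expect_identical(sasa(iso, list(atom_sphere(c(0.5, 0, 0), 10))), 0)
  b <- atom_sphere(c(4, 0, 0), 3.1)
  exposed <- sasa(iso, list(b))
  buried <- contact_area(iso, b, sides = "a")
  expect_equal(exposed + buried, 4 * pi * 3.1^2, tolerance = 1e-9)
})

test_that("coincident centers are rejected as degenerate", {
  a <- atom_sphere(c(0, 0, 0), 1.5)
  b <- atom_sphere(c(0.001, 0, 0), 1.5)
  expect_error(contact_area(a, b), "degenerate")
  expect_error(contact_volume(a, b), "degenerate")
})

test_that("model engine emits symmetric inter-residue records only", {
  # three single-atom residues in a row; middle one contacts both ends
  atoms <- data.frame(name = c("O", "CB", "CB"),
                      resname = c("GLY", "ALA", "ALA"), chain = "A",
                      resseq = 1:3, x = c(0, 3, 6), y = 0, z = 0,
                      element = c("O", "C", "C"), stringsAsFactors = FALSE)
  m <- assigned_model(atoms)
  eng <- compute_model_contacts(m, with_sasa = TRUE)
  cc <- eng$contacts
  expect_equal(nrow(cc), 3)  # 1-2, 2-3 strong; 1-3 thin overlap at 6 A
  expect_true(all(cc$serial1 < cc$serial2))
  expect_true(all(cc$volume >= 0) && all(cc$area >= 0))
  expect_true(all(cc$aowv >= 2 * cc$volume - 1e-9))

  # engine SASA agrees with the standalone operation
  sp <- grid_spec()
  ctx <- lapply(2:3, function(i) atom_sphere(c(m$x[i], 0, 0), m$vdw[i] + 1.4))
  expect_equal(unname(eng$atom_sasa["1"]),
               sasa(atom_sphere(c(0, 0, 0), m$vdw[1] + 1.4), ctx, sp))
})

test_that("intra-residue pairs are never emitted", {
  atoms <- data.frame(name = c("CA", "CB"), resname = "ALA", chain = "A",
                      resseq = 1, x = c(0, 1.5), y = 0, z = 0,
                      element = "C", stringsAsFactors = FALSE)
  m <- assigned_model(atoms)
  expect_equal(nrow(compute_model_contacts(m)$contacts), 0)
})

test_that("custom contact distance restricts the emitted pairs", {
  atoms <- data.frame(name = c("CB", "CB"), resname = "ALA", chain = "A",
                      resseq = 1:2, x = c(0, 5.5), y = 0, z = 0,
                      element = "C", stringsAsFactors = FALSE)
  m <- assigned_model(atoms)
  # expanded spheres (1.7+1.4 each) overlap at 5.5 A; vdW gap is 2.1 A
  expect_equal(nrow(compute_model_contacts(m)$contacts), 1)
  expect_equal(nrow(compute_model_contacts(m, custom_d = 2.0)$contacts), 0)
  expect_equal(nrow(compute_model_contacts(m, custom_d = 2.5)$contacts), 1)
})

test_that("peptide-bonded neighbors are flagged covalent", {
  m <- assigned_model(toy_tripeptide_atoms())
  cc <- compute_model_contacts(m)$contacts
  adjacent <- abs(as.integer(sub("^A:(\\d+):.*", "\\1", cc$residue1)) -
                    as.integer(sub("^A:(\\d+):.*", "\\1", cc$residue2))) == 1
  pep <- cc[cc$atom1 == "C" & cc$atom2 == "N" & adjacent, ]
  expect_gt(nrow(pep), 0)
  expect_true(all(pep$covalent))
  expect_true(all(pep$contact == "Cova"))
  expect_false(any(cc$covalent[!(cc$atom1 == "C" & cc$atom2 == "N" & adjacent)]))
})
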