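test_that("PDB parsing resolves altlocs and keeps correct coordinates", {
  f <- write_pdb_fixture(pdb_atom_line(1, "CA", "ALA", "A", 1, 1.5, 2.5, 3.5))
  m <- read_structure(f)
  expect_equal(nrow(m), 1)
  expect_equal(unname(unlist(m[1, c("x", "y", "z")])), c(1.5, 2.5, 3.5))
  expect_equal(m$chain, "A")

  # two altlocs at occupancy 0.6/0.4: the 0.6 conformer survives
  f2 <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.4, alt = "B")))
  m2 <- read_structure(f2)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$x, 0)

  expect_error(read_structure(tempfile(fileext = ".pdb")), "parse")
})

test_that("the same model parses identically from PDB and mmCIF", {
  s <- make_structure(n_res = 4, seed = 6)
  fp <- tempfile(fileext = ".pdb")
  write_structure(s$model, fp)
  fc <- write_cif_fixture(s$model)
  mp <- read_structure(fp)
  mc <- read_structure(fc)
  expect_equal(mp$resno, mc$resno)
  expect_equal(mp$elety, mc$elety)
  expect_equal(mp$resid, mc$resid)
  # coordinates agree to the 3-decimal precision both formats carry
  expect_equal(as.matrix(mp[, c("x", "y", "z")]),
               as.matrix(mc[, c("x", "y", "z")]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("atom distances are Euclidean, precise, and rigid-motion invariant", {
  atoms <- data.frame(chain = "A", resno = c(1, 2), resid = "GLY",
                      elety = "CA", element = "C",
                      x = c(0, 3), y = c(0, 4), z = c(0, 0))
  m <- structure_model(atoms)
  expect_equal(atom_distance(m, list(chain = "A", resno = 1, elety = "CA"),
                             list(chain = "A", resno = 2, elety = "CA")), 5)
  expect_error(atom_distance(m, list(chain = "A", resno = 1, elety = "CZ"),
                             list(chain = "A", resno = 2, elety = "CA")),
               "CZ in residue 1")

  set.seed(41)
  s <- make_structure(n_res = 6, seed = 41)
  d0 <- atom_distance(s$model, list("A", 2, "CA"), list("A", 5, "C"))
  for (rep in 1:5) {
    rm_ <- random_rigid_motion()
    mt <- transform_model(s$model, rm_$rotation, rm_$translation)
    expect_equal(atom_distance(mt, list("A", 2, "CA"), list("A", 5, "C")),
                 d0, tolerance = 1e-9)
  }
})

test_that("torsion measurement agrees with an independent implementation", {
  set.seed(43)
  for (rep in 1:20) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 bio3d::torsion.xyz(as.numeric(t(p))),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("construct-then-measure dihedral round trip is exact", {
  set.seed(47)
  for (rep in 1:10) {
    n <- 12
    phi <- runif(n, -179.9, 180)
    psi <- runif(n, -179.9, 180)
    s <- make_structure(n_res = n, phi = phi, psi = psi, seed = rep)
    dh <- backbone_dihedrals(s$model, "A", 2:(n - 1))
    expect_equal(dh$phi, phi[2:(n - 1)], tolerance = 1e-6)
    expect_equal(dh$psi, psi[2:(n - 1)], tolerance = 1e-6)
  }

  # ideal trans-planar strand: Psi at 180 degrees
  s <- make_structure(n_res = 3, phi = -180 + 1e-9, psi = 180, seed = 1)
  dh <- backbone_dihedrals(s$model, "A", 2)
  expect_equal(abs(dh$psi), 180, tolerance = 1e-6)

  # termini yield missing markers
  dh_all <- backbone_dihedrals(s$model, "A", 1:3)
  expect_true(is.na(dh_all$phi[1]))
  expect_true(is.na(dh_all$psi[3]))
})

test_that("dihedrals flip sign under a coordinate mirror", {
  s <- make_structure(n_res = 8, phi = c(0, -77.8, -64.3, -90.6, -91.5,
                                         -69.5, -60, -60),
                      psi = c(133.2, 162, 42.6, 174, -13.6, -45, -45, 0),
                      seed = 2)
  dh <- backbone_dihedrals(s$model, "A", 2:7)
  mir <- s$model
  mir$x <- -mir$x
  dhm <- backbone_dihedrals(mir, "A", 2:7)
  flip <- function(a) ifelse(a <= -180, a + 360, a)
  expect_equal(dhm$phi, flip(-dh$phi), tolerance = 1e-9)
  expect_equal(dhm$psi, flip(-dh$psi), tolerance = 1e-9)
})

test_that("chain breaks suppress dihedrals across the gap with a warning", {
  s1 <- make_structure(n_res = 3, seed = 1)
  s2 <- make_structure(n_res = 3, resno_start = 4, seed = 1)
  m2 <- s2$model
  m2$x <- m2$x + 50
  joined <- structure_model(rbind(as.data.frame(s1$model),
                                  as.data.frame(m2)))
  w <- capture_warnings(dh <- backbone_dihedrals(joined, "A", 1:6))
  expect_true(any(grepl("chain break", w)))
  expect_true(is.na(dh$psi[3]))
  expect_true(is.na(dh$phi[4]))
  expect_false(is.na(dh$phi[3]))
})

test_that("disulfide detection is exact on planted bridges and monotone", {
  s <- make_structure(n_res = 12, disulfide = list(residues = c(3, 9),
                                                   distance = 2.05),
                      seed = 3)
  ds <- detect_disulfides(s$model)
  expect_equal(nrow(ds), 1)
  expect_equal(c(ds$resno1, ds$resno2), c(3, 9))
  expect_equal(ds$sg_distance, 2.05, tolerance = 1e-9)

  # two cysteines 5 A apart: nothing at the default cutoff, found at 6
  far <- make_structure(n_res = 12, disulfide = list(residues = c(3, 9),
                                                     distance = 5),
                        seed = 3)
  expect_equal(nrow(detect_disulfides(far$model)), 0)
  expect_equal(nrow(detect_disulfides(far$model, max_sg_distance = 6)), 1)

  # a bridge planted at the Cys106/Cys174 candidate pair
  a2 <- make_structure(n_res = 80, resno_start = 100,
                       disulfide = list(residues = c(106, 174),
                                        distance = 2.05), seed = 4)
  ds2 <- detect_disulfides(a2$model)
  expect_equal(sort(c(ds2$resno1, ds2$resno2)), c(106, 174))

  # SG-less cysteine is skipped with a warning
  noSG <- as.data.frame(s$model)
  noSG <- noSG[!(noSG$resno == 9 & noSG$elety == "SG"), ]
  expect_warning(ds3 <- detect_disulfides(structure_model(noSG)),
                 "lacks an SG")
  expect_equal(nrow(ds3), 0)
})

test_that("spine contact status reflects planted spacing", {
  stack <- function(gap3) {
    atoms <- do.call(rbind, lapply(1:4, function(i) {
      z <- c(0, 3.8, 7.6, 7.6 + gap3)[i]
      data.frame(chain = "A", resno = i * 10, resid = "LEU",
                 elety = c("N", "CA", "C", "CB", "CD1"),
                 element = c("N", "C", "C", "C", "C"),
                 x = c(-3, -2, -1, 0, 0.5), y = 0, z = z)
    }))
    structure_model(atoms)
  }
  ok <- spine_contacts(stack(3.8), c(10, 20, 30, 40))
  expect_equal(ok$status, "intact")
  broken <- spine_contacts(stack(8), c(10, 20, 30, 40))
  expect_equal(broken$status, "broken")
  expect_equal(broken$breaking$res1, 30)

  # pair distances equal an exhaustive double-loop minimum
  m <- stack(5.1)
  sp <- spine_contacts(m, c(10, 20, 30, 40))
  for (k in 1:3) {
    r1 <- sp$pairs$res1[k]; r2 <- sp$pairs$res2[k]
    side <- function(r) as.matrix(m[m$resno == r &
                                    !(m$elety %in% c("N", "CA", "C", "O")),
                                    c("x", "y", "z")])
    expect_equal(sp$pairs$min_distance[k],
                 oracle_min_distance(side(r1), side(r2)), tolerance = 1e-12)
  }
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  s <- make_structure(n_res = 10, seed = 51)
  xyz <- atom_coords(s$model, chain = "A")
  self <- superpose(xyz, xyz)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  set.seed(53)
  for (rep in 1:5) {
    rm_ <- random_rigid_motion()
    moved <- apply_transform(xyz, rm_$rotation, rm_$translation)
    fit <- superpose(xyz, moved)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(fit$rotation, rm_$rotation, tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # rmsd invariant when both sets share an extra pre-rotation
    rm2 <- random_rigid_motion()
    a2 <- apply_transform(xyz, rm2$rotation, rm2$translation)
    b2 <- apply_transform(moved, rm2$rotation, rm2$translation)
    expect_equal(superpose(a2, b2)$rmsd, fit$rmsd, tolerance = 1e-9)
  }

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(xyz[1:2, ], xyz[1:2, ]), "3 paired atoms")
})
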