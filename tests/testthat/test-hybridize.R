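# BREED-style hybridization: cut-site enumeration, geometric matching,
# recombination and library generation.

simple_ligand <- function(smiles, coords, elements, bonds, id = "L") {
  # build a parsed ligand directly from literal geometry
  structure(list(id = id, elements = elements, coords = coords,
                 bonds = bonds, n_atoms = length(elements)),
            class = "hyb_ligand")
}

test_that("cut-site enumeration respects ring, order and size rules", {
  p1 <- hybridization_params(min_fragment_heavy_atoms = 1)
  ethane <- simple_ligand("CC", matrix(c(0, 0, 0, 1.5, 0, 0), 2, byrow = TRUE),
                          c("C", "C"), data.frame(a = 1L, b = 2L, order = 1L))
  cb <- enumerate_cuttable_bonds(ethane, p1)
  expect_equal(nrow(cb), 2)  # one bond, both directions
  expect_setequal(cb$atom_a, c(1, 2))

  # benzene: all bonds in the ring, nothing cuttable
  th <- seq(0, 300, by = 60) * pi / 180
  benz <- simple_ligand("c1ccccc1",
                        cbind(1.39 * cos(th), 1.39 * sin(th), 0),
                        rep("C", 6),
                        data.frame(a = 1:6, b = c(2:6, 1L),
                                   order = rep(c(1L, 2L), 3)))
  expect_equal(nrow(enumerate_cuttable_bonds(benz, p1)), 0)

  # toluene: only the exocyclic bond, and only if fragments are big enough
  tol <- simple_ligand("Cc1ccccc1",
                       rbind(cbind(1.39 * cos(th), 1.39 * sin(th), 0),
                             c(2.9, 0, 0)),
                       rep("C", 7),
                       rbind(data.frame(a = 1:6, b = c(2:6, 1L),
                                        order = rep(c(1L, 2L), 3)),
                             data.frame(a = 1L, b = 7L, order = 1L)))
  expect_equal(nrow(enumerate_cuttable_bonds(tol, p1)), 2)
  expect_equal(nrow(enumerate_cuttable_bonds(
    tol, hybridization_params(min_fragment_heavy_atoms = 3))), 0)
})

test_that("bond-vector matching is inclusive at both boundaries", {
  p <- hybridization_params()  # d_max 1.0, theta_max 15
  mk <- function(pa, pb) data.frame(ax = pa[1], ay = pa[2], az = pa[3],
                                    bx = pb[1], by = pb[2], bz = pb[3])
  b0 <- mk(c(0, 0, 0), c(1, 0, 0))
  same <- match_bond_vectors(b0, b0, p)
  expect_true(same$accept)
  expect_equal(same$displacement, 0)
  expect_equal(same$angle, 0)

  # exactly 15 degrees, shared endpoint a: boundary inclusive
  b15 <- mk(c(0, 0, 0), c(cos(15 * pi / 180), sin(15 * pi / 180), 0))
  m15 <- match_bond_vectors(b0, b15, p)
  expect_equal(m15$angle, 15, tolerance = 1e-9)
  expect_true(m15$accept)
  m16 <- match_bond_vectors(
    b0, mk(c(0, 0, 0), c(cos(15.5 * pi / 180), sin(15.5 * pi / 180), 0)), p)
  expect_false(m16$accept)

  # displacement boundary: 1.0 accepted, 1.01 rejected
  expect_true(match_bond_vectors(b0, mk(c(0, 0, 0), c(1, 0, 1.0)), p)$accept ==
                (match_bond_vectors(b0, mk(c(0, 0, 0), c(1, 0, 1.0)),
                                    p)$angle <= 15))
  shifted <- mk(c(0, 0, 1.01), c(1, 0, 1.01))  # parallel, both ends 1.01 off
  expect_false(match_bond_vectors(b0, shifted, p)$accept)
  at_one <- mk(c(0, 0, 1.0), c(1, 0, 1.0))
  expect_true(match_bond_vectors(b0, at_one, p)$accept)

  expect_error(match_bond_vectors(b0, mk(c(0, 0, 0), c(0, 0, 0)), p),
               "degenerac")
})

test_that("matching is symmetric in its arguments", {
  set.seed(4)
  p <- hybridization_params(d_max = 1.2, theta_max = 25)
  for (k in 1:50) {
    b1 <- data.frame(ax = rnorm(1), ay = rnorm(1), az = rnorm(1),
                     bx = rnorm(1), by = rnorm(1), bz = rnorm(1))
    b2 <- data.frame(ax = b1$ax + runif(1, -1, 1), ay = b1$ay,
                     az = b1$az, bx = b1$bx, by = b1$by + runif(1, -1, 1),
                     bz = b1$bz)
    m12 <- match_bond_vectors(b1, b2, p)
    m21 <- match_bond_vectors(b2, b1, p)
    expect_equal(m12$accept, m21$accept)
    expect_equal(m12$displacement, m21$displacement)
    expect_equal(m12$angle, m21$angle, tolerance = 1e-9)
  }
})

test_that("self-hybridization of superimposed copies yields nothing novel", {
  fx <- make_aligned_set(k = 2)
  one <- fx$sdfset[1]
  both <- c(hybscreen:::as_ligand_list(one), hybscreen:::as_ligand_list(one))
  both[[2]]$id <- "copy2"
  lib <- generate_library(both)
  expect_equal(nrow(lib$hybrids), 0)
  expect_gt(lib$report$totals$matches, 0)
})

test_that("tail-swap pair produces exactly the two expected hybrids", {
  fx <- make_aligned_set(k = 2)
  lib <- generate_library(fx$sdfset)
  expect_equal(nrow(lib$hybrids), 2)
  expect_setequal(lib$hybrids$smiles, fx$manifest_novel)
  expect_true(all(lib$hybrids$parent_head_id != lib$hybrids$parent_tail_id))
  expect_true(all(lib$hybrids$displacement <= 1.0))
  expect_true(all(lib$hybrids$angle <= 15))
})

test_that("generate_library matches the exhaustive enumerator", {
  for (k in c(2, 3, 4)) {
    fx <- make_aligned_set(k = k)
    got <- generate_library(fx$sdfset)$hybrids$smiles
    want <- oracle_hybridize(fx$sdfset)
    expect_identical(got, want)
    expect_identical(sort(got), fx$manifest_novel)
  }
})

test_that("a perturbed ligand contributes no matches at the default tolerance", {
  fx <- make_aligned_set(k = 3, perturb = 3)
  lib <- generate_library(fx$sdfset)
  expect_false(any(lib$hybrids$parent_head_id == "L3" |
                     lib$hybrids$parent_tail_id == "L3"))
  # the other two still swap tails
  expect_equal(nrow(lib$hybrids), 2)
  # the brute-force oracle agrees
  expect_identical(lib$hybrids$smiles, oracle_hybridize(fx$sdfset))
})

test_that("library size is monotone in the geometric tolerances", {
  fx <- make_aligned_set(k = 3, perturb = 3)
  sizes_d <- vapply(c(0.5, 1.0, 1.6, 2.5), function(d) {
    nrow(generate_library(fx$sdfset,
                          hybridization_params(d_max = d))$hybrids)
  }, numeric(1))
  expect_true(all(diff(sizes_d) >= 0))
  sizes_t <- vapply(c(5, 15, 60, 120), function(t) {
    nrow(generate_library(fx$sdfset, hybridization_params(
      d_max = 2.5, theta_max = t))$hybrids)
  }, numeric(1))
  expect_true(all(diff(sizes_t) >= 0))
  sizes_m <- vapply(c(1, 3, 7), function(m) {
    nrow(generate_library(fx$sdfset, hybridization_params(
      min_fragment_heavy_atoms = m))$hybrids)
  }, numeric(1))
  expect_true(all(diff(sizes_m) <= 0))
})

test_that("hybrids conserve heavy atoms and never equal a parent", {
  fx <- make_aligned_set(k = 4)
  lib <- generate_library(fx$sdfset)
  ligs <- hybscreen:::as_ligand_list(fx$sdfset)
  heavies <- vapply(ligs, function(l) sum(l$elements != "H"), numeric(1))
  # every head keeps its scaffold (ring + decoration), every tail its 3 atoms
  for (r in seq_len(nrow(lib$hybrids))) {
    h <- lib$hybrids[r, ]
    head_heavy <- heavies[match(h$parent_head_id, c("L1", "L2", "L3", "L4"))] - 3
    expect_equal(h$n_heavy, head_heavy + 3)
  }
  expect_length(intersect(lib$hybrids$smiles, fx$manifest_parents), 0)
})

test_that("valence sanitization drops chemically impossible hybrids", {
  # an input drawn with a pentavalent carbon in the tail: the hybrid that
  # inherits that tail must be dropped, the complementary hybrid kept
  fx <- make_aligned_set(k = 2)
  ligs <- hybscreen:::as_ligand_list(fx$sdfset)
  bad <- ligs[[2]]
  bad$id <- "bad"
  n <- bad$n_atoms
  bad$elements <- c(bad$elements, "C")
  bad$coords <- rbind(bad$coords, c(6.5, 2.5, 0))
  # five explicit neighbours on the terminal tail atom's carbon
  bad$bonds <- rbind(bad$bonds, data.frame(a = 8L, b = n + 1L, order = 3L))
  bad$n_atoms <- n + 1L
  p <- hybridization_params()
  c1 <- enumerate_cuttable_bonds(ligs[[1]], p)
  c2 <- enumerate_cuttable_bonds(bad, p)
  rec <- recombine(c1[1, ], c2[1, ], ligs[[1]], bad, p)
  expect_equal(length(rec$hybrids), 1)
  expect_equal(rec$dropped, 1)
  expect_equal(rec$hybrids[[1]]$parent_head_id, "bad")
})

test_that("untangle relaxes a stretched junction without changing topology", {
  fx <- make_aligned_set(k = 2)
  ligs <- hybscreen:::as_ligand_list(fx$sdfset)
  ligs[[2]]$coords[7:9, 1] <- ligs[[2]]$coords[7:9, 1] + 0.9
  p <- hybridization_params()
  c1 <- enumerate_cuttable_bonds(ligs[[1]], p)
  c2 <- enumerate_cuttable_bonds(ligs[[2]], p)
  h <- recombine(c1[1, ], c2[1, ], ligs[[1]], ligs[[2]], p)$hybrids[[1]]
  lig_h <- hybscreen:::parse_molblock_ligand(h$molblock, "h")
  before <- sqrt(sum((lig_h$coords[1, ] - lig_h$coords[7, ])^2))
  expect_gt(before, 2.0)
  u <- untangle_hybrid(h$molblock, steps = 500)
  expect_true(u$relaxed)
  expect_identical(hybscreen:::molblocks_to_smiles(u$molblock), h$smiles)
  lr <- hybscreen:::parse_molblock_ligand(u$molblock, "h")
  after <- sqrt(sum((lr$coords[1, ] - lr$coords[7, ])^2))
  expect_gte(after, 1.3)
  expect_lte(after, 1.7)

  # an already-clean hybrid barely moves
  clean <- generate_library(fx$sdfset)$molblocks[1]
  u2 <- untangle_hybrid(clean, steps = 200)
  expect_true(u2$relaxed)
  a <- hybscreen:::parse_molblock_ligand(clean, "a")$coords
  b <- hybscreen:::parse_molblock_ligand(u2$molblock, "b")$coords
  b <- b[seq_len(nrow(a)), , drop = FALSE]  # minimizer appends explicit H
  expect_lt(sqrt(mean(rowSums((a - b)^2))), 0.5)
})

test_that("second-generation output feeds on first-generation hybrids", {
  fx <- make_aligned_set(k = 3)
  g1 <- generate_library(fx$sdfset, hybridization_params(generations = 1))
  g2 <- generate_library(fx$sdfset, hybridization_params(generations = 2))
  expect_true(all(g1$hybrids$smiles %in% g2$hybrids$smiles))
  expect_gte(nrow(g2$hybrids), nrow(g1$hybrids))
  expect_equal(length(g2$report$generations), 2)
})

test_that("the convenience aligner recovers a rigid transform exactly", {
  fx <- make_aligned_set(k = 2)
  ligs <- hybscreen:::as_ligand_list(fx$sdfset)
  ref <- ligs[[1]]; mov <- ligs[[2]]
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  mov$coords <- sweep(mov$coords %*% t(Rz), 2, c(3, -2, 1), "+")
  back <- align_ligand(mov, ref, pairs = cbind(1:6, 1:6))
  rmsd <- sqrt(mean(rowSums((back$coords[1:6, ] - ref$coords[1:6, ])^2)))
  expect_lt(rmsd, 1e-8)
})

test_that("degenerate inputs are rejected with clear errors", {
  # a molblock whose coordinates are all zero has no conformer
  blk <- hybscreen:::build_molblock(
    "flat", c("C", "C", "C", "C"), matrix(0, 4, 3),
    data.frame(a = 1:3, b = 2:4, order = 1L))
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(paste0(blk, "\n$$$$"), "\n")[[1]]))
  expect_error(enumerate_cuttable_bonds(sdf[[1]]), "conformer")
  expect_error(generate_library(list()), "at least 2")
})
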