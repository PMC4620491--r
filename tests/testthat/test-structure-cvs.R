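test_that("switching function hits its landmark values", {
  p <- switching_params(4, 8, r0 = 0.4)
  expect_equal(switching(0, p), 1)
  expect_equal(switching(0.4, p), 0.5)      # L'Hopital limit n/m
  p2 <- switching_params(4, 8, r0 = 0.4, d0 = 0)
  expect_equal(switching(0.2, p2), (1 - 0.5^4) / (1 - 0.5^8),
               tolerance = 1e-6)            # 0.94118
  ## monotone non-increasing, bounded in (0, 1]
  r <- seq(0, 2, by = 0.01)
  v <- switching(r, p)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(v > 0 & v <= 1))
})

test_that("coordination number counts a single pair at r0 as one half", {
  pep <- make_toy_peptide(3, "CCC", seed = 1)
  ## place two CB atoms exactly 4 A (0.4 nm) apart, far from everything
  a <- pep$atoms
  a[a$resno == 1 & a$elety == "CB", c("x", "y", "z")] <- c(100, 0, 0)
  a[a$resno == 3 & a$elety == "CB", c("x", "y", "z")] <- c(104, 0, 0)
  conf <- conformation(pep$sequence, a)
  expect_equal(coordination_number(conf, residue_set = c(1, 3)), 0.5,
               tolerance = 1e-9)
  expect_equal(coordination_number(conf, residue_set = 2), 0)
})

test_that("compact helix has more hydrophobic contacts than extended coil", {
  helix <- make_toy_peptide(20, strrep("H", 20), seed = 1,
                            sequence = rep("L", 20))
  ext <- make_toy_peptide(20, strrep("E", 20), seed = 1,
                          sequence = rep("L", 20))
  expect_gt(coordination_number(helix), coordination_number(ext))
})

test_that("alpha segment count is near the window count on an ideal helix", {
  helix <- make_toy_peptide(40, strrep("H", 40), seed = 1)
  expect_equal(ss_segment_count(helix, "alpha"), 35, tolerance = 1 / 35)
  expect_lt(ss_segment_count(helix, "antibeta"), 1)
})

test_that("all-coil peptides have negligible alpha content on average", {
  vals <- vapply(1:20, function(s)
    ss_segment_count(make_toy_peptide(10, strrep("C", 10), seed = s),
                     "alpha"),
    numeric(1))
  expect_lt(mean(vals), 0.5)
})

test_that("short chains yield zero segment count with a warning", {
  pep <- make_toy_peptide(5, "CCCCC", seed = 1)
  expect_warning(v <- ss_segment_count(pep, "alpha"), "fewer than 6")
  expect_equal(v, 0)
})

test_that("alphabeta similarity scores reference, opposite and orthogonal
           rotamers as 1, 0 and 0.5 per residue", {
  pep <- make_toy_peptide(5, "CCCCC", seed = 1, sequence = rep("L", 5),
                          chi1 = -60)
  n_counted <- 5
  expect_equal(alphabeta_similarity(pep, reference_angles = -60,
                                    class = "hydrophobic"), n_counted,
               tolerance = 1e-9)
  expect_equal(alphabeta_similarity(pep, reference_angles = 120,
                                    class = "hydrophobic"), 0,
               tolerance = 1e-9)
  expect_equal(alphabeta_similarity(pep, reference_angles = 30,
                                    class = "hydrophobic"),
               0.5 * n_counted, tolerance = 1e-9)
})

test_that("secondary-structure assignment labels ideal fixtures correctly
           and partitions residues", {
  helix <- make_toy_peptide(12, strrep("H", 12), seed = 1)
  lab_h <- assign_secondary_structure(helix)
  expect_true(all(lab_h[2:11] == "H"))
  strand <- make_toy_peptide(8, strrep("E", 8), seed = 1)
  lab_e <- assign_secondary_structure(strand)
  expect_true(all(lab_e[2:7] == "E"))
  expect_true(all(lab_e %in% c("H", "E", "P", "C")))
  ## two-residue chain: no complete (phi, psi) pair anywhere -> coil
  pep3 <- make_toy_peptide(3, "CCC", seed = 1)
  a2 <- pep3$atoms[pep3$atoms$resno <= 2, ]
  conf2 <- conformation(pep3$sequence[1:2], a2)
  expect_equal(assign_secondary_structure(conf2), c("C", "C"))
})

test_that("all structural CVs are invariant under rigid-body transforms", {
  pep <- make_toy_peptide(10, "HHHHCCCEEE", seed = 2,
                          sequence = rep("L", 10))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  a2 <- pep$atoms
  xyz <- as.matrix(a2[, c("x", "y", "z")]) %*% R
  a2[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -3, 11), "+")
  pep2 <- conformation(pep$sequence, a2)
  expect_equal(coordination_number(pep2), coordination_number(pep),
               tolerance = 1e-9)
  expect_equal(ss_segment_count(pep2, "alpha"),
               ss_segment_count(pep, "alpha"), tolerance = 1e-7)
  expect_equal(radius_of_gyration(pep2), radius_of_gyration(pep),
               tolerance = 1e-9)
  expect_identical(assign_secondary_structure(pep2),
                   assign_secondary_structure(pep))
})

test_that("radius of gyration matches closed forms and orderings", {
  atoms <- data.frame(resno = c(1, 1, 1, 1), resid = "GLY",
                      elety = c("N", "CA", "C", "O"),
                      x = c(0, 0, 100, 100), y = 0, z = 0)
  ## two clusters 100 A apart act like two points 100 apart: Rg = 50
  conf <- conformation("G", atoms)
  expect_equal(radius_of_gyration(conf), 50, tolerance = 1e-9)
  helix <- make_toy_peptide(40, strrep("H", 40), seed = 1)
  ext <- make_toy_peptide(40, strrep("E", 40), seed = 1)
  expect_gt(radius_of_gyration(ext), radius_of_gyration(helix))
})
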