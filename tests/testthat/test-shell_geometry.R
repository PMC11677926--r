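write_xyz <- function(atoms, path, comment = "test") {
  writeLines(c(nrow(atoms), comment,
               sprintf("%s %.6f %.6f %.6f", atoms$element,
                       atoms$x, atoms$y, atoms$z)), path)
  path
}

test_that("XYZ structures parse with validation", {
  f <- withr::local_tempfile(fileext = ".xyz")
  water <- data.frame(element = c("O", "H", "H"),
                      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93),
                      z = c(0, 0, 0))
  write_xyz(water, f)
  m <- read_structure(f)
  expect_s3_class(m, "shell_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(sum(m$atoms$element == "O"), 1L)

  # malformed coordinate names its line
  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "bad", "O 0 0 0", "H nope 0 0"), f2)
  expect_error(read_structure(f2), "line 4")

  # unknown element
  f3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "x", "Qz 0 0 0"), f3)
  expect_error(read_structure(f3), "unknown element")

  # empty file
  f4 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(), f4)
  expect_error(read_structure(f4), "malformed XYZ")
})

test_that("PDB HETATM water records are indexed", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            1:2, 1:2, c(0, 2.8), c(0, 0), c(0, 0)),
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$element, c("O", "O"))
  expect_equal(m$atoms$x, c(0, 2.8))
})

test_that("first-shell oxygens are selected by distance to the solute", {
  # five waters at known radii from a one-atom solute: exactly three inside
  radii <- c(2.8, 3.0, 3.4, 3.6, 4.0)
  atoms <- rbind(data.frame(element = "C", x = 0, y = 0, z = 0),
                 data.frame(element = "O", x = radii, y = 0, z = 0))
  m <- shell_model(atoms, solute_selection = 1L)
  sel <- first_shell_oxygens(m, cutoff = 3.5)
  expect_length(sel, 3L)
  expect_setequal(m$atoms$x[sel], c(2.8, 3.0, 3.4))
  # boundary cases from the construction
  expect_true(2L %in% first_shell_oxygens(m, 3.0))        # at 3.0: included
  expect_false(5L %in% first_shell_oxygens(m, 3.5))       # at 3.6: excluded
  # empty solute selection gives an empty set, not an error
  m2 <- shell_model(atoms, solute_selection = integer())
  expect_length(first_shell_oxygens(m2), 0L)
})

test_that("pairwise O-O distances match the brute-force oracle", {
  # two oxygens 2.80 apart
  m <- make_toy_shell(oo_target_distances = 2.8)
  ox <- which(m$atoms$element == "O")
  expect_equal(oo_distances(m, ox), 2.8, tolerance = 1e-12)

  # equilateral triangle: three equal distances
  side <- 2.9
  tri <- data.frame(element = "O",
                    x = c(0, side, side / 2), y = c(0, 0, side * sqrt(3) / 2),
                    z = 0)
  mt <- shell_model(rbind(data.frame(element = "C", x = 0, y = 0, z = 10),
                          tri), solute_selection = 1L)
  expect_equal(oo_distances(mt, 2:4), rep(side, 3L), tolerance = 1e-12)

  # random clouds vs the double-loop oracle, several sizes
  for (n in c(10, 25, 50)) {
    m <- make_toy_shell(n_waters = n, radial_range = c(2.0, 4.5),
                        seed = n)
    ox <- which(m$atoms$element == "O")
    xyz <- as.matrix(m$atoms[ox, c("x", "y", "z")])
    expect_equal(oo_distances(m, ox), brute_force_oo(xyz),
                 tolerance = 1e-12)
  }

  # fewer than two oxygens: empty result
  expect_length(oo_distances(m, ox[1L]), 0L)
})

test_that("distances and curves are invariant under rigid-body motion", {
  m <- make_toy_shell(n_waters = 20, radial_range = c(2.0, 4.5), seed = 9)
  ox <- which(m$atoms$element == "O")
  d0 <- oo_distances(m, ox)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  moved <- rigid_motion(xyz)
  atoms2 <- m$atoms; atoms2[, c("x", "y", "z")] <- moved
  m2 <- shell_model(atoms2, solute_selection = m$solute_selection)
  d1 <- oo_distances(m2, ox)
  expect_equal(d1, d0, tolerance = 1e-9)
  # atom reordering leaves the multiset unchanged
  perm <- c(1L, sample(ox))
  m3 <- shell_model(m$atoms[perm, ], solute_selection = 1L)
  expect_equal(oo_distances(m3, 2:(length(ox) + 1L)), d0, tolerance = 1e-12)
})

test_that("interaction curves normalise rank to [0, 1]", {
  c1 <- normalized_interaction_curve(2.8)
  expect_equal(c1$normalized_index, 1)
  c2 <- normalized_interaction_curve(c(2.9, 2.7))
  expect_equal(c2$sorted_distances, c(2.7, 2.9))
  expect_equal(c2$normalized_index, c(0.5, 1))
  # curves of different sizes end at 1 by construction
  c3 <- normalized_interaction_curve(runif(17, 2.6, 3.0))
  expect_equal(max(c3$normalized_index), 1)
  expect_true(all(diff(c3$sorted_distances) >= 0))
  expect_error(normalized_interaction_curve(numeric()), "empty")
})

test_that("uniformly shortened shells shift the curve downward", {
  m <- make_toy_shell(n_waters = 15, radial_range = c(2.4, 3.3), seed = 4)
  ox <- which(m$atoms$element == "O")
  d <- oo_distances(m, ox, r_range = c(0.1, 99))
  shifted <- normalized_interaction_curve(d - 0.05)
  orig <- normalized_interaction_curve(d)
  expect_true(all(shifted$sorted_distances < orig$sorted_distances))
})

test_that("bimodal distance sets produce a second-difference inflection", {
  # two tight populations: strong bonds near 2.7, loose bonds near 2.92
  d <- c(seq(2.68, 2.72, length.out = 8), seq(2.88, 2.96, length.out = 8))
  cv <- normalized_interaction_curve(d)
  d2 <- diff(cv$sorted_distances, differences = 2L)
  k <- which.max(d2)
  # the kink sits at the junction of the two populations
  expect_equal(cv$sorted_distances[k + 1L], 2.72, tolerance = 0.05)
  # and dominates the curvature elsewhere
  expect_gt(max(d2), 10 * stats::median(abs(d2)))
})
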