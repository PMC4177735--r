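test_that("side-chain vectors are C-alpha to vector-atom differences", {
  pdb <- pdb_from_residues(list(
    list(aa = "ASP", resno = 1, ca = c(0, 0, 0), sv = c(1, 2, 2)),
    list(aa = "GLY", resno = 2, ca = c(5, 0, 0)),
    list(aa = "SER", resno = 3, ca = c(9, 0, 0))   # eligible type, OG absent
  ))
  st <- strip_nonprotein(read_structure(pdb))
  sv <- side_chain_vectors(st)
  expect_equal(nrow(sv), 1)
  expect_equal(unlist(sv[1, c("sx", "sy", "sz")], use.names = FALSE), c(1, 2, 2))
  expect_equal(sv$norm, 3)
})

test_that("zero-length side-chain vectors are excluded with a warning", {
  pdb <- pdb_from_residues(list(
    list(aa = "ASP", resno = 1, ca = c(0, 0, 0), sv = c(0, 0, 0)),
    list(aa = "ASP", resno = 2, ca = c(5, 0, 0), sv = c(6, 0, 0))
  ))
  st <- strip_nonprotein(read_structure(pdb))
  expect_warning(sv <- side_chain_vectors(st), "zero-length")
  expect_equal(st$residues$resno[sv$idx], 2)
})

test_that("the grid spans the C-alpha bounding box with spacing extent/29", {
  pdb <- pdb_from_residues(list(
    list(aa = "ALA", resno = 1, ca = c(0, 0, 0)),
    list(aa = "ALA", resno = 2, ca = c(29, 29, 29))
  ))
  g <- build_grid(read_structure(pdb))
  expect_equal(g$origin, c(0, 0, 0))
  expect_equal(g$spacing, c(1, 1, 1))
  expect_equal(g$n, 30L)

  pdb2 <- pdb_from_residues(list(
    list(aa = "ALA", resno = 1, ca = c(0, 0, 0)),
    list(aa = "ALA", resno = 2, ca = c(58, 29, 29))
  ))
  g2 <- build_grid(read_structure(pdb2))
  expect_equal(g2$spacing, c(2, 1, 1))

  # degenerate axis falls back to 0.5 A spacing
  pdb3 <- pdb_from_residues(list(
    list(aa = "ALA", resno = 1, ca = c(0, 0, 0)),
    list(aa = "ALA", resno = 2, ca = c(29, 29, 0))
  ))
  expect_equal(build_grid(read_structure(pdb3))$spacing, c(1, 1, 0.5))

  pdb4 <- pdb_from_residues(list(list(aa = "ALA", resno = 1, ca = c(1, 1, 1))))
  expect_error(build_grid(read_structure(pdb4)), "degenerate")
})

test_that("surrounding membership uses a strict 10 A cutoff and needs a vector", {
  pdb <- pdb_from_residues(list(
    list(aa = "ASP", resno = 1, ca = c(9.99, 0, 0), sv = c(10.99, 0, 0)),
    list(aa = "ASP", resno = 2, ca = c(10.01, 0, 0), sv = c(11.01, 0, 0)),
    list(aa = "SER", resno = 3, ca = c(1, 0, 0)),   # no OG -> ineligible
    list(aa = "GLY", resno = 4, ca = c(2, 0, 0))
  ))
  st <- strip_nonprotein(read_structure(pdb))
  idx <- surrounding_residues(c(0, 0, 0), st, radius = 10)
  expect_equal(st$residues$resno[idx], 1)
})

test_that("theta matches hand geometry for parallel, orthogonal, antiparallel", {
  pdb <- pdb_from_residues(list(
    list(aa = "ASP", resno = 1, ca = c(0, 0, 0), sv = c(2, 0, 0))
  ))
  st <- strip_nonprotein(read_structure(pdb))
  expect_equal(angle_theta(c(1, 0, 0), st, 1), 0)
  expect_equal(angle_theta(c(0, 3, 0), st, 1), 90)
  expect_equal(angle_theta(c(-1, 0, 0), st, 1), 180)
  expect_error(angle_theta(c(0, 0, 0), st, 1), "coincides")
})

test_that("theta is invariant under rigid rotation plus translation", {
  set.seed(3)
  # random rotation matrix via QR
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- c(12, -7, 3)
  ca <- c(1, 2, 3); sv <- ca + c(1.5, -0.5, 1); pt <- c(4, 4, 4)
  mk <- function(ca, sv) {
    strip_nonprotein(read_structure(pdb_from_residues(list(
      list(aa = "GLU", resno = 1, ca = ca, sv = sv)
    ))))
  }
  # PDB coordinates carry 3 decimals, so transform before formatting and
  # compare at the formatting precision
  a1 <- angle_theta(pt, mk(round(ca, 3), round(sv, 3)), 1)
  a2 <- angle_theta(as.numeric(Q %*% pt + shift),
                    mk(round(as.numeric(Q %*% ca + shift), 3),
                       round(as.numeric(Q %*% sv + shift), 3)), 1)
  expect_lt(abs(a1 - a2), 0.15)
  # and exactly (to 1e-9 degrees) when geometry is not routed through PDB text
  v <- pt - ca; s <- sv - ca
  ang <- function(v, s) acos(sum(v * s) / sqrt(sum(v^2) * sum(s^2))) * 180 / pi
  expect_lt(abs(ang(v, s) - ang(as.numeric(Q %*% v), as.numeric(Q %*% s))), 1e-9)
})

test_that("candidate points obey the N >= 3 and mean-theta <= 80 filters", {
  spec <- toy_site_spec(seed = 5)
  st <- strip_nonprotein(read_structure(make_toy_structure(spec)))
  cand <- candidate_points(st)
  expect_gt(cand$n_after_theta, 0)
  expect_true(all(lengths(cand$surrounding) >= 3))
  expect_true(all(cand$mean_theta <= 80))
  expect_true(all(unlist(cand$theta) >= 0 & unlist(cand$theta) <= 180))
  # mean theta equals the arithmetic mean of the per-residue angles
  expect_equal(cand$mean_theta, vapply(cand$theta, mean, 0))
})

test_that("points with fewer than three surrounding residues are removed first", {
  # two inward-pointing residues only: every point has N < 3
  pdb <- pdb_from_residues(list(
    list(aa = "ASP", resno = 1, ca = c(4, 0, 0), sv = c(2, 0, 0)),
    list(aa = "GLU", resno = 2, ca = c(-4, 0, 0), sv = c(-2, 0, 0)),
    list(aa = "GLY", resno = 3, ca = c(0, 4, 18))
  ))
  st <- strip_nonprotein(read_structure(pdb))
  cand <- candidate_points(st)
  expect_equal(cand$n_after_theta, 0)
  expect_equal(length(cand$surrounding), 0)
})

test_that("an inward-pointing ring yields near-zero mean theta at its center", {
  # 6 vector-bearing residues on a ring, side chains at the centroid
  n <- 6
  res <- lapply(seq_len(n), function(i) {
    a <- 2 * pi * (i - 1) / n
    ca <- c(6 * cos(a), 6 * sin(a), 0)
    list(aa = "ASP", resno = i, ca = ca, sv = ca - 2.4 * ca / sqrt(sum(ca^2)))
  })
  res[[n + 1]] <- list(aa = "GLY", resno = n + 1, ca = c(0, 0, 15))
  st <- strip_nonprotein(read_structure(pdb_from_residues(res)))
  cand <- candidate_points(st)
  d_center <- sqrt(rowSums(cand$points^2))
  near <- which(d_center < 1.5)
  expect_gt(length(near), 0)
  expect_true(all(cand$mean_theta[near] < 15))
})

test_that("inward sites show smaller angles than outward controls at the same geometry", {
  for (seed in 1:8) {
    inward <- toy_site_spec(seed = seed, jitter_deg = 8)
    outward <- toy_site_spec(seed = seed, displacement = -2.4, jitter_deg = 8)
    th <- function(spec) {
      st <- strip_nonprotein(read_structure(make_toy_structure(spec)))
      mean(vapply(seq_len(spec$n_site),
                  function(i) angle_theta(c(0, 0, 0), st, i), 0))
    }
    expect_lt(th(inward), th(outward))
  }
})
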