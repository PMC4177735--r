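# small scoring fixtures: structure + manually chosen candidate sets so
# triplet combinatorics are fully controlled

scoring_fixture <- function(seed, n = 12, max_points = 40) {
  st <- strip_nonprotein(read_structure(random_blob_pdb(n = n, seed = seed,
                                                        spread = 18)))
  fl <- wcn(st)
  sv_idx <- which(st$residues$has_sv)
  list(st = st, fl = fl, sv_idx = sv_idx)
}

test_that("triplet feature scores follow w_n + z_w + z_a", {
  expect_equal(score_triplet(c(0, 0, 0), c(0, 0, 0)), c(0, 0, 0))
  expect_equal(score_triplet(c(1, 1, 1), c(0, 0, 0)), c(2, 2, 2))
  expect_equal(score_triplet(c(3, 0, 0), c(0, 0, 0)), c(4, 1, 1))
})

test_that("brute-force accumulation has the expected triplet combinatorics", {
  set.seed(1)
  fx <- scoring_fixture(101)
  pr <- default_profiles()
  stopifnot(length(fx$sv_idx) >= 5)
  # one point with N = 3: every member scored exactly once
  cand3 <- manual_candidates(list(fx$sv_idx[1:3]))
  s3 <- accumulate_scores_bruteforce(fx$st, cand3, fx$fl, pr)
  expect_equal(sort(s3$triplet_count[s3$idx %in% fx$sv_idx[1:3]]), c(1L, 1L, 1L))
  # one point with N = 5: C(5,3) = 10 triplets, each member in C(4,2) = 6
  cand5 <- manual_candidates(list(fx$sv_idx[1:5]))
  s5 <- accumulate_scores_bruteforce(fx$st, cand5, fx$fl, pr)
  expect_equal(sum(s5$triplet_count) / 3, 10)
  expect_true(all(s5$triplet_count[s5$idx %in% fx$sv_idx[1:5]] == 6L))
  # residue surrounding two points accumulates both contributions
  cand2 <- manual_candidates(list(fx$sv_idx[1:3], fx$sv_idx[c(1, 4, 5)]))
  s2 <- accumulate_scores_bruteforce(fx$st, cand2, fx$fl, pr)
  expect_equal(s2$triplet_count[s2$idx == fx$sv_idx[1]], 2L)
})

test_that("with a uniform profile, z_a vanishes and scores reduce to WCN terms", {
  fx <- scoring_fixture(7)
  u <- matrix(1 / 19, 20, 20,
              dimnames = list(rownames(default_profiles()),
                              colnames(default_profiles())))
  cand <- manual_candidates(list(fx$sv_idx[1:4]))
  expect_warning(s <- accumulate_scores_bruteforce(fx$st, cand, fx$fl, u),
                 "constant")
  # N = 4: member j in C(3,2) = 3 triplets; hand formula for the WCN part
  j <- fx$sv_idx[1]
  zw <- fx$fl$z_w
  others <- setdiff(fx$sv_idx[1:4], j)
  expected <- 3 * (4 / 3) * zw[j] + (2 / 3) * sum(zw[others])
  expect_equal(s$S[s$idx == j], expected, tolerance = 1e-12)
})

test_that("fast accumulation equals the brute-force oracle", {
  pr <- default_profiles()
  for (seed in 1:25) {
    set.seed(seed)
    fx <- scoring_fixture(seed + 300, n = 14)
    k <- length(fx$sv_idx)
    if (k < 5) next
    sets <- lapply(1:6, function(i) {
      sz <- sample(3:min(12, k), 1)
      sample(fx$sv_idx, sz)
    })
    cand <- manual_candidates(sets)
    a <- accumulate_scores_bruteforce(fx$st, cand, fx$fl, pr)
    b <- accumulate_scores_fast(fx$st, cand, fx$fl, pr)
    expect_lt(max(abs(a$S - b$S)), 1e-9)
    expect_identical(a$triplet_count, b$triplet_count)
    expect_equal(attr(a, "a_mean"), attr(b, "a_mean"), tolerance = 1e-12)
    expect_equal(attr(a, "a_sd"), attr(b, "a_sd"), tolerance = 1e-12)
  }
})

test_that("scores are additive over disjoint candidate-point sets", {
  fx <- scoring_fixture(55, n = 14)
  pr <- default_profiles()
  set.seed(9)
  k <- length(fx$sv_idx)
  setsA <- lapply(1:3, function(i) sample(fx$sv_idx, sample(3:min(8, k), 1)))
  setsB <- lapply(1:3, function(i) sample(fx$sv_idx, sample(3:min(8, k), 1)))
  # additivity holds for the WCN part of S; the z_a normalization is
  # protein-wide, so fix a shared degenerate (uniform) profile where z_a = 0
  u <- matrix(1 / 19, 20, 20, dimnames = dimnames(unclass(pr)))
  sA <- suppressWarnings(accumulate_scores_fast(fx$st, manual_candidates(setsA), fx$fl, u))
  sB <- suppressWarnings(accumulate_scores_fast(fx$st, manual_candidates(setsB), fx$fl, u))
  sAB <- suppressWarnings(accumulate_scores_fast(fx$st, manual_candidates(c(setsA, setsB)),
                                                 fx$fl, u))
  expect_equal(sA$S + sB$S, sAB$S, tolerance = 1e-10)
})

test_that("empty candidate lists give all-zero scores", {
  fx <- scoring_fixture(3)
  s <- accumulate_scores_fast(fx$st, manual_candidates(list()), fx$fl,
                              default_profiles())
  expect_true(all(s$S == 0))
  expect_true(all(s$triplet_count == 0L))
})

test_that("ranking is descending with deterministic tie-breaks", {
  df <- data.frame(idx = 1:4, chain = "A", resno = c(10, 7, 3, 1),
                   icode = "", aa = "ASP", S = c(5, 5, 2, 3),
                   triplet_count = c(4L, 4L, 1L, 2L),
                   z_wcn = 0, mean_z_a = 0, stringsAsFactors = FALSE)
  r <- rank_residues(df)
  expect_equal(r$resno, c(7, 10, 1, 3))
  expect_equal(r$rank, 1:4)
  # unscored residues go last even against negative scores
  df2 <- df
  df2$S <- c(-1, -2, 0, 0)
  df2$triplet_count <- c(1L, 1L, 0L, 0L)
  r2 <- rank_residues(df2)
  expect_equal(r2$resno, c(10, 7, 1, 3))
})

test_that("the backbone report covers exactly the 8 non-vector types", {
  pdb <- pdb_from_residues(list(
    list(aa = "GLY", resno = 1, ca = c(0, 0, 0)),
    list(aa = "ASP", resno = 2, ca = c(4, 0, 0), sv = c(5, 1, 0)),
    list(aa = "MET", resno = 3, ca = c(8, 0, 0)),
    list(aa = "GLU", resno = 4, ca = c(4, 4, 0), sv = c(5, 5, 0))
  ))
  st <- strip_nonprotein(read_structure(pdb))
  fl <- wcn(st)
  pr <- default_profiles()
  rep <- backbone_report(st, fl, pr)
  expect_setequal(rep$aa, c("GLY", "MET"))
  expect_false("ASP" %in% rep$aa)
  expect_equal(rep$best_profile_affinity[rep$aa == "GLY"],
               max(pr["GLY", ]))
  # backbone residues never enter the ranked list
  cand <- manual_candidates(list(which(st$residues$has_sv)))
  ranked <- rank_residues(suppressWarnings(
    accumulate_scores_fast(st, cand, fl, pr)))
  expect_false(any(ranked$aa %in% c("GLY", "MET")))
})
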