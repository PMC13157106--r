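make_pair_ensemble <- function(distances) {
  # one frame per distance: two CA-only residues that far apart
  frames <- lapply(distances, two_residue_structure)
  cv_ensemble(frames)
}

test_that("contact probability is the pooled contact fraction, exactly", {
  cm <- make_pair_ensemble(c(5, 7, 9, 20))  # 3 of 4 within 12 A
  p <- contact_map(cm)$p
  expect_equal(p["1", "2"], 0.75)
  always <- contact_map(make_pair_ensemble(rep(11.9, 3)))$p
  expect_equal(always["1", "2"], 1)
  never <- contact_map(make_pair_ensemble(rep(12.1, 3)))$p
  expect_equal(never["1", "2"], 0)
})

test_that("a pair at exactly the cutoff counts as a contact", {
  p <- contact_map(make_pair_ensemble(12.0))$p
  expect_equal(p["1", "2"], 1)
})

test_that("contact maps are symmetric with unit diagonal", {
  fx <- make_toy_complex(toy_fixture_spec(25), seed = 13, with_cb = FALSE)
  ens <- make_synthetic_ensemble(fx$structure, n_frames = 8, noise_sd = 1,
                                 seed = 3)
  cm <- contact_map(ens)
  expect_equal(cm$p, t(cm$p))
  expect_true(all(diag(cm$p) == 1))
  expect_true(all(cm$p >= 0 & cm$p <= 1))
  expect_equal(cm$n_frames, 8)
})

test_that("model-set contact maps average across models", {
  s1 <- two_residue_structure(5)
  s2 <- two_residue_structure(30)
  one <- contact_map_from_models(list(s1))
  expect_true(all(one$p %in% c(0, 1)))  # single model: binary map
  expect_equal(one$p["1", "2"], 1)
  five <- contact_map_from_models(list(s1, s2, s2, s1, s2))
  expect_equal(five$p["1", "2"], 0.4)  # within cutoff in 2 of 5
  copies <- contact_map_from_models(list(s1, s1, s1))
  expect_equal(copies$p, one$p)  # idempotent over identical copies
})

test_that("mismatched model topologies are rejected", {
  s1 <- two_residue_structure(5)
  s3 <- build_structure(data.frame(chain = "A", resno = 1, resname = "GLY",
                                   atom = "CA", x = 0, y = 0, z = 0))
  expect_error(contact_map_from_models(list(s1, s3)), "topology")
})

test_that("domain contact summary reproduces planted blocks", {
  ann <- domain_annotation(c("D1", "D2"), c(1, 4), c(3, 6),
                           c(TRUE, FALSE))
  p <- matrix(0, 6, 6, dimnames = list(1:6, 1:6))
  diag(p) <- 1
  p[1:3, 4:6] <- 0.6; p[4:6, 1:3] <- 0.6
  map <- structure(list(p = p, cutoff = 12, n_frames = 10,
                        replicates = table(1)), class = "contact_map")
  s <- domain_contact_summary(map, ann)
  expect_equal(s["D1", "D2"], 0.6)
  expect_equal(s["D2", "D1"], 0.6)
  expect_equal(s["D1", "D1"], 0)  # off-diagonal intra block is empty here
  zero <- map; zero$p <- matrix(0, 6, 6); diag(zero$p) <- 1
  sz <- domain_contact_summary(zero, ann)
  expect_equal(sz["D1", "D2"], 0)
  one_dom <- domain_annotation("ALL", 1, 6, TRUE)
  expect_equal(dim(domain_contact_summary(map, one_dom)), c(1, 1))
  short <- domain_annotation("D1", 1, 3, TRUE)
  expect_error(domain_contact_summary(map, short), "does not cover")
})

test_that("superposition matches bio3d and recovers rigid motions", {
  set.seed(21)
  for (rep in 1:5) {
    P <- matrix(rnorm(60, sd = 5), 20, 3)
    Q <- matrix(rnorm(60, sd = 5), 20, 3)
    kf <- kabsch_fit(P, Q)
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)),
                                              mobile = as.vector(t(P))))
    ref <- sqrt(mean(colSums(matrix((fitted - as.vector(t(Q)))^2,
                                    nrow = 3))))
    expect_equal(kf$rmsd, ref, tolerance = 1e-6)
    expect_equal(det(kf$rotation), 1, tolerance = 1e-9)
  }
  # exact recovery of a pure rigid motion
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  Q <- sweep(P %*% rotation_about_z(1.2), 2, c(4, -6, 2), "+")
  expect_lt(kabsch_fit(P, Q)$rmsd, 1e-9)
  expect_error(kabsch_fit(P[1:2, ], Q[1:2, ]), "at least 3")
})

test_that("rigidly moved frames give zero RMSD after superposition", {
  fx <- g3bp1_gr20_fixture(seed = 5)
  moved <- transform_structure(fx$structure, rotation_about_z(0.7),
                               c(10, -4, 3))
  ens <- cv_ensemble(list(moved))
  tr <- per_domain_rmsd(ens, fx$structure, fx$annotation,
                        align_on = "NTF2L")
  expect_lt(max(tr$values), 1e-6)
  # copies of the reference itself are trivially zero
  ens0 <- cv_ensemble(list(fx$structure, fx$structure))
  tr0 <- per_domain_rmsd(ens0, fx$structure, fx$annotation)
  expect_equal(max(tr0$values), 0)
})

test_that("a planted uniform domain displacement is measured exactly", {
  fx <- g3bp1_gr20_fixture(seed = 11)
  s <- fx$structure
  rows <- s$atom$resid %in% domain_indices(fx$annotation, "RRM")
  s$atom$x[rows] <- s$atom$x[rows] + 2
  tr <- per_domain_rmsd(cv_ensemble(list(s)), fx$structure, fx$annotation,
                        align_on = "NTF2L")
  expect_equal(unname(tr$values[1, "RRM"]), 2, tolerance = 1e-9)
  others <- setdiff(colnames(tr$values), "RRM")
  expect_lt(max(tr$values[1, others]), 1e-9)
})

test_that("heavy-only RMSD ignores hydrogens", {
  fx <- make_toy_complex(toy_fixture_spec(10, structured = TRUE), seed = 3,
                         with_cb = TRUE, with_h = TRUE)
  s <- fx$structure
  hrows <- !s$atom$heavy
  expect_gt(sum(hrows), 0)
  s$atom$x[hrows] <- s$atom$x[hrows] + 50  # scatter hydrogens only
  tr <- per_domain_rmsd(cv_ensemble(list(s)), fx$structure, fx$annotation,
                        align_on = "CHAIN")
  expect_lt(max(tr$values), 1e-9)
  tr_all <- per_domain_rmsd(cv_ensemble(list(s)), fx$structure,
                            fx$annotation, align_on = "CHAIN",
                            heavy_only = FALSE)
  expect_gt(max(tr_all$values), 1)
})

test_that("replicate mean and SD match the closed form", {
  fx <- make_toy_complex(toy_fixture_spec(8), seed = 2, with_cb = FALSE)
  # two replicates of two frames: displace all atoms along x by known amounts
  mk <- function(dx) transform_structure(fx$structure, diag(3), c(dx, 0, 0))
  ens <- cv_ensemble(list(mk(1), mk(3), mk(2), mk(6)),
                     replicate = c(1, 1, 2, 2))
  tr <- per_domain_rmsd(ens, fx$structure, fx$annotation, align_on = "none")
  expect_equal(unname(tr$values[, "CHAIN"]), c(1, 3, 2, 6))
  # time point 1: replicates {1, 2}; time point 2: {3, 6}; population SD
  expect_equal(unname(tr$mean[, "CHAIN"]), c(1.5, 4.5))
  expect_equal(unname(tr$sd[, "CHAIN"]), c(0.5, 1.5))
})

test_that("alignment domains with too few residues are rejected", {
  fx <- make_toy_complex(fixture_spec(list(list(id = "A", segments = list(
    list(label = "TINY", length = 2, structured = TRUE),
    list(label = "REST", length = 10, structured = FALSE))))), seed = 1)
  ens <- cv_ensemble(list(fx$structure))
  expect_error(per_domain_rmsd(ens, fx$structure, fx$annotation,
                               align_on = "TINY"), ">= 3")
})
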