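test_that("restraint loss matches hand-computed displacement cases", {
  ref <- matrix(0, 2, 3, dimnames = list(1:2, NULL))
  sp <- restraint_spec(1:2, ref)
  expect_equal(restraint_loss(ref, sp), 0)
  shifted <- ref; shifted[, 1] <- 3
  expect_equal(restraint_loss(shifted, sp), 9)
  # residues displaced by (1,0,0) and (0,2,0): mean(1, 4) = 2.5
  two <- ref; two[1, 1] <- 1; two[2, 2] <- 2
  expect_equal(restraint_loss(two, sp), 2.5)
  expect_error(restraint_loss(ref[1, , drop = FALSE], sp),
               "restrained residue")
})

test_that("attractive loss clamps the mean, not the pairs", {
  line <- function(xs) matrix(c(xs, rep(0, 2 * length(xs))),
                              ncol = 3, dimnames = list(seq_along(xs), NULL))
  tm1 <- cv_term("attractive", residue_group("a", 1), residue_group("b", 2))
  expect_equal(attractive_loss(line(c(0, 5)), tm1), 0)   # within cutoff
  expect_equal(attractive_loss(line(c(0, 10)), tm1), 2)  # 10 - 8
  # 2x2 all-pairs distances {10, 12, 6, 8}: mean({2, 4, -2, 0}) = 1
  coords <- rbind("1" = c(0, 0, 0), "2" = c(18, 0, 0),
                  "3" = c(10, 0, 0), "4" = c(12, 0, 0))
  tm2 <- cv_term("attractive", residue_group("a", c(1, 2)),
                 residue_group("b", c(3, 4)))
  d <- oracle_pair_distances(coords, tm2)
  expect_setequal(d, c(10, 12, 8, 6))
  expect_equal(attractive_loss(coords, tm2), 1)
  # flat-bottom variant clamps per pair: mean({2, 4, 0, 0}) = 1.5
  expect_equal(attractive_loss(coords, tm2, per_pair_clamp = TRUE), 1.5)
})

test_that("repulsive loss mirrors the attractive semantics", {
  line <- rbind("1" = c(0, 0, 0), "2" = c(5, 0, 0))
  tm <- cv_term("repulsive", residue_group("a", 1), residue_group("b", 2))
  expect_equal(repulsive_loss(line, tm), 3)  # 8 - 5
  far <- rbind("1" = c(0, 0, 0), "2" = c(9, 0, 0))
  expect_equal(repulsive_loss(far, tm), 0)
  # pairs at {5, 12}: mean({3, -4}) < 0, clamped to 0
  coords <- rbind("1" = c(0, 0, 0), "2" = c(5, 0, 0), "3" = c(12, 0, 0))
  tm2 <- cv_term("repulsive", residue_group("a", 1),
                 residue_group("b", c(2, 3)))
  expect_equal(repulsive_loss(coords, tm2), 0)
})

test_that("positional pairing requires equal sizes and pairs i-with-i", {
  expect_error(cv_term("attractive", residue_group("a", 1:2),
                       residue_group("b", 1:3), pairing = "positional"),
               "equal group sizes")
  coords <- rbind("1" = c(0, 0, 0), "2" = c(0, 5, 0),
                  "3" = c(10, 0, 0), "4" = c(0, 25, 0))
  tm <- cv_term("attractive", residue_group("a", c(1, 2)),
                residue_group("b", c(3, 4)), pairing = "positional")
  expect_equal(attractive_loss(coords, tm), mean(c(10, 20)) - 8)
})

test_that("regularization loss is the sum of the three confidence gaps", {
  expect_equal(regularization_loss(confidence_bundle(rep(1, 4), 1, 1)), 0)
  expect_equal(regularization_loss(confidence_bundle(rep(0, 4), 0, 0)), 3)
  b <- confidence_bundle(c(0.7, 0.9), 0.7, 0.9)  # mean pLDDT 0.8
  expect_equal(regularization_loss(b), 0.6)
  expect_error(regularization_loss(list(plddt = c(0.5, 1.2), ptm = 1,
                                        iptm = 1)), "\\[0, 1\\]")
})

test_that("composite loss assembles l_cv and l_afex with the weights", {
  coords <- rbind("1" = c(0, 0, 0), "2" = c(10, 0, 0))
  tm <- cv_term("attractive", residue_group("a", 1), residue_group("b", 2))
  b <- confidence_bundle(c(0.7, 0.9), 0.7, 0.9)
  lb <- afex_loss(coords, NULL, list(tm), b, w_c = 0.1, w_r = 1)
  expect_s3_class(lb, "loss_breakdown")
  expect_equal(lb$l_cv, lb$l_rest + lb$l_attr + lb$l_repl)
  expect_equal(lb$l_attr, 2)
  expect_equal(lb$l_regular, 0.6)
  expect_equal(lb$l_afex, 0.1 * 2 + 1 * 0.6)
  # weight corner cases
  expect_equal(afex_loss(coords, NULL, list(tm), b, 1, 0)$l_afex, lb$l_cv)
  perfect <- confidence_bundle(c(1, 1), 1, 1)
  near <- rbind("1" = c(0, 0, 0), "2" = c(5, 0, 0))
  expect_equal(afex_loss(near, NULL, list(tm), perfect, 0, 1)$l_afex, 0)
  expect_error(afex_loss(coords, w_c = -1), ">= 0")
})

test_that("losses match the brute-force oracle on random structures", {
  for (seed in c(3, 17, 91)) {
    n <- 40
    coords <- random_coords(n, seed)
    terms <- random_terms(n, seed)
    spec <- restraint_spec(1:8, random_coords(n, seed + 1)[1:8, , drop = FALSE])
    expect_equal(restraint_loss(coords, spec), oracle_restraint(coords, spec),
                 tolerance = 1e-12)
    for (tm in terms) {
      if (tm$kind == "attractive")
        expect_equal(attractive_loss(coords, tm),
                     oracle_attractive(coords, tm), tolerance = 1e-12)
      else
        expect_equal(repulsive_loss(coords, tm),
                     oracle_repulsive(coords, tm), tolerance = 1e-12)
    }
  }
})

test_that("all-pairs losses are invariant to residue order within groups", {
  coords <- random_coords(20, 5)
  tm <- cv_term("attractive", residue_group("a", c(1, 4, 7)),
                residue_group("b", c(12, 15, 18, 20)), cutoff = 6)
  tm_perm <- cv_term("attractive", residue_group("a", c(7, 1, 4)),
                     residue_group("b", c(20, 12, 18, 15)), cutoff = 6)
  expect_equal(attractive_loss(coords, tm), attractive_loss(coords, tm_perm))
})

test_that("distance losses are rigid-motion invariant; restraint is not", {
  coords <- random_coords(15, 11)
  R <- rotation_about_z(0.8)
  moved <- sweep(coords %*% R, 2, c(5, -3, 2), "+")
  dimnames(moved) <- dimnames(coords)
  tma <- cv_term("attractive", residue_group("a", 1:3),
                 residue_group("b", 10:12), cutoff = 10)
  tmr <- cv_term("repulsive", residue_group("a", 4:5),
                 residue_group("b", 13:14), cutoff = 30)
  expect_equal(attractive_loss(moved, tma), attractive_loss(coords, tma))
  expect_equal(repulsive_loss(moved, tmr), repulsive_loss(coords, tmr))
  spec <- restraint_spec(1:15, coords)
  expect_equal(restraint_loss(coords, spec), 0)
  expect_gt(restraint_loss(moved, spec), 0)
})

test_that("attractive loss is non-decreasing in any single pair distance", {
  base <- rbind("1" = c(0, 0, 0), "2" = c(4, 0, 0), "3" = c(9, 0, 0),
                "4" = c(14, 0, 0))
  tm <- cv_term("attractive", residue_group("a", c(1, 2)),
                residue_group("b", c(3, 4)))
  tr <- cv_term("repulsive", residue_group("a", c(1, 2)),
                residue_group("b", c(3, 4)), cutoff = 20)
  pulls <- seq(0, 10, by = 0.5)
  la <- lr <- numeric(length(pulls))
  for (k in seq_along(pulls)) {
    cc <- base; cc["4", 1] <- base["4", 1] + pulls[k]
    la[k] <- attractive_loss(cc, tm)
    lr[k] <- repulsive_loss(cc, tr)
  }
  expect_true(all(diff(la) >= -1e-12))
  expect_true(all(diff(lr) <= 1e-12))
})
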