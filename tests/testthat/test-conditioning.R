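test_that("nothing to optimize leaves theta unchanged with a zero trace", {
  fx <- make_toy_complex(toy_fixture_spec(10), seed = 2, with_cb = FALSE)
  gen <- toy_chain_generator(fx$structure)  # perfect-confidence surrogate
  fit <- afex_condition(gen, NULL, list(), weight_schedule(20), seed = 1)
  expect_equal(max(abs(coef(fit))), 0)
  expect_equal(max(abs(fit$trace$l_afex)), 0)
  expect_true(fit$converged)
})

test_that("an attractive singleton pair 20 A apart is pulled within cutoff", {
  s <- two_residue_structure(20)
  gen <- toy_chain_generator(s)
  tm <- list(cv_term("attractive", residue_group("a", 1),
                     residue_group("b", 2)))
  fit <- afex_condition(gen, NULL, tm, weight_schedule(500), seed = 1)
  d <- sqrt(sum((fit$coords["1", ] - fit$coords["2", ])^2))
  expect_lte(d, 8.5)
  expect_equal(attractive_loss(fit$coords, tm[[1]]), 0)
})

test_that("identical seed and config reproduce the trace bit for bit", {
  fx <- make_toy_complex(toy_fixture_spec(20), seed = 4, with_cb = FALSE)
  gen <- toy_chain_generator(fx$structure, sigma = 3)
  tm <- list(cv_term("attractive", residue_group("a", 3),
                     residue_group("b", 18)))
  f1 <- afex_condition(gen, NULL, tm, weight_schedule(100), seed = 7)
  f2 <- afex_condition(gen, NULL, tm, weight_schedule(100), seed = 7)
  expect_identical(f1$trace, f2$trace)
  expect_identical(fitted(f1), fitted(f2))
})

test_that("with w_r = 0 and small steps, L_CV decreases monotonically", {
  fx <- make_toy_complex(toy_fixture_spec(15), seed = 9, with_cb = FALSE)
  gen <- toy_chain_generator(fx$structure)
  tm <- list(cv_term("attractive", residue_group("a", 1),
                     residue_group("b", 15)))
  sched <- weight_schedule(300, w_c_start = 1, w_c_end = 1,
                           w_r_start = 0, w_r_end = 0)
  fit <- afex_condition(gen, NULL, tm, sched, step_size = 1e-3, seed = 1)
  expect_lt(fit$trace$l_cv[300], fit$trace$l_cv[1])
  expect_true(all(diff(fit$trace$l_cv) <= 1e-12))
})

test_that("annealing shifts the composite from CV share to confidence", {
  s <- two_residue_structure(25)
  gen <- toy_chain_generator(s, sigma = 4)
  tm <- list(cv_term("attractive", residue_group("a", 1),
                     residue_group("b", 2)))
  fit <- afex_condition(gen, NULL, tm, weight_schedule(400), seed = 1)
  tr <- fit$trace
  share <- (tr$w_c * tr$l_cv) / pmax(tr$l_afex, 1e-12)
  # early iterates are dominated by the CV term, late ones are not
  expect_gt(mean(share[1:20]), 0.99)
  expect_lt(mean(share[381:400]), mean(share[1:20]))
})

test_that("the best iterate by composite loss is kept, not the last", {
  # craft a run where the composite rises late: constraint satisfied early,
  # then the rising w_r makes the (imperfect) surrogate confidence dominate
  s <- two_residue_structure(12)
  gen <- toy_chain_generator(s, sigma = 2, ptm = 0.5, iptm = 0.5)
  tm <- list(cv_term("attractive", residue_group("a", 1),
                     residue_group("b", 2)))
  fit <- afex_condition(gen, NULL, tm, weight_schedule(300), seed = 1)
  expect_equal(fit$trace$l_afex[fit$best_step + 1],
               min(fit$trace$l_afex))
  expect_equal(unname(fit$trace$l_afex[fit$best_step + 1]),
               afex_loss(fit$coords, NULL, tm, fit$confidence,
                         w_c = fit$trace$w_c[fit$best_step + 1],
                         w_r = fit$trace$w_r[fit$best_step + 1])$l_afex)
})

test_that("satisfaction report covers the preset term inventory", {
  fx <- g3bp1_gr20_fixture(seed = 1)
  cfg <- load_cv_config(cv_preset("g3bp1-gr20"), fx$structure,
                        fx$annotation)
  rep <- cv_satisfaction(ca_coords(fx$structure), cfg$restraint, cfg$terms)
  expect_equal(nrow(rep), 4)  # 2 attractive + 1 repulsive + 1 restraint
  expect_equal(sum(rep$kind == "attractive"), 2)
  expect_equal(sum(rep$kind == "repulsive"), 1)
  expect_equal(sum(rep$kind == "restraint"), 1)
  expect_equal(rep$loss[rep$kind == "restraint"], 0)  # at reference
})

test_that("satisfaction flags and excess distances are arithmetic", {
  coords <- rbind("1" = c(0, 0, 0), "2" = c(10, 0, 0))
  tm <- cv_term("attractive", residue_group("a", 1), residue_group("b", 2))
  rep <- cv_satisfaction(coords, NULL, list(tm))
  expect_false(rep$satisfied)
  expect_equal(rep$loss, 2)
  expect_equal(rep$mean_distance, 10)
  pd <- cv_pair_distances(coords, tm)
  expect_equal(pd$distance, 10)
  expect_false(pd$within_cutoff)
  near <- rbind("1" = c(0, 0, 0), "2" = c(6, 0, 0))
  expect_true(cv_satisfaction(near, NULL, list(tm))$satisfied)
})

test_that("non-finite losses abort with a diagnostic naming the step", {
  s <- two_residue_structure(20)
  gen <- toy_chain_generator(s)
  bad_gen <- gen
  bad_gen$produce <- function(theta) {
    out <- gen$produce(theta)
    out$coords["1", 1] <- Inf
    out
  }
  tm <- list(cv_term("attractive", residue_group("a", 1),
                     residue_group("b", 2)))
  expect_error(afex_condition(bad_gen, NULL, tm, weight_schedule(10),
                              seed = 1), "non-finite loss at step 0")
})
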