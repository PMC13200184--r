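test_that("residual vector is sqrt-weighted model minus reference", {
  cf <- chain_fixture()
  recs <- chain_records(cf$params, n = 2)
  # model == reference: zero residuals
  r0 <- fm_residuals(cf$params, recs)
  expect_equal(max(abs(r0)), 0, tolerance = 1e-12)

  # one record, one active atom, known offset, w_atomic = 4 -> residual 2x
  rec <- recs[[1]]
  rec$ref_forces[1, ] <- rec$ref_forces[1, ] - c(1, 0, 0)
  rec$mask <- c(TRUE, FALSE, FALSE, FALSE)
  stage <- fit_stage_spec("A|T1-T1", w_atomic = 4)
  r <- fm_residuals(cf$params, list(rec), stage)
  expect_equal(r[1:3], c(2, 0, 0))

  # squared norm equals the brute-force component sum
  set.seed(4)
  p2 <- cf$params
  p2$pairs$A <- p2$pairs$A * 1.1
  stage1 <- fit_stage_spec("A|T1-T1")
  rr <- fm_residuals(p2, recs, stage1)
  brute <- 0
  for (rc in recs) {
    ev <- evaluate_energy_forces(rc$config, p2, cutoff = 12)
    dF <- ev$forces - rc$ref_forces
    brute <- brute + sum(dF^2)
    mt_m <- molecular_force_torque(ev$forces, rc$config)
    mt_r <- molecular_force_torque(rc$ref_forces, rc$config)
    brute <- brute + sum((mt_m[, 2:7] - mt_r[, 2:7])^2)
  }
  expect_equal(sum(rr^2), brute, tolerance = 1e-10)

  expect_error(fm_residuals(cf$params, list()), "empty training set")
})

test_that("regression metrics follow the least-squares conventions", {
  x <- c(1, 2, 3)
  m <- regression_metrics(x, x)
  expect_equal(unname(m), c(0, 1, 1))

  m2 <- regression_metrics(x + 3, x)
  expect_equal(m2[["rmse"]], 3)

  m3 <- regression_metrics(2 * x, x)
  expect_equal(m3[["slope"]], 2)
  expect_equal(m3[["rmse"]], sqrt(14 / 3))
  expect_equal(m3[["r_squared"]], 1)

  expect_error(regression_metrics(1, 1), "at least 2")
  expect_error(regression_metrics(1:3, 1:4), "length mismatch")
})

test_that("linear parameters are recovered exactly from noiseless data", {
  recs <- gen_training_set(7, n_configs = 6, n_molecules = 4,
                           phase = "neat", sigma = 0)
  truth <- attr(recs, "ground_truth")$params
  start <- truth
  start$pairs$A <- truth$pairs$A * 1.3
  start$bonds$k <- truth$bonds$k * 0.8
  start$angles$k <- truth$angles$k * 1.2
  fit <- fit_forcefield(start, recs, default_fit_stages(start),
                        cutoff = 12)
  expect_rel_equal(fit$pairs$A, truth$pairs$A, 1e-6)
  expect_rel_equal(fit$bonds$k, truth$bonds$k, 1e-6)
  expect_rel_equal(fit$angles$k, truth$angles$k, 1e-6)
  # frozen parameters bit-identical
  expect_identical(fit$pairs$C6, start$pairs$C6)
  expect_identical(fit$pairs$b, start$pairs$b)
})

test_that("a free repulsion decay b is recovered from a start within 20%", {
  truth <- chain_fixture()$params
  recs <- chain_pair_records(truth, n = 6)
  start <- truth
  start$pairs["T2-T2", "b"] <- truth$pairs["T2-T2", "b"] * 1.18
  start$pairs$A <- truth$pairs$A * 1.2
  stage <- fit_stage_spec(c("A|T1-T1", "A|T1-T2", "A|T2-T2", "b|T2-T2"))
  fit <- fit_stage(start, recs, stage, cutoff = 9)
  expect_rel_equal(fit$pairs["T2-T2", "b"], truth$pairs["T2-T2", "b"],
                   1e-3)
  expect_rel_equal(fit$pairs$A, truth$pairs$A, 1e-3)
})

test_that("linear estimates are unbiased under Gaussian force noise", {
  sigma <- 0.5
  errs <- sapply(1:25, function(s) {
    recs <- gen_training_set(100 + s, n_configs = 6, n_molecules = 3,
                             phase = "neat", sigma = sigma)
    truth <- attr(recs, "ground_truth")$params
    start <- truth
    start$bonds$k <- truth$bonds$k * 0.9
    stage <- fit_stage_spec(paste0("kbond|", rownames(truth$bonds)))
    fit <- fit_stage(start, recs, stage, cutoff = 12)
    mean(fit$bonds$k - truth$bonds$k)
  })
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 2 * se + 1e-12)
})

test_that("each completed stage does not increase its own objective", {
  recs <- gen_training_set(17, n_configs = 4, n_molecules = 3,
                           phase = "neat", sigma = 0.8)
  truth <- attr(recs, "ground_truth")$params
  start <- truth
  start$pairs$A <- truth$pairs$A * 1.4
  start$bonds$k <- truth$bonds$k * 0.7
  for (st in default_fit_stages(start)) {
    before <- sum(fm_residuals(start, recs, st, cutoff = 12)^2)
    fitted <- fit_stage(start, recs, st, cutoff = 12)
    after <- sum(fm_residuals(fitted, recs, st, cutoff = 12)^2)
    expect_lte(after, before * (1 + 1e-10))
    start <- fitted
  }
  # and the full fit beats the initial guess on training RMSE
  init <- truth
  init$pairs$A <- truth$pairs$A * 1.4
  init$bonds$k <- truth$bonds$k * 0.7
  full <- fit_forcefield(init, recs, default_fit_stages(init), cutoff = 12)
  m_init <- fit_metrics(init, recs, cutoff = 12)
  m_fit <- fit_metrics(full, recs, cutoff = 12)
  expect_lte(m_fit$rmse[1], m_init$rmse[1])
})

test_that("singular designs are reported with the unconstrained parameters", {
  cf <- chain_fixture()
  recs <- chain_records(cf$params, n = 3)
  # a pair type that never occurs in the configurations -> zero column
  p <- cf$params
  p$pairs <- rbind(p$pairs, data.frame(type1 = "ZZ", type2 = "ZZ",
                                       A = 1, b = 3, C6 = 0, C8 = 0))
  p <- forcefield_params(p$pairs, p$charges, p$bonds, p$angles,
                         p$dihedrals)
  stage <- fit_stage_spec(c("A|T1-T1", "A|ZZ-ZZ"))
  expect_error(fit_stage(p, recs, stage, cutoff = 10,
                         singular_action = "error"),
               "A\\|ZZ-ZZ")
  expect_warning(fit_stage(p, recs, stage, cutoff = 10),
                 "rank-deficient")
})

test_that("mixed-phase fit leaves solute-solvent parameters invariant", {
  truth <- ground_truth_params("hydrated", with_solvent = TRUE)
  start <- truth
  start$pairs$A <- truth$pairs$A * 1.25
  start$bonds$k <- truth$bonds$k * 0.85
  neat <- gen_training_set(11, n_configs = 6, n_molecules = 4,
                           phase = "neat", scheme = "hydrated",
                           params = truth, sigma = 0.3)
  hyd <- gen_training_set(12, n_configs = 6, n_molecules = 6,
                          phase = "hydrated", params = truth, sigma = 0.3)
  fit_h <- suppressWarnings(
    fit_forcefield(start, hyd, default_fit_stages(start), cutoff = 12))
  fit_j <- suppressWarnings(
    joint_mixed_phase_fit(neat, hyd, start, cutoff = 12))
  cross <- vapply(strsplit(rownames(truth$pairs), "-"), function(p)
    any(p %in% c("OW", "HW")) && !all(p %in% c("OW", "HW")), logical(1))
  expect_lt(max(abs(fit_j$pairs$A[cross] - fit_h$pairs$A[cross])), 1e-10)
  # charge policy: charges pinned to the hydrated values
  expect_identical(fit_j$charges, start$charges)
  # empty neat set reduces to the hydrated-only fit
  fit_empty <- suppressWarnings(
    joint_mixed_phase_fit(list(), hyd, start, cutoff = 12))
  expect_equal(fit_empty$pairs, fit_h$pairs)
  expect_error(joint_mixed_phase_fit(neat, list(), start),
               "hydrated record set is empty")
})

test_that("joint fit recovers a common ground truth from both phases", {
  truth <- ground_truth_params("hydrated", with_solvent = TRUE)
  start <- truth
  start$pairs$A <- truth$pairs$A * 1.25
  start$bonds$k <- truth$bonds$k * 0.85
  neat0 <- gen_training_set(21, n_configs = 10, n_molecules = 6,
                            phase = "neat", scheme = "hydrated",
                            params = truth, sigma = 0)
  hyd0 <- gen_training_set(22, n_configs = 10, n_molecules = 7,
                           phase = "hydrated", params = truth, sigma = 0)
  fit0 <- suppressWarnings(
    joint_mixed_phase_fit(neat0, hyd0, start, cutoff = 12))
  solv_only <- vapply(strsplit(rownames(truth$pairs), "-"), function(p)
    all(p %in% c("OW", "HW")), logical(1))
  expect_rel_equal(fit0$pairs$A[!solv_only], truth$pairs$A[!solv_only],
                   1e-3)
  bsolv <- vapply(strsplit(rownames(truth$bonds), "-"), function(p)
    all(p %in% c("OW", "HW")), logical(1))
  expect_rel_equal(fit0$bonds$k[!bsolv], truth$bonds$k[!bsolv], 1e-3)
})
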