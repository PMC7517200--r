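test_that("shipped profiles load with the documented parameter values", {
  cfg <- load_profile("pob_step4", quiet = TRUE)
  expect_equal(cfg$pol$N, 600)
  expect_equal(cfg$pol$C_m, 90)
  expect_equal(cfg$pol$p, 200)
  expect_equal(cfg$pol$w, 0.45)
  expect_equal(cfg$pol$tau2_fast, 33.3)
  expect_equal(cfg$pob$N, 200)
  expect_equal(cfg$pob$C_m, 150)
  expect_equal(cfg$pob$w, 0.5)
  expect_equal(cfg$pob$tau2_fast, 11.1)
  expect_equal(cfg$pob$tau2_slow, 33.3)
  expect_equal(cfg$pob$gamma2_fast, 0.5)
  expect_equal(cfg$pob$tau_A, 2)
  expect_equal(cfg$pob$gamma_A, 0.3)
  expect_true(cfg$pob$dynamic_threshold)
  expect_equal(cfg$pob$S, 7)
  expect_equal(cfg$pob$a, 0.25)
  expect_equal(cfg$pob$beta, 12.5)
  expect_equal(cfg$pob$U, 0.1)
  expect_equal(cfg$coupling$C_m_het, 150)
  expect_equal(cfg$coupling$lambda_word, 0.2)
  expect_equal(unlist(cfg$coupling$g_cascade), c(1.0, 0.9, 0.8))
  expect_equal(cfg$protocol$n_batches, 3)
  expect_equal(cfg$protocol$n_words, 50)

  sob <- load_profile("sob_default", quiet = TRUE)
  expect_equal(sob$pob$N, 201)
  expect_equal(sob$pob$a, 51 / 201)
  expect_equal(sob$sob$a_sign, 31 / 67, tolerance = 1e-12)
  expect_equal(sob$coupling$lambda_sign, 1.4)
  expect_equal(sob$sob$b_fast, 0.09)
  expect_equal(sob$sob$b_slow, 0.03)
  expect_equal(sob$sob$n_signs, 25)
  expect_equal(sob$sob$n_words, 25)
})

test_that("unknown profile keys are a hard error", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kind: pob", "pol:", "  'N': 10", "  C_m: 5", "  tua1: 3.3"),
             bad)
  expect_error(load_profile(bad, quiet = TRUE), "tua1")
  expect_error(load_profile("no_such_profile"), "unknown profile")
})

test_that("missing protocol keys are filled from defaults with a notice", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kind: pob",
               "pol: {'N': 10, C_m: 5, w: 0.4, tau2_fast: 10}",
               "pob: {'N': 10, C_m: 5, w: 0.4, tau2_fast: 10}",
               "protocol: {n_batches: 2}"), p)
  expect_message(cfg <- load_profile(p), "defaults used")
  expect_equal(cfg$protocol$n_batches, 2)
  expect_equal(cfg$protocol$theta_on, 0.5)
})

test_that("ablation flags modify exactly their component", {
  cfg <- load_profile("pob_step4", quiet = TRUE)
  a1 <- apply_ablation(cfg, "no_slow_adaptation")
  expect_equal(a1$pob$gamma2_fast, 1.0)
  expect_equal(a1$pob$tau2_fast, cfg$pob$tau2_fast)
  a2 <- apply_ablation(cfg, "no_dynamic_threshold")
  expect_false(a2$pob$dynamic_threshold)
  expect_equal(a2$pob$U, 0.216)
  a3 <- apply_ablation(cfg, "no_fast_local_inhibition")
  expect_equal(a3$pob$gamma_A, 0)
  expect_error(apply_ablation(cfg, "no_such_flag"), "unknown ablation")

  # ablation profiles shipped as files agree with the flags
  expect_equal(load_profile("pob_no_dynamic_threshold", quiet = TRUE)$pob$U,
               0.216)
  expect_equal(load_profile("pob_no_fast_inhibition", quiet = TRUE)$pob$gamma_A,
               0)
  expect_equal(load_profile("pob_no_slow_adaptation",
                            quiet = TRUE)$pob$gamma2_fast, 1)
})

test_that("seed fan-out is deterministic and key-sensitive", {
  expect_identical(seed_for(1, "patterns"), seed_for(1, "patterns"))
  expect_false(seed_for(1, "patterns") == seed_for(1, "connectivity"))
  expect_false(seed_for(1, "patterns") == seed_for(2, "patterns"))
  expect_true(seed_for(123456, "x") < 2^31)
})
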