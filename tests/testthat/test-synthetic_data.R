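test_that("cohort defaults encode the group-by-valence double dissociation", {
  hc <- cohort_spec("HC", n_subjects = 4, seed = 1)
  md <- cohort_spec("rMDD", n_subjects = 4, seed = 2)
  expect_equal(hc$truth_by_emotion, list(happy = 5L, sad = 21L))
  expect_equal(md$truth_by_emotion, list(happy = 21L, sad = 2L))
  expect_error(cohort_spec("HC", n_subjects = 0, seed = 1))
})

test_that("subjects carry the cohort's true modulatory patterns", {
  d <- short_design()
  s <- sample_subject(cohort_spec("HC", n_subjects = 2, seed = 11,
                                  weak_ofc_fraction = 0), d, 1)
  p <- s$true_params
  edge_set <- function(Bm) {
    nz <- which(Bm != 0, arr.ind = TRUE)
    sort(sprintf("%s->%s", colnames(Bm)[nz[, 2]], rownames(Bm)[nz[, 1]]))
  }
  # happy: the single backward OFC->FG edge of Model 5
  expect_equal(edge_set(p$B$happy), "OFC->FG")
  # sad: the four bidirectional edges of Model 21
  expect_equal(edge_set(p$B$sad),
               sort(c("AMY->OFC", "OFC->AMY", "FG->OFC", "OFC->FG")))
  m <- sample_subject(cohort_spec("rMDD", n_subjects = 2, seed = 12,
                                  weak_ofc_fraction = 0), d, 1)
  expect_equal(edge_set(m$true_params$B$happy),
               sort(c("AMY->OFC", "OFC->AMY", "FG->OFC", "OFC->FG")))
  expect_equal(edge_set(m$true_params$B$sad), "FG->OFC")
})

test_that("snr fixes the noise level relative to the evoked signal", {
  d <- short_design()
  s1 <- sample_subject(cohort_spec("HC", n_subjects = 2, seed = 3,
                                   snr = 1), d, 1)
  s5 <- sample_subject(cohort_spec("HC", n_subjects = 2, seed = 3,
                                   snr = 5), d, 1)
  sig <- sd(as.numeric(scale(s1$noiseless$data, scale = FALSE)))
  expect_equal(s1$true_params$noise_sd, sig, tolerance = 1e-12)
  expect_equal(s5$true_params$noise_sd, sig / 5, tolerance = 1e-12)
  # the realised residual scale matches the nominal noise SD
  resid <- s1$bold$data - s1$noiseless$data
  expect_lt(abs(sd(resid) / s1$true_params$noise_sd - 1), 0.25)
})

test_that("subject simulation is deterministic and index-sensitive", {
  d <- short_design()
  co <- cohort_spec("HC", n_subjects = 3, seed = 7)
  a1 <- sample_subject(co, d, 1)
  a2 <- sample_subject(co, d, 1)
  b <- sample_subject(co, d, 2)
  expect_identical(a1$bold$data, a2$bold$data)
  expect_identical(a1$true_params$A, a2$true_params$A)
  expect_false(identical(a1$bold$data, b$bold$data))
  # the subject seed does not leak into the session RNG
  set.seed(123); x <- rnorm(1)
  set.seed(123); invisible(sample_subject(co, d, 3)); y <- rnorm(1)
  expect_identical(x, y)
})

test_that("couplings are dispersed around the population means", {
  d <- short_design()
  co <- cohort_spec("HC", n_subjects = 6, seed = 13,
                    weak_ofc_fraction = 0)
  subs <- lapply(1:6, function(i) sample_subject(co, d, i))
  b_fg_ofc <- vapply(subs, function(s) s$true_params$B$sad["OFC", "FG"],
                     1.0)
  expect_gt(sd(b_fg_ofc), 0)                  # subjects differ
  expect_lt(abs(mean(b_fg_ofc) - co$b_mean), 4 * co$dispersion)
  expect_true(all(vapply(subs, function(s) s$madrs, 1.0) >= 0))
  expect_true(all(vapply(subs, function(s)
    all(diag(s$true_params$A) <= -0.1), TRUE)))
})

test_that("the weak-OFC fraction switches the attenuated subtype", {
  d <- short_design()
  all_weak <- cohort_spec("HC", n_subjects = 3, seed = 17,
                          weak_ofc_fraction = 1)
  none <- cohort_spec("HC", n_subjects = 3, seed = 17,
                      weak_ofc_fraction = 0)
  sw <- lapply(1:3, function(i) sample_subject(all_weak, d, i))
  sn <- lapply(1:3, function(i) sample_subject(none, d, i))
  expect_true(all(vapply(sw, `[[`, TRUE, "weak_ofc")))
  expect_false(any(vapply(sn, `[[`, TRUE, "weak_ofc")))
  # attenuation shrinks the incoming OFC couplings
  expect_lt(max(abs(sw[[1]]$true_params$A["OFC", c("FG", "AMY")])),
            max(abs(sn[[1]]$true_params$A["OFC", c("FG", "AMY")])) + 1e-9)
})

test_that("make_cohorts writes a complete, deterministic manifest", {
  d <- short_design()
  hc <- cohort_spec("HC", n_subjects = 2, seed = 21)
  md <- cohort_spec("rMDD", n_subjects = 2, seed = 22)
  dir <- withr::local_tempdir()
  out <- make_cohorts(hc, md, d, out_dir = dir)
  expect_equal(nrow(out$manifest), 4)
  expect_equal(out$manifest$group, c("HC", "HC", "rMDD", "rMDD"))
  expect_true(all(file.exists(file.path(dir,
    paste0(out$manifest$subject_id, ".tsv")))))
  m2 <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(m2$seed, out$manifest$seed)
  # regenerating reproduces the series files bit-for-bit
  back <- read_bold_ts(file.path(dir, paste0(out$manifest$subject_id[1],
                                             ".tsv")))
  again <- sample_subject(hc, d, 1)
  expect_equal(back$data, again$bold$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(make_cohorts(hc, cohort_spec("rMDD", 2, seed = 21), d),
               "distinct seeds")
})
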