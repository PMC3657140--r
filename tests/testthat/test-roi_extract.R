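test_that("the high-pass cutoff and DCT filter behave as documented", {
  d <- full_design()
  # longest spacing between same-condition onsets fixes the cutoff
  conds <- setdiff(unique(d$blocks$condition), "R")
  gap <- max(unlist(lapply(conds, function(k)
    diff(sort(d$blocks$onset[d$blocks$condition == k])))))
  expect_equal(design_hp_cutoff(d), 2 * gap)
  # filtering removes slow drift but leaves task-band structure
  t <- (seq_len(d$n_volumes) - 1) * d$tr_s
  slow <- 3 * cos(2 * pi * t / 900)             # period >> cutoff
  fast <- sin(2 * pi * t / 42)                  # period << cutoff
  yf <- highpass_filter(slow + fast, d)
  expect_lt(sd(yf - (fast - mean(fast))), 0.12 * sd(fast))
  expect_equal(mean(yf), 0, tolerance = 1e-10)
  # matrix input keeps its shape; absurd cutoff errors
  M <- cbind(slow, fast)
  expect_equal(dim(highpass_filter(M, d)), dim(M))
  expect_error(highpass_filter(fast, d, cutoff_s = 1), "twice the TR")
})

test_that("GLM t statistics match R's reference implementation", {
  set.seed(21)
  d <- short_design()
  # the faces column equals the sum of the condition columns, so use the
  # faces-vs-rest design the pipeline uses: faces regressor + intercept
  X <- build_glm_regressors(d, canonical_hrf(0.3))[, "faces",
                                                   drop = FALSE]
  y <- as.numeric(0.7 * X[, 1] + rnorm(nrow(X), sd = 1))
  g <- glm_activation(y, X)
  ref <- summary(lm(y ~ X[, 1]))$coefficients[2, ]
  expect_equal(g$t, unname(ref["t value"]), tolerance = 1e-8)
  expect_equal(g$df, nrow(X) - 2)
  expect_equal(g$p, unname(ref["Pr(>|t|)"]) / 2, tolerance = 1e-8)
  # perfect fit hits the cap rather than returning Inf
  exact <- glm_activation(X[, "faces"], X, contrast = 1)
  expect_true(is.finite(exact$t))
  expect_error(glm_activation(y, cbind(X, faces2 = X[, 1])),
               "rank deficient")
  expect_error(glm_activation(y, X, contrast = "nope"), "no column")
})

test_that("the inclusion rule requires activation and locality jointly", {
  base <- data.frame(region = c("V1", "FG", "AMY", "OFC"),
                     t = c(8, 6, 5, 4), df = 200,
                     distance = c(2, 5, 9, 13))
  expect_true(subject_included(base)$included)
  # one region just over 14 mm away fails the subject
  far <- base; far$distance[4] <- 14.5
  r <- subject_included(far)
  expect_false(r$included)
  expect_false(r$reasons$locality[4])
  expect_true(all(r$reasons$activation))
  # weak (or negative) activation fails even at distance zero
  weak <- base; weak$t[3] <- 0.5; weak$distance[3] <- 0
  expect_false(subject_included(weak)$included)
  # exact boundary distance is allowed; missing region is an error
  edge <- base; edge$distance[1] <- 14
  expect_true(subject_included(edge)$included)
  expect_error(subject_included(base[-2, ]), "FG")
})

test_that("the eigenvariate reproduces a rank-1 patch's source series", {
  d <- short_design()
  co <- cohort_spec("HC", n_subjects = 2, seed = 5)
  s <- sample_subject(co, d, 1)
  patch <- render_patch(s, "AMY", shape = c(5, 5, 5),
                        voxel_noise_sd = 0, seed = 99)
  ev <- extract_eigenvariate(patch, center = c(0, 0, 0), radius_mm = 8)
  src <- s$bold$data[, "AMY"]
  expect_gt(abs(cor(ev$values, src)), 0.999)
  expect_gt(cor(ev$values, src), 0)        # sign aligned with the mean
  expect_gt(ev$explained_variance, 0.999)
  # the eigenvariate is on a single-voxel scale (the smoothing kernel
  # attenuates off-focus voxels below 1), not on the patch-sum scale
  ratio <- sd(ev$values) / sd(src - mean(src))
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 1.5)
  expect_error(extract_eigenvariate(patch, c(100, 100, 100), 2),
               "no voxels")
})

test_that("patch geometry places the focus at the requested coordinate", {
  d <- short_design()
  s <- sample_subject(cohort_spec("HC", n_subjects = 2, seed = 6), d, 1)
  p <- render_patch(s, "FG", shape = c(5, 5, 5), voxel_noise_sd = 0.01,
                    focus_mm = c(40, -52, -14))
  co <- emoconn:::patch_coords(p)
  # the center voxel sits exactly at the focus
  mid <- (prod(c(5, 5, 5)) + 1) / 2
  expect_equal(unname(co[mid, ]), c(40, -52, -14))
  # signal amplitude decays with distance from the focus
  amp <- apply(matrix(aperm(p$data, c(4, 1, 2, 3)),
                      dim(p$data)[4]), 2, sd)
  d2 <- rowSums(sweep(co, 2, c(40, -52, -14), `-`)^2)
  expect_gt(amp[which.min(d2)], amp[which.max(d2)])
})
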