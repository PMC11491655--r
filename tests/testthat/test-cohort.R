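test_that("cohort specs validate their parameters and name violations", {
  expect_error(tiny_spec(age_min = 80, age_max = 74), "age_min")
  expect_error(tiny_spec(noise_sd = -1), "noise_sd")
  expect_error(tiny_spec(disease_fraction = 1.5), "disease_fraction")
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(tiny_spec(feature_dim = 0), "feature_dim")
  expect_error(tiny_spec(age_sd = 0, age_mean = 20), "age_mean")
})

test_that("sampled ages reproduce the preset moments and bounds", {
  spec <- cohort_preset("ukb_like", seed = 11)
  a <- sample_ages(spec)
  expect_length(a, spec$n_subjects)
  expect_true(all(a >= 40 & a <= 74))
  expect_lt(abs(mean(a) - 52.32), 0.5)
  expect_identical(a, sample_ages(spec))

  # BRSET-like sd over 20 seeds
  sds <- vapply(1:20, function(s) {
    sd(sample_ages(cohort_preset("brset_like", seed = s)))
  }, numeric(1))
  expect_lt(max(abs(sds - 17.46)), 2.0)
  expect_true(all(vapply(1:5, function(s) {
    all(sample_ages(cohort_preset("brset_like", seed = s)) >= 6)
  }, logical(1))))

  degen <- tiny_spec(age_sd = 0, age_mean = 52.32)
  expect_true(all(sample_ages(degen) == 52.32))
})

test_that("generated cohorts have two eye records per subject with shared metadata", {
  co <- generate_cohort(tiny_spec(n_subjects = 25, disease_fraction = 0.2))
  expect_s3_class(co, "fedgap_cohort")
  expect_identical(nrow(co$meta), 50L)
  expect_identical(dim(co$features), c(50L, 16L))
  per <- split(seq_len(50), co$meta$subject_id)
  expect_true(all(lengths(per) == 2L))
  for (idx in per) {
    expect_setequal(co$meta$eye[idx], c("L", "R"))
    expect_identical(co$meta$age[idx[1]], co$meta$age[idx[2]])
    expect_identical(co$meta$center_id[idx[1]], co$meta$center_id[idx[2]])
    expect_identical(co$meta$group[idx[1]], co$meta$group[idx[2]])
  }
  expect_identical(sum(co$meta$group == "disease"),
                   as.integer(2 * round(25 * 0.2)))

  # byte-identical determinism
  co2 <- generate_cohort(tiny_spec(n_subjects = 25, disease_fraction = 0.2))
  expect_identical(co$features, co2$features)
  expect_identical(co$meta, co2$meta)
})

test_that("the noiseless cohort is an exact affine function of age", {
  co <- generate_cohort(noiseless_spec())
  # an exact least-squares readout recovers age with zero error
  fit <- lm.fit(cbind(1, co$features), co$meta$age)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # the latent signal is perfectly correlated with age when the quadratic
  # term is off: the feature projection on any informative direction is
  # an affine map of age, so check via the first principal direction
  ctr <- scale(co$features, scale = FALSE)
  proj <- ctr %*% svd(ctr, nu = 0, nv = 1)$v
  expect_equal(abs(cor(proj, co$meta$age))[1], 1, tolerance = 1e-9)
})

test_that("a ridge oracle reaches the intended difficulty band and detects disease", {
  spec <- cohort_preset("ukb_like", n_subjects = 3200, seed = 5)
  co <- generate_cohort(spec)
  net <- build_network(co)
  healthy <- net$subjects$subject_id[net$subjects$group == "healthy"]
  set.seed(1)
  train_ids <- sample(healthy, 2400)
  test_ids <- sample(setdiff(healthy, train_ids), 400)
  pick <- function(ids) {
    k <- match(ids, net$subjects$subject_id)
    rows <- as.integer(t(net$rows[k, , drop = FALSE]))
    list(X = co$features[rows, , drop = FALSE], y = co$meta$age[rows])
  }
  tr <- pick(train_ids)
  te <- pick(test_ids)
  oracle <- ridge_oracle(tr$X, tr$y)
  mae <- mean(abs(oracle(te$X) - te$y))
  expect_gte(mae, 3.0)
  expect_lte(mae, 4.0)
  # strictly better than the constant mean-age predictor
  expect_lt(mae, mean(abs(mean(tr$y) - te$y)))

  # healthy-trained oracle sees disease retinas as older than they are
  dis <- net$subjects$subject_id[net$subjects$group == "disease"]
  dd <- pick(dis)
  expect_gt(mean(oracle(dd$X) - dd$y), 0)
})

test_that("cohort CSV round trips exactly and rejects malformed files", {
  co <- generate_cohort(tiny_spec(n_subjects = 4, feature_dim = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header[1:5],
                   c("subject_id", "eye", "center", "group", "age"))
  expect_identical(header[6], "f0000")
  expect_identical(header[length(header)], "f0007")

  back <- read_cohort(path)
  expect_identical(back$meta, co$meta)
  expect_identical(back$features, co$features)

  # writing twice yields identical bytes
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path2)
  expect_identical(readLines(path), readLines(path2))

  # three records for one subject
  lines <- readLines(path)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines, lines[2]), bad)
  expect_error(read_cohort(bad), "records")

  # non-numeric feature names the row
  lines2 <- lines
  lines2[3] <- sub("(,[^,]*)$", ",abc", lines2[3])
  writeLines(lines2, bad)
  expect_error(read_cohort(bad), "row 2")

  # malformed header
  writeLines(c(sub("subject_id", "subject", lines[1]), lines[-1]), bad)
  expect_error(read_cohort(bad), "header")
})
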