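test_that("standardization identities hold and invert", {
  params <- tibble::tibble(
    feature = c("age_at_onset", "bmi", "homa_b", "homa_ir"),
    mean = c(55, 28, 150, 2), sd = c(8, 4, 50, 1)
  )
  x <- tibble::tibble(age_at_onset = 55, bmi = 28, homa_b = 150, homa_ir = 2)
  expect_equal(unname(standardize(x, params)[1, ]), rep(0, 4))

  ident <- params
  ident$mean <- rep(0, 4)
  ident$sd <- rep(1, 4)
  y <- tibble::tibble(age_at_onset = 1.3, bmi = -0.2, homa_b = 0.7, homa_ir = 2.2)
  expect_equal(unname(standardize(y, ident)[1, ]), as.numeric(y[1, ]))

  x2 <- x
  x2$bmi <- 28 + 2 * 4
  expect_equal(standardize(x2, params)[1, "bmi"], c(bmi = 2))

  # inverse transform recovers raw values
  z <- standardize(y, params)
  expect_equal(
    unname(diabtraj:::destandardize(z, params)[1, ]),
    as.numeric(y[1, ]),
    tolerance = 1e-9
  )
  expect_error(
    standardize(x[, 1:2], params),
    "homa_b",
    class = "diabtraj_contract_error"
  )
})

test_that("k-means centroid fitting recovers well-separated blobs with labels", {
  set.seed(101)
  n <- 40
  blob <- function(age, bmi, b, ir) {
    tibble::tibble(
      age_at_onset = rnorm(n, age, 0.5), bmi = rnorm(n, bmi, 0.2),
      homa_b = rnorm(n, b, 1), homa_ir = rnorm(n, ir, 0.05)
    )
  }
  truth <- list(
    SIDD = c(50, 26, 40, 2.0), # lowest beta-cell function
    SIRD = c(55, 30, 150, 6.0), # highest insulin resistance
    MOD = c(45, 40, 160, 2.5), # highest BMI among remaining
    MARD = c(65, 25, 155, 1.5)
  )
  training <- dplyr::bind_rows(lapply(truth, function(v) do.call(blob, as.list(v))))
  cen <- fit_centroids(training, variant = "glycemia_free", seed = 7)
  # oracle: standardized blob means, computed directly
  for (s in names(truth)) {
    mu <- setNames(truth[[s]], cen$feature_names)
    z_mu <- standardize(mu, cen$standardization)[1, ]
    expect_lt(sqrt(sum((cen$centroids[s, ] - z_mu)^2)), 0.1)
  }
  # determinism under a fixed seed
  cen2 <- fit_centroids(training, variant = "glycemia_free", seed = 7)
  expect_identical(cen$centroids, cen2$centroids)
})

test_that("degenerate training sets are fitting errors", {
  one <- tibble::tibble(age_at_onset = 50, bmi = 30, homa_b = 100, homa_ir = 2)
  dup <- one[rep(1, 8), ]
  expect_error(
    fit_centroids(dup, variant = "glycemia_free"),
    "zero-variance",
    class = "diabtraj_fitting_error"
  )
  expect_error(fit_centroids(one[1:3, ], variant = "glycemia_free"),
    class = "diabtraj_fitting_error"
  )
})

test_that("centroid files round-trip and enforce the variant schema", {
  co <- simulate_cohort(separated_config(seed = 4))
  feats <- build_case_features(co)
  cen <- fit_centroids(feats, variant = "fpg", seed = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_centroids(cen, path)
  back <- load_centroids(path)
  expect_equal(back$variant, cen$variant)
  expect_equal(back$centroids, cen$centroids, tolerance = 1e-8)
  expect_equal(back$standardization, cen$standardization, tolerance = 1e-8)
  expect_identical(back$provenance, "loaded_from_file")

  # declaring a 4-feature file as the 5-feature hba1c variant is a schema error
  obj <- yaml::read_yaml(path)
  obj$variant <- "hba1c"
  yaml::write_yaml(obj, path)
  expect_error(load_centroids(path), "hba1c", class = "diabtraj_schema_error")

  # glycemia-free with 4 features is accepted
  cen4 <- fit_centroids(feats, variant = "glycemia_free", seed = 2)
  write_centroids(cen4, path)
  expect_s3_class(load_centroids(path), "subtype_centroids")
})

test_that("a destandardized centroid is assigned to itself at distance 0", {
  centers <- rbind(
    SIDD = c(-1, 0, -2, 0), SIRD = c(0, 1, 1, 2),
    MOD = c(0, 2, 0, 0), MARD = c(1, -1, 0, -1)
  )
  params_mean <- c(age_at_onset = 55, bmi = 28, homa_b = 150, homa_ir = 2)
  params_sd <- c(age_at_onset = 8, bmi = 4, homa_b = 40, homa_ir = 1)
  cen <- manual_centroids(centers, means = params_mean, sds = params_sd)
  raw <- diabtraj:::destandardize(centers["SIRD", , drop = FALSE], cen$standardization)
  res <- assign_subtype(tibble::as_tibble(raw), cen)
  expect_equal(res$subtype, "SIRD")
  expect_equal(res$dist_SIRD, 0, tolerance = 1e-12)
})

test_that("GADA positivity gates assignment to SAID with no distances", {
  cen <- manual_centroids(rbind(
    SIDD = c(-1, 0, -2, 0), SIRD = c(0, 1, 1, 2),
    MOD = c(0, 2, 0, 0), MARD = c(1, -1, 0, -1)
  ))
  x <- tibble::tibble(
    age_at_onset = 0.5, bmi = 0.5, homa_b = 0.5, homa_ir = 0.5,
    gada_positive = TRUE
  )
  res <- assign_subtype(x, cen)
  expect_equal(res$subtype, "SAID")
  expect_true(all(is.na(res[, paste0("dist_", c("SIDD", "SIRD", "MOD", "MARD"))])))
})

test_that("exact distance ties break in the fixed subtype order", {
  # SIDD and MARD sit symmetrically about the origin; SIRD/MOD far away
  cen <- manual_centroids(rbind(
    SIDD = c(1, 0, 0, 0), SIRD = c(0, 5, 0, 0),
    MOD = c(0, 0, 5, 0), MARD = c(-1, 0, 0, 0)
  ), means = c(age_at_onset = 55, bmi = 28, homa_b = 150, homa_ir = 2))
  midpoint <- tibble::tibble(age_at_onset = 55, bmi = 28, homa_b = 150, homa_ir = 2)
  res <- assign_subtype(midpoint, cen)
  expect_equal(res$dist_SIDD, res$dist_MARD) # verified equidistant
  expect_lt(res$dist_SIDD, res$dist_SIRD)
  expect_equal(res$subtype, "SIDD")
})

test_that("a missing feature is a classification error naming it", {
  centers <- diag(4)
  rownames(centers) <- c("SIDD", "SIRD", "MOD", "MARD")
  cen <- manual_centroids(centers)
  x <- tibble::tibble(age_at_onset = 1, bmi = 1, homa_b = 1)
  expect_error(assign_subtype(x, cen), "homa_ir",
    class = "diabtraj_classification_error"
  )
})

test_that("assignment matches the brute-force oracle on random inputs", {
  set.seed(20)
  for (rep in 1:5) {
    centers <- matrix(rnorm(16, sd = 2), 4,
      dimnames = list(c("SIDD", "SIRD", "MOD", "MARD"), NULL)
    )
    means <- c(age_at_onset = 55, bmi = 28, homa_b = 150, homa_ir = 2)
    sds <- c(age_at_onset = 8, bmi = 4, homa_b = 40, homa_ir = 1)
    cen <- manual_centroids(centers, means = means, sds = sds)
    x <- tibble::tibble(
      age_at_onset = runif(40, 30, 80), bmi = runif(40, 18, 45),
      homa_b = runif(40, 20, 300), homa_ir = runif(40, 0.3, 8)
    )
    res <- assign_subtype(x, cen)
    z <- standardize(x, cen$standardization)
    oracle <- vapply(
      seq_len(nrow(z)),
      function(i) oracle_nearest(z[i, ], cen$centroids), character(1)
    )
    expect_identical(res$subtype, oracle)
    # reported subtype attains the minimum of the four reported distances
    dmat <- as.matrix(res[, paste0("dist_", c("SIDD", "SIRD", "MOD", "MARD"))])
    expect_equal(
      paste0("dist_", res$subtype),
      colnames(dmat)[apply(dmat, 1, which.min)]
    )
  }
})

test_that("assignment is invariant to positive rescaling refit on rescaled data", {
  co <- simulate_cohort(separated_config(seed = 12))
  feats <- build_case_features(co)
  cen <- fit_centroids(feats, variant = "fpg", seed = 5)
  res <- assign_subtype(feats, cen)
  scaled <- feats
  scaled$bmi <- scaled$bmi * 3.7
  scaled$homa_ir <- scaled$homa_ir * 0.25
  cen2 <- fit_centroids(scaled, variant = "fpg", seed = 5)
  res2 <- assign_subtype(scaled, cen2)
  expect_identical(res$subtype, res2$subtype)
})

test_that("concordance counts identical pairs as a percentage", {
  a <- rep(c("SIDD", "SIRD", "MOD", "MARD"), length.out = 50)
  expect_equal(concordance(a, a)$agreement, 100.0)
  b <- c(rep("SIDD", 8), rep("MARD", 2))
  a10 <- rep("SIDD", 10)
  expect_equal(concordance(a10, b)$agreement, 80.0)
  expect_equal(concordance(rep("MOD", 7), rep("MARD", 7))$agreement, 0.0)
  # symmetry
  set.seed(1)
  x <- sample(c("SIDD", "SIRD"), 30, TRUE)
  y <- sample(c("SIDD", "SIRD"), 30, TRUE)
  expect_equal(concordance(x, y)$agreement, concordance(y, x)$agreement)
  expect_error(concordance(a10, b[1:5]), class = "diabtraj_contract_error")
})
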