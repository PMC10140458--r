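test_that("encode_slide maps tiles through the encoder row by row", {
  enc <- encoder_channel_mean()
  tiles <- lapply(1:10, function(i) {
    a <- array(0, c(8, 8, 3))
    for (c in 1:3) a[, , c] <- i * c / 10
    a
  })
  bag <- encode_slide(tiles, enc, patient_id = "P1")
  expect_identical(dim(bag$features), c(10L, 3L))
  expect_equal(bag$features[4L, ], c(0.4, 0.8, 1.2))
  # identical tiles give identical rows
  bag2 <- encode_slide(tiles[c(1L, 1L, 1L)], enc, patient_id = "P1")
  expect_equal(bag2$features[1L, ], bag2$features[3L, ])
  # zero tiles is an error naming the slide
  expect_error(encode_slide(list(), enc, patient_id = "P9", slide_id = "S9"),
               "S9")
})

test_that("random-projection encoder equals its matrix-product oracle", {
  enc <- encoder_random_projection(dim = 8L, pool_px = 4L, seed = 5L)
  W <- wsimil:::with_seed(5L, matrix(stats::rnorm(4^2 * 3 * 8, sd = 1 / sqrt(48)),
                                     48, 8))
  set.seed(11)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  # oracle: block means computed with a double loop, then the projection
  th <- array(0, c(4, 4, 3))
  for (c in 1:3) for (i in 1:4) for (j in 1:4) {
    th[i, j, c] <- mean(x[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j), c])
  }
  expect_equal(enc$apply(x), as.vector(as.vector(th) %*% W),
               tolerance = 1e-12)
})

test_that("clinical encoder learns imputation and scaling on the training fold", {
  rec <- data.frame(PATIENT = c("a", "b", "c", "d"),
                    SEX = c("male", "female", "male", NA),
                    AGE = c(50, 60, 70, NA),
                    SIDEDNESS = c("left", "right", "left", "right"),
                    ORGAN = c("colon", "colon", "rectum", "colon"),
                    stringsAsFactors = FALSE)
  enc <- fit_clinical_encoder(rec, training_ids = c("a", "b", "c"))
  # ages {50, 60, 70}: population sd sqrt(200/3), standardized -1.2247..
  v <- encode_clinical(rec[1L, ], enc)
  expect_equal(unname(v["age"]), -10 / sqrt(200 / 3), tolerance = 1e-10)
  expect_equal(unname(encode_clinical(rec[2L, ], enc)["age"]), 0,
               tolerance = 1e-12)
  # missing age imputes to the training mean and standardizes to 0
  expect_equal(unname(encode_clinical(rec[4L, ], enc)["age"]), 0,
               tolerance = 1e-12)
  # records identical up to sex differ only in the sex dimension
  r1 <- rec[1L, ]; r2 <- r1; r2$SEX <- "female"
  d <- encode_clinical(r1, enc) - encode_clinical(r2, enc)
  expect_true(d["sex"] != 0)
  expect_equal(unname(d[c("sidedness", "organ", "age")]), c(0, 0, 0))
  # a fully missing record encodes to the zero vector
  miss <- data.frame(PATIENT = "z", SEX = NA, AGE = NA, SIDEDNESS = NA,
                     ORGAN = NA)
  expect_equal(unname(encode_clinical(miss, enc)), rep(0, 4L))
})

test_that("clinical statistics never leak from outside the training fold", {
  rec <- data.frame(PATIENT = sprintf("p%d", 1:8),
                    SEX = rep("male", 8),
                    AGE = c(40, 40, 40, 40, 90, 90, 90, 90),
                    SIDEDNESS = rep("left", 8), ORGAN = rep("colon", 8),
                    stringsAsFactors = FALSE)
  enc <- suppressWarnings(
    fit_clinical_encoder(rec, training_ids = sprintf("p%d", 1:4)))
  # training ages are constant 40 -> sd 0 -> encoded as constant 0, and the
  # test-fold age 90 must be centered with the *training* mean
  expect_equal(unname(encode_clinical(rec[5L, ], enc)["age"]), 0)
  expect_equal(enc$stats$age$impute, 40)
})

test_that("attaching clinical data broadcasts a 4-vector to every row", {
  bag <- toy_bag(K = 5L, D = 2048L)
  clin <- c(sex = 1, sidedness = -0.5, organ = 0, age = 1.2)
  out <- attach_clinical(bag, clin)
  expect_identical(ncol(out$features), 2052L)
  for (i in 1:5) expect_equal(unname(out$features[i, 2049:2052]),
                              unname(clin))
  # zero clinical vector leaves image columns unchanged
  z <- attach_clinical(bag, rep(0, 4L))
  expect_equal(z$features[, 1:2048], bag$features)
})

test_that("zero_image_features is an idempotent image-ablation", {
  bag <- attach_clinical(toy_bag(K = 3L, D = 6L), c(1, 0, 1, 0.5))
  z1 <- zero_image_features(bag)
  expect_true(all(z1$features[, 1:6] == 0))
  expect_equal(z1$features[, 7:10], bag$features[, 7:10])
  expect_identical(zero_image_features(z1)$features, z1$features)
  expect_error(zero_image_features(toy_bag()), "clinical")
})

test_that("bag scores after image ablation are encoder-independent", {
  params <- init_attmil_params(attmil_config(input_dim = 10L, embed_dim = 16L,
                                             attn_hidden = 8L), seed = 2L)
  clin <- c(0.3, -1, 0.2, 0.8)
  b1 <- zero_image_features(attach_clinical(toy_bag(K = 6L, D = 6L, seed = 1L),
                                            clin))
  b2 <- zero_image_features(attach_clinical(toy_bag(K = 6L, D = 6L, seed = 99L),
                                            clin))
  expect_equal(forward_bag(b1, params)$score, forward_bag(b2, params)$score,
               tolerance = 1e-12)
})

test_that("bag subsampling is uniform, seeded, and caps at the bag size", {
  big <- toy_bag(K = 300L, D = 4L)
  expect_identical(nrow(sample_bag(big, k = 512L)$features), 300L)
  b1 <- sample_bag(toy_bag(K = 1000L, D = 2L), k = 512L, seed = 7L)
  b2 <- sample_bag(toy_bag(K = 1000L, D = 2L), k = 512L, seed = 7L)
  expect_identical(b1$features, b2$features)
  # inclusion frequency 0.5 +/- 0.05 over 1000 seeded draws (K=10, k=5)
  b10 <- toy_bag(K = 10L, D = 1L)
  counts <- integer(10L)
  for (s in 1:1000) {
    sb <- sample_bag(b10, k = 5L, seed = s)
    counts[match(sb$features[, 1L], b10$features[, 1L])] <-
      counts[match(sb$features[, 1L], b10$features[, 1L])] + 1L
  }
  expect_true(all(abs(counts / 1000 - 0.5) < 0.05))
})

test_that("feature-bag containers round-trip losslessly", {
  bag <- toy_bag(K = 7L, D = 5L, label = 1L)
  bag$witness <- c(TRUE, rep(FALSE, 6L))
  attr(bag, "encoder_name") <- "unit-test"
  path <- withr::local_tempfile(fileext = ".bag.rds")
  write_feature_bag(bag, path)
  back <- read_feature_bag(path)
  expect_identical(back$features, bag$features)
  expect_identical(back$tile_coords, bag$tile_coords)
  expect_identical(back$label, bag$label)
  expect_identical(back$witness, bag$witness)
  expect_identical(attr(back, "encoder_name"), "unit-test")
})
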