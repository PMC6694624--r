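test_that("corruption: identity cases and masking rate", {
  x <- rnorm(50)
  expect_identical(corrupt(x, corruption_spec("none")), x)
  expect_identical(corrupt(x, corruption_spec("masking", 0)), x)
  expect_identical(corrupt(x, corruption_spec("gaussian", 0)), x)

  ones <- rep(1, 1e4)
  masked <- corrupt(ones, corruption_spec("masking", 0.3, seed = 7))
  frac <- mean(masked == 0)
  # binomial concentration: qbinom(c(1e-6, 1-1e-6), 1e4, 0.3)/1e4 is
  # within [0.278, 0.322]; assert the tighter spec band 0.3 +/- 0.02
  expect_gt(frac, 0.28)
  expect_lt(frac, 0.32)
  expect_true(all(masked %in% c(0, 1)))
  # deterministic for a fixed seed, and leaves the caller's RNG alone
  set.seed(1); before <- runif(1)
  set.seed(1)
  again <- corrupt(ones, corruption_spec("masking", 0.3, seed = 7))
  expect_identical(masked, again)
  expect_equal(runif(1), before)
})

test_that("corruption validates its level", {
  expect_error(corruption_spec("masking", 1.5), "<= 1")
  expect_error(corruption_spec("masking", -0.1), ">= 0")
})

test_that("encode matches closed forms and a naive mat-vec oracle", {
  set.seed(5)
  p <- 4; q <- 3; k <- 2
  params <- init_encoder_params(p, q, k)

  zero <- params
  zero$W1[] <- 0; zero$V1[] <- 0; zero$b_enc <- c(1, -1)
  z <- encode(zero, rep(1, p), rep(1, q), g = "sigmoid")
  expect_equal(z, plogis(c(1, -1)))

  one <- init_encoder_params(1, 1, 1)
  one$W1[] <- 2; one$V1[] <- 0; one$b_enc <- 0
  expect_equal(encode(one, 1, 5, g = "identity"), 2)

  profile <- rnorm(p); sim <- rnorm(q)
  expected <- plogis(naive_matvec(params$W1, profile) +
                       naive_matvec(params$V1, sim) + params$b_enc)
  expect_equal(encode(params, profile, sim), expected, tolerance = 1e-12)
  expect_error(encode(params, rnorm(p + 1), sim), "length")
})

test_that("decoders match closed forms and the mat-vec oracle", {
  set.seed(6)
  params <- init_encoder_params(4, 3, 2)
  zero <- params
  zero$W2[] <- 0; zero$V2[] <- 0
  z <- rnorm(2)
  expect_equal(decode_profile(zero, z), rep(0.5, 4))
  expect_equal(decode_similarity(zero, z), rep(0.5, 3))

  one <- init_encoder_params(1, 1, 1)
  one$W2[] <- 3
  expect_equal(decode_profile(one, 1, f = "identity"), 3)

  expect_equal(decode_profile(params, z),
               plogis(naive_matvec(params$W2, z) + params$b_dec_profile),
               tolerance = 1e-12)
  expect_equal(decode_similarity(params, z),
               plogis(naive_matvec(params$V2, z) + params$b_dec_sim),
               tolerance = 1e-12)
  expect_error(decode_profile(params, rnorm(3)), "length")
})

test_that("reconstruction loss: closed forms, oracle, and properties", {
  set.seed(7)
  params <- init_encoder_params(2, 2, 2)
  s <- c(1, 0); sim <- c(0.5, 0.5)

  expect_equal(
    reconstruction_loss(params, s, sim, s, sim, balance = 0.3, reg = 0),
    0
  )
  expect_equal(
    reconstruction_loss(params, s, sim, c(0, 0), sim, balance = 0.7, reg = 0),
    0.7
  )

  # random instance vs from-scratch scalar recomputation
  ph <- runif(2); sh <- runif(2); a <- 0.4; lam <- 0.02
  manual <- a * ((s[1] - ph[1])^2 + (s[2] - ph[2])^2) +
    (1 - a) * ((sim[1] - sh[1])^2 + (sim[2] - sh[2])^2) +
    lam * (sum(params$W1^2) + sum(params$W2^2) +
             sum(params$V1^2) + sum(params$V2^2))
  expect_equal(
    reconstruction_loss(params, s, sim, ph, sh, balance = a, reg = lam),
    manual, tolerance = 1e-12
  )

  # monotone in the regularization weight; alpha extremes decouple terms
  l1 <- reconstruction_loss(params, s, sim, ph, sh, balance = a, reg = 0.1)
  l2 <- reconstruction_loss(params, s, sim, ph, sh, balance = a, reg = 0.2)
  expect_gt(l2, l1)
  expect_equal(
    reconstruction_loss(params, s, sim, ph, sh, balance = 1, reg = 0),
    reconstruction_loss(params, s, sim, ph, rev(sh), balance = 1, reg = 0)
  )
  expect_equal(
    reconstruction_loss(params, s, sim, ph, sh, balance = 0, reg = 0),
    reconstruction_loss(params, s, sim, rev(ph), sh, balance = 0, reg = 0)
  )
  expect_error(
    reconstruction_loss(params, s, sim, ph, sh, balance = 1.2, reg = 0),
    "balance"
  )
})

test_that("an uncorrupted encoder can overfit one profile to near zero loss", {
  set.seed(8)
  p <- 6; q <- 6; k <- 4
  params <- init_encoder_params(p, q, k)
  s <- c(1, 0, 1, 0, 0, 1)
  sim <- runif(q)
  lr <- 0.5
  for (step in 1:4000) {
    z <- encode(params, s, sim)
    ph <- decode_profile(params, z)
    sh <- decode_similarity(params, z)
    # plain gradient descent on the balance-weighted reconstruction error
    a <- 0.5
    dC <- 2 * a * (ph - s) * ph * (1 - ph)
    dD <- 2 * (1 - a) * (sh - sim) * sh * (1 - sh)
    dz <- drop(crossprod(params$W2, dC) + crossprod(params$V2, dD))
    dA <- dz * z * (1 - z)
    params$W2 <- params$W2 - lr * dC %o% z
    params$b_dec_profile <- params$b_dec_profile - lr * dC
    params$V2 <- params$V2 - lr * dD %o% z
    params$b_dec_sim <- params$b_dec_sim - lr * dD
    params$W1 <- params$W1 - lr * dA %o% s
    params$V1 <- params$V1 - lr * dA %o% sim
    params$b_enc <- params$b_enc - lr * dA
  }
  z <- encode(params, s, sim)
  final <- reconstruction_loss(params, s, sim,
                               decode_profile(params, z),
                               decode_similarity(params, z),
                               balance = 0.5, reg = 0)
  expect_lt(final, 1e-3)
})
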