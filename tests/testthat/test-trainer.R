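test_that("negative sampling: reductions, exhaustion and hygiene", {
  R <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(nrow(sample_negatives(R, 0)), 0)
  neg <- sample_negatives(R, 3, seed = 1)
  expect_equal(nrow(neg), 3)
  expect_setequal(paste(neg$drug, neg$disease), c("1 2", "2 1", "2 2"))
  expect_warning(sample_negatives(R, 4, seed = 1), "unobserved")
  set.seed(10)
  d <- rand_dataset(m = 9, n = 7, density = 0.2, seed = 61)
  for (rep in 1:20) {
    neg <- sample_negatives(d$R, 2)
    expect_equal(nrow(neg), 2 * sum(d$R))
    expect_true(all(d$R[cbind(neg$drug, neg$disease)] == 0))
    expect_equal(anyDuplicated(paste(neg$drug, neg$disease)), 0L)
  }
})

test_that("negative draws are uniform over unobserved cells", {
  R <- matrix(0, 10, 10)
  R[cbind(1:5, 1:5)] <- 1 # 5 positives, 95 unobserved cells
  counts <- integer(100)
  n_draws <- 1000
  set.seed(67)
  for (s in 1:n_draws) {
    neg <- sample_negatives(R, 10) # 50 negatives per draw
    idx <- (neg$disease - 1L) * 10L + neg$drug
    counts[idx] <- counts[idx] + 1L
  }
  zeros <- which(R == 0)
  expect_equal(sum(counts[-zeros]), 0) # positives never drawn
  # chi-square against uniform inclusion over the 95 unobserved cells
  observed <- counts[zeros]
  expected <- n_draws * 50 / 95
  chi <- sum((observed - expected)^2 / (expected * (1 - 50 / 95)))
  # df = 94; 1e-6 upper quantile ~ 180
  expect_lt(chi, stats::qchisq(1 - 1e-6, df = 94))
})

test_that("joint loss reduces to its components and matches a scalar oracle", {
  d <- rand_dataset(m = 4, n = 4, k_true = 2, density = 0.3, seed = 71)
  ctl <- tiny_control(k = 2, phi = 0, psi = 0, seed = 2)
  model <- init_anmf(d, ctl)
  pairs <- cbind(c(1, 2, 3), c(2, 3, 4))
  targets <- c(1, 0, 1)
  # phi = psi = 0: joint loss is the sum of prediction losses alone
  scores <- predict_matrix(model)
  expect_equal(
    as.numeric(joint_loss(model, pairs, targets)),
    sum(prediction_loss(scores[pairs], targets)),
    tolerance = 1e-10
  )

  # full objective vs an independently coded scalar recomputation
  ctl2 <- tiny_control(k = 2, seed = 2, alpha = 0.6, beta = 0.4,
                       lambda = 0.01, delta = 0.02, phi = 0.5, psi = 0.25)
  m2 <- init_anmf(d, ctl2)
  expected <- 0
  for (t in seq_len(nrow(pairs))) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    g2 <- m2$control$g; f2 <- m2$control$f
    zd <- encode(m2$drug_encoder, m2$train_R[i, ], m2$drug_sim[i, ], g = g2)
    ze <- encode(m2$disease_encoder, m2$train_R[, j], m2$disease_sim[j, ],
                 g = g2)
    pred <- prediction_loss(predict_pair(m2$h, zd, ze), targets[t])
    ld <- reconstruction_loss(
      m2$drug_encoder, m2$train_R[i, ], m2$drug_sim[i, ],
      decode_profile(m2$drug_encoder, zd, f = f2),
      decode_similarity(m2$drug_encoder, zd, f = f2),
      balance = 0.6, reg = 0.01
    )
    le <- reconstruction_loss(
      m2$disease_encoder, m2$train_R[, j], m2$disease_sim[j, ],
      decode_profile(m2$disease_encoder, ze, f = f2),
      decode_similarity(m2$disease_encoder, ze, f = f2),
      balance = 0.4, reg = 0.02
    )
    expected <- expected + pred + 0.5 * ld + 0.25 * le
  }
  got <- joint_loss(m2, pairs, targets)
  expect_equal(as.numeric(got), expected, tolerance = 1e-10)
  comp <- attr(got, "components")
  expect_equal(as.numeric(got),
               comp[["prediction"]] + 0.5 * comp[["drug_recon"]] +
                 0.25 * comp[["disease_recon"]],
               tolerance = 1e-10)
})

test_that("analytic joint-loss gradients match central differences", {
  d <- rand_dataset(m = 4, n = 4, k_true = 2, density = 0.3, seed = 73)
  pairs <- cbind(c(1, 2, 4, 3), c(1, 3, 2, 4))
  targets <- c(1, 0, 0, 1)
  for (ctl in list(
    tiny_control(k = 2, seed = 5, alpha = 0.7, beta = 0.3,
                 lambda = 0.001, delta = 0.01),
    local({ c2 <- tiny_control(k = 2, seed = 5); c2$use_sim <- FALSE; c2 })
  )) {
    model <- init_anmf(d, ctl)
    v0 <- model_param_vector(model)
    f <- function(v) as.numeric(joint_loss(model_with_params(model, v),
                                           pairs, targets))
    num <- central_diff_grad(f, v0, h = 1e-5)
    ana <- analytic_full_grads(model, pairs, targets)
    rel <- abs(ana - num) / pmax(abs(ana) + abs(num), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("fit with lr = 0 is a no-op relative to the seeded initialization", {
  d <- rand_dataset(m = 6, n = 5, seed = 79)
  ctl <- tiny_control(seed = 4, lr = 0, epochs = 3)
  fit <- fit_anmf(d, ctl)
  ref <- init_anmf(d, ctl)
  expect_identical(fit$drug_encoder, ref$drug_encoder)
  expect_identical(fit$disease_encoder, ref$disease_encoder)
  expect_identical(fit$h, ref$h)
  # same no-op for the ablation
  gfit <- fit_gmf(d, ctl)
  gref <- init_anmf(d, local({ c2 <- ctl; c2$use_sim <- FALSE; c2 }))
  expect_identical(gfit$drug_encoder, gref$drug_encoder)
})

test_that("training descends and is reproducible under one seed", {
  syn <- synthetic_dataset(m = 25, n = 15, k_true = 2, density = 0.15,
                           sim_signal = 0.9, seed = 83)
  d <- syn$dataset
  ctl <- anmf_control(k = 8, epochs = 30, batch_size = 32, n_neg = 3,
                      lr = 2.5, validation = FALSE, seed = 7)
  fit <- fit_anmf(d, ctl)
  expect_lt(fit$report$loss[nrow(fit$report)], fit$report$loss[1])
  fit2 <- fit_anmf(d, ctl)
  expect_identical(fit$drug_encoder, fit2$drug_encoder)
  expect_identical(fit$disease_encoder, fit2$disease_encoder)
  expect_identical(fit$h, fit2$h)
  expect_identical(fit$report, fit2$report)
  # tidiers expose the trace
  expect_identical(tidy(fit), fit$report)
  g <- glance(fit)
  expect_equal(g$epochs_run, nrow(fit$report))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("GMF ablation drops the similarity pathway but shares the predictor", {
  d <- rand_dataset(m = 6, n = 5, seed = 89)
  ctl <- tiny_control(seed = 6)
  anmf_m <- init_anmf(d, ctl)
  gmf_c <- ctl; gmf_c$use_sim <- FALSE
  gmf_m <- init_anmf(d, gmf_c)
  expect_true(all(gmf_m$drug_encoder$V1 == 0))
  expect_true(all(gmf_m$disease_encoder$V2 == 0))
  # with V frozen at 0 the GMF prediction equals ANMF's at V = 0
  anmf_v0 <- anmf_m
  anmf_v0$drug_encoder$V1[] <- 0; anmf_v0$drug_encoder$V2[] <- 0
  anmf_v0$disease_encoder$V1[] <- 0; anmf_v0$disease_encoder$V2[] <- 0
  anmf_v0$h <- gmf_m$h
  anmf_v0$drug_encoder$W1 <- gmf_m$drug_encoder$W1
  anmf_v0$drug_encoder$b_enc <- gmf_m$drug_encoder$b_enc
  anmf_v0$disease_encoder$W1 <- gmf_m$disease_encoder$W1
  anmf_v0$disease_encoder$b_enc <- gmf_m$disease_encoder$b_enc
  expect_equal(predict_matrix(anmf_v0), predict_matrix(gmf_m),
               tolerance = 1e-12)
  pairs <- cbind(1:3, 1:3); targets <- c(1, 0, 1)
  comp_a <- attr(joint_loss(anmf_v0, pairs, targets), "components")
  comp_g <- attr(joint_loss(gmf_m, pairs, targets), "components")
  expect_equal(comp_a[["prediction"]], comp_g[["prediction"]],
               tolerance = 1e-12)
})

test_that("divergence is detected and reported", {
  d <- rand_dataset(m = 6, n = 5, seed = 97)
  ctl <- tiny_control(seed = 8, lr = 1e6, epochs = 20)
  expect_error(fit_anmf(d, ctl), "diverged|non-finite")
})

test_that("model checkpoints round-trip through plain text", {
  d <- rand_dataset(m = 5, n = 4, seed = 99)
  ctl <- tiny_control(seed = 9, lr = 1, epochs = 2)
  fit <- fit_anmf(d, ctl)
  dir <- withr::local_tempdir()
  write_model(fit, dir)
  back <- read_model(dir)
  expect_equal(back$drug_encoder$W1, fit$drug_encoder$W1)
  expect_equal(back$h, fit$h)
  expect_identical(predict_matrix(back), predict_matrix(fit))
})
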