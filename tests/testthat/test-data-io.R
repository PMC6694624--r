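test_that("a 2x2 identity-style dataset validates and exposes its pieces", {
  d <- toy_dataset()
  expect_s3_class(d, "anmf_dataset")
  s <- dataset_stats(d)
  expect_equal(s$n_drugs, 2)
  expect_equal(s$n_diseases, 2)
  expect_equal(s$n_interactions, 2L)
  expect_equal(s$sparsity, 0.5)
})

test_that("sparsity reproduces the benchmark dataset statistics", {
  # 593 drugs x 313 diseases with 1933 associations, and 409 x 663 with 2532
  expect_equal(signif(1933 / (593 * 313), 4), 1.041e-2)
  g <- anmf_dataset(
    R = matrix(0, 4, 4), drug_sim = diag(4), disease_sim = diag(4)
  )
  expect_equal(dataset_stats(g)$sparsity, 0)
})

test_that("interaction profiles are row/column copies with bounds checks", {
  d <- toy_dataset()
  expect_equal(unname(drug_profile(d, 1)), c(1, 0))
  expect_equal(unname(drug_profile(d, "drugA")), c(1, 0))
  expect_equal(unname(disease_profile(d, 1)), c(1, 0))
  p <- drug_profile(d, 1)
  p[1] <- 99
  expect_equal(unname(drug_profile(d, 1)), c(1, 0)) # copy semantics
  expect_error(drug_profile(d, 3), "out of range")
  expect_error(disease_profile(d, 0), "out of range")
  expect_error(drug_profile(d, "nope"), "unknown drug")
})

test_that("validation rejects malformed inputs and repairs asymmetry", {
  S <- diag(2)
  expect_error(
    anmf_dataset(matrix(c(1, 0, 0, 0.5), 2, 2), S, S),
    "binary"
  )
  expect_error(
    anmf_dataset(matrix(0, 2, 2), diag(3), S),
    "must be 2x2"
  )
  expect_error(
    anmf_dataset(matrix(0, 2, 2), S, S, drug_ids = c("a", "a")),
    "duplicate drug"
  )
  asym <- matrix(c(1, 0.2, 0.6, 1), 2, 2)
  expect_warning(
    d <- anmf_dataset(matrix(0, 2, 2), asym, S),
    "symmetrized"
  )
  expect_equal(d$drug_sim[1, 2], 0.4)
  expect_equal(d$drug_sim, t(d$drug_sim))
})

test_that("dense TSV round trip is bit-exact", {
  d <- rand_dataset(m = 7, n = 5, seed = 4)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- read_dataset(file.path(dir, "assoc.tsv"),
                     file.path(dir, "drug_sim.tsv"),
                     file.path(dir, "disease_sim.tsv"))
  expect_identical(d2$R, d$R)
  expect_identical(d2$drug_sim, d$drug_sim)
  expect_identical(d2$disease_sim, d$disease_sim)
  expect_identical(d2$drug_ids, d$drug_ids)
})

test_that("edge-list and dense renderings load to identical datasets", {
  d <- rand_dataset(m = 6, n = 4, seed = 9)
  dense_dir <- withr::local_tempdir()
  edge_dir <- withr::local_tempdir()
  write_dataset(d, dense_dir, assoc_format = "dense")
  write_dataset(d, edge_dir, assoc_format = "edges")
  dd <- read_dataset(file.path(dense_dir, "assoc.tsv"),
                     file.path(dense_dir, "drug_sim.tsv"),
                     file.path(dense_dir, "disease_sim.tsv"))
  de <- read_dataset(file.path(edge_dir, "assoc.tsv"),
                     file.path(edge_dir, "drug_sim.tsv"),
                     file.path(edge_dir, "disease_sim.tsv"))
  expect_identical(dd$R, de$R)
  expect_identical(dataset_stats(dd), dataset_stats(de))
})

test_that("a single-edge list yields the expected matrix", {
  dir <- withr::local_tempdir()
  sim2 <- function(ids) {
    m <- diag(2); dimnames(m) <- list(ids, ids); m
  }
  d0 <- anmf_dataset(matrix(0, 2, 2), sim2(c("drugA", "drugB")),
                     sim2(c("disX", "disY")),
                     drug_ids = c("drugA", "drugB"),
                     disease_ids = c("disX", "disY"))
  write_dataset(d0, dir) # for the similarity files
  writeLines("drugA\tdisX", file.path(dir, "assoc.tsv"))
  d <- read_dataset(file.path(dir, "assoc.tsv"),
                    file.path(dir, "drug_sim.tsv"),
                    file.path(dir, "disease_sim.tsv"))
  expect_equal(unname(d$R), matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
})

test_that("unknown identifiers in the association file are named in the error", {
  d <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  writeLines(c("drugA\tdisX", "drugZZZ\tdisY"), file.path(dir, "assoc.tsv"))
  expect_error(
    read_dataset(file.path(dir, "assoc.tsv"),
                 file.path(dir, "drug_sim.tsv"),
                 file.path(dir, "disease_sim.tsv")),
    "drugZZZ"
  )
  expect_error(
    read_dataset(file.path(dir, "nope.tsv"),
                 file.path(dir, "drug_sim.tsv"),
                 file.path(dir, "disease_sim.tsv")),
    "nope.tsv"
  )
})
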