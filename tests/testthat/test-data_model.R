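ext <- system.file("extdata", package = "aftfuse")

test_that("load_cancer_dataset joins expression and clinical tables", {
  d <- load_cancer_dataset(file.path(ext, "expression_A.tsv"),
                           file.path(ext, "clinical_A.tsv"), "A")
  # clinical table misses the 12th expression sample on purpose
  expect_equal(d$n, 11)
  expect_equal(d$p, 5)
  expect_false(d$canonical)
  expect_true(all(d$delta %in% c(0, 1)))
  clin <- read.delim(file.path(ext, "clinical_A.tsv"))
  expect_equal(d$delta, as.numeric(clin$OS_STATUS == "DECEASED"))
})

test_that("status mapping and load errors behave as documented", {
  td <- withr::local_tempdir()
  expr <- data.frame(Hugo_Symbol = c("G1", "G2"),
                     S1 = c(1, 2), S2 = c(3, 4), S3 = c(5, 6))
  write.table(expr, file.path(td, "e.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  clin <- data.frame(SAMPLE_ID = c("S1", "S2", "S3"),
                     OS_MONTHS = c(5, 10, 2),
                     OS_STATUS = c("1:DECEASED", "0:LIVING", "DECEASED"))
  write.table(clin, file.path(td, "c.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  d <- load_cancer_dataset(file.path(td, "e.tsv"), file.path(td, "c.tsv"))
  expect_equal(d$delta, c(1, 0, 1))

  bad <- clin; names(bad)[2] <- "MONTHS"
  write.table(bad, file.path(td, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_cancer_dataset(file.path(td, "e.tsv"),
                                   file.path(td, "bad.tsv")),
               "missing required column")

  none <- clin; none$SAMPLE_ID <- c("X1", "X2", "X3")
  write.table(none, file.path(td, "none.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_cancer_dataset(file.path(td, "e.tsv"),
                                   file.path(td, "none.tsv")),
               "no overlapping samples")

  neg <- clin; neg$OS_MONTHS[2] <- 0
  write.table(neg, file.path(td, "neg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_cancer_dataset(file.path(td, "e.tsv"),
                                   file.path(td, "neg.tsv")),
               "S2")
})

test_that("canonicalize sorts, logs, breaks ties events-first, idempotent", {
  d <- cancer_dataset(matrix(1:3, 3, 1), c(2, 1, 3), c(1, 1, 0))
  cd <- canonicalize(d)
  expect_equal(cd$y, log(c(1, 2, 3)))
  expect_equal(cd$X[, 1], c(2, 1, 3))
  # tie: event before censoring
  t2 <- canonicalize(cancer_dataset(matrix(1:2, 2, 1), c(2, 2), c(0, 1)))
  expect_equal(t2$delta, c(1, 0))
  expect_equal(t2$X[, 1], c(2, 1))
  # idempotence
  expect_equal(canonicalize(cd), cd)
  expect_error(canonicalize(cancer_dataset(matrix(0, 1, 1), -1, 1)),
               "nonpositive")
})

test_that("align_genes intersects, sorts, honours the panel", {
  dA <- cancer_dataset(matrix(1:8, 2, 4,
                              dimnames = list(NULL, c("C", "A", "B", "D"))),
                       c(1, 2), c(1, 1), "A")
  dB <- cancer_dataset(matrix(1:6, 2, 3,
                              dimnames = list(NULL, c("B", "C", "E"))),
                       c(1, 2), c(1, 1), "B")
  md <- align_genes(list(dA, dB))
  expect_equal(md$gene_ids, c("B", "C"))
  expect_equal(md$datasets[[1]]$X[, "B"], dA$X[, "B"])
  md_panel <- align_genes(list(dA, dB), panel = "C")
  expect_equal(md_panel$gene_ids, "C")
  # order of cohorts only permutes the cohort labels
  md_swap <- align_genes(list(dB, dA))
  expect_equal(md_swap$gene_ids, md$gene_ids)
  dC <- cancer_dataset(matrix(1:2, 2, 1, dimnames = list(NULL, "Z")),
                       c(1, 2), c(1, 1), "C")
  expect_error(align_genes(list(dA, dC)), "empty gene intersection")
})

test_that("weighted standardization reproduces hand-computed moments", {
  # equal weights, symmetric column: unchanged up to the 1/n scale rule
  d <- canonicalize(cancer_dataset(cbind(a = c(1, -1), b = c(2, 2)),
                                   c(1, 2), c(1, 1)))
  w <- compute_km_weights(d)
  std <- weighted_standardize(d, w)
  expect_equal(std$record$x_center[["a"]], 0)
  expect_false(std$record$keep[["b"]])     # constant column flagged
  expect_equal(std$Xs[, "b"], c(0, 0))
  # 3-row fixture with unequal weights, moments by hand
  d3 <- canonicalize(cancer_dataset(cbind(g = c(1, 2, 4)),
                                    c(1, 2, 3), c(1, 0, 1)))
  w3 <- compute_km_weights(d3)             # w = (1/3, 0, 2/3)
  s3 <- weighted_standardize(d3, w3)
  expect_equal(s3$record$y_center,
               (1 / 3 * log(1) + 2 / 3 * log(3)))
  expect_equal(s3$record$x_center[["g"]], 1 / 3 * 1 + 2 / 3 * 4)
  ms <- (1 / 3 * (1 - 3)^2 + 2 / 3 * (4 - 3)^2) / 3
  expect_equal(s3$record$x_scale[["g"]], sqrt(ms))
  # degenerate weights error
  d0 <- canonicalize(cancer_dataset(cbind(1:3), c(1, 2, 3), c(0, 0, 0)))
  expect_error(weighted_standardize(d0, compute_km_weights(d0)),
               "degenerate weights")
})

test_that("standardization round trip reproduces fitted values", {
  d <- make_cohort(40, 3, seed = 9, beta = c(1, -0.5, 0), censor = 0.25)
  w <- compute_km_weights(d)
  std <- weighted_standardize(d, w)
  eta_std <- c(0.8, -0.3, 0.1)
  back <- aftfuse:::unstandardize_coef(eta_std, std$record)
  fitted_std <- as.numeric(std$Xs %*% eta_std) + std$record$y_center
  fitted_orig <- back$alpha + as.numeric(d$X %*% back$eta)
  expect_lt(max(abs(fitted_std - fitted_orig)), 1e-10)
})
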