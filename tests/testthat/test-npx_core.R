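test_that("long-format NPX read/write round trip preserves values exactly", {
  m <- tiny_npx()
  path <- withr::local_tempfile(fileext = ".csv")
  write_npx_long(m, path)
  m2 <- read_npx_long(path)
  expect_identical(m2$values, m$values)
  expect_identical(m2$lod, m$lod)
  expect_identical(m2$batch, m$batch)

  # file -> matrix -> file reproduces the file up to row order
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_npx_long(m2, path2)
  a <- read.csv(path); b <- read.csv(path2)
  key <- function(d) d[order(d$sample_id, d$assay_id), ]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("reader rejects malformed long files", {
  m <- tiny_npx()
  path <- withr::local_tempfile(fileext = ".csv")
  write_npx_long(m, path)
  df <- read.csv(path)

  dup <- rbind(df, df[df$sample_id == "s1" & df$assay_id == "DDC_panelA", ])
  pd <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, pd, row.names = FALSE)
  expect_error(read_npx_long(pd), "s1.*DDC_panelA")

  nocol <- df[, setdiff(names(df), "lod")]
  pn <- withr::local_tempfile(fileext = ".csv")
  write.csv(nocol, pn, row.names = FALSE)
  expect_error(read_npx_long(pn), "required column.*lod")

  bad <- df
  bad$npx <- as.character(bad$npx)
  bad$npx[2] <- "not_a_number"
  pb <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, pb, row.names = FALSE)
  expect_error(read_npx_long(pb), "non-numeric NPX.*2")

  # column aliases map vendor headers onto the standard names
  ali <- df
  names(ali)[names(ali) == "sample_id"] <- "SampleID"
  pa <- withr::local_tempfile(fileext = ".csv")
  write.csv(ali, pa, row.names = FALSE)
  expect_identical(read_npx_long(pa, aliases = c(sample_id = "SampleID"))$values,
                   m$values)
})

test_that("detectability filter uses a strict > LOD with an inclusive 85% boundary", {
  n <- 100
  mk <- function(n_above) {
    v <- c(rep(1, n_above), rep(-1, n - n_above)) # LOD = 0
    v
  }
  values <- cbind(a84 = mk(84), a85 = mk(85), a_eq = rep(0, n), all_up = rep(2, n))
  rownames(values) <- sprintf("s%03d", 1:n)
  m <- npx_matrix(values, lod = c(a84 = 0, a85 = 0, a_eq = 0, all_up = 0))
  res <- filter_by_detectability(m, 0.85)
  expect_setequal(res$dropped, c("a84", "a_eq")) # values AT the LOD do not count
  expect_setequal(assay_ids(res$matrix), c("a85", "all_up"))
  # sub-LOD values of retained assays are untouched
  expect_identical(res$matrix$values[, "a85"], values[, "a85"])

  # idempotence
  res2 <- filter_by_detectability(res$matrix, 0.85)
  expect_identical(res2$matrix$values, res$matrix$values)
  expect_length(res2$dropped, 0)

  # missing values are excluded from the denominator: 85 above / 15 NA
  v3 <- cbind(na_assay = c(rep(1, 85), rep(NA, 15)))
  rownames(v3) <- sprintf("s%03d", 1:100)
  m3 <- npx_matrix(v3, lod = c(na_assay = 0))
  expect_length(filter_by_detectability(m3)$dropped, 0)

  expect_error(filter_by_detectability(m, 1.2), "min_frac")
  expect_error(filter_by_detectability(m[, 0], 0.85), "empty")
})

test_that("bridging normalization removes a constant batch offset exactly", {
  set.seed(1)
  base <- matrix(rnorm(8 * 4), 8, 4,
                 dimnames = list(sprintf("s%d", 1:8), sprintf("a%d", 1:4)))
  # samples 1-4 in batch A; 5-8 are re-measurements of 1-4 in batch B, +0.7
  values <- base
  values[5:8, ] <- base[1:4, ] + 0.7
  m <- npx_matrix(values, lod = rep(-10, 4),
                  batch = rep(c("A", "B"), each = 4))
  bridges <- data.frame(sample_id = sprintf("s%d", 1:8),
                        bridge_id = rep(sprintf("b%d", 1:4), 2))
  norm <- bridge_normalize(m, bridges, reference_batch = "A")
  expect_equal(norm$values[5:8, ], base[1:4, ], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(norm$values[1:4, ], values[1:4, ]) # reference unchanged
})

test_that("bridging normalization recovers planted per-assay offsets with zero bridge noise", {
  d <- small_design(n_batches = 2, batch_sd = 0.5, n_bridges = 8,
                    bridge_noise_sd = 0)
  sim <- generate_cohort(d, seed = 21)
  norm <- bridge_normalize(sim$npx, sim$bridges, reference_batch = "R1")
  # after normalization, each bridge pair agrees exactly on every assay
  b <- sim$bridges
  r1 <- b$sample_id[b$batch == "R1"][order(b$bridge_id[b$batch == "R1"])]
  r2 <- b$sample_id[b$batch == "R2"][order(b$bridge_id[b$batch == "R2"])]
  expect_equal(norm$values[r2, ], norm$values[r1, ], ignore_attr = TRUE,
               tolerance = 1e-10)

  # single batch: output equals input
  d1 <- small_design(n_batches = 1, n_bridges = 0)
  sim1 <- generate_cohort(d1, seed = 22)
  expect_identical(
    bridge_normalize(sim1$npx, data.frame(sample_id = character(),
                                          bridge_id = character()),
                     "R1")$values,
    sim1$npx$values)

  # no shared bridges between batches -> error
  bad <- sim$bridges
  bad <- bad[bad$batch == "R1", ]
  expect_error(bridge_normalize(sim$npx, bad, "R1"), "shared bridging")
})

test_that("replicate assay correlations behave as QC expects", {
  set.seed(3)
  n <- 4000
  latent <- rnorm(n, sd = 1)
  v <- cbind(dup1 = latent, dup2 = latent, neg = -latent,
             n1 = latent + rnorm(n, sd = 1), n2 = latent + rnorm(n, sd = 1))
  rownames(v) <- sprintf("s%05d", 1:n)
  m <- npx_matrix(v, lod = rep(-10, 5))
  res <- replicate_correlation(m, list(P1 = c("dup1", "dup2"),
                                       P2 = c("dup1", "neg"),
                                       P3 = c("n1", "n2")))
  expect_equal(res$spearman_r[res$protein == "P1"], 1)
  expect_equal(res$spearman_r[res$protein == "P2"], -1)
  # attenuation: Pearson rho = 0.5 => Spearman (6/pi) asin(rho/2) ~ 0.483
  expect_equal(res$spearman_r[res$protein == "P3"], (6 / pi) * asin(0.25),
               tolerance = 0.04)

  # < 3 complete pairs -> NA
  v2 <- v[1:4, c("n1", "n2")]
  v2[1:2, 1] <- NA
  m2 <- npx_matrix(v2, lod = c(-10, -10))
  r2 <- replicate_correlation(m2, list(P = c("n1", "n2")))
  expect_true(is.na(r2$spearman_r))

  # collapsing replicates averages member columns
  mc <- collapse_replicates(m, list(P1 = c("dup1", "dup2")))
  expect_true("P1" %in% assay_ids(mc))
  expect_false(any(c("dup1", "dup2") %in% assay_ids(mc)))
  expect_equal(mc$values[, "P1"], (v[, "dup1"] + v[, "dup2"]) / 2,
               ignore_attr = TRUE)
})
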