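test_that("a well-formed delimited table round-trips through the reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(make_variants(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ds <- read_summary_table(path, column_map = c(snp = "rsid"))
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds), 4L)
  expect_equal(ds$beta, make_variants()$beta)
  expect_equal(nrow(attr(ds, "drop_log")), 0L)

  # comma-delimited dialect with renamed columns reads identically
  v <- make_variants()
  names(v) <- c("SNP", "EA", "OA", "FRQ", "BETA", "SE", "P", "N")
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(v, csv, row.names = FALSE, quote = FALSE)
  ds2 <- read_summary_table(csv, column_map = c(
    snp = "SNP", effect_allele = "EA", other_allele = "OA", eaf = "FRQ",
    beta = "BETA", se = "SE", pval = "P", n = "N"))
  expect_equal(ds2$beta, ds$beta)
  expect_equal(ds2$rsid, ds$rsid)
})

test_that("invalid rows are dropped with logged reasons, never silently", {
  v <- make_variants()
  v$se[2] <- 0
  expect_warning(ds <- summary_dataset(v), "se not > 0")
  expect_equal(nrow(ds), 3L)
  expect_equal(attr(ds, "drop_log")$rsid, "rs2")

  # duplicated rsid: first occurrence kept, deterministically
  v2 <- make_variants(rsid = c("rs1", "rs1", "rs3", "rs4"))
  expect_warning(ds2 <- summary_dataset(v2), "duplicate")
  expect_equal(ds2$rsid, c("rs1", "rs3", "rs4"))
  expect_equal(ds2$beta[ds2$rsid == "rs1"], 0.10) # the first row's beta

  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(v2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ds3 <- read_summary_table(path, c(snp = "rsid")))
  expect_equal(as.data.frame(ds3), as.data.frame(ds2), ignore_attr = TRUE)
})

test_that("configuration and empty-dataset errors are raised", {
  path <- withr::local_tempfile(fileext = ".tsv")
  v <- make_variants()
  utils::write.table(v[, setdiff(names(v), "se")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_summary_table(path, c(snp = "rsid")), "not found")

  v_bad <- make_variants(se = rep(0, 4))
  expect_error(suppressWarnings(summary_dataset(v_bad)), "no variants survive")
  expect_error(summary_dataset(make_variants()[, 1:3]), "missing required")
})

test_that("harmonisation aligns swapped, identical and complemented codings", {
  exp <- make_dataset(trait_name = "exposure")
  # outcome 1: rs1 swapped (G/A vs A/G), rs2 identical, rs3 strand-complemented
  out_v <- make_variants(
    effect_allele = c("G", "C", "C", "A"),
    other_allele = c("A", "T", "T", "T"),
    beta = c(-0.05, 0.02, 0.03, 0.01),
    eaf = c(0.30, 0.25, 0.40, 0.30),
    se = rep(0.02, 4), pval = rep(0.01, 4))
  out <- summary_dataset(out_v, trait_name = "outcome")
  expect_warning(h <- harmonise(exp, out), "irreconcilable")

  expect_equal(h$beta_y[h$rsid == "rs1"], +0.05) # sign flipped
  expect_equal(h$eaf_y[h$rsid == "rs1"], 0.70)
  expect_true(h$was_flipped[h$rsid == "rs1"])

  expect_equal(h$beta_y[h$rsid == "rs2"], 0.02) # identical coding untouched
  expect_false(h$was_flipped[h$rsid == "rs2"])

  # rs3: exposure G/A, outcome C/T -> complement to G/A, kept unchanged
  expect_equal(h$beta_y[h$rsid == "rs3"], 0.03)
  expect_false(h$was_flipped[h$rsid == "rs3"])

  # rs4: exposure T/C, outcome A/T -> irreconcilable, dropped with reason
  expect_false("rs4" %in% h$rsid)
  expect_equal(attr(h, "drop_log")$rsid, "rs4")
})

test_that("palindromic variants are retained and flagged, not excluded", {
  exp <- summary_dataset(make_variants(rsid = c("rs1", "rs2"),
                                       effect_allele = c("A", "G"),
                                       other_allele = c("T", "C"),
                                       beta = c(0.1, 0.1), se = c(0.01, 0.01),
                                       eaf = c(0.2, 0.3),
                                       pval = c(1e-9, 1e-9), n = 100)[1:2, ])
  out <- summary_dataset(make_variants(rsid = c("rs1", "rs2"),
                                       effect_allele = c("A", "C"),
                                       other_allele = c("T", "G"),
                                       beta = c(0.05, 0.04), se = c(0.02, 0.02),
                                       eaf = c(0.2, 0.7),
                                       pval = c(0.1, 0.1), n = 100)[1:2, ])
  expect_warning(h <- harmonise(exp, out), NA)
  expect_equal(nrow(h), 2L)
  expect_true(all(h$is_palindromic))
  # forward-strand assumption: rs1 same coding kept, rs2 swapped coding flipped
  expect_equal(h$beta_y, c(0.05, -0.04))
})

test_that("harmonisation is an involution and orientation-invariant", {
  for (seed in 1:5) {
    pair <- simulate_pair(sim_config(seed = seed, J = 8, theta = 0.4,
                                     scramble_alleles = TRUE))
    h1 <- harmonise(pair$exposure, pair$outcome)

    # re-feed the harmonised orientation as an outcome dataset: nothing changes
    out2 <- summary_dataset(data.frame(
      rsid = h1$rsid,
      effect_allele = pair$exposure$effect_allele[match(h1$rsid, pair$exposure$rsid)],
      other_allele = pair$exposure$other_allele[match(h1$rsid, pair$exposure$rsid)],
      eaf = h1$eaf_y, beta = h1$beta_y, se = h1$se_y, pval = 0.5,
      stringsAsFactors = FALSE), trait_name = "outcome")
    h2 <- harmonise(pair$exposure, out2)
    expect_equal(h2$beta_y, h1$beta_y)
    expect_equal(h2$eaf_y, h1$eaf_y)
    expect_false(any(h2$was_flipped))

    # flipping the outcome file's reported alleles (and negating beta,
    # complementing eaf) yields an identical harmonised instrument
    ov <- as.data.frame(pair$outcome)
    flipped <- ov
    flipped$effect_allele <- ov$other_allele
    flipped$other_allele <- ov$effect_allele
    flipped$beta <- -ov$beta
    flipped$eaf <- 1 - ov$eaf
    h3 <- harmonise(pair$exposure, summary_dataset(flipped, "outcome"))
    expect_equal(h3$beta_y, h1$beta_y)
    expect_equal(h3$se_y, h1$se_y)
    expect_equal(h3$eaf_y, h1$eaf_y)
    expect_equal(h3$is_palindromic, h1$is_palindromic)

    # conservation: shared = harmonised + dropped-with-reason
    shared <- length(intersect(pair$exposure$rsid, pair$outcome$rsid))
    expect_equal(shared, nrow(h1) + nrow(attr(h1, "drop_log")))
  }
})

test_that("disjoint exposure and outcome rsids raise an empty-instrument error", {
  a <- make_dataset()
  b_v <- make_variants(rsid = paste0("rs", 11:14))
  expect_error(harmonise(a, summary_dataset(b_v)), "no shared rsids")
})

test_that("a harmonised instrument serialises with its flag columns", {
  pair <- simulate_pair(sim_config(seed = 4, J = 5))
  h <- harmonise(pair$exposure, pair$outcome)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonised(h, path)
  back <- utils::read.delim(path)
  expect_equal(back$beta_y, h$beta_y)
  expect_equal(back$was_flipped, h$was_flipped)
  expect_equal(back$is_palindromic, h$is_palindromic)
})
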