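test_that("structural audit counts hold for the reference set", {
  audit <- audit_parameters()
  expect_true(all(audit$pass))
  expect_equal(audit$observed[audit$check == "n_parameters_raw"], 73)
  expect_equal(audit$observed[audit$check == "n_parameters_free"], 54)
})

test_that("the packaged reference file reproduces the defaults exactly", {
  path <- reference_parameter_file()
  expect_identical(load_parameters(path), default_parameters())
})

test_that("write/load round trip is bit-identical", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  p <- default_parameters()
  p[["ka_plx_pg"]] <- 0.123456789012345
  write_parameters(p, tmp)
  expect_identical(load_parameters(tmp), p)
})

test_that("schema violations are reported with the offending field", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameters(default_parameters(), tmp)
  txt <- readLines(tmp)
  writeLines(txt[!grepl("ka_plx_pg", txt)], tmp)
  expect_error(load_parameters(tmp), "ka_plx_pg")
  expect_error(validate_parameters(c(default_parameters(), bogus = 1)),
               "bogus")
  p <- default_parameters(); p[["kd_mos_0"]] <- -1
  expect_error(validate_parameters(p), "kd_mos_0")
})

test_that("interventions modify exactly the referenced parameters", {
  p <- default_parameters()
  expect_identical(apply_intervention(p, intervention(character(0))), p)
  q <- apply_intervention(p, intervention("ks_mos_c1", "zero"))
  expect_equal(q[["ks_mos_c1"]], 0)
  expect_identical(q[setdiff(names(q), "ks_mos_c1")],
                   p[setdiff(names(p), "ks_mos_c1")])
  q2 <- apply_intervention(p, intervention("ks_emi_c4", "scale", 5))
  expect_equal(q2[["ks_emi_c4"]], 5 * p[["ks_emi_c4"]])
  expect_error(apply_intervention(p, intervention("not_a_param", "zero")),
               "not_a_param")
  expect_error(apply_intervention(p, intervention("ks_mos_c1", "scale", -2)),
               "negative")
})

test_that("interaction parameters are a subset of the free parameters", {
  tab <- parameter_table()
  expect_true(all(tab$status[tab$interaction] == "free"))
  expect_gte(sum(tab$interaction), 25)
})
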