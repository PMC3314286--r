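test_that("export writes a structurally valid document with matching counts", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 10))
  path <- withr::local_tempfile(fileext = ".xml")
  h <- export_sbml(sys, path)
  expect_identical(h$level, 3L)
  expect_identical(h$version, 1L)
  expect_identical(h$n_species, nrow(model_species(sys)))
  expect_identical(h$n_reactions, length(sys$reactions))
  expect_true(h$valid)
  expect_identical(h$errors, character(0))
  rep_path <- withr::local_tempfile(fileext = ".json")
  val <- validate_sbml(path, report = rep_path)
  expect_true(val$valid)
  expect_true(file.exists(rep_path))
})

test_that("export/import round trip preserves the vector field exactly", {
  for (mech in c("REPRESSOR", "COMPETITION", "INTEGRATED")) {
    sys <- build_model(mech, init = c(TIF1g_n = 10))
    path <- withr::local_tempfile(fileext = ".xml")
    export_sbml(sys, path)
    imp <- import_sbml(path)
    expect_identical(nrow(model_species(imp)), nrow(model_species(sys)))
    expect_identical(sort(names(imp$conservation)), sort(names(sys$conservation)))
    set.seed(42)
    for (i in 1:20) {
      st <- stats::runif(nrow(model_species(sys)), 0, 50)
      a <- model_rhs(sys, st, 0, ligand = 10)
      b <- model_rhs(imp, st, 0, ligand = 10)
      expect_lt(max(abs(a - b) / pmax(abs(a), 1e-12)), 1e-12)
    }
  }
})

test_that("a depletion-variant model round-trips with its ligand species", {
  sys <- build_model(model_variant("INTEGRATED", ligand_depletion = TRUE),
                     init = c(TIF1g_n = 5))
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(sys, path)
  imp <- import_sbml(path)
  expect_true(imp$variant$ligand_depletion)
  expect_true("TGFb" %in% model_species(imp)$name)
})

test_that("defective documents are rejected with typed errors", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 10))
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(sys, path)

  doc <- xml2::read_xml(path); xml2::xml_ns_strip(doc)
  node <- xml2::xml_find_first(doc, "//parameter[@id='k_on']")
  xml2::xml_set_attr(node, "value", "-1")
  bad1 <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, bad1)
  expect_false(validate_sbml(bad1)$valid)
  expect_error(import_sbml(bad1), "nonnegative")

  doc2 <- xml2::read_xml(path); xml2::xml_ns_strip(doc2)
  math <- xml2::xml_find_first(doc2,
    "//reaction[@id='hetero_n_on']/kineticLaw/math/apply")
  xml2::xml_add_child(math, "plus")
  bad2 <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc2, bad2)
  expect_error(import_sbml(bad2), "hetero_n_on")
})

test_that("an imported TIF1g-free system still reduces to the base model", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 0))
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(sys, path)
  imp <- import_sbml(path)
  tg <- seq(0, 7200, by = 600)
  base <- build_model("BASE")
  t_imp <- simulate_system(imp, sustained10(), tg)
  t_base <- simulate_system(base, sustained10(), tg)
  common <- colnames(t_base$mat)
  rel <- abs(t_imp$mat[, common] - t_base$mat[, common]) /
    pmax(abs(t_base$mat[, common]), 1e-8)
  expect_lt(max(rel), 1e-8)
})
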