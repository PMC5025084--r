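# SBML export of the single-compartment kinetic core.

test_that("the SBML document is well-formed and complete", {
  f <- tempfile(fileext = ".xml")
  export_sbml(structural_params(), f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  species <- xml2::xml_find_all(doc, ".//sbml:species", ns)
  expect_length(species, 17 + 7)
  reactions <- xml2::xml_find_all(doc, ".//sbml:reaction", ns)
  expect_length(reactions, 27)
  # blood species are boundary conditions
  bc <- xml2::xml_attr(species, "boundaryCondition")
  expect_equal(sum(bc == "true"), 7)
  # every reaction carries a kinetic law with MathML
  kl <- xml2::xml_find_all(doc, ".//sbml:kineticLaw", ns)
  expect_length(kl, 27)
  # spot-check stoichiometry: lipogenesis consumes 8 acetyl-CoA
  lg <- xml2::xml_find_first(doc, ".//sbml:reaction[@id='R_lgen']", ns)
  reac <- xml2::xml_find_all(lg, ".//sbml:speciesReference", ns)
  sp <- xml2::xml_attr(reac, "species")
  st <- as.numeric(xml2::xml_attr(reac, "stoichiometry"))
  expect_equal(st[sp == "acetyl_coa"], 8)
  unlink(f)
})

test_that("reversible transport is flagged reversible in the export", {
  f <- tempfile(fileext = ".xml")
  export_sbml(structural_params(), f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  for (id in c("R_glut", "R_lact", "R_glyt", "R_ak")) {
    r <- xml2::xml_find_first(doc, sprintf(".//sbml:reaction[@id='%s']", id), ns)
    expect_equal(xml2::xml_attr(r, "reversible"), "true", info = id)
  }
  gk <- xml2::xml_find_first(doc, ".//sbml:reaction[@id='R_gk']", ns)
  expect_equal(xml2::xml_attr(gk, "reversible"), "false")
  unlink(f)
})
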