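# FMU packaging, structural compliance checking, and archive round trips.

test_that("zip writer round-trips entries through utils::unzip", {
  entries <- list("a/b.txt" = charToRaw("hello archive\n"),
                  "c.bin" = as.raw(c(0:255, 255:0)))
  path <- tempfile(fileext = ".zip")
  cardiocosim:::zip_write(entries, path)
  exdir <- tempfile()
  unzip(path, exdir = exdir)
  expect_identical(readBin(file.path(exdir, "a", "b.txt"), "raw", 100),
                   entries[["a/b.txt"]])
  expect_identical(readBin(file.path(exdir, "c.bin"), "raw", 1000),
                   entries[["c.bin"]])
})

test_that("packaged FMU declares FMI 2.0 co-simulation and passes the checker", {
  path <- tempfile(fileext = ".fmu")
  package_fmu(default_config(), path)
  listing <- unzip(path, list = TRUE)
  expect_true("modelDescription.xml" %in% listing$Name)
  exdir <- tempfile()
  unzip(path, files = "modelDescription.xml", exdir = exdir)
  doc <- xml2::read_xml(file.path(exdir, "modelDescription.xml"))
  expect_equal(xml2::xml_attr(doc, "fmiVersion"), "2.0")
  expect_length(xml2::xml_find_all(doc, "./CoSimulation"), 1)
  expect_false(is.na(xml2::xml_attr(doc, "guid")))

  rep <- check_fmu(path)
  expect_true(rep$pass)
  expect_length(rep$findings, 0)
})

test_that("package -> load round trip is lossless for the registry", {
  m <- build_norwood_lpm(default_config())
  path <- tempfile(fileext = ".fmu")
  package_fmu(m, path)
  fmu <- load_fmu(path)
  orig <- variable_registry(m)
  got <- fmu$variables[, c("name", "value_reference", "causality", "unit",
                           "start")]
  rownames(got) <- NULL
  expect_equal(got$name, orig$name)
  expect_equal(got$value_reference, orig$value_reference)
  expect_equal(got$causality, orig$causality)
  expect_equal(got$unit, orig$unit)
  expect_equal(got$start, orig$start)
  expect_equal(fmu$cfg, validate_config(m$cfg))
})

test_that("a reloaded FMU steps identically to a fresh follower", {
  path <- tempfile(fileext = ".fmu")
  package_fmu(default_config(), path)
  sl1 <- load_fmu(path)$slave
  sl2 <- cosim_slave(build_norwood_lpm(default_config()))
  q <- c(20, 3, 3, 3, 6, 5, 5)
  qn <- paste0("Q_", boundary_set()$name)
  for (b in 1:7) { set_input(sl1, qn[b], q[b]); set_input(sl2, qn[b], q[b]) }
  do_step(sl1, 0, 1e-3); do_step(sl2, 0, 1e-3)
  expect_identical(sl1$state, sl2$state)
})

test_that("structural findings: missing description, duplicate references", {
  # archive without a model description
  bad1 <- tempfile(fileext = ".fmu")
  cardiocosim:::zip_write(list("resources/x.txt" = charToRaw("x")), bad1)
  rep <- check_fmu(bad1)
  expect_false(rep$pass)
  expect_match(rep$findings, "missing model description", all = FALSE)

  # duplicate value reference 3, input without start, bogus causality
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<fmiModelDescription fmiVersion="2.0" modelName="bad" guid="{0}">\n',
    '<CoSimulation modelIdentifier="bad"/>\n',
    '<ModelVariables>\n',
    '<ScalarVariable name="u" valueReference="3" causality="input"><Real/></ScalarVariable>\n',
    '<ScalarVariable name="v" valueReference="3" causality="output"><Real/></ScalarVariable>\n',
    '<ScalarVariable name="w" valueReference="4" causality="sideways"><Real start="1"/></ScalarVariable>\n',
    '</ModelVariables>\n',
    '</fmiModelDescription>\n')
  bad2 <- tempfile(fileext = ".fmu")
  cardiocosim:::zip_write(list("modelDescription.xml" = charToRaw(xml)), bad2)
  rep <- check_fmu(bad2)
  expect_false(rep$pass)
  expect_match(rep$findings, "duplicate value reference 3", all = FALSE)
  expect_match(rep$findings, "unknown causality 'sideways'", all = FALSE)
  expect_match(rep$findings, "input 'u' has no start", all = FALSE)

  expect_error(check_fmu(tempfile()), "I/O error")
})
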