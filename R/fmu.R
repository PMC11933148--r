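## FMU archive packaging (FMI 2.0 co-simulation, source-based) and a
## structural compliance checker.
##
## Archives are plain ZIP files written by a small built-in writer (deflate
## streams via memCompress, CRC32 in compiled code); reading goes through
## utils::unzip.

int_le <- function(x, nbytes) {
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

deflate_raw <- function(data) {
  z <- memCompress(data, type = "gzip")   # zlib stream: 2-byte hdr, 4-byte adler
  z[seq.int(3, length(z) - 4)]
}

## entries: named list of raw vectors (names are archive paths)
zip_write <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dos_time <- int_le(0, 2)
  dos_date <- int_le(bitwOr(bitwShiftL(46L, 9L), bitwOr(bitwShiftL(1L, 5L), 1L)), 2)
  offsets <- integer(length(entries))
  sizes <- vector("list", length(entries))
  off <- 0
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    comp <- deflate_raw(data)
    crc <- .crc32_cpp(data)
    hdr <- c(charToRaw("PK\x03\x04"), int_le(20, 2), int_le(0, 2), int_le(8, 2),
             dos_time, dos_date, int_le(crc, 4), int_le(length(comp), 4),
             int_le(length(data), 4), int_le(length(nm), 2), int_le(0, 2))
    writeBin(c(hdr, nm, comp), con)
    offsets[i] <- off
    sizes[[i]] <- list(crc = crc, csize = length(comp), usize = length(data))
    off <- off + length(hdr) + length(nm) + length(comp)
  }
  cd <- raw(0)
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    s <- sizes[[i]]
    cd <- c(cd, charToRaw("PK\x01\x02"), int_le(20, 2), int_le(20, 2),
            int_le(0, 2), int_le(8, 2), dos_time, dos_date, int_le(s$crc, 4),
            int_le(s$csize, 4), int_le(s$usize, 4), int_le(length(nm), 2),
            int_le(0, 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
            int_le(0, 4), int_le(offsets[i], 4), nm)
  }
  writeBin(cd, con)
  writeBin(c(charToRaw("PK\x05\x06"), int_le(0, 2), int_le(0, 2),
             int_le(length(entries), 2), int_le(length(entries), 2),
             int_le(length(cd), 4), int_le(off, 4), int_le(0, 2)), con)
  invisible(path)
}

model_description_xml <- function(vars, model_name, guid, stop_time) {
  doc <- xml2::xml_new_root("fmiModelDescription",
                            fmiVersion = "2.0", modelName = model_name,
                            guid = guid, generationTool = "cardiocosim",
                            numberOfEventIndicators = "0")
  xml2::xml_add_child(doc, "CoSimulation",
                      modelIdentifier = model_name,
                      canHandleVariableCommunicationStepSize = "true")
  xml2::xml_add_child(doc, "DefaultExperiment", startTime = "0",
                      stopTime = format(stop_time, digits = 17),
                      tolerance = "1e-6")
  mv <- xml2::xml_add_child(doc, "ModelVariables")
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    sv <- xml2::xml_add_child(mv, "ScalarVariable",
                              name = v$name,
                              valueReference = as.character(v$value_reference),
                              causality = v$causality,
                              variability = if (v$causality == "parameter")
                                "fixed" else "continuous")
    attrs <- list()
    if (!is.na(v$unit)) attrs$unit <- v$unit
    if (!is.na(v$start)) attrs$start <- format(v$start, digits = 17)
    do.call(xml2::xml_add_child, c(list(sv, "Real"), attrs))
  }
  ms <- xml2::xml_add_child(doc, "ModelStructure")
  outs <- which(vars$causality == "output")
  if (length(outs)) {
    on <- xml2::xml_add_child(ms, "Outputs")
    for (i in outs)
      xml2::xml_add_child(on, "Unknown", index = as.character(i))
  }
  as.character(doc)
}

#' Package a follower as an FMU archive
#'
#' Writes a ZIP archive with `modelDescription.xml` at its root declaring FMI
#' version 2.0 and co-simulation capability, the full variable registry
#' (names, value references, causalities, units, start values), and the model
#' configuration under `resources/` (source-based packaging: the follower's
#' equations and solver are executed by this framework when the archive is
#' loaded back).
#'
#' @param slave A `cosim_slave`, `circulation_model`, or configuration list.
#' @param path Output path (conventionally `.fmu`).
#' @param model_name FMI model identifier.
#' @return `path`, invisibly.
#' @export
package_fmu <- function(slave, path, model_name = "norwood_lpm") {
  m <- if (inherits(slave, "cosim_slave")) slave$model
       else if (inherits(slave, "circulation_model")) slave
       else build_norwood_lpm(slave)
  vars <- variable_registry(m)
  dup <- unique(vars$value_reference[duplicated(vars$value_reference)])
  if (length(dup))
    stop("packaging refused: duplicate value reference(s) ",
         paste(dup, collapse = ", "))
  cfg_yaml <- yaml::as.yaml(m$cfg, precision = 17)
  tf <- tempfile(); writeLines(cfg_yaml, tf)
  guid <- paste0("{", unname(tools::md5sum(tf)), "}")
  unlink(tf)
  stop_time <- m$cfg$coupling$n_cycles * m$cfg$heart$T
  entries <- list(
    "modelDescription.xml" =
      charToRaw(model_description_xml(vars, model_name, guid, stop_time)),
    "resources/config.yaml" = charToRaw(cfg_yaml),
    "resources/IMPLEMENTATION.txt" = charToRaw(paste0(
      "Source-based FMU: the follower model (closed-loop univentricular\n",
      "circulation) and its subdivided RK4 solver are defined by\n",
      "resources/config.yaml and executed by the cardiocosim framework.\n"))
  )
  zip_write(entries, path)
  invisible(path)
}

#' Structural FMI compliance check of an FMU archive
#'
#' Re-implementation of the structural checks an FMI compliance checker
#' performs on an archive: presence and well-formedness of
#' `modelDescription.xml`, declared FMI version, a CoSimulation element,
#' unique value references, start values on inputs and parameters, and known
#' causalities.  An empty findings list is a pass.
#'
#' @param path Path to an FMU archive.
#' @return An object of class `fmu_report` with elements `findings`
#'   (character) and `pass` (logical).
#' @export
check_fmu <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read archive ", path)
  findings <- character()
  listing <- tryCatch(unzip(path, list = TRUE),
                      error = function(e) NULL, warning = function(w) NULL)
  if (is.null(listing) || !nrow(listing))
    stop("I/O error: not a readable ZIP archive: ", path)
  if (!"modelDescription.xml" %in% listing$Name) {
    findings <- c(findings, "missing model description (modelDescription.xml not at archive root)")
  } else {
    exdir <- tempfile("fmu_check_")
    unzip(path, files = "modelDescription.xml", exdir = exdir)
    doc <- tryCatch(xml2::read_xml(file.path(exdir, "modelDescription.xml")),
                    error = function(e) NULL)
    if (is.null(doc)) {
      findings <- c(findings, "malformed XML in modelDescription.xml")
    } else {
      ver <- xml2::xml_attr(doc, "fmiVersion")
      if (is.na(ver) || ver != "2.0")
        findings <- c(findings, sprintf("fmiVersion is '%s', expected '2.0'", ver))
      if (is.na(xml2::xml_attr(doc, "guid")))
        findings <- c(findings, "missing guid attribute")
      if (length(xml2::xml_find_all(doc, "./CoSimulation")) == 0)
        findings <- c(findings, "missing CoSimulation element")
      sv <- xml2::xml_find_all(doc, "./ModelVariables/ScalarVariable")
      if (length(sv)) {
        vr <- xml2::xml_attr(sv, "valueReference")
        caus <- xml2::xml_attr(sv, "causality")
        nm <- xml2::xml_attr(sv, "name")
        dup <- unique(vr[duplicated(vr)])
        for (d in dup)
          findings <- c(findings, sprintf("duplicate value reference %s", d))
        bad <- !caus %in% c("input", "output", "parameter",
                            "calculatedParameter", "local", "independent")
        for (i in which(bad))
          findings <- c(findings,
                        sprintf("unknown causality '%s' on variable '%s'",
                                caus[i], nm[i]))
        needs_start <- caus %in% c("input", "parameter")
        start <- vapply(sv, function(x)
          xml2::xml_attr(xml2::xml_find_first(x, "./*"), "start"), "")
        for (i in which(needs_start & is.na(start)))
          findings <- c(findings,
                        sprintf("%s '%s' has no start value", caus[i], nm[i]))
      } else {
        findings <- c(findings, "no ScalarVariable declarations found")
      }
    }
  }
  structure(list(path = path, findings = findings,
                 pass = length(findings) == 0L),
            class = "fmu_report")
}

#' @export
print.fmu_report <- function(x, ...) {
  cat("FMU structural compliance report:", x$path, "\n")
  if (x$pass) cat("  PASS (no findings)\n")
  else for (f in x$findings) cat("  FINDING:", f, "\n")
  invisible(x)
}

#' Load an FMU archive back into a slave
#'
#' Extracts the archive, parses the declared variable registry from
#' `modelDescription.xml`, reconstructs the follower from
#' `resources/config.yaml` and returns a ready-to-step slave.
#'
#' @param path Path to an FMU archive produced by [package_fmu()].
#' @return A list of class `fmu` with elements `variables`, `cfg`, `slave`,
#'   `guid`, `model_name`.
#' @export
load_fmu <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read archive ", path)
  exdir <- tempfile("fmu_")
  unzip(path, exdir = exdir)
  md <- file.path(exdir, "modelDescription.xml")
  if (!file.exists(md)) stop("missing model description in archive")
  doc <- xml2::read_xml(md)
  sv <- xml2::xml_find_all(doc, "./ModelVariables/ScalarVariable")
  vars <- data.frame(
    name = xml2::xml_attr(sv, "name"),
    value_reference = as.integer(xml2::xml_attr(sv, "valueReference")),
    causality = xml2::xml_attr(sv, "causality"),
    unit = vapply(sv, function(x)
      xml2::xml_attr(xml2::xml_find_first(x, "./*"), "unit"), ""),
    start = as.numeric(vapply(sv, function(x)
      xml2::xml_attr(xml2::xml_find_first(x, "./*"), "start"), "")),
    stringsAsFactors = FALSE
  )
  cfg <- yaml::read_yaml(file.path(exdir, "resources", "config.yaml"))
  slave <- cosim_slave(build_norwood_lpm(cfg))
  structure(list(variables = vars, cfg = validate_config(cfg), slave = slave,
                 guid = xml2::xml_attr(doc, "guid"),
                 model_name = xml2::xml_attr(doc, "modelName")),
            class = "fmu")
}
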