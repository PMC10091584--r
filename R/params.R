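# Parameter-file interface: a declared registry of parameters (each with a
# pattern, a default, a documentation string and a verbosity class), readable
# and writable in two semantically equivalent dialects: the human-readable
# `prm` (section/keyword text) format and `json`.

# verbosity classes: "minimal" parameters appear at every verbosity,
# "standard" from standard up, "full" only in full listings.
param_registry <- function() {
  p <- function(section, name, pattern, default, doc, verbosity = "minimal")
    list(section = section, name = name, pattern = pattern, default = default,
         doc = doc, verbosity = verbosity)
  angles <- function(section) list(
    p(section, "alpha endo", "double", "-60",
      "Helical angle on the endocardium [deg]"),
    p(section, "alpha epi", "double", "60",
      "Helical angle on the epicardium [deg]"),
    p(section, "beta endo", "double", "0",
      "Sheetlet angle on the endocardium [deg]"),
    p(section, "beta epi", "double", "0",
      "Sheetlet angle on the epicardium [deg]"))
  c(list(
    p("Mesh and space discretization", "Geometry type",
      "selection:Slab|Left ventricle|Left ventricle complete|Left atrium",
      "Slab", "Kind of geometry in input; algorithm parameters are parsed from the subsection named after this value"),
    p("Mesh and space discretization", "Element type", "selection:Tet|Hex",
      "Tet", "Volumetric element type of the input mesh"),
    p("Mesh and space discretization", "FE space degree", "integer:1|10", "1",
      "Degree of the continuous FE space used for the Laplace-Dirichlet problems",
      "standard"),
    p("Mesh and space discretization", "Scaling factor", "double_positive", "1",
      "Coordinate scaling applied on mesh read (1e-3 converts millimeters to meters)"),
    p("Mesh and space discretization", "Filename", "string", "",
      "Path of the input mesh file (*.msh)")),
    list(
    p("Slab", "Sphere slab", "bool", "false",
      "true for the spherical slab, false for the ventricular slab"),
    p("Slab", "Sphere with radial fibers", "bool", "false",
      "Exchange the fiber and sheet directions on the spherical slab"),
    p("Slab", "Tags endo", "int_list", "1", "Boundary labels of the endocardium"),
    p("Slab", "Tags epi", "int_list", "2", "Boundary labels of the epicardium"),
    p("Slab", "Tags base up", "int_list", "3",
      "Boundary labels of the top surface (ventricular slab)"),
    p("Slab", "Tags base down", "int_list", "4",
      "Boundary labels of the bottom surface (ventricular slab)"),
    p("Slab", "North pole", "vec3", "0, 0, 1",
      "Epicardial north pole coordinates (spherical slab) [m]"),
    p("Slab", "South pole", "vec3", "0, 0, -1",
      "Epicardial south pole coordinates (spherical slab) [m]")),
    angles("Slab"),
    list(
    p("Left ventricle", "Algorithm type", "selection:BT|RL", "BT",
      "Apico-basal direction: BT (Laplace problem) or RL (constant basal normal)"),
    p("Left ventricle", "Tags endo", "int_list", "1", "Boundary labels of the endocardium"),
    p("Left ventricle", "Tags epi", "int_list", "2", "Boundary labels of the epicardium"),
    p("Left ventricle", "Tags base", "int_list", "3", "Boundary labels of the basal plane"),
    p("Left ventricle", "Normal to base", "vec3", "0, 0, 1",
      "Outward normal to the basal plane (RL algorithm)"),
    p("Left ventricle", "Apex", "vec3", "0, 0, 0",
      "Epicardial apex coordinates (BT algorithm) [m]")),
    angles("Left ventricle"),
    list(
    p("Left ventricle complete", "Tags endo", "int_list", "1",
      "Boundary labels of the endocardium"),
    p("Left ventricle complete", "Tags epi", "int_list", "2",
      "Boundary labels of the epicardium"),
    p("Left ventricle complete", "Tags MV", "int_list", "3",
      "Boundary labels of the mitral valve ring"),
    p("Left ventricle complete", "Tags AV", "int_list", "4",
      "Boundary labels of the aortic valve ring"),
    p("Left ventricle complete", "Apex", "vec3", "0, 0, 0",
      "Epicardial apex coordinates [m]")),
    angles("Left ventricle complete"),
    list(
    p("Left ventricle complete", "alpha endo OT", "double", "-60",
      "Helical angle on the endocardium in the outflow-tract region [deg]"),
    p("Left ventricle complete", "alpha epi OT", "double", "60",
      "Helical angle on the epicardium in the outflow-tract region [deg]"),
    p("Left ventricle complete", "beta endo OT", "double", "0",
      "Sheetlet angle on the endocardium in the outflow-tract region [deg]"),
    p("Left ventricle complete", "beta epi OT", "double", "0",
      "Sheetlet angle on the epicardium in the outflow-tract region [deg]"),
    p("Left atrium", "Appendage", "bool", "false",
      "true for a realistic atrium with appendage apex, false for the idealized atrium"),
    p("Left atrium", "Tags endo", "int_list", "1", "Boundary labels of the endocardium"),
    p("Left atrium", "Tags epi", "int_list", "2", "Boundary labels of the epicardium"),
    p("Left atrium", "Tags MV", "int_list", "3",
      "Boundary labels of the mitral valve ring"),
    p("Left atrium", "Tags LPV", "int_list", "4",
      "Boundary labels of the left pulmonary vein rings"),
    p("Left atrium", "Tags RPV", "int_list", "5",
      "Boundary labels of the right pulmonary vein rings"),
    p("Left atrium", "Apex", "vec3", "0, 0, 0",
      "Epicardial coordinates of the appendage apex (Appendage = true) [m]"),
    p("Left atrium", "Tau bundle MV", "double_unit", "0.15",
      "Dimension of the mitral valve ring bundle, in [0, 1]"),
    p("Left atrium", "Tau bundle LPV", "double_unit", "0.15",
      "Dimension of the left pulmonary vein bundle, in [0, 1]"),
    p("Left atrium", "Tau bundle RPV", "double_unit", "0.15",
      "Dimension of the right pulmonary vein bundle, in [0, 1]"),
    p("Output", "Enable output", "bool", "true",
      "Write the generated fields to disk"),
    p("Output", "Filename", "string", "fibers",
      "Basename of the output file (a .vtu extension is appended)"),
    p("Linear solver", "Tolerance", "double_positive", "1e-10",
      "Relative residual tolerance of the conjugate-gradient solver", "full"),
    p("Linear solver", "Max iterations", "integer:1|1000000", "10000",
      "Maximum number of conjugate-gradient iterations", "full")))
}

pattern_description <- function(pattern) {
  if (startsWith(pattern, "selection:"))
    return(sprintf("one of: %s",
                   gsub("\\|", ", ", sub("^selection:", "", pattern))))
  if (startsWith(pattern, "integer:")) {
    rng <- strsplit(sub("^integer:", "", pattern), "\\|")[[1]]
    return(sprintf("an integer in [%s, %s]", rng[1], rng[2]))
  }
  switch(pattern,
         double = "a floating-point number",
         double_positive = "a positive floating-point number",
         double_unit = "a floating-point number in [0, 1]",
         bool = "a boolean (true or false)",
         int_list = "a comma-separated list of integers",
         vec3 = "three comma-separated floating-point numbers",
         string = "any string")
}

check_pattern <- function(value, pattern, where) {
  bad <- function() stop(sprintf(
    "invalid value '%s' for parameter '%s': expected %s",
    value, where, pattern_description(pattern)), call. = FALSE)
  v <- trimws(value)
  if (startsWith(pattern, "selection:")) {
    if (!v %in% strsplit(sub("^selection:", "", pattern), "\\|")[[1]]) bad()
  } else if (startsWith(pattern, "integer:")) {
    rng <- as.numeric(strsplit(sub("^integer:", "", pattern), "\\|")[[1]])
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n) || n != round(n) || n < rng[1] || n > rng[2]) bad()
  } else if (pattern == "double") {
    if (is.na(suppressWarnings(as.numeric(v)))) bad()
  } else if (pattern == "double_positive") {
    n <- suppressWarnings(as.numeric(v)); if (is.na(n) || n <= 0) bad()
  } else if (pattern == "double_unit") {
    n <- suppressWarnings(as.numeric(v)); if (is.na(n) || n < 0 || n > 1) bad()
  } else if (pattern == "bool") {
    if (!v %in% c("true", "false")) bad()
  } else if (pattern == "int_list") {
    parts <- strsplit(v, ",")[[1]]
    n <- suppressWarnings(as.numeric(trimws(parts)))
    if (length(n) == 0 || anyNA(n) || any(n != round(n))) bad()
  } else if (pattern == "vec3") {
    n <- suppressWarnings(as.numeric(trimws(strsplit(v, ",")[[1]])))
    if (length(n) != 3 || anyNA(n)) bad()
  }
  invisible(TRUE)
}

registry_sections <- function(reg = param_registry()) {
  secs <- unique(vapply(reg, `[[`, character(1), "section"))
  secs
}

#' Default parameter set
#'
#' The complete set of declared parameters at their hard-coded defaults, as a
#' nested named list `section -> parameter -> value` (all values as strings,
#' the representation shared by the `prm` and `json` dialects).
#'
#' @return an object of class `ldrbm_params`.
#' @export
default_params <- function() {
  reg <- param_registry()
  out <- list()
  for (e in reg) out[[e$section]][[e$name]] <- e$default
  structure(out, class = "ldrbm_params")
}

params_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("prm", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext == "xml")
    stop("xml parameter files are not supported; use prm or json", call. = FALSE)
  if (!ext %in% c("prm", "json"))
    stop(sprintf("unknown parameter file extension '.%s' (use .prm or .json)", ext),
         call. = FALSE)
  ext
}

#' Generate a parameter file with all default values
#'
#' Writes every declared parameter at its default value, with its pattern
#' description and documentation string as comments (`prm` dialect) so the
#' file is self-documenting. `minimal` verbosity omits the numerical solver
#' parameters and the FE degree; `full` includes everything.
#'
#' @param path output path; the extension selects the format unless `format`
#'   is given.
#' @param verbosity `"minimal"`, `"standard"` or `"full"`.
#' @param format `"prm"`, `"json"`, or `NULL` to infer from the extension.
#' @return the path, invisibly.
#' @export
generate_params <- function(path, verbosity = "standard", format = NULL) {
  verbosity <- match.arg(verbosity, c("minimal", "standard", "full"))
  fmt <- params_format(path, format)
  reg <- param_registry()
  keep <- switch(verbosity,
                 minimal = "minimal",
                 standard = c("minimal", "standard"),
                 full = c("minimal", "standard", "full"))
  reg <- reg[vapply(reg, function(e) e$verbosity %in% keep, logical(1))]
  prm <- list()
  for (e in reg) prm[[e$section]][[e$name]] <- e$default
  prm <- structure(prm, class = "ldrbm_params")
  write_params(prm, path, format = fmt, registry = reg)
  invisible(path)
}

#' Write a parameter set
#'
#' @param params an `ldrbm_params` nested list.
#' @param path output path.
#' @param format `"prm"`, `"json"`, or `NULL` to infer from the extension.
#' @param registry internal: registry subset used for documentation comments.
#' @return the path, invisibly.
#' @export
write_params <- function(params, path, format = NULL, registry = NULL) {
  fmt <- params_format(path, format)
  if (fmt == "json") {
    jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(path))
  }
  reg_all <- param_registry()
  doc_of <- function(sec, nm) {
    for (e in reg_all) if (e$section == sec && e$name == nm) return(e)
    NULL
  }
  lines <- character(0)
  for (sec in names(params)) {
    lines <- c(lines, sprintf("subsection %s", sec))
    for (nm in names(params[[sec]])) {
      e <- doc_of(sec, nm)
      if (!is.null(e))
        lines <- c(lines,
                   sprintf("  # %s", e$doc),
                   sprintf("  # Pattern: %s", pattern_description(e$pattern)))
      lines <- c(lines, sprintf("  set %s = %s", nm, params[[sec]][[nm]]), "")
    }
    lines <- c(lines, "end", "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a parameter file
#'
#' Parses a `prm` or `json` parameter file, rejects unknown subsections,
#' unknown parameter names and out-of-pattern values with located messages,
#' and merges the result over the defaults: every parameter missing from the
#' file takes its hard-coded default value.
#'
#' @param path input path.
#' @param format `"prm"`, `"json"`, or `NULL` to infer from the extension.
#' @return an `ldrbm_params` object with the effective (merged) values.
#' @export
read_params <- function(path, format = NULL) {
  if (!file.exists(path))
    stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  fmt <- params_format(path, format)
  raw <- if (fmt == "prm") parse_prm(path) else parse_params_json(path)
  reg <- param_registry()
  known <- new.env()
  for (e in reg) assign(paste0(e$section, "\r", e$name), e, envir = known)
  merged <- default_params()
  for (sec in names(raw)) {
    if (!sec %in% registry_sections(reg))
      stop(sprintf("unknown subsection '%s' in parameter file %s", sec, path),
           call. = FALSE)
    for (nm in names(raw[[sec]])) {
      key <- paste0(sec, "\r", nm)
      if (!exists(key, envir = known, inherits = FALSE))
        stop(sprintf("unknown parameter '%s' in subsection '%s' of %s",
                     nm, sec, path), call. = FALSE)
      e <- get(key, envir = known)
      val <- as.character(raw[[sec]][[nm]])
      check_pattern(val, e$pattern, sprintf("%s / %s", sec, nm))
      merged[[sec]][[nm]] <- trimws(val)
    }
  }
  merged
}

parse_prm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  stack <- character(0)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^subsection\\s+", ln)) {
      stack <- c(stack, trimws(sub("^subsection\\s+", "", ln)))
    } else if (ln == "end") {
      if (!length(stack))
        stop(sprintf("%s:%d: 'end' without matching 'subsection'", path, i),
             call. = FALSE)
      stack <- stack[-length(stack)]
    } else if (grepl("^set\\s+", ln)) {
      if (length(stack) != 1L)
        stop(sprintf("%s:%d: 'set' outside a (single-level) subsection", path, i),
             call. = FALSE)
      body <- sub("^set\\s+", "", ln)
      eq <- regexpr("=", body, fixed = TRUE)
      if (eq < 0)
        stop(sprintf("%s:%d: malformed 'set' line (missing '=')", path, i),
             call. = FALSE)
      nm <- trimws(substr(body, 1, eq - 1))
      val <- trimws(substr(body, eq + 1, nchar(body)))
      out[[stack[1]]][[nm]] <- val
    } else {
      stop(sprintf("%s:%d: unrecognized line: %s", path, i, ln), call. = FALSE)
    }
  }
  if (length(stack))
    stop(sprintf("%s: unterminated subsection '%s'", path, stack[length(stack)]),
         call. = FALSE)
  out
}

parse_params_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(x, function(sec) lapply(sec, as.character))
}

parse_int_list <- function(v) as.integer(trimws(strsplit(v, ",")[[1]]))
parse_vec3 <- function(v) as.numeric(trimws(strsplit(v, ",")[[1]]))
parse_bool <- function(v) identical(trimws(v), "true")

#' Build a typed run configuration from a parameter set
#'
#' Converts the string-valued parameter set into an [ldrbm_config()], reading
#' the geometry-specific parameters from the subsection named after the
#' `Geometry type` value.
#'
#' @param params an `ldrbm_params` from [read_params()] or [default_params()].
#' @return an [ldrbm_config()].
#' @export
params_to_config <- function(params) {
  mesh_sec <- params[["Mesh and space discretization"]]
  gt <- mesh_sec[["Geometry type"]]
  g <- params[[gt]]
  if (is.null(g))
    stop(sprintf("missing subsection '%s' for Geometry type = %s", gt, gt),
         call. = FALSE)
  num <- function(nm, default = NULL) {
    if (is.null(g[[nm]])) return(default)
    as.numeric(g[[nm]])
  }
  tags <- list()
  tag_map <- c("Tags endo" = "endo", "Tags epi" = "epi", "Tags base" = "base",
               "Tags base up" = "base_up", "Tags base down" = "base_down",
               "Tags MV" = "mv", "Tags AV" = "av", "Tags LPV" = "lpv",
               "Tags RPV" = "rpv")
  for (nm in names(tag_map))
    if (!is.null(g[[nm]])) tags[[tag_map[[nm]]]] <- parse_int_list(g[[nm]])

  solver <- params[["Linear solver"]]
  appendage <- if (!is.null(g[["Appendage"]])) parse_bool(g[["Appendage"]]) else FALSE
  apex <- if (!is.null(g[["Apex"]])) parse_vec3(g[["Apex"]])
  if (gt == "Left atrium" && !appendage) apex <- NULL

  ldrbm_config(
    geometry_type = gt,
    tags = tags,
    alpha_endo = num("alpha endo", -60), alpha_epi = num("alpha epi", 60),
    beta_endo = num("beta endo", 0), beta_epi = num("beta epi", 0),
    alpha_endo_ot = num("alpha endo OT", num("alpha endo", -60)),
    alpha_epi_ot = num("alpha epi OT", num("alpha epi", 60)),
    beta_endo_ot = num("beta endo OT", num("beta endo", 0)),
    beta_epi_ot = num("beta epi OT", num("beta epi", 0)),
    algorithm_type = if (!is.null(g[["Algorithm type"]])) g[["Algorithm type"]] else "BT",
    normal_to_base = if (!is.null(g[["Normal to base"]]))
      parse_vec3(g[["Normal to base"]]) else c(0, 0, 1),
    apex = apex,
    sphere_slab = if (!is.null(g[["Sphere slab"]])) parse_bool(g[["Sphere slab"]]) else FALSE,
    sphere_radial_fibers = if (!is.null(g[["Sphere with radial fibers"]]))
      parse_bool(g[["Sphere with radial fibers"]]) else FALSE,
    north_pole = if (!is.null(g[["North pole"]])) parse_vec3(g[["North pole"]]),
    south_pole = if (!is.null(g[["South pole"]])) parse_vec3(g[["South pole"]]),
    appendage = appendage,
    taus = c(mv = num("Tau bundle MV", 0.15),
             lpv = num("Tau bundle LPV", 0.15),
             rpv = num("Tau bundle RPV", 0.15)),
    fe_degree = as.integer(mesh_sec[["FE space degree"]]),
    scaling_factor = as.numeric(mesh_sec[["Scaling factor"]]),
    mesh_filename = mesh_sec[["Filename"]],
    enable_output = parse_bool(params[["Output"]][["Enable output"]]),
    output_filename = params[["Output"]][["Filename"]],
    rtol = as.numeric(solver[["Tolerance"]]),
    maxit = as.integer(solver[["Max iterations"]]))
}
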