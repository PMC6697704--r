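# SBML Level 3 import/export (Level 2 accepted on import).  Covers the
# constructs the pathway model uses: compartments, species with initial
# amounts and boundary conditions, global parameters, and reactions with
# kinetic laws whose MathML is restricted to arithmetic operators
# (plus, minus, times, divide, power) over identifiers and numbers.
# Species roles and parameter free-flags ride in the SBML `name`
# attribute so the structural round trip is exact; local parameters are
# promoted to global ones on import.

.SBML_NS3 <- "http://www.sbml.org/sbml/level3/version2/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# ---- R expression <-> MathML ---------------------------------------------

.expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    v <- as.numeric(e)
    if (v == round(v) && abs(v) < 1e15)
      return(paste0("<cn type=\"integer\">", format(v, scientific = FALSE),
                    "</cn>"))
    return(paste0("<cn>", format(v, digits = 17), "</cn>"))
  }
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.expr_to_mathml(e[[2]]))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  stop("unsupported operator in rate law: ", op))
    args <- lapply(as.list(e)[-1], .expr_to_mathml)
    return(paste0("<apply><", tag, "/>",
                  paste0(unlist(args), collapse = ""), "</apply>"))
  }
  stop("unsupported rate-law element: ", deparse(e))
}

.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("malformed MathML: expected one child")
    return(.mathml_to_expr(kids[[1]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    fun <- switch(op, plus = "+", minus = "-", times = "*",
                  divide = "/", power = "^",
                  stop("unsupported MathML operator: ", op))
    args <- lapply(kids[-1], .mathml_to_expr)
    if (length(args) == 1 && fun == "-")
      return(call("-", args[[1]]))
    out <- args[[1]]
    for (a in args[-1]) out <- call(fun, out, a)
    return(out)
  }
  stop("unsupported MathML node: ", nm)
}

# ---- export --------------------------------------------------------------

#' Export a pathway model to an SBML Level 3 file
#'
#' @param model a `pathway_model`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  comps <- unique(model$species$compartment)
  buf <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", .SBML_NS3,
           "\" level=\"3\" version=\"2\">"),
    "<model id=\"hgfmet\" name=\"HGF-Met signaling model\">",
    "<listOfCompartments>",
    paste0("<compartment id=\"", comps,
           "\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/>"),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    buf <- c(buf, paste0(
      "<species id=\"", s$name, "\" name=\"", esc(s$role),
      "\" compartment=\"", s$compartment,
      "\" initialAmount=\"", format(s$initial, digits = 17),
      "\" hasOnlySubstanceUnits=\"true\" boundaryCondition=\"",
      tolower(as.character(s$clamped)), "\" constant=\"false\"/>"))
  }
  buf <- c(buf, "</listOfSpecies>", "<listOfParameters>")
  for (i in seq_len(nrow(model$parameters))) {
    p <- model$parameters[i, ]
    buf <- c(buf, paste0(
      "<parameter id=\"", p$name, "\" name=\"",
      if (p$free) "free" else "fixed",
      "\" value=\"", format(p$value, digits = 17),
      "\" constant=\"true\"/>"))
  }
  buf <- c(buf, "</listOfParameters>", "<listOfReactions>")
  for (r in model$reactions) {
    buf <- c(buf, paste0("<reaction id=\"", r$id,
                         "\" reversible=\"false\">"))
    if (length(r$reactants)) {
      buf <- c(buf, "<listOfReactants>",
               paste0("<speciesReference species=\"", names(r$reactants),
                      "\" stoichiometry=\"", unname(r$reactants),
                      "\" constant=\"true\"/>"),
               "</listOfReactants>")
    }
    if (length(r$products)) {
      buf <- c(buf, "<listOfProducts>",
               paste0("<speciesReference species=\"", names(r$products),
                      "\" stoichiometry=\"", unname(r$products),
                      "\" constant=\"true\"/>"),
               "</listOfProducts>")
    }
    if (length(r$modifiers)) {
      buf <- c(buf, "<listOfModifiers>",
               paste0("<modifierSpeciesReference species=\"",
                      r$modifiers, "\"/>"),
               "</listOfModifiers>")
    }
    buf <- c(buf,
             "<kineticLaw>",
             paste0("<math xmlns=\"", .MATHML_NS, "\">"),
             .expr_to_mathml(str2lang(r$rate)),
             "</math>", "</kineticLaw>", "</reaction>")
  }
  buf <- c(buf, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(buf, path)
  # parse back to guarantee the document is well-formed XML
  xml2::read_xml(path)
  invisible(path)
}

# ---- import --------------------------------------------------------------

#' Import a pathway model from SBML
#'
#' Accepts SBML Level 2 or 3 documents restricted to the constructs
#' described in the module header.  Local (reaction-scoped) parameters are
#' promoted to global parameters named `<reaction>__<parameter>` so the
#' calibration machinery can address every parameter uniformly.  When the
#' imported structure matches the native reference layout, the native
#' conservation groups, readouts, and fast derivative path apply;
#' otherwise each species doubles as its own readout and the generic
#' rate-law evaluator is used.
#'
#' @param path SBML file path.
#' @return a `pathway_model`.
#' @export
import_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML: ",
                                           conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  level <- xml2::xml_attr(doc, "level")
  if (!level %in% c("2", "3"))
    stop("unsupported SBML level: ", level %||% "missing")

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes)) stop("no species found in SBML document")
  roles <- c("ligand", "receptor", "integrin", "complex",
             "signaling_inactive", "signaling_active", "drug")
  att <- function(nodes, a, default = NA_character_) {
    v <- xml2::xml_attr(nodes, a)
    ifelse(is.na(v), default, v)
  }
  init <- att(sp_nodes, "initialAmount", "0")
  species <- data.frame(
    name = xml2::xml_attr(sp_nodes, "id"),
    compartment = att(sp_nodes, "compartment", "cytosolic"),
    role = ifelse(att(sp_nodes, "name") %in% roles,
                  att(sp_nodes, "name"), "complex"),
    initial = as.numeric(init),
    clamped = att(sp_nodes, "boundaryCondition", "false") == "true",
    stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(doc, ".//s:model/s:listOfParameters/s:parameter",
                                  ns)
  params <- data.frame(
    name = xml2::xml_attr(par_nodes, "id"),
    value = as.numeric(att(par_nodes, "value", "0")),
    free = att(par_nodes, "name") == "free",
    stringsAsFactors = FALSE)
  params$free[is.na(params$free)] <- FALSE

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- list()
  for (rn in rx_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    getrefs <- function(xp) {
      refs <- xml2::xml_find_all(rn, xp, ns)
      if (!length(refs)) return(c())
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      setNames(st, xml2::xml_attr(refs, "species"))
    }
    reac <- getrefs("./s:listOfReactants/s:speciesReference")
    prod <- getrefs("./s:listOfProducts/s:speciesReference")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(rn, "./s:listOfModifiers/s:modifierSpeciesReference",
                         ns), "species")
    math <- xml2::xml_find_first(rn, "./s:kineticLaw//m:math",
                                 c(ns, m = .MATHML_NS))
    if (is.na(xml2::xml_name(math)))
      stop("reaction '", rid, "' has no kinetic law math")
    expr <- tryCatch(.mathml_to_expr(math),
                     error = function(e)
                       stop("reaction '", rid, "': ", conditionMessage(e)))
    # promote local parameters to globals with reaction-scoped names
    loc <- xml2::xml_find_all(
      rn, "./s:kineticLaw//s:localParameter | ./s:kineticLaw//s:parameter",
      ns)
    if (length(loc)) {
      lid <- xml2::xml_attr(loc, "id")
      gnames <- paste0(rid, "__", lid)
      sub_env <- setNames(lapply(gnames, as.name), lid)
      expr <- eval(call("substitute", expr, sub_env))
      params <- rbind(params, data.frame(
        name = gnames, value = as.numeric(xml2::xml_attr(loc, "value")),
        free = FALSE, stringsAsFactors = FALSE))
    }
    reactions[[length(reactions) + 1L]] <-
      list(id = rid, reactants = reac, products = prod,
           rate = paste(deparse(expr), collapse = " "),
           modifiers = if (length(mods)) mods else character())
  }

  params$lower <- params$value / 100
  params$upper <- params$value * 100
  native <- identical(species$name, names(.SPI)) &&
    setequal(params$name, .parameter_table()$name)
  model <- structure(list(
    species = species, parameters = params, reactions = reactions,
    groups = if (native) .conservation_groups() else list(),
    readouts = if (native) .readout_defs() else
      setNames(as.list(species$name), species$name),
    met_pools = if (native) .met_pools() else NULL,
    scalable = if (native) .scalable_proteins() else list(),
    cache = new.env(parent = emptyenv())
  ), class = "pathway_model")
  validate_model(model)
  model
}
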