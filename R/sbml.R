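# SBML Level 3 exchange. The document carries real SBML structure
# (compartments, species, parameters, reactions with MathML kinetic laws,
# and the inhibition events), plus a package annotation holding the
# declarative model encoding, which import uses to reconstruct the
# ModelSpec exactly (round-trip contract).

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.CM_NS <- "https://chondromir.r-lib.org/modelspec"

.xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# --- tiny MathML builders ---------------------------------------------------
.mml_ci <- function(x) paste0("<ci> ", x, " </ci>")
.mml_cn <- function(v) paste0("<cn> ", format(v, digits = 17), " </cn>")
.mml_apply <- function(op, ...) paste0("<apply><", op, "/>",
                                       paste0(c(...), collapse = ""),
                                       "</apply>")

# denominator 1 + sum(ci * Ti) for divisive inhibition
.mml_denom <- function(inh_species, inh_params) {
  terms <- mapply(function(s, p) .mml_apply("times", .mml_ci(p), .mml_ci(s)),
                  inh_species, inh_params)
  .mml_apply("plus", .mml_cn(1), paste0(terms, collapse = ""))
}

.rate_mathml <- function(r, sid, sscale_id) {
  switch(r$type,
    source = .mml_apply("times", .mml_ci(r$k),
                        .mml_ci(sscale_id[[r$target]])),
    sink = .mml_apply("times", .mml_ci(r$k), .mml_ci(sid[[r$target]])),
    activation = .mml_apply("times", .mml_ci(r$k),
                            .mml_ci(sid[[r$activator]])),
    sat_activation = .mml_apply(
      "divide",
      .mml_apply("times", .mml_ci(r$k), .mml_ci(sid[[r$activator]])),
      .mml_apply("plus", .mml_ci(r$km), .mml_ci(sid[[r$activator]]))),
    mirna_decay = .mml_apply("times", .mml_ci(r$k), .mml_ci(sid[[r$mirna]]),
                             .mml_ci(sid[[r$target]])),
    inhibited_conversion = .mml_apply(
      "divide",
      .mml_apply("times", .mml_ci(r$k), .mml_ci(sid[[r$reactant]])),
      .mml_denom(sid[names(r$inhibitors)], unname(r$inhibitors))),
    inhibited_source = .mml_apply(
      "divide",
      .mml_apply("times", .mml_ci(r$k), .mml_ci(sscale_id[[r$target]])),
      .mml_denom(sid[names(r$inhibitors)], unname(r$inhibitors))),
    stop("unknown rate law: ", r$type))
}

.rx_species_refs <- function(r, sid) {
  reac <- prod <- mods <- character(0)
  switch(r$type,
    source = { prod <- r$target },
    sink = { reac <- r$target },
    activation = { prod <- r$target; mods <- r$activator },
    sat_activation = { prod <- r$target; mods <- r$activator },
    mirna_decay = { reac <- r$target; mods <- r$mirna },
    inhibited_conversion = { reac <- r$reactant; prod <- r$product
                             mods <- names(r$inhibitors) },
    inhibited_source = { prod <- r$target; mods <- names(r$inhibitors) })
  fmt <- function(tag, ss) if (!length(ss)) "" else paste0(
    "<listOf", tag, "s>",
    paste0("<", tolower(substr(tag, 1, 1)), substr(tag, 2, nchar(tag)),
           " species=\"", sid[ss], "\"",
           if (tag != "Modifier") " stoichiometry=\"1\" constant=\"true\"",
           "/>", collapse = ""),
    "</listOf", tag, "s>")
  paste0(fmt("Reactant", reac), fmt("Product", prod), fmt("Modifier", mods))
}

#' Export a kinetic model as SBML Level 3
#'
#' Writes compartments, species, global parameters, reactions with MathML
#' kinetic laws, and the timed inhibition events (instantaneous knockdown
#' assignment plus a synthesis-scale parameter toggled at t_on / t_off).
#' A package annotation embeds the declarative model encoding so that
#' [import_sbml()] reconstructs the model exactly.
#'
#' @param model A `kinetic_model`.
#' @param path Optional file path; when given the document is written there.
#' @return An `xml2` document (invisibly when `path` is given).
#' @export
export_sbml <- function(model, path = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  validate_model(model)
  sp <- model$species
  sid <- stats::setNames(.pkey(sp$name), sp$name)
  if (anyDuplicated(sid)) stop("species names collide after id sanitization")
  sscale_id <- stats::setNames(paste0("sscale_", sid), sp$name)
  comps <- unique(sp$compartment)

  species_xml <- paste0(
    "<species id=\"", sid, "\" name=\"", .xesc(sp$name), "\"",
    " compartment=\"", .pkey(sp$compartment), "\"",
    " initialAmount=\"", format(unname(model$initial[sp$name]), digits = 17),
    "\" hasOnlySubstanceUnits=\"true\" boundaryCondition=\"false\"",
    " constant=\"false\"/>", collapse = "")
  par_xml <- paste0(
    paste0("<parameter id=\"", names(model$params), "\" value=\"",
           format(unname(model$params), digits = 17),
           "\" constant=\"true\"/>", collapse = ""),
    paste0("<parameter id=\"", sscale_id, "\" value=\"1\"",
           " constant=\"false\"/>", collapse = ""))
  rx_xml <- paste0(vapply(model$reactions, function(r) paste0(
    "<reaction id=\"", .pkey(r$name), "\" reversible=\"false\">",
    .rx_species_refs(r, sid),
    "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    .rate_mathml(r, sid, sscale_id), "</math></kineticLaw></reaction>"), ""),
    collapse = "")

  ev_xml <- ""
  if (length(model$events)) {
    time_ge <- function(t) paste0(
      "<math xmlns=\"http://www.w3.org/1998/Math/MathML\"><apply><geq/>",
      "<csymbol encoding=\"text\" definitionURL=",
      "\"http://www.sbml.org/sbml/symbols/time\"> t </csymbol>",
      .mml_cn(t), "</apply></math>")
    asg <- function(var, math) paste0(
      "<eventAssignment variable=\"", var, "\">",
      "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">", math,
      "</math></eventAssignment>")
    ev_xml <- paste0(vapply(seq_along(model$events), function(i) {
      e <- model$events[[i]]
      mir <- sid[[e$mirna]]
      drug <- .drug_for(e$mirna)
      dr <- if (drug %in% sp$name) sid[[drug]] else NULL
      on <- paste0(
        "<event id=\"ev_on_", i, "\" useValuesFromTriggerTime=\"true\">",
        "<trigger initialValue=\"true\" persistent=\"true\">",
        time_ge(e$t_on), "</trigger><listOfEventAssignments>",
        asg(mir, .mml_apply("times", .mml_cn(1 - e$eps), .mml_ci(mir))),
        asg(paste0("sscale_", mir), .mml_cn(1 - e$eps)),
        if (!is.null(dr)) asg(dr, .mml_cn(1)) else "",
        "</listOfEventAssignments></event>")
      off <- paste0(
        "<event id=\"ev_off_", i, "\" useValuesFromTriggerTime=\"true\">",
        "<trigger initialValue=\"true\" persistent=\"true\">",
        time_ge(e$t_off), "</trigger><listOfEventAssignments>",
        asg(paste0("sscale_", mir), .mml_cn(1)),
        if (!is.null(dr)) asg(dr, .mml_cn(0)) else "",
        "</listOfEventAssignments></event>")
      paste0(on, off)
    }, ""), collapse = "")
    ev_xml <- paste0("<listOfEvents>", ev_xml, "</listOfEvents>")
  }

  # named atomic vectors lose their names in JSON arrays; keep them as objects
  reactions_enc <- lapply(model$reactions, function(r) {
    if (!is.null(r$inhibitors)) r$inhibitors <- as.list(r$inhibitors)
    r
  })
  enc <- jsonlite::toJSON(
    list(variant = model$variant,
         species = sp,
         reactions = reactions_enc,
         params = as.list(model$params),
         initial = as.list(model$initial),
         events = model$events,
         horizon = model$horizon),
    auto_unbox = TRUE, digits = NA)
  doc_str <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<sbml xmlns=\"", .SBML_NS, "\" level=\"3\" version=\"2\">",
    "<model id=\"chondromir_", model$variant, "\" name=\"miR-199a/b-5p ",
    "chondrogenesis model (", model$variant, " variant)\">",
    "<annotation><chondromir:modelSpec xmlns:chondromir=\"", .CM_NS, "\">",
    .xesc(as.character(enc)),
    "</chondromir:modelSpec></annotation>",
    "<listOfCompartments>",
    paste0("<compartment id=\"", .pkey(comps), "\" name=\"", .xesc(comps),
           "\" size=\"1\" constant=\"true\"/>", collapse = ""),
    "</listOfCompartments>",
    "<listOfSpecies>", species_xml, "</listOfSpecies>",
    "<listOfParameters>", par_xml, "</listOfParameters>",
    "<listOfReactions>", rx_xml, "</listOfReactions>",
    ev_xml,
    "</model></sbml>")
  doc <- xml2::read_xml(doc_str)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Import a kinetic model from SBML written by [export_sbml()]
#'
#' Reads the package annotation embedded in the document, reconstructs the
#' declarative model, and cross-checks it against the SBML species list
#' (ids, counts and initial amounts). Documents lacking the annotation --
#' e.g. models from other tools -- are rejected with an explanatory error,
#' since their arbitrary MathML rate laws are outside the supported subset.
#'
#' @param x An `xml2` document or a file path.
#' @return A validated `kinetic_model`.
#' @export
import_sbml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  ns <- c(s = .SBML_NS, cm = .CM_NS)
  node <- xml2::xml_find_first(doc, ".//cm:modelSpec", ns)
  if (inherits(node, "xml_missing"))
    stop("document lacks the chondromir modelSpec annotation; ",
         "only SBML written by export_sbml() can be reconstructed")
  raw <- jsonlite::fromJSON(xml2::xml_text(node), simplifyVector = FALSE)
  enc <- jsonlite::fromJSON(xml2::xml_text(node), simplifyVector = TRUE,
                            simplifyDataFrame = TRUE,
                            simplifyMatrix = FALSE)
  flatten1 <- function(r) lapply(r, function(f)
    if (is.list(f)) unlist(f) else f)
  reactions <- lapply(raw$reactions, flatten1)
  events <- lapply(raw$events, flatten1)
  model <- structure(
    list(variant = enc$variant,
         species = as.data.frame(enc$species, stringsAsFactors = FALSE),
         reactions = reactions,
         params = unlist(enc$params),
         initial = unlist(enc$initial),
         events = events,
         horizon = enc$horizon),
    class = "kinetic_model")
  validate_model(model)

  # structural cross-check against the SBML proper
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) != nrow(model$species))
    stop("schema violation: annotation and listOfSpecies species counts ",
         "differ (", nrow(model$species), " vs ", length(sp_nodes), ")")
  sbml_init <- as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  ids <- xml2::xml_attr(sp_nodes, "id")
  want <- .pkey(model$species$name)
  if (!setequal(ids, want))
    stop("schema violation: species ids differ: ",
         paste(symdiff <- c(setdiff(ids, want), setdiff(want, ids)),
               collapse = ", "))
  if (max(abs(sbml_init[match(want, ids)] -
                unname(model$initial[model$species$name]))) > 1e-12)
    stop("schema violation: initial amounts disagree with annotation")
  model
}
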