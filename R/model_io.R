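## Model input/output.
##
## Two formats:
##  * "tabular": a directory with four TSV files -- reactions.tsv
##    (reaction_id, lower_bound, upper_bound, gpr, subsystem),
##    metabolites.tsv (metabolite_id), stoichiometry.tsv (metabolite_id,
##    reaction_id, coefficient; one row per nonzero entry) and objectives.tsv
##    (role in {biomass, maintenance}, reaction_id).
##  * "sbml": SBML Level 3 Version 1 with the fbc extension (bounds as
##    parameters, GPRs as geneProductAssociation); legacy COBRA-style notes
##    (GENE_ASSOCIATION, SUBSYSTEM) are also understood on reading.

DEFAULT_BOUND <- 1000  # COBRA convention when a bound is absent

readTsvStrict <- function(path) {
  if (!file.exists(path)) stop("missing model file: ", path, call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a metabolic model
#'
#' @param path for \code{format = "tabular"}, a directory containing the
#'   four-file TSV bundle; for \code{"sbml"}, an SBML file.
#' @param format \code{"auto"} (directory -> tabular, file -> sbml),
#'   \code{"tabular"} or \code{"sbml"}.
#' @return a validated \linkS4class{MetabolicModel}. Reactions without a
#'   subsystem get the label \code{"unassigned"}; a missing GPR becomes the
#'   empty rule; missing bounds default to (-1000, 1000) for reversible and
#'   (0, 1000) for irreversible reactions.
#' @seealso \code{\link{writeMetabolicModel}}
#' @export
readMetabolicModel <- function(path, format = c("auto", "tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "tabular" else "sbml"
  switch(format,
         tabular = readModelTabular(path),
         sbml = readModelSBML(path))
}

readModelTabular <- function(dir) {
  rx <- readTsvStrict(file.path(dir, "reactions.tsv"))
  mets <- readTsvStrict(file.path(dir, "metabolites.tsv"))
  st <- readTsvStrict(file.path(dir, "stoichiometry.tsv"))
  objs <- readTsvStrict(file.path(dir, "objectives.tsv"))

  need <- function(df, cols, f) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
      stop(sprintf("model file %s lacks column(s): %s", f,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(rx, "reaction_id", "reactions.tsv")
  need(mets, "metabolite_id", "metabolites.tsv")
  need(st, c("metabolite_id", "reaction_id", "coefficient"),
       "stoichiometry.tsv")
  need(objs, c("role", "reaction_id"), "objectives.tsv")

  if (anyDuplicated(rx$reaction_id))
    stop("duplicate reaction id in reactions.tsv: ",
         rx$reaction_id[duplicated(rx$reaction_id)][1], call. = FALSE)

  rid <- as.character(rx$reaction_id)
  mid <- as.character(mets$metabolite_id)
  lb <- if ("lower_bound" %in% colnames(rx)) as.numeric(rx$lower_bound)
        else rep(NA_real_, length(rid))
  ub <- if ("upper_bound" %in% colnames(rx)) as.numeric(rx$upper_bound)
        else rep(NA_real_, length(rid))
  lb[is.na(lb)] <- -DEFAULT_BOUND
  ub[is.na(ub)] <- DEFAULT_BOUND
  gpr <- if ("gpr" %in% colnames(rx)) as.character(rx$gpr) else NULL
  sub <- if ("subsystem" %in% colnames(rx)) as.character(rx$subsystem) else NULL

  S <- matrix(0, length(mid), length(rid), dimnames = list(mid, rid))
  im <- match(st$metabolite_id, mid)
  ir <- match(st$reaction_id, rid)
  if (anyNA(im))
    stop("stoichiometry.tsv references unknown metabolite: ",
         st$metabolite_id[which(is.na(im))[1]], call. = FALSE)
  if (anyNA(ir))
    stop("stoichiometry.tsv references unknown reaction: ",
         st$reaction_id[which(is.na(ir))[1]], call. = FALSE)
  S[cbind(im, ir)] <- as.numeric(st$coefficient)

  pick <- function(role) {
    hit <- objs$reaction_id[objs$role == role]
    if (length(hit) != 1L)
      stop("objectives.tsv must designate exactly one '", role,
           "' reaction", call. = FALSE)
    idx <- match(hit, rid)
    if (is.na(idx))
      stop("objective reaction '", hit, "' not in reactions.tsv",
           call. = FALSE)
    idx
  }
  MetabolicModel(rid, mid, S, lb, ub, gpr = gpr, subsystem = sub,
                 biomassIndex = pick("biomass"),
                 maintenanceIndex = pick("maintenance"))
}

#' Write a metabolic model as a tabular bundle
#'
#' Writes the four-file TSV bundle read by \code{\link{readMetabolicModel}}.
#' Reading the written bundle reproduces the model field by field.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeMetabolicModel <- function(model, dir) {
  stopifnot(is(model, "MetabolicModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(data.frame(reaction_id = model@reactionIds,
                lower_bound = model@lowerBounds,
                upper_bound = model@upperBounds,
                gpr = model@gpr,
                subsystem = model@subsystem), "reactions.tsv")
  wt(data.frame(metabolite_id = model@metaboliteIds), "metabolites.tsv")
  nz <- which(model@S != 0, arr.ind = TRUE)
  wt(data.frame(metabolite_id = model@metaboliteIds[nz[, 1]],
                reaction_id = model@reactionIds[nz[, 2]],
                coefficient = model@S[nz]), "stoichiometry.tsv")
  wt(data.frame(role = c("biomass", "maintenance"),
                reaction_id = model@reactionIds[c(model@biomassIndex,
                                                  model@maintenanceIndex)]),
     "objectives.tsv")
  invisible(dir)
}

## ---- SBML ----

xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, sub("^.*:", "", name))
  v
}

notesField <- function(node, key) {
  notes <- xml2::xml_find_first(node, ".//notes")
  if (inherits(notes, "xml_missing")) return(NA_character_)
  txt <- xml2::xml_text(xml2::xml_find_all(notes, ".//p"))
  if (!length(txt)) txt <- xml2::xml_text(notes)
  hit <- grep(paste0("^\\s*", key, "\\s*:"), txt, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(paste0("^\\s*", key, "\\s*:"), "", hit[1]))
}

fbcAssociation <- function(node) {
  ## serialise an fbc:geneProductAssociation subtree back into a rule string
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(xattr(node, "fbc:geneProduct"))
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbcAssociation, character(1))
  parts <- parts[nzchar(parts)]
  if (nm == "and") return(paste0("(", paste(parts, collapse = " AND "), ")"))
  if (nm == "or") return(paste0("(", paste(parts, collapse = " OR "), ")"))
  if (length(parts)) parts[1] else ""
}

readModelSBML <- function(path) {
  if (!file.exists(path)) stop("missing SBML file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  xml2::xml_ns_strip(doc)
  modelNode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(modelNode, "xml_missing"))
    stop("SBML parse failure: no <model> element in ", path, call. = FALSE)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- setNames(as.numeric(vapply(params, xattr, "", "value")),
                   vapply(params, xattr, "", "id"))

  spp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mid <- vapply(spp, xattr, "", "id")
  boundary <- vapply(spp, xattr, "", "boundaryCondition") %in% "true"
  mid <- mid[!boundary]

  rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxNodes))
    stop("SBML parse failure: model has no reactions", call. = FALSE)
  nr <- length(rxNodes)
  rid <- vapply(rxNodes, xattr, "", "id")
  if (anyDuplicated(rid))
    stop("duplicate reaction id in SBML: ", rid[duplicated(rid)][1],
         call. = FALSE)

  S <- matrix(0, length(mid), nr, dimnames = list(mid, rid))
  lb <- ub <- rep(NA_real_, nr)
  gpr <- character(nr)
  sub <- rep(NA_character_, nr)

  for (k in seq_len(nr)) {
    rn <- rxNodes[[k]]
    rev <- !identical(xattr(rn, "reversible"), "false")
    for (side in c(-1, 1)) {
      lof <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rn, sprintf("./%s/speciesRef | ./%s/speciesReference",
                                             lof, lof))
      for (sr in refs) {
        sp <- xattr(sr, "species")
        if (!sp %in% mid) next   # boundary species are outside the balance
        coef <- xattr(sr, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        S[sp, k] <- S[sp, k] + side * coef
      }
    }
    lbid <- xattr(rn, "fbc:lowerFluxBound")
    ubid <- xattr(rn, "fbc:upperFluxBound")
    if (!is.na(lbid) && lbid %in% names(pval)) lb[k] <- pval[[lbid]]
    if (!is.na(ubid) && ubid %in% names(pval)) ub[k] <- pval[[ubid]]
    if (is.na(lb[k])) lb[k] <- if (rev) -DEFAULT_BOUND else 0
    if (is.na(ub[k])) ub[k] <- DEFAULT_BOUND

    gpa <- xml2::xml_find_first(rn, "./geneProductAssociation")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      gpr[k] <- if (length(kids)) fbcAssociation(kids[[1]]) else ""
    } else {
      ga <- notesField(rn, "GENE_ASSOCIATION")
      gpr[k] <- if (is.na(ga)) "" else gsub("\\band\\b", "AND",
                                            gsub("\\bor\\b", "OR", ga))
    }
    sub[k] <- notesField(rn, "SUBSYSTEM")
  }

  objRefs <- xml2::xml_find_all(doc, ".//listOfObjectives//fluxObjective")
  roles <- vapply(objRefs, xattr, "", "fbc:name")
  orx <- vapply(objRefs, xattr, "", "fbc:reaction")
  getObj <- function(role, fallback) {
    hit <- orx[roles %in% role]
    if (length(hit) == 1L && hit %in% rid) return(match(hit, rid))
    hit <- grep(fallback, rid, ignore.case = TRUE)
    if (length(hit) >= 1L) return(hit[1])
    stop("cannot identify the ", role, " objective reaction in the SBML file",
         call. = FALSE)
  }
  MetabolicModel(rid, mid, S, lb, ub, gpr = gpr, subsystem = sub,
                 biomassIndex = getObj("biomass", "biomass"),
                 maintenanceIndex = getObj("maintenance", "atp|maintenance"))
}

#' Write a metabolic model as SBML (L3V1 + fbc)
#'
#' Minimal writer producing an SBML document that
#' \code{\link{readMetabolicModel}} parses back to the same model: fbc bound
#' parameters, fbc gene-product associations, subsystem and objective roles.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModelSBML <- function(model, path) {
  stopifnot(is(model, "MetabolicModel"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('<model id="model" fbc:strict="true">')
  bounds <- sort(unique(c(model@lowerBounds, model@upperBounds)))
  w("<listOfParameters>")
  for (i in seq_along(bounds))
    w(sprintf('<parameter id="b%d" value="%s" constant="true"/>', i,
              format(bounds[i], digits = 17)))
  w("</listOfParameters>")
  w("<listOfSpecies>")
  for (m in model@metaboliteIds)
    w(sprintf('<species id="%s" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
              esc(m)))
  w("</listOfSpecies>")
  w("<listOfReactions>")
  gprXml <- function(ast) {
    if (ast$op == "gene")
      return(sprintf('<geneProductRef fbc:geneProduct="%s"/>', esc(ast$gene)))
    ## namespace is stripped on read; plain and/or tags keep the writer simple
    tag <- ast$op
    paste0("<", tag, ">", paste(vapply(ast$args, gprXml, character(1)),
                                collapse = ""), "</", tag, ">")
  }
  for (k in seq_along(model@reactionIds)) {
    lbk <- sprintf("b%d", match(model@lowerBounds[k], bounds))
    ubk <- sprintf("b%d", match(model@upperBounds[k], bounds))
    w(sprintf('<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
              esc(model@reactionIds[k]),
              if (model@lowerBounds[k] < 0) "true" else "false", lbk, ubk))
    w(sprintf('<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: %s</p></body></notes>',
              esc(model@subsystem[k])))
    if (nzchar(model@gpr[k]))
      w(paste0("<geneProductAssociation>", gprXml(parseGPR(model@gpr[k])),
               "</geneProductAssociation>"))
    sc <- model@S[, k]
    for (side in c(-1, 1)) {
      sel <- which(sign(sc) == side)
      if (!length(sel)) next
      lof <- if (side < 0) "listOfReactants" else "listOfProducts"
      w("<", lof, ">")
      for (i in sel)
        w(sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  esc(model@metaboliteIds[i]), format(abs(sc[i]), digits = 17)))
      w("</", lof, ">")
    }
    w("</reaction>")
  }
  w("</listOfReactions>")
  w('<fbc:listOfObjectives fbc:activeObjective="obj1">')
  w('<fbc:objective fbc:id="obj1" fbc:type="maximize">')
  w("<fbc:listOfFluxObjectives>")
  w(sprintf('<fbc:fluxObjective fbc:name="biomass" fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(model@reactionIds[model@biomassIndex])))
  w(sprintf('<fbc:fluxObjective fbc:name="maintenance" fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(model@reactionIds[model@maintenanceIndex])))
  w("</fbc:listOfFluxObjectives>")
  w("</fbc:objective>")
  w("</fbc:listOfObjectives>")
  w("</model>")
  w("</sbml>")
  invisible(path)
}
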