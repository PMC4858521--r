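## The shipped architecture-template library: declarative role-multiplicity
## models of the ten most abundant archaeal T4P variants plus the archaellum.
## Templates are data (serializable to YAML), not code.

#' Built-in architecture templates
#'
#' Returns the v1 library of eleven [ArchitectureTemplate-class] models: the
#' complex clade-1 pilus of methanococci/thermococci (two TadC platforms, at
#' least five locus-encoded minor pilins, the 9-TM prepilin peptidase EppA,
#' majors frequently encoded in trans), the seven-component archaellum
#' (FlaI/FlaH/FlaJ/FlaF/FlaG, 1-9 archaellins, 1-3 FlaC/D/E), the two
#' euryarchaeal clade-2 variants (the PilA-based system with the shared
#' arCOG02911-like signature minor pilin, and the variant with its own pilin
#' set), their crenarchaeal-hybrid relatives 4C and 4F, the simple
#' three-component Sulfolobales/Desulfurococcales system, the Thermoproteales
#' systems 4B, 4E (membrane + cytoplasmic accessory pair) and the highly
#' complex 4G, and the two-component 4D system that never carries pilins or
#' secreted proteins.
#'
#' S-layer-like proteins are optional throughout: the census excludes
#' `s_layer` families from the final set (keeping them as potential
#' components), so no template requires one.
#'
#' @return Named list of `ArchitectureTemplate`.
#' @export
builtinTemplates <- function() {
  tpl <- list(
    ArchitectureTemplate("clade1",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(2L, 2L),
                      minor_pilin = c(5L, 9L), major_pilin = c(1L, 9L),
                      peptidase_9TM = c(1L, 1L)),
      optional = c("adhesin", "fleN_minD", "membrane_accessory",
                   "cytoplasmic_accessory", "s_layer", "regulator",
                   "peptidase_5TM")),
    ArchitectureTemplate("archaellum",
      required = list(secretion_ATPase = c(1L, 1L), flaH = c(1L, 1L),
                      tadC = c(1L, 1L), flaF = c(1L, 1L), flaG = c(1L, 1L),
                      archaellin = c(1L, 9L), flaCDE = c(1L, 3L)),
      optional = c("regulator", "peptidase_5TM", "s_layer")),
    ArchitectureTemplate("clade2_pilA",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(2L, 2L),
                      major_pilin = c(1L, 6L), minor_pilin = c(1L, 1L)),
      optional = c("s_layer", "fleN_minD", "regulator", "peptidase_5TM")),
    ArchitectureTemplate("clade2_B",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(1L, 1L),
                      major_pilin = c(1L, 2L), minor_pilin = c(2L, 6L)),
      optional = c("s_layer", "fleN_minD")),
    ArchitectureTemplate("sub4C",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(1L, 1L),
                      major_pilin = c(1L, 2L), minor_pilin = c(1L, 1L),
                      adhesin = c(1L, 1L)),
      optional = c("s_layer")),
    ArchitectureTemplate("sub4F",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(1L, 1L),
                      major_pilin = c(1L, 3L),
                      cytoplasmic_accessory = c(1L, 1L)),
      optional = c("s_layer", "regulator")),
    ArchitectureTemplate("sulfolobales_simple",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(1L, 2L),
                      major_pilin = c(1L, 3L)),
      forbidden = "archaellin",
      optional = c("s_layer", "membrane_accessory")),
    ArchitectureTemplate("sub4B",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(2L, 2L),
                      major_pilin = c(2L, 2L), adhesin = c(1L, 1L)),
      optional = c("s_layer", "regulator")),
    ArchitectureTemplate("sub4E",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(1L, 1L),
                      major_pilin = c(1L, 2L), minor_pilin = c(1L, 3L),
                      membrane_accessory = c(1L, 1L),
                      cytoplasmic_accessory = c(1L, 1L)),
      optional = character(0)),
    ArchitectureTemplate("sub4G",
      required = list(secretion_ATPase = c(1L, 1L), tadC = c(1L, 1L),
                      major_pilin = c(1L, 2L), minor_pilin = c(2L, 6L),
                      adhesin = c(1L, 1L), fleN_minD = c(1L, 1L),
                      cytoplasmic_accessory = c(2L, 2L)),
      optional = c("s_layer", "membrane_accessory", "regulator")),
    ArchitectureTemplate("sub4D",
      required = list(secretion_ATPase = c(1L, 1L),
                      membrane_accessory = c(1L, 1L)),
      forbidden = c("major_pilin", "minor_pilin", "archaellin", "adhesin"),
      optional = "regulator")
  )
  names(tpl) <- vapply(tpl, function(t) t@name, "")
  tpl
}

#' Read / write architecture templates as YAML
#'
#' The config schema is a top-level mapping of template name to a mapping with
#' keys `required` (role: `[min, max]` or a single integer), `forbidden` and
#' `optional` (role lists).
#'
#' @param path YAML file path.
#' @return `readTemplates`: named list of [ArchitectureTemplate-class].
#' @export
readTemplates <- function(path) {
  raw <- yaml::read_yaml(path)
  tpl <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    ArchitectureTemplate(nm,
      required = lapply(x$required, function(r) as.integer(rep_len(unlist(r), 2L))),
      forbidden = as.character(unlist(x$forbidden)),
      optional = as.character(unlist(x$optional)))
  })
  names(tpl) <- names(raw)
  tpl
}

#' @rdname readTemplates
#' @param templates Named list of `ArchitectureTemplate`.
#' @return `writeTemplates`: `path`, invisibly.
#' @export
writeTemplates <- function(templates, path) {
  out <- lapply(templates, function(t) list(
    required = lapply(t@required, as.integer),
    forbidden = as.list(t@forbidden),
    optional = as.list(t@optional)))
  names(out) <- vapply(templates, function(t) t@name, "")
  yaml::write_yaml(out, path)
  invisible(path)
}
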