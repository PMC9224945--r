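#' @include AllClasses.R
NULL

CORE_METADATA_SLOTS <- c(
  Title = "title", Type = "type", Abstract = "abstract",
  ProjectCentre = "projectCentre", Description = "description",
  SampleTaxonId = "sampleTaxonId", SampleTitle = "sampleTitle")

#' Construct a metadata record
#'
#' @param title,type,abstract,projectCentre,description,sampleTaxonId,sampleTitle
#'   core field values (single strings; default empty).
#' @param extensions named character vector of extension attributes.
#' @return a \code{\link{MetadataRecord}}.
#' @examples
#' md <- MetadataRecord(title = "WGS study", sampleTaxonId = "9606")
#' metadataFields(md)
#' @export
MetadataRecord <- function(title = "", type = "", abstract = "",
                           projectCentre = "", description = "",
                           sampleTaxonId = "", sampleTitle = "",
                           extensions = setNames(character(0), character(0))) {
  new("MetadataRecord", title = title, type = type, abstract = abstract,
      projectCentre = projectCentre, description = description,
      sampleTaxonId = sampleTaxonId, sampleTitle = sampleTitle,
      extensions = extensions)
}

#' Core fields of a metadata record
#'
#' @param md a \code{\link{MetadataRecord}}.
#' @return named list of the seven core fields, using the standard element
#'   names (Title, Type, Abstract, ProjectCentre, Description, SampleTaxonId,
#'   SampleTitle).
#' @export
metadataFields <- function(md) {
  setNames(lapply(CORE_METADATA_SLOTS, function(s) slot(md, s)),
           names(CORE_METADATA_SLOTS))
}

#' Extension attributes of a metadata record
#'
#' @param md a \code{\link{MetadataRecord}}.
#' @return named character vector of extensions, in insertion order.
#' @export
metadataExtensions <- function(md) md@extensions

getField <- function(fields, name) {
  v <- fields[[name]]
  if (is.null(v) || is.na(v)) "" else as.character(v)
}

#' Map EGA study/assembly metadata onto a record
#'
#' EGA uses a structure close to the container's metadata model, so the
#' mapping is a direct field-for-field copy: Title from Study-STUDY_TITLE,
#' Type from Study-STUDY_TYPE, Abstract from Study-STUDY_ABSTRACT,
#' ProjectCentre from Study-CENTER_PROJECT_NAME, Description from
#' Study-STUDY_DESCRIPTION, Sample-TaxonId from Assembly-TAXON_ID and
#' Sample-Title from Assembly-TITLE.  Missing source fields yield empty
#' targets.
#'
#' @param fields named list or character vector of EGA fields.
#' @return a \code{\link{MetadataRecord}}.
#' @export
mapFromEga <- function(fields = list()) {
  MetadataRecord(
    title         = getField(fields, "Study-STUDY_TITLE"),
    type          = getField(fields, "Study-STUDY_TYPE"),
    abstract      = getField(fields, "Study-STUDY_ABSTRACT"),
    projectCentre = getField(fields, "Study-CENTER_PROJECT_NAME"),
    description   = getField(fields, "Study-STUDY_DESCRIPTION"),
    sampleTaxonId = getField(fields, "Assembly-TAXON_ID"),
    sampleTitle   = getField(fields, "Assembly-TITLE"))
}

#' Map NCBI BioProject/BioSample metadata onto a record
#'
#' Title from BioProject-Title, Type from BioProject-ProjectTypeSubmission
#' (copied verbatim; the two type vocabularies are not identical and no
#' translation is attempted), ProjectCentre from BioProject-Organization,
#' Description from BioProject-Description, Sample-TaxonId from
#' BioSample-TAXON_ID and Sample-Title from BioSample-TITLE.  NCBI metadata
#' has no Abstract, so the Abstract field is always left empty.
#'
#' @param fields named list or character vector of NCBI fields.
#' @return a \code{\link{MetadataRecord}}.
#' @export
mapFromNcbi <- function(fields = list()) {
  MetadataRecord(
    title         = getField(fields, "BioProject-Title"),
    type          = getField(fields, "BioProject-ProjectTypeSubmission"),
    abstract      = "",
    projectCentre = getField(fields, "BioProject-Organization"),
    description   = getField(fields, "BioProject-Description"),
    sampleTaxonId = getField(fields, "BioSample-TAXON_ID"),
    sampleTitle   = getField(fields, "BioSample-TITLE"))
}

#' NCBI BioSample attributes carried as extension fields
#'
#' StudyDesign (BioSample attribute "study design"), BodySite ("body site"),
#' AnalyteType ("analyte type") and IsTumor ("is tumor").
#' @export
NCBI_EXTENSION_FIELDS <- c(
  StudyDesign = "BioSample-Attribute-study design",
  BodySite    = "BioSample-Attribute-body site",
  AnalyteType = "BioSample-Attribute-analyte type",
  IsTumor     = "BioSample-Attribute-is tumor")

#' Add an extension attribute to a metadata record
#'
#' Extensions carry additional information the core fields cannot, e.g. the
#' NCBI BioSample attributes in \code{\link{NCBI_EXTENSION_FIELDS}}.
#' Re-adding an existing name replaces its value (last write wins) while
#' keeping the original position.
#'
#' @param md a \code{\link{MetadataRecord}}.
#' @param name nonempty extension name.
#' @param value extension value (single string).
#' @return the updated record.
#' @export
addExtension <- function(md, name, value) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ext <- md@extensions
  ext[name] <- as.character(value)
  initialize(md, extensions = ext)
}

#' Serialize a metadata record to XML
#'
#' The schema is a flat \code{<Metadata>} root with one child element per
#' core field (in the fixed order of \code{\link{metadataFields}}) followed
#' by \code{<Extension name="...">} elements, so serialization is
#' deterministic and diff-friendly.
#'
#' @param md a \code{\link{MetadataRecord}}.
#' @return raw vector of UTF-8 XML bytes.
#' @export
metadataToXml <- function(md) {
  doc <- xml2::xml_new_root("Metadata")
  flds <- metadataFields(md)
  for (nm in names(flds))
    xml2::xml_add_child(doc, nm, flds[[nm]])
  for (nm in names(md@extensions)) {
    node <- xml2::xml_add_child(doc, "Extension", md@extensions[[nm]])
    xml2::xml_set_attr(node, "name", nm)
  }
  charToRaw(as.character(doc))
}

#' Parse a metadata record from XML
#'
#' Inverse of \code{\link{metadataToXml}}.  Unknown child elements are folded
#' into extensions (keyed by element name) rather than rejected, honoring the
#' extension mechanism of the metadata model.
#'
#' @param xml raw vector or string of XML.
#' @return a \code{\link{MetadataRecord}}.
#' @export
metadataFromXml <- function(xml) {
  if (is.raw(xml)) xml <- rawToChar(xml)
  doc <- xml2::read_xml(xml)
  if (xml2::xml_name(doc) != "Metadata")
    stop("metadata XML root must be <Metadata>")
  md <- MetadataRecord()
  ext <- setNames(character(0), character(0))
  for (node in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(node)
    val <- xml2::xml_text(node)
    if (nm %in% names(CORE_METADATA_SLOTS)) {
      slot(md, CORE_METADATA_SLOTS[[nm]]) <- val
    } else if (nm == "Extension") {
      key <- xml2::xml_attr(node, "name")
      if (is.na(key) || !nzchar(key))
        stop("metadata <Extension> element lacks a name attribute")
      ext[key] <- val
    } else {
      ext[nm] <- val
    }
  }
  initialize(md, extensions = ext)
}
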