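#' @include gradcam.R
NULL

.templateCache <- new.env(parent = emptyenv())

#' Clinical report templates
#'
#' The per-label report texts, loaded from the editable resource file
#' `inst/extdata/report_templates.tsv` (tab-separated, UTF-8, columns
#' `label` and `report`) so deployments can localise the wording.
#'
#' @return named character vector, one template per class.
#' @export
reportTemplates <- function() {
  if (is.null(.templateCache$templates)) {
    path <- system.file("extdata", "report_templates.tsv", package = "cxrnet",
                        mustWork = TRUE)
    tab <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                      quote = "")
    .templateCache$templates <- stats::setNames(tab$report, tab$label)
  }
  .templateCache$templates
}

#' Generate the clinical report text for a label
#'
#' Returns the registered template for the label, verbatim.
#'
#' @param label one of [cxrClasses()].
#' @return character(1) report text.
#' @examples
#' substr(generateReport("Cardiomegaly"), 1, 25)
#' @export
generateReport <- function(label) {
  .checkLabel(label)
  tpl <- reportTemplates()
  unname(tpl[[label]])
}

#' Classify an image and produce a structured report
#'
#' Runs the full inference path on one image file: read, preprocess into
#' the three-channel stack, classify, compute the Grad-CAM heatmap for
#' the predicted class, and attach the label's report template.  Errors
#' are re-raised with the failing stage name and no outputs are written
#' on failure.
#'
#' @param model a trained `CxrModel`.
#' @param imagePath image file.
#' @param outJson optional path for a JSON record with fields `label`,
#'   `probability`, `report_text`, `heatmap_png`, `model_id`,
#'   `timestamp`, `disclaimer`.
#' @param heatmapPath optional path for the heatmap overlay PNG.
#' @param mode preprocessing mode (see [buildChannelStack()]).
#' @return list with `report` (the JSON record as a list), `output` (the
#'   classifier output of [predictStack()]) and `heatmap` (the
#'   [Heatmap-class]).
#' @export
classifyAndReport <- function(model, imagePath, outJson = NULL,
                              heatmapPath = NULL,
                              mode = c("preprocessed", "raw-replicate")) {
  mode <- match.arg(mode)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(name, ": ", conditionMessage(e), call. = FALSE))
  img <- stage("read", readGrayImage(imagePath))
  stack <- stage("preprocess",
                 buildChannelStack(img, size = model$config$inputSize,
                                   mode = mode))
  out <- stage("classify", predictStack(model, stack))
  hm <- stage("explain", gradCam(model, stack, targetClass = out$label))
  reportText <- stage("report", generateReport(out$label))
  if (!is.null(heatmapPath))
    stage("write-heatmap",
          overlayHeatmap(hm, resizeGray(img, model$config$inputSize),
                         path = heatmapPath))
  record <- list(
    label = out$label,
    probability = unname(out$probabilities[out$label]),
    report_text = reportText,
    heatmap_png = if (is.null(heatmapPath)) NA_character_ else heatmapPath,
    model_id = sprintf("%s-%s-%dp", model$config$arch, model$config$scale,
                       countParams(model)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    disclaimer = paste("Automated decision-support output;",
                       "not a substitute for radiologist review."))
  if (!is.null(outJson))
    stage("write-json",
          jsonlite::write_json(record, outJson, auto_unbox = TRUE,
                               pretty = TRUE))
  list(report = record, output = out, heatmap = hm)
}
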