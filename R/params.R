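# Mapping between the external (config-file) parameter names and slots.
.paramKeyMap <- c(
  wsize = "wsize", C = "C", Irange = "Irange",
  MinSolid = "minSolidity", MinSize = "minSize", MaxSize = "maxSize",
  MinInertia = "minInertia",
  recovery_solidity = "recoverySolidity", dice_threshold = "diceThreshold",
  kirsch_edge_threshold = "kirschEdgeThreshold", blur_kernel = "blurKernel",
  mean_type = "meanType"
)

#' Construct a parameter set for the segmentation pipeline
#'
#' The defaults are the published values tuned for 512x512 synthetic
#' challenge images (wsize 55, C 40, Irange 30, MinSolid 0.8, MinSize 20,
#' MaxSize 140, MinInertia 0.4); they generally need retuning per dataset
#' (see [gridSearch()]).
#'
#' @param wsize,C adaptive-threshold window size (odd pixels) and offset
#'   (intensity levels).
#' @param Irange recovery intensity range (levels).
#' @param minSolidity,minSize,maxSize,minInertia contour filter bounds.
#' @param recoverySolidity solidity at which region growth stops (fixed
#'   method constant, default 0.75).
#' @param diceThreshold true-positive Dice gate (fixed method constant,
#'   default 0.6).
#' @param kirschEdgeThreshold gradient cut-off for the edge map; `Inf`
#'   disables edge subtraction.
#' @param blurKernel Gaussian blur kernel size (odd pixels; 1 = no blur).
#' @param meanType `"box"` or `"gaussian"` local mean for thresholding.
#' @return a validated [NucleusParams-class] object.
#' @examples
#' p <- nucleusParams(wsize = 35, C = 50, Irange = 40,
#'                    minSolidity = 0.8, minSize = 5, maxSize = 50,
#'                    minInertia = 0.3)
#' p
#' @export
nucleusParams <- function(wsize = 55, C = 40, Irange = 30,
                          minSolidity = 0.8, minSize = 20, maxSize = 140,
                          minInertia = 0.4, recoverySolidity = 0.75,
                          diceThreshold = 0.6, kirschEdgeThreshold = 255,
                          blurKernel = 5, meanType = c("box", "gaussian")) {
  meanType <- match.arg(meanType)
  # NB: new("NucleusParams", C = ...) would partially match new()'s
  # 'Class' formal, so slots are assigned explicitly.
  p <- new("NucleusParams")
  p@wsize <- as.numeric(wsize); p@C <- as.numeric(C)
  p@Irange <- as.numeric(Irange)
  p@minSolidity <- as.numeric(minSolidity)
  p@minSize <- as.numeric(minSize); p@maxSize <- as.numeric(maxSize)
  p@minInertia <- as.numeric(minInertia)
  p@recoverySolidity <- as.numeric(recoverySolidity)
  p@diceThreshold <- as.numeric(diceThreshold)
  p@kirschEdgeThreshold <- as.numeric(kirschEdgeThreshold)
  p@blurKernel <- as.numeric(blurKernel)
  p@meanType <- meanType
  validObject(p)
  p
}

#' Convert a parameter set to a named list with config-file keys
#'
#' @param x a [NucleusParams-class] object.
#' @param ... ignored.
#' @return a named list using the external key names (`wsize`, `C`,
#'   `Irange`, `MinSolid`, `MinSize`, `MaxSize`, `MinInertia`, plus the
#'   fixed-constant keys).
#' @export
setMethod("as.list", "NucleusParams", function(x, ...) {
  out <- lapply(.paramKeyMap, function(s) slot(x, s))
  names(out) <- names(.paramKeyMap)
  out
})

#' Modify selected fields of a parameter set
#'
#' @param params a [NucleusParams-class] object.
#' @param ... fields to replace, by external config key (e.g. `MinSolid`)
#'   or by slot name (e.g. `minSolidity`).
#' @return a new validated `NucleusParams` object.
#' @examples
#' updateParams(nucleusParams(), C = 48, MinSolid = 0.6)
#' @export
updateParams <- function(params, ...) {
  updates <- list(...)
  if (length(updates) == 1L && is.null(names(updates)) &&
      is.list(updates[[1L]]))
    updates <- updates[[1L]]
  for (key in names(updates)) {
    s <- if (key %in% names(.paramKeyMap)) .paramKeyMap[[key]]
         else if (key %in% slotNames("NucleusParams")) key
         else stop("unknown parameter '", key, "'", call. = FALSE)
    value <- updates[[key]]
    slot(params, s) <- if (s == "meanType") as.character(value)
                       else as.numeric(value)
  }
  validObject(params)
  params
}

#' Read / write a parameter configuration file
#'
#' Configuration files are YAML or JSON maps using the published parameter
#' names (`wsize`, `C`, `Irange`, `MinSolid`, `MinSize`, `MaxSize`,
#' `MinInertia`) plus optional keys `recovery_solidity`, `dice_threshold`,
#' `kirsch_edge_threshold`, `blur_kernel`, `mean_type`. Missing keys keep
#' their defaults.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param params a [NucleusParams-class] object (for writing).
#' @return `readParams` returns a [NucleusParams-class] object;
#'   `writeParams` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeParams(nucleusParams(C = 48), f)
#' readParams(f)
#' @export
readParams <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "'", call. = FALSE))
  updateParams(nucleusParams(), cfg)
}

#' @rdname readParams
#' @export
writeParams <- function(params, path) {
  stopifnot(is(params, "NucleusParams"))
  cfg <- as.list(params)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format '.", ext, "'", call. = FALSE))
  invisible(path)
}
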