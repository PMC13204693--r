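#' Montage configuration
#'
#' An electrode montage partitioned into left-hemisphere, right-hemisphere and
#' midline (sagittal, z-suffixed) electrode sets.  The midline electrodes are
#' dropped before hemisphere-wise modelling; the left/right lists fix the
#' channel ordering used when hemisphere features are concatenated.
#'
#' @param left,right ordered electrode-name character vectors.
#' @param midline electrode-name character vector (may be empty).
#' @return an object of class `montage_config`.
#' @examples
#' montage_config(left = c("F3", "C3"), right = c("F4", "C4"),
#'                midline = character())
#' @export
montage_config <- function(left, right, midline = character()) {
  m <- structure(list(left = as.character(left),
                      right = as.character(right),
                      midline = as.character(midline)),
                 class = "montage_config")
  all_names <- c(m$left, m$right, m$midline)
  dup <- unique(all_names[duplicated(all_names)])
  if (length(dup))
    stop("electrodes assigned to more than one montage set: ",
         paste(dup, collapse = ", "))
  if (length(m$left) == 0L || length(m$right) == 0L)
    stop("left and right electrode sets must be non-empty")
  m
}

#' @export
print.montage_config <- function(x, ...) {
  cat(sprintf("<montage_config> %d left / %d right / %d midline electrodes\n",
              length(x$left), length(x$right), length(x$midline)))
  invisible(x)
}

#' Load a montage from a YAML or JSON file
#'
#' The file must contain keys `left`, `right` and `midline`, each a list of
#' electrode names.  The three sets must be disjoint.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [montage_config()].
#' @seealso [default_montage()] for the bundled 62-channel montage.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!all(c("left", "right") %in% names(doc)))
    stop("montage file must define `left` and `right` electrode lists")
  montage_config(doc$left, doc$right, doc$midline %||% character())
}

#' The bundled 62-channel montage
#'
#' The default montage for 62-channel recordings (ESI NeuroScan layout used by
#' the SEED-series datasets, 10-20 extended system): 27 left, 27 right and 8
#' midline electrodes (FPZ, FZ, FCZ, CZ, CPZ, PZ, POZ, OZ).  The left/right
#' assignment follows electrode-name parity (odd = left, even = right) in
#' front-to-back order; ships as an editable YAML file under
#' `inst/extdata/montage62.yaml`.
#'
#' @return a [montage_config()] with 27/27/8 electrodes.
#' @examples
#' m <- default_montage()
#' length(m$left)
#' @export
default_montage <- function() {
  m <- load_montage(system.file("extdata", "montage62.yaml",
                                package = "bihada", mustWork = TRUE))
  if (length(m$left) != 27L || length(m$right) != 27L ||
      length(m$midline) != 8L)
    stop("bundled montage must have 27 left / 27 right / 8 midline electrodes")
  m
}
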