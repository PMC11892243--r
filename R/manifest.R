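#' TIL annotation manifest
#'
#' The training annotations behind the TIL detector are described by a
#' small per-dataset manifest (slides, annotated regions and annotated TIL
#' points per source dataset). `annotation_manifest()` loads the manifest
#' shipped with the package; `validate_annotation_manifest()` checks its
#' internal consistency and returns the dataset totals.
#'
#' @param path Manifest CSV path (columns `dataset, wsis, regions, tils`);
#'   defaults to the packaged manifest.
#' @return `annotation_manifest()` returns the manifest data frame.
#' @export
annotation_manifest <- function(path = system.file("extdata",
                                                   "annotation_manifest.csv",
                                                   package = "itilscore")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname annotation_manifest
#' @param manifest A manifest data frame.
#' @return `validate_annotation_manifest()` returns a list with
#'   `per_dataset`, `total_wsis`, `total_regions`, `total_tils`.
#' @export
validate_annotation_manifest <- function(manifest = annotation_manifest()) {
  need <- c("dataset", "wsis", "regions", "tils")
  if (!all(need %in% names(manifest))) {
    itil_error("itil_invalid_argument",
               paste("manifest needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(manifest$dataset)) {
    itil_error("itil_invalid_argument", "duplicate dataset entries in manifest")
  }
  num <- manifest[c("wsis", "regions", "tils")]
  if (any(!vapply(num, is.numeric, logical(1))) || any(unlist(num) < 0) ||
      any(unlist(num) != round(unlist(num)))) {
    itil_error("itil_invalid_argument", "manifest counts must be nonnegative integers")
  }
  if (any(manifest$regions > manifest$tils & manifest$tils > 0)) {
    warning("some datasets report more regions than annotated TILs")
  }
  list(per_dataset = manifest,
       total_wsis = sum(manifest$wsis),
       total_regions = sum(manifest$regions),
       total_tils = sum(manifest$tils))
}
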