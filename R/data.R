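#' Reference per-subject benchmark accuracies
#'
#' Per-subject test accuracies (percent) reported in the BCI literature for
#' the squeeze-and-excitation CNN backbone (SE-CNN) and the full
#' subject-to-subject semantic style transfer pipeline (SSSTN) on the BCI
#' Competition IV-2a (9 subjects, 4 classes) and IV-2b (9 subjects, 2
#' classes) benchmarks. These printed values are inputs for the worked
#' examples of source selection, illiteracy flagging and summary
#' statistics; the package does not recompute them (doing so requires the
#' competition recordings and full-scale training).
#'
#' @param dataset `"iv2a"`, `"iv2b"`, or `NULL` for both.
#' @param method `"SE-CNN"`, `"SSSTN"`, or `NULL` for both.
#' @return A tibble with columns `dataset`, `method`, `subject_id`,
#'   `accuracy`.
#' @export
published_accuracies <- function(dataset = NULL, method = NULL) {
  path <- system.file("extdata", "published_accuracies.csv",
                      package = "ssstn", mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  tab$subject_id <- as.character(tab$subject_id)
  if (!is.null(dataset)) tab <- tab[tab$dataset %in% dataset, ]
  if (!is.null(method)) tab <- tab[tab$method %in% method, ]
  tab
}
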