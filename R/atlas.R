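#' Desikan-Killiany cortical parcellation labels
#'
#' The 68 cortical region labels (34 per hemisphere) of the Desikan-Killiany
#' atlas, the default node set for connectivity matrices and graphs built by
#' this package. The parcellation itself (surface extraction, region
#' assignment) is upstream of this pipeline; the labels survive only as node
#' metadata.
#'
#' @return A character vector of length 68, `"lh.<region>"` then
#'   `"rh.<region>"`.
#' @export
#' @examples
#' length(dk_labels())
dk_labels <- function() {
  regions <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  )
  c(paste0("lh.", regions), paste0("rh.", regions))
}
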