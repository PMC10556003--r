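#' @importFrom methods new validObject is slot setValidity
#' @importFrom stats cor dist prcomp rnorm runif sd quantile setNames
#' @importFrom utils head tail
NULL

## The 31 cortical parcels of the Desikan-Killiany-Tourville (DKT) atlas.
## Ordering is alphabetical and authoritative for every 62-column matrix in
## the package: left hemisphere first, then right, each in this base order.
.dkt_base_regions <- c(
  "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus", "entorhinal",
  "fusiform", "inferiorparietal", "inferiortemporal", "isthmuscingulate",
  "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal",
  "transversetemporal", "insula"
)

#' DKT cortical region roster
#'
#' The fixed roster of 62 cortical regions (31 Desikan-Killiany-Tourville
#' parcels per hemisphere) that keys every thickness feature vector in the
#' package. Column order of any feature matrix follows this roster: all
#' left-hemisphere parcels (prefix `lh_`), then all right-hemisphere parcels
#' (prefix `rh_`).
#'
#' @return Character vector of length 62, unique region names.
#' @examples
#' roster <- dktRegionRoster()
#' length(roster)   # 62
#' grep("superiorfrontal", roster, value = TRUE)
#' @export
dktRegionRoster <- function() {
  c(paste0("lh_", .dkt_base_regions), paste0("rh_", .dkt_base_regions))
}

## Indices (into the roster) of the AD-signature parcels used as the default
## site of converter-specific atrophy: regions reported as most strongly
## loaded on the principal embedding axis in thickness studies of AD.
.signature_base_regions <- c(
  "entorhinal", "supramarginal", "superiorfrontal", "superiortemporal",
  "inferiorparietal", "middletemporal"
)

#' Default AD-signature region indices
#'
#' Indices into [dktRegionRoster()] of the bilateral AD-signature parcels
#' (entorhinal, supramarginal, superior frontal, superior temporal, inferior
#' parietal, middle temporal) where simulated converters accrue extra atrophy.
#'
#' @return Integer vector of length 12.
#' @export
signatureRegionIndices <- function() {
  which(sub("^(lh|rh)_", "", dktRegionRoster()) %in% .signature_base_regions)
}
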