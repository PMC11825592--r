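desikanCortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

subcorticalStructures <- c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala"
)

#' Default network node labels
#'
#' The default 82-region node set: the 34 Desikan-Killiany cortical
#' parcels and 6 supratentorial subcortical grey-matter structures per
#' hemisphere, plus a manually delineated piriform-cortex region of
#' interest per hemisphere (`lh_piriform`, `rh_piriform`).
#'
#' @return Character vector of 82 unique region labels, left hemisphere
#'   first.
#' @examples
#' length(defaultNodeLabels())  # 82
#' @export
defaultNodeLabels <- function() {
  per_hemi <- c(desikanCortical, subcorticalStructures, "piriform")
  c(paste0("lh_", per_hemi), paste0("rh_", per_hemi))
}

# Generic labels for non-default node counts; the two piriform ROIs are
# always present so the default effect node exists at any size n >= 3.
syntheticNodeLabels <- function(n) {
  if (n == 82L) return(defaultNodeLabels())
  stopifnot(n >= 3L)
  c("lh_piriform", "rh_piriform", sprintf("node%03d", seq_len(n - 2L)))
}
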