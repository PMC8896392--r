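#' Closed annotation vocabularies
#'
#' The annotation layer uses three closed vocabularies: 19 merged main
#' subcellular-localization classes (including `"UNKNOWN"`), 15 merged
#' functional process classes, and 5 tissue-expression categories. Interaction
#' records from SignaLink-style tables carry one of six interaction-type
#' categories.
#'
#' @return A character vector of class labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
localization_classes <- function() {
  c("Ribosomes", "Cytosol", "Nucleus", "Cell membrane", "Microfilaments",
    "Mitochondria", "Endoplasmic reticulum", "Extracellular",
    "Cell-ECM junctions", "Golgi apparatus", "Proteasome", "Other vesicles",
    "Cilia, centrosome", "Cell-cell junctions", "Lysosomes", "Peroxisomes",
    "Focal adhesion sites", "Cell cortex", "UNKNOWN")
}

#' @rdname vocabularies
#' @export
process_classes <- function() {
  c("Signaling", "Metabolism",
    "Protein translation, folding, modification and degradation",
    "Transcription", "Unknown", "Cytoskeleton", "Organelles", "Other",
    "Immune system and Inflammation", "Chromatin organization and DNA repair",
    "Neuronal System, synapses, channels", "ECM organization",
    "Cell junction and adhesion", "Developmental", "DNA Replication")
}

#' @rdname vocabularies
#' @export
tissue_classes <- function() {
  c("Not detected", "Detected in single", "Detected in some",
    "Detected in many", "Detected in all")
}

#' @rdname vocabularies
#' @export
signalink_interaction_types <- function() {
  c("Interaction between pathway members",
    "Directed protein-protein interaction",
    "Post-translational modification",
    "Transcriptional regulation",
    "Pathway regulation",
    "Interaction from external databases")
}

# The first four categories describe two proteins in direct physical contact;
# these define interaction-type ("directness") compatibility.
direct_interaction_types <- function() {
  signalink_interaction_types()[1:4]
}

# Directionality labels admitted from SignaLink-style tables.
admitted_directness_labels <- function() {
  c("directed", "predicted as directed")
}
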