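#' AAL-90 cortical and subcortical region labels
#'
#' Region names and short abbreviations for the 90-region Automated
#' Anatomical Labeling parcellation (cerebrum only, interleaved
#' left/right), in standard atlas order. These are the default node
#' labels of every network built by the package.
#'
#' @return `aal90_labels()` returns a character vector of 90 region
#'   names; `aal90_abbrev()` the matching short abbreviations with `.L`
#'   / `.R` hemisphere suffixes.
#' @examples
#' head(aal90_labels())
#' aal90_abbrev()[57:58]  # postcentral gyri
#' @export
aal90_labels <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup",
    "Temporal_Pole_Sup", "Temporal_Mid", "Temporal_Pole_Mid",
    "Temporal_Inf")
  paste0(rep(base, each = 2L), c("_L", "_R"))
}

#' @rdname aal90_labels
#' @export
aal90_abbrev <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc",
    "IFGtriang", "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed",
    "REC", "INS", "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL",
    "CUN", "LING", "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL",
    "SMG", "ANG", "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES",
    "STG", "TPOsup", "MTG", "TPOmid", "ITG")
  paste0(rep(base, each = 2L), c(".L", ".R"))
}

# default planted-effect set: a sensorimotor-analog sextet
# (pre/postcentral gyri + supplementary motor areas)
sensorimotor_regions <- function() c(1L, 2L, 19L, 20L, 57L, 58L)
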