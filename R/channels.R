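#' The 19 scalp electrodes of the international 10-20 system
#'
#' Labels follow the classical nomenclature (T3/T4/T5/T6 rather than
#' T7/T8/P7/P8), ordered front to back, left to right.
#'
#' @return Character vector of 19 electrode labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Electrode to lobe / hemisphere map
#'
#' Standard 10-20 assignment: Fp and F prefixes are frontal, C central,
#' T temporal, P parietal, O occipital; odd indices left, even right,
#' `z` midline. Returned as an editable data frame so the roll-up used by
#' the phenotype study can be customised.
#'
#' @param labels electrode labels; defaults to the full 10-20 montage.
#' @return data.frame with columns `electrode`, `lobe`, `hemisphere`.
#' @export
electrode_anatomy <- function(labels = montage_1020()) {
  lobe <- function(lab) {
    if (grepl("^Fp", lab)) return("frontal")
    switch(substr(lab, 1L, 1L),
           F = "frontal", C = "central", T = "temporal",
           P = "parietal", O = "occipital",
           stop("unknown electrode label: ", lab))
  }
  hemi <- function(lab) {
    suffix <- sub("^[A-Za-z]+", "", lab)
    if (suffix == "z" || suffix == "") return("midline")
    if (as.integer(suffix) %% 2L == 1L) "left" else "right"
  }
  data.frame(electrode  = labels,
             lobe       = vapply(labels, lobe, character(1)),
             hemisphere = vapply(labels, hemi, character(1)),
             row.names  = NULL, stringsAsFactors = FALSE)
}

# Spatial adjacency of the 19-electrode 10-20 montage: each edge joins
# physically neighbouring scalp positions. Used as the electrode gene's
# neighbourhood graph.
electrode_edges <- function() {
  rbind(
    c("Fp1", "Fp2"), c("Fp1", "F3"), c("Fp1", "F7"),
    c("Fp2", "F4"), c("Fp2", "F8"),
    c("F7", "F3"), c("F7", "T3"),
    c("F3", "Fz"), c("F3", "C3"),
    c("Fz", "F4"), c("Fz", "Cz"),
    c("F4", "F8"), c("F4", "C4"),
    c("F8", "T4"),
    c("T3", "C3"), c("T3", "T5"),
    c("C3", "Cz"), c("C3", "P3"),
    c("Cz", "C4"), c("Cz", "Pz"),
    c("C4", "P4"), c("C4", "T4"),
    c("T4", "T6"),
    c("T5", "P3"), c("T5", "O1"),
    c("P3", "Pz"), c("P3", "O1"),
    c("Pz", "P4"),
    c("P4", "T6"), c("P4", "O2"),
    c("T6", "O2"),
    c("O1", "O2"))
}
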