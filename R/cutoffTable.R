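#' Curated clinical cutoff table for CCLE drugs
#'
#' Resistant and sensitive cutoffs on the -log10 molar scale for the 24
#' CCLE screening drugs, as curated from literature Cmax values (source
#' \code{"literature"}) or from the EC50 distribution across cell lines
#' (source \code{"statistical"}) where no reliable clinical concentration
#' exists. Printed to 3 decimals; literature rows satisfy
#' \code{sensitive = resistant + 2*log10(1.5)} up to rounding and the
#' 5.000 floor clamp.
#'
#' @return data.frame with columns \code{drug}, \code{resistant},
#'   \code{sensitive}, \code{source}.
#' @export
clinicalCutoffTable <- function() {
  read.table(system.file("extdata", "clinical_cutoffs.csv",
                         package = "netbc", mustWork = TRUE),
             sep = ",", header = TRUE, stringsAsFactors = FALSE)
}
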