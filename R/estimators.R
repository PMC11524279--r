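# Ct-based estimators for CRISPR cutting efficiency.
#
# All estimators assume perfect amplification efficiency (one cycle = one
# doubling), so every quantity is a power of 2 in a Ct difference. A
# non-amplifying ("undetermined") well is represented by NA, never by a
# number; each estimator states how it treats NA.

#' Broken-DNA abundance from a double Ct difference
#'
#' Computes the delta-delta-Ct for a target-site amplicon measured in
#' edited ("test") plants against untreated ("control") plants, each
#' referenced to an internal single-copy amplicon, and converts it to an
#' abundance of broken target DNA.
#'
#' The double difference is
#' \deqn{\Delta\Delta Ct = Ct(T) - Ct(T_{inter}) - Ct(C) + Ct(C_{inter})}
#' where \eqn{T} denotes the test sample and \eqn{C} the control. Broken DNA
#' does not amplify, so the intact fraction of target DNA in the test sample
#' is \eqn{2^{-\Delta\Delta Ct}}.
#'
#' Two conversions are offered. `mode = "canonical"` (the default) returns
#' the broken fraction \eqn{1 - 2^{-\Delta\Delta Ct}}, which is consistent
#' with the in vitro estimator [in_vitro_efficiency()] and with the
#' benchmark reading that a delta-delta-Ct of 2 corresponds to 75 percent
#' broken DNA. `mode = "literal"` returns \eqn{2^{-\Delta\Delta Ct}} itself,
#' i.e. the surviving intact fraction, for users who want the raw
#' relative-quantification value.
#'
#' @param ct_t Ct of the target-site amplicon in the test sample (cycles).
#' @param ct_t_inter Ct of the internal reference amplicon in the test sample.
#' @param ct_c Ct of the target-site amplicon in the control sample.
#' @param ct_c_inter Ct of the internal reference amplicon in the control
#'   sample.
#' @param mode `"canonical"` for the broken fraction, `"literal"` for the
#'   intact fraction \eqn{2^{-\Delta\Delta Ct}}.
#' @return A numeric value (vectorised over the Ct arguments) with attribute
#'   `"ddct"` carrying the delta-delta-Ct. Values may be negative under
#'   measurement noise; they are reported raw.
#' @seealso [relative_cutting_efficiency()], [in_vitro_efficiency()]
#' @examples
#' broken_dna_abundance(24, 20, 22, 20)                   # 0.75
#' broken_dna_abundance(24, 20, 22, 20, mode = "literal") # 0.25
#' @export
broken_dna_abundance <- function(ct_t, ct_t_inter, ct_c, ct_c_inter,
                                 mode = c("canonical", "literal")) {
  mode <- match.arg(mode)
  .check_ct(ct_t, "target_region (test)")
  .check_ct(ct_t_inter, "genomic_reference (test)")
  .check_ct(ct_c, "target_region (control)")
  .check_ct(ct_c_inter, "genomic_reference (control)")
  ddct <- ct_t - ct_t_inter - ct_c + ct_c_inter
  intact <- 2^(-ddct)
  out <- if (mode == "canonical") 1 - intact else intact
  attr(out, "ddct") <- ddct
  attr(out, "mode") <- mode
  out
}

#' Cas9 transcript abundance from cDNA Ct values
#'
#' Relative Cas9 expression in the edited sample, measured by RT-qPCR
#' against an internal reference transcript:
#' \eqn{2^{-(Ct(Cas) - Ct(inter))}}.
#'
#' An undetermined Cas9 well is an error, not a zero: without detectable
#' Cas9 expression the cutting efficiency is undefined.
#'
#' @param ct_cas Ct of the Cas9 transcript assay (cycles, cDNA template).
#' @param ct_inter Ct of the reference transcript assay in the same sample.
#' @return Positive numeric, vectorised.
#' @examples
#' cas9_abundance(23, 20) # 0.125
#' cas9_abundance(18, 20) # 4
#' @export
cas9_abundance <- function(ct_cas, ct_inter) {
  .check_ct(ct_cas, "cas9_transcript")
  .check_ct(ct_inter, "transcript_reference")
  2^(-(ct_cas - ct_inter))
}

#' Relative cutting efficiency
#'
#' The broken-DNA abundance divided by the Cas9 transcript abundance.
#' Normalising by Cas9 expression makes the quantity comparable across
#' samples that received different amounts of the editing machinery (for
#' example after a treatment that boosts transformation).
#'
#' @param broken Broken-DNA abundance, as returned by
#'   [broken_dna_abundance()] in either mode. Passed through unchanged:
#'   this function never clamps or renormalises.
#' @param cas9 Cas9 abundance from [cas9_abundance()]; must be positive.
#' @return `broken / cas9`, vectorised.
#' @examples
#' relative_cutting_efficiency(0.75, 0.5) # 1.5
#' @export
relative_cutting_efficiency <- function(broken, cas9) {
  if (any(!is.finite(cas9)) || any(cas9 <= 0)) {
    stop("Cas9 abundance must be finite and > 0; efficiency is undefined without Cas9 expression.",
         call. = FALSE)
  }
  as.numeric(broken) / cas9
}

#' In vitro digestion efficiency
#'
#' For a purified amplicon digested by a Cas9/gRNA ribonucleoprotein in
#' vitro, the cut fraction is estimated from two qPCR assays on the
#' digestion products: one amplicon containing the target site (delayed by
#' digestion) and one reference amplicon without it (measuring total DNA):
#' \deqn{eff = 1 - 2^{-(Ct(a) - Ct(inter))}}
#'
#' Noise can push `ct_a` below `ct_inter`, giving a negative raw value; the
#' raw value is returned, with a `[0, 1]`-clamped copy in the `"clamped"`
#' attribute. An undetermined (NA) `ct_a` means the target amplicon never
#' amplified, i.e. digestion was complete: the efficiency is reported as 1
#' with a `"complete_digestion"` flag. An undetermined `ct_inter` is an
#' error (no measure of total DNA).
#'
#' @param ct_a Ct of the amplicon containing the target site.
#' @param ct_inter Ct of the reference amplicon without the target site.
#' @return Numeric, vectorised, with attributes `"clamped"` (values forced
#'   into `[0, 1]`) and `"complete_digestion"` (logical, TRUE where `ct_a`
#'   was undetermined).
#' @examples
#' in_vitro_efficiency(22, 20) # 0.75
#' in_vitro_efficiency(21, 20) # 0.5
#' @export
in_vitro_efficiency <- function(ct_a, ct_inter) {
  .check_ct(ct_inter, "invitro_reference")
  complete <- is.na(ct_a)
  if (any(!complete & (!is.finite(ct_a) | ct_a <= 0))) {
    stop("Ct values must be finite and > 0 (use NA for an undetermined well).",
         call. = FALSE)
  }
  eff <- 1 - 2^(-(ct_a - ct_inter))
  eff[complete] <- 1
  if (any(complete)) {
    warning("undetermined target-amplicon Ct: digestion reported as complete (efficiency 1)",
            call. = FALSE)
  }
  attr(eff, "clamped") <- pmin(pmax(eff, 0), 1)
  attr(eff, "complete_digestion") <- complete
  eff
}

#' Fold-normalise efficiencies to the weakest target
#'
#' Divides every per-target efficiency by the smallest one, so the target
#' with the lowest cutting efficiency reads exactly 1 and every other value
#' is a fold change over it. This is the convention used to compare target
#' sites within one experiment.
#'
#' All values must be strictly positive: noise-driven zero or negative
#' efficiencies must be clamped (and flagged) by the caller before
#' normalising. [tcep_quantify()] does this with its `clamp_floor`.
#'
#' @param efficiencies Named numeric vector of per-target efficiencies.
#' @return Named numeric vector of the same length and order, minimum
#'   mapped to 1. Exact ties for the minimum all map to 1; the first-seen
#'   minimum is recorded in the `"reference"` attribute.
#' @examples
#' normalize_to_lowest(c(a = 0.2, b = 0.6, c = 1.3)) # 1, 3, 6.5
#' @export
normalize_to_lowest <- function(efficiencies) {
  if (length(efficiencies) == 0) {
    stop("no efficiencies to normalise", call. = FALSE)
  }
  if (any(is.na(efficiencies))) {
    stop("efficiencies contain NA; drop or flag unusable targets first", call. = FALSE)
  }
  if (any(efficiencies <= 0)) {
    stop("efficiencies must be strictly positive; clamp or flag non-positive values before fold-normalisation",
         call. = FALSE)
  }
  m <- min(efficiencies)
  out <- efficiencies / m
  ref <- names(efficiencies)[which.min(efficiencies)]
  attr(out, "reference") <- if (is.null(ref)) which.min(efficiencies) else ref
  out
}

# Shared Ct sanity check: finite positive, NA = undetermined well.
.check_ct <- function(ct, what) {
  if (any(is.na(ct))) {
    stop(sprintf("undetermined Ct for %s well", what), call. = FALSE)
  }
  if (any(!is.finite(ct) | ct <= 0)) {
    stop(sprintf("Ct for %s must be finite and > 0", what), call. = FALSE)
  }
  invisible(ct)
}
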