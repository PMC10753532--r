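# Singly charged adduct mass shifts, Da, electron-mass corrected:
# observed m/z = neutral monoisotopic mass + shift.
#   [M+H]+  : +m(H) - m(e)  = +1.00727646
#   [M+Na]+ : +m(Na) - m(e) = +22.98922070
#   [M-H]-  : -m(H) + m(e)  = -1.00727646
#   [M+Cl]- : +m(Cl) + m(e) = +34.96940126
.adductShifts <- c(
    "[M+H]+"  =  1.00727646,
    "[M+Na]+" = 22.98922070,
    "[M-H]-"  = -1.00727646,
    "[M+Cl]-" = 34.96940126
)

.adductPolarity <- c(
    "[M+H]+"  = "positive",
    "[M+Na]+" = "positive",
    "[M-H]-"  = "negative",
    "[M+Cl]-" = "negative"
)

#' Adduct definitions used for neutral-mass hypothesis generation
#'
#' The common singly charged MALDI adducts: \code{[M+H]+} and \code{[M+Na]+}
#' in positive mode, \code{[M-H]-} and \code{[M+Cl]-} in negative mode.
#' Mass shifts are electron-mass corrected so that for a singly charged ion
#' observed m/z = neutral mass + shift.
#'
#' @param polarity "positive", "negative" or "both".
#' @return data.frame with columns \code{label}, \code{polarity},
#'   \code{mass_shift_da}.
#' @examples
#' adductTable("positive")
#' @export
adductTable <- function(polarity = c("both", "positive", "negative")) {
    polarity <- match.arg(polarity)
    out <- data.frame(
        label = names(.adductShifts),
        polarity = unname(.adductPolarity),
        mass_shift_da = unname(.adductShifts),
        stringsAsFactors = FALSE
    )
    if (polarity != "both") out <- out[out$polarity == polarity, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Signed parts-per-million mass error
#'
#' \code{(observed - calculated) / calculated * 1e6}. Vectorized with the
#' usual recycling.
#'
#' @param observed observed mass or m/z, Da.
#' @param calculated reference mass, Da; must be > 0.
#' @return signed ppm error.
#' @examples
#' ppmError(500.0025, 500)  # +5
#' @export
ppmError <- function(observed, calculated) {
    if (any(!is.finite(calculated) | calculated <= 0))
        stop("'calculated' must be a positive finite mass")
    (observed - calculated) / calculated * 1e6
}

#' Neutral-mass hypotheses for a precursor m/z
#'
#' For each adduct of the given polarity, the neutral monoisotopic mass the
#' precursor would have if it carried that adduct:
#' \code{M = precursor_mz - mass_shift}. Hypotheses with non-positive M are
#' dropped. Precursors are assumed singly charged.
#'
#' @param precursor_mz observed precursor m/z, Thomson; must be > 0.
#' @param polarity "positive" or "negative".
#' @return data.frame with columns \code{adduct}, \code{mass_shift_da},
#'   \code{neutral_mass}; zero rows when every hypothesis is non-positive.
#' @examples
#' neutralHypotheses(760.5851, "positive")
#' @export
neutralHypotheses <- function(precursor_mz,
                              polarity = c("positive", "negative")) {
    polarity <- match.arg(polarity)
    if (length(precursor_mz) != 1L || !is.finite(precursor_mz) ||
        precursor_mz <= 0)
        stop("'precursor_mz' must be a positive scalar")
    ad <- adductTable(polarity)
    ad$neutral_mass <- precursor_mz - ad$mass_shift_da
    out <- ad[ad$neutral_mass > 0, , drop = FALSE]
    names(out)[names(out) == "label"] <- "adduct"
    out$polarity <- NULL
    rownames(out) <- NULL
    out
}
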