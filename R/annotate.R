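#' Exact-mass matching of neutral hypotheses against a library
#'
#' Pairs every neutral-mass hypothesis with every library entry whose
#' neutral exact mass lies within \code{tol_ppm} of it. Entries declaring an
#' adduct are only eligible for the matching hypothesis adduct; entries with
#' an unspecified adduct are eligible for all. Several isomers, adducts and
#' collision energies can — and routinely do — match one precursor: the
#' ambiguity is resolved later by fragment-spectrum scoring, not here.
#'
#' @param hypotheses data.frame from \code{\link{neutralHypotheses}}.
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param tol_ppm exact-mass tolerance, ppm (default 5).
#' @return data.frame of candidate matches: \code{entry} (1-based library
#'   row), \code{compound_id}, \code{adduct} (the hypothesis adduct),
#'   \code{neutral_mass_hypothesis}, \code{ppm_error} (hypothesis vs library
#'   exact mass), plus the entry's \code{formula} and \code{provenance}.
#' @export
matchLibrary <- function(hypotheses, lib, tol_ppm = 5) {
    if (tol_ppm <= 0) stop("tol_ppm must be > 0")
    en <- lib@entries
    out <- list()
    for (h in seq_len(nrow(hypotheses))) {
        M <- hypotheses$neutral_mass[h]
        ad <- hypotheses$adduct[h]
        ppm <- ppmError(M, en$exact_mass)
        hit <- abs(ppm) <= tol_ppm &
            (is.na(en$adduct) | en$adduct == ad)
        if (any(hit))
            out[[length(out) + 1L]] <- data.frame(
                entry = which(hit),
                compound_id = en$compound_id[hit],
                adduct = ad,
                neutral_mass_hypothesis = M,
                ppm_error = ppm[hit],
                formula = en$formula[hit],
                provenance = en$provenance[hit],
                stringsAsFactors = FALSE)
    }
    if (length(out) == 0)
        return(data.frame(entry = integer(), compound_id = character(),
                          adduct = character(),
                          neutral_mass_hypothesis = numeric(),
                          ppm_error = numeric(), formula = character(),
                          provenance = character(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Cosine similarity between two centroid MS2 spectra
#'
#' Peaks are paired greedily by nearest m/z: all cross-spectrum pairs within
#' the fragment tolerance are sorted by their m/z distance and assigned in
#' order, each peak used at most once. The score is the normalized dot
#' product \code{sum(paired a*b) / (||a|| ||b||)} over the full intensity
#' vectors, so unpaired peaks dilute the score through the norms. Identical
#' spectra score 1, spectra with no pairable peaks score 0, and the score is
#' invariant to uniform intensity scaling of either spectrum.
#'
#' The fragment tolerance is the wider of a ppm window at the fragment m/z
#' and an absolute floor, accommodating both high-resolution (Orbitrap) and
#' low-resolution (ion trap) MS2 detection.
#'
#' @param a,b two-column \code{(mz, intensity)} matrices, non-empty.
#' @param frag_tol_ppm ppm component of the fragment tolerance (default 5).
#' @param frag_tol_da absolute floor in Da (default 0.01).
#' @param weighted square-root-transform intensities before scoring
#'   (default FALSE: plain cosine on raw intensities).
#' @return cosine similarity in [0, 1].
#' @examples
#' a <- cbind(c(100, 200), c(1, 2))
#' b <- cbind(c(100, 200), c(2, 1))
#' cosineScore(a, b)  # 0.8
#' @export
cosineScore <- function(a, b, frag_tol_ppm = 5, frag_tol_da = 0.01,
                        weighted = FALSE) {
    a <- as.matrix(a); b <- as.matrix(b)
    if (nrow(a) == 0 || nrow(b) == 0)
        stop("cannot score an empty spectrum")
    ia <- a[, 2]; ib <- b[, 2]
    if (weighted) { ia <- sqrt(ia); ib <- sqrt(ib) }
    tol <- function(mz) pmax(mz * frag_tol_ppm * 1e-6, frag_tol_da)
    # candidate pairs within tolerance
    d <- abs(outer(a[, 1], b[, 1], "-"))
    lim <- outer(tol(a[, 1]), tol(b[, 1]), pmax)
    cand <- which(d <= lim, arr.ind = TRUE)
    num <- 0
    if (nrow(cand) > 0) {
        ord <- order(d[cand])
        usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
        for (k in ord) {
            i <- cand[k, 1]; j <- cand[k, 2]
            if (usedA[i] || usedB[j]) next
            usedA[i] <- TRUE; usedB[j] <- TRUE
            num <- num + ia[i] * ib[j]
        }
    }
    den <- sqrt(sum(ia^2)) * sqrt(sum(ib^2))
    if (den == 0) return(0)
    min(num / den, 1)
}

#' Score candidates against an MS2 spectrum and keep the best hit
#'
#' The final stage of the annotation cascade: every candidate match is
#' scored by cosine similarity between the empirical MS2 spectrum and the
#' candidate's library spectrum, and only the highest score is retained.
#' Ties are broken by smaller absolute ppm error, then lexicographic
#' compound id (deterministic output).
#'
#' @param ms2_peaks the empirical MS2 spectrum, \code{(mz, intensity)}.
#' @param candidates data.frame from \code{\link{matchLibrary}}.
#' @param lib the \linkS4class{SpectralLibrary} the candidates refer to.
#' @param frag_tol_ppm,frag_tol_da,weighted see \code{\link{cosineScore}}.
#' @return one-row data.frame (the candidate row plus \code{cosine_score}),
#'   or NULL when there are no candidates.
#' @export
annotateScan <- function(ms2_peaks, candidates, lib, frag_tol_ppm = 5,
                         frag_tol_da = 0.01, weighted = FALSE) {
    if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
    scores <- vapply(seq_len(nrow(candidates)), function(k) {
        cosineScore(ms2_peaks, lib@peaks[[candidates$entry[k]]],
                    frag_tol_ppm = frag_tol_ppm, frag_tol_da = frag_tol_da,
                    weighted = weighted)
    }, numeric(1))
    candidates$cosine_score <- scores
    ord <- order(-candidates$cosine_score, abs(candidates$ppm_error),
                 candidates$compound_id)
    best <- candidates[ord[1], , drop = FALSE]
    rownames(best) <- NULL
    best
}

#' Annotate every QC-valid MS2 scan of a run
#'
#' Runs the full cascade per valid MS2 scan: adduct-resolved neutral-mass
#' hypotheses from the instrument-reported precursor m/z, exact-mass
#' matching against the library at \code{tol_ppm}, cosine scoring of every
#' candidate, best-hit retention. Each record carries the pixel the MS2
#' scan's acquisition time maps to.
#'
#' @param run an \linkS4class{MsiRun}.
#' @param geom a \linkS4class{RasterGeometry}.
#' @param log a \linkS4class{PositionLog}.
#' @param lib a \linkS4class{SpectralLibrary}.
#' @param mode acquisition mode, sets the QC consistency window.
#' @param tol_ppm precursor/exact-mass tolerance, ppm (default 5).
#' @param frag_tol_ppm,frag_tol_da,weighted fragment-pairing parameters,
#'   see \code{\link{cosineScore}}.
#' @param qc optional precomputed result of \code{\link{assessRun}}; when
#'   omitted it is computed here with the same \code{mode} and
#'   \code{tol_ppm}.
#' @return data.frame with one row per annotated MS2 scan (columns of
#'   \code{\link{writeAnnotationTable}}); zero rows when nothing annotates.
#' @export
annotateRun <- function(run, geom, log, lib,
                        mode = c("parallel", "sequential"), tol_ppm = 5,
                        frag_tol_ppm = tol_ppm, frag_tol_da = 0.01,
                        weighted = FALSE, qc = NULL) {
    mode <- match.arg(mode)
    if (length(lib) == 0) stop("spectral library is empty")
    if (is.null(qc)) qc <- assessRun(run, log, mode, tol_ppm)
    si <- run@scanInfo
    valid_idx <- qc$verdicts$scan_index[qc$verdicts$valid]
    out <- list()
    for (idx in valid_idx) {
        i <- which(si$index == idx)
        pmz <- si$precursor_mz[i]
        emp <- run@peaks[[i]]
        if (nrow(emp) == 0) next
        hyp <- neutralHypotheses(pmz, run@polarity)
        cand <- matchLibrary(hyp, lib, tol_ppm)
        best <- annotateScan(emp, cand, lib, frag_tol_ppm = frag_tol_ppm,
                             frag_tol_da = frag_tol_da, weighted = weighted)
        if (is.null(best)) next
        px <- scanToPixel(si$time_s[i], geom, log)
        out[[length(out) + 1L]] <- data.frame(
            scan_index = idx,
            precursor_mz = pmz,
            adduct = best$adduct,
            neutral_mass_hypothesis = best$neutral_mass_hypothesis,
            compound_id = best$compound_id,
            formula = best$formula,
            ppm_error = best$ppm_error,
            cosine_score = best$cosine_score,
            provenance = best$provenance,
            pixel_row = px[1, 1], pixel_col = px[1, 2],
            stringsAsFactors = FALSE)
    }
    if (length(out) == 0)
        return(as.data.frame(setNames(
            list(integer(), numeric(), character(), numeric(), character(),
                 character(), numeric(), numeric(), character(), integer(),
                 integer()),
            .annotationCols)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Per-compound annotation summary
#'
#' Aggregates an annotation table by compound: number of supporting MS2
#' events, best cosine score, and the adducts under which the compound was
#' observed (the per-adduct view behind adduct-resolved ion images).
#'
#' @param records annotation data.frame from \code{\link{annotateRun}}.
#' @return data.frame with columns \code{compound_id}, \code{n_events},
#'   \code{best_score}, \code{adducts} (comma-joined), sorted by descending
#'   event count.
#' @export
compoundSummary <- function(records) {
    if (nrow(records) == 0)
        return(data.frame(compound_id = character(), n_events = integer(),
                          best_score = numeric(), adducts = character(),
                          stringsAsFactors = FALSE))
    sp <- split(records, records$compound_id)
    out <- do.call(rbind, lapply(sp, function(g) data.frame(
        compound_id = g$compound_id[1],
        n_events = nrow(g),
        best_score = max(g$cosine_score),
        adducts = paste(sort(unique(g$adduct)), collapse = ","),
        stringsAsFactors = FALSE)))
    out <- out[order(-out$n_events, out$compound_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
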