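#' @include lei.R
NULL

#' Filter markers by minimum score
#'
#' Retains exactly the markers whose score is greater than or equal to the
#' threshold (the comparison is inclusive), preserving the original row
#' order. Markers with missing scores are dropped.
#'
#' @param table a [ScoredMarkerTable-class].
#' @param threshold finite minimum score. For LEI sensible values lie in
#'   [0, min(3, k) - 1]: up to 1 for two populations, up to 2 for three or
#'   more.
#' @return The filtered [ScoredMarkerTable-class].
#' @export
thresholdFilter <- function(table, threshold) {
    stopifnot(is(table, "ScoredMarkerTable"), is.finite(threshold))
    table[which(!is.na(table@score) & table@score >= threshold)]
}

#' Thin markers by physical distance
#'
#' A proxy for removing linkage-disequilibrium redundancy: on each
#' chromosome, markers are visited in order of descending score (ties:
#' ascending position, then lexicographic id) and a marker is kept only if
#' it lies at least `spacingKb` kilobases from every already-kept marker on
#' the same chromosome. Markers on different chromosomes never conflict.
#' Kept markers are returned in their original table order.
#'
#' @param table a [ScoredMarkerTable-class]; every marker must have a
#'   chromosome and position when `spacingKb > 0`.
#' @param spacingKb minimum pairwise distance in kilobases (1 kb = 1000 bp);
#'   0 disables thinning.
#' @return The thinned [ScoredMarkerTable-class].
#' @export
spacingFilter <- function(table, spacingKb) {
    stopifnot(is(table, "ScoredMarkerTable"), spacingKb >= 0)
    if (spacingKb == 0 || nrow(table@freqs) == 0L) return(table)
    info <- table@info
    bad <- is.na(info$chromosome) | is.na(info$position)
    if (any(bad))
        stop("marker spacing requires chromosome and position for every ",
             "marker; missing for: ",
             paste(utils::head(info$id[bad], 5L), collapse = ", "),
             if (sum(bad) > 5L) ", ..." else "")
    minbp <- spacingKb * 1000
    visit <- order(-table@score, info$position, info$id)
    keep <- logical(length(visit))
    keptPos <- list()
    for (i in visit) {
        chr <- info$chromosome[i]
        pos <- info$position[i]
        prev <- keptPos[[chr]]
        if (is.null(prev) || all(abs(prev - pos) >= minbp)) {
            keep[i] <- TRUE
            keptPos[[chr]] <- c(prev, pos)
        }
    }
    table[which(keep)]
}

#' Build an ancestry-informative marker panel
#'
#' The full panel pipeline: score threshold, then physical-distance
#' thinning, then an optional cap on panel size, returned sorted by
#' descending score (ties: ascending position, then id). Repeating the call
#' with the same settings on its own output returns the same panel.
#'
#' @param table a [ScoredMarkerTable-class].
#' @param threshold minimum score (inclusive); default 0 keeps all
#'   non-missing markers.
#' @param spacingKb minimum marker spacing in kb; default 0 (off).
#' @param topK optional maximum panel size, applied after the other
#'   filters by descending score.
#' @return A [ScoredMarkerTable-class], best marker first.
#' @examples
#' tab <- leiTable(MarkerFrequencyTable(
#'     rbind(rs7289657 = c(0.55, 0.55, 0.55),
#'           rs2294368 = c(0.79, 0.17, 0.99)),
#'     c("CEU", "CHB", "YRI")))
#' markerInfo(buildPanel(tab, threshold = 0.2))$id   # rs2294368 only
#' @export
buildPanel <- function(table, threshold = 0, spacingKb = 0, topK = NULL) {
    out <- thresholdFilter(table, threshold)
    out <- spacingFilter(out, spacingKb)
    ord <- order(-out@score, out@info$position, out@info$id)
    out <- out[ord]
    if (!is.null(topK)) {
        stopifnot(topK >= 0)
        out <- out[seq_len(min(topK, nrow(out@freqs)))]
    }
    out
}
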